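#' Burst model for synthetic multi-unit activity
#'
#' Parameterizes the generative model for one electrode's bursty MUA:
#' burst onsets follow a homogeneous Poisson process (thinned so that a new
#' burst never starts before the previous one has ended), each burst carries
#' `3 + rnbinom(size, mu)` spikes with gamma-distributed intra-burst ISIs,
#' and isolated background spikes form an independent Poisson process that
#' may fall anywhere, including inside bursts.
#'
#' Defaults emulate subplate-like activity in neonatal cortical slices:
#' occurrence about 2 bursts per minute, 8-30 spikes per burst, burst
#' durations of roughly 0.5-0.9 s, intra-burst rates of 15-30 Hz.
#'
#' @param burst_rate burst occurrence, events per minute.
#' @param spikes_nb_size,spikes_nb_mu negative-binomial parameters of the
#'   spikes-per-burst count; the draw is `3 + rnbinom(size, mu)` so every
#'   burst has at least 3 spikes.
#' @param isi_shape,isi_mean_s gamma intra-burst ISI: shape and mean (s).
#'   Draws at or above `isi_max_s` are resampled so a generated burst cannot
#'   be split by the downstream burst detector.
#' @param isi_max_s the burst-breaking ISI threshold the ISIs must stay
#'   under (seconds).
#' @param isolated_rate_hz rate of isolated background spikes (Hz).
#' @param span_s recording span (seconds).
#' @return An object of class `burst_model` (a parameter list).
#' @export
burst_model <- function(burst_rate = 2, spikes_nb_size = 5, spikes_nb_mu = 10,
                        isi_shape = 2, isi_mean_s = 0.05, isi_max_s = 0.3,
                        isolated_rate_hz = 0.05, span_s = 1800) {
  stopifnot(burst_rate >= 0, spikes_nb_size > 0, spikes_nb_mu >= 0,
            isi_shape > 0, isolated_rate_hz >= 0, span_s > 0)
  if (isi_mean_s <= 0) stop("intra-burst ISI mean must be positive")
  if (isi_mean_s >= isi_max_s)
    stop("intra-burst ISI mean must be below the burst-breaking threshold")
  structure(as.list(environment()), class = "burst_model")
}

# Draw one burst's spike times starting at `onset`.
draw_burst <- function(model, onset) {
  n <- 3L + stats::rnbinom(1, size = model$spikes_nb_size, mu = model$spikes_nb_mu)
  isi <- stats::rgamma(n - 1L, shape = model$isi_shape,
                       scale = model$isi_mean_s / model$isi_shape)
  bad <- isi >= model$isi_max_s
  while (any(bad)) {  # resample so the burst survives detection intact
    isi[bad] <- stats::rgamma(sum(bad), shape = model$isi_shape,
                              scale = model$isi_mean_s / model$isi_shape)
    bad <- isi >= model$isi_max_s
  }
  onset + c(0, cumsum(isi))
}

#' Generate one synthetic bursty spike train
#'
#' @param model a [burst_model()].
#' @param seed integer seed; identical seeds give identical trains. `NULL`
#'   uses the current RNG state.
#' @param channel_id,region,layer metadata stored on the result.
#' @return A [spike_train()] with attribute `"ground_truth"`: a list with the
#'   true burst onsets/offsets and logical spike membership `in_burst`.
#' @examples
#' st <- generate_burst_train(burst_model(span_s = 300), seed = 1)
#' st
#' @export
generate_burst_train <- function(model, seed = NULL, channel_id = "ch1",
                                 region = NA_character_, layer = NA_character_) {
  stopifnot(inherits(model, "burst_model"))
  with_seed_or_not(seed, {
    span <- model$span_s
    bursts <- list()
    if (model$burst_rate > 0) {
      rate_s <- model$burst_rate / 60
      t <- stats::rexp(1, rate_s)
      while (t < span) {
        b <- draw_burst(model, t)
        b <- b[b <= span]
        if (length(b) >= 1) bursts[[length(bursts) + 1L]] <- b
        # thinning: next onset after the end of this burst
        t <- max(b, t) + stats::rexp(1, rate_s)
      }
    }
    burst_spikes <- unlist(bursts, use.names = FALSE)
    if (is.null(burst_spikes)) burst_spikes <- numeric()
    n_iso <- stats::rpois(1, model$isolated_rate_hz * span)
    iso <- sort(stats::runif(n_iso, 0, span))
    times <- c(burst_spikes, iso)
    membership <- c(rep(TRUE, length(burst_spikes)), rep(FALSE, length(iso)))
    o <- order(times)
    times <- times[o]
    # exact duplicates are astronomically unlikely but would break sortedness
    keep <- !duplicated(times)
    st <- spike_train(times[keep], t_start = 0, t_stop = span,
                      channel_id = channel_id, region = region, layer = layer)
    attr(st, "ground_truth") <- list(
      burst_onsets = vapply(bursts, min, numeric(1)),
      burst_offsets = vapply(bursts, max, numeric(1)),
      in_burst = membership[o][keep])
    st
  })
}

#' Coupling specification between two synthetic channels
#'
#' Each burst of the source channel triggers, with probability
#' `coupling_prob`, an extra burst in the target channel whose onset lags the
#' source onset by a draw from a gamma lag distribution (positive lag =
#' target follows source).
#'
#' @param source_channel,target_channel channel identifiers.
#' @param coupling_prob probability in \[0, 1\] that a source burst triggers a
#'   target burst.
#' @param lag_mean_s,lag_shape gamma onset-lag distribution: mean (s) and
#'   shape. `lag_shape = Inf` makes the lag deterministic at `lag_mean_s`.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(source_channel, target_channel, coupling_prob,
                          lag_mean_s = 0.15, lag_shape = 9) {
  stopifnot(coupling_prob >= 0, coupling_prob <= 1, lag_mean_s > 0,
            lag_shape > 0)
  structure(list(source_channel = as.character(source_channel),
                 target_channel = as.character(target_channel),
                 coupling_prob = coupling_prob, lag_mean_s = lag_mean_s,
                 lag_shape = lag_shape), class = "coupling_spec")
}

draw_lags <- function(spec, n) {
  if (is.infinite(spec$lag_shape)) rep(spec$lag_mean_s, n)
  else stats::rgamma(n, shape = spec$lag_shape,
                     scale = spec$lag_mean_s / spec$lag_shape)
}

#' Generate an ensemble of coupled spike trains
#'
#' Background activity of every channel is drawn independently from its
#' `burst_model`; then, for each coupling, every burst of the source channel
#' inserts (with probability `coupling_prob`) a burst into the target train
#' at the source onset plus a lag draw. Inserted bursts falling partly
#' outside the recording span are truncated.
#'
#' @param models named list of [burst_model()]s, one per channel; names are
#'   channel ids and must be unique.
#' @param couplings list of [coupling_spec()]s (may be empty).
#' @param seed integer seed; expands to per-channel substreams.
#' @param meta optional data frame with columns `channel_id`, `region`,
#'   `layer` used to label the trains.
#' @return Named list of [spike_train()]s, same names as `models`.
#' @export
generate_coupled_ensemble <- function(models, couplings = list(), seed = NULL,
                                      meta = NULL) {
  ids <- names(models)
  if (is.null(ids) || anyDuplicated(ids))
    stop("`models` must be a named list with unique channel ids")
  for (cp in couplings) {
    if (!cp$source_channel %in% ids || !cp$target_channel %in% ids)
      stop("coupling refers to unknown channel")
  }
  label <- function(id, what) {
    if (is.null(meta)) return(NA_character_)
    i <- match(id, meta$channel_id)
    if (is.na(i)) NA_character_ else meta[[what]][i]
  }
  trains <- list()
  for (id in ids) {
    s <- if (is.null(seed)) NULL else sub_seed(seed, paste0("bg_", id))
    trains[[id]] <- generate_burst_train(models[[id]], seed = s,
                                         channel_id = id,
                                         region = label(id, "region"),
                                         layer = label(id, "layer"))
  }
  k <- 0L
  for (cp in couplings) {
    k <- k + 1L
    src <- trains[[cp$source_channel]]
    tgt <- trains[[cp$target_channel]]
    onsets <- attr(src, "ground_truth")$burst_onsets
    s <- if (is.null(seed)) NULL else sub_seed(seed, paste0("cpl_", k))
    extra <- with_seed_or_not(s, {
      hit <- stats::runif(length(onsets)) < cp$coupling_prob
      lags <- draw_lags(cp, sum(hit))
      spikes <- mapply(function(on, lag) {
        b <- draw_burst(models[[cp$target_channel]], on + lag)
        b[b >= 0 & b <= tgt$t_stop]  # truncate at span
      }, onsets[hit], lags, SIMPLIFY = FALSE)
      spikes
    })
    extra_spk <- unlist(extra, use.names = FALSE)
    if (length(extra_spk)) {
      all_t <- sort(c(tgt$times, extra_spk))
      all_t <- all_t[!duplicated(all_t)]
      gt <- attr(tgt, "ground_truth")
      tgt <- spike_train(all_t, t_start = tgt$t_start, t_stop = tgt$t_stop,
                         channel_id = tgt$channel_id, region = tgt$region,
                         layer = tgt$layer)
      keep <- lengths(extra) > 0
      gt$burst_onsets <- c(gt$burst_onsets, vapply(extra[keep], min, numeric(1)))
      gt$burst_offsets <- c(gt$burst_offsets, vapply(extra[keep], max, numeric(1)))
      gt$in_burst <- NULL  # membership no longer tracked after merging
      attr(tgt, "ground_truth") <- gt
      trains[[cp$target_channel]] <- tgt
    }
  }
  trains
}
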