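#' Detect burst discharges in a spike train
#'
#' A burst is a maximal run of at least `min_spikes` successive spikes whose
#' inter-spike intervals are each at or below `isi_max` (the boundary ISI,
#' exactly `isi_max`, is inside the burst). Detected bursts are disjoint,
#' ordered, and not extendable by any adjacent spike.
#'
#' @param train a [spike_train()].
#' @param isi_max maximum intra-burst inter-spike interval (s), default 0.3.
#' @param min_spikes minimum number of spikes per burst, default 3.
#' @return A data frame of class `burst_set`, one row per burst, with columns
#'   `onset`, `offset`, `n_spikes`, `duration`, `intra_freq` (Hz, defined as
#'   `(n_spikes - 1) / duration`), `first_idx`, `last_idx` (spike indices
#'   into `train$times`).
#' @examples
#' st <- spike_train(c(0, 0.1, 0.2, 1.5, 3, 3.1, 3.25, 3.4), t_stop = 5)
#' detect_bursts(st)
#' @export
detect_bursts <- function(train, isi_max = 0.3, min_spikes = 3L) {
  stopifnot(inherits(train, "spike_train"), isi_max > 0, min_spikes >= 2)
  t <- train$times
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      n_spikes = integer(), duration = numeric(),
                      intra_freq = numeric(), first_idx = integer(),
                      last_idx = integer())
  class(empty) <- c("burst_set", "data.frame")
  if (length(t) < min_spikes) return(empty)
  linked <- diff(t) <= isi_max            # spike i linked to spike i+1
  r <- rle(linked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= (min_spikes - 1L)
  if (!any(keep)) return(empty)
  first_idx <- starts[keep]               # runs of linked gaps -> spike runs
  last_idx <- ends[keep] + 1L
  onset <- t[first_idx]
  offset <- t[last_idx]
  n <- last_idx - first_idx + 1L
  out <- data.frame(onset = onset, offset = offset, n_spikes = n,
                    duration = offset - onset,
                    intra_freq = (n - 1) / (offset - onset),
                    first_idx = first_idx, last_idx = last_idx)
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Summary statistics of detected bursts
#'
#' @param bursts a `burst_set` from [detect_bursts()].
#' @param span_s recording span in seconds (must be positive).
#' @return A one-row data frame: `n_bursts`, `occurrence_per_min`,
#'   `mean_duration_ms`, `mean_n_spikes`, `mean_intra_freq_hz`. Means are
#'   `NA` when there are no bursts; occurrence is then 0.
#' @export
burst_stats <- function(bursts, span_s) {
  stopifnot(span_s > 0)
  n <- nrow(bursts)
  data.frame(
    n_bursts = n,
    occurrence_per_min = n / (span_s / 60),
    mean_duration_ms = if (n) mean(bursts$duration) * 1000 else NA_real_,
    mean_n_spikes = if (n) mean(bursts$n_spikes) else NA_real_,
    mean_intra_freq_hz = if (n) mean(bursts$intra_freq) else NA_real_)
}

#' Match coincident bursts between two electrodes
#'
#' Two bursts coincide when at least one spike of either burst falls within
#' the bursting interval of the other (a symmetric rule; because a burst's
#' interval is spanned by its own spikes, this is equivalent to overlap of
#' the two burst intervals). Each burst joins at most one pair: matching is
#' greedy in time order, the earliest-onset available partner winning.
#'
#' @param bursts_a,bursts_b `burst_set`s from the two electrodes.
#' @return A data frame with one row per coincident pair: `idx_a`, `idx_b`
#'   (row numbers into the inputs), `onset_a`, `onset_b`.
#' @export
coincident_bursts <- function(bursts_a, bursts_b) {
  na <- nrow(bursts_a); nb <- nrow(bursts_b)
  ia <- 1L; ib <- 1L
  idx_a <- integer(); idx_b <- integer()
  while (ia <= na && ib <= nb) {
    if (bursts_a$onset[ia] <= bursts_b$offset[ib] &&
        bursts_b$onset[ib] <= bursts_a$offset[ia]) {
      idx_a <- c(idx_a, ia); idx_b <- c(idx_b, ib)
      ia <- ia + 1L; ib <- ib + 1L
    } else if (bursts_a$offset[ia] < bursts_b$offset[ib]) {
      ia <- ia + 1L
    } else {
      ib <- ib + 1L
    }
  }
  data.frame(idx_a = idx_a, idx_b = idx_b,
             onset_a = bursts_a$onset[idx_a], onset_b = bursts_b$onset[idx_b])
}

#' Coincidence ratio of an electrode pair
#'
#' The number of coincident burst pairs divided by the total number of
#' bursts in the electrode with the lower burst activity.
#'
#' @param pairs result of [coincident_bursts()].
#' @param n_bursts_a,n_bursts_b burst counts of the two electrodes.
#' @return Scalar in \[0, 1\]; `NA` if both electrodes have zero bursts.
#' @export
coincidence_ratio <- function(pairs, n_bursts_a, n_bursts_b) {
  denom <- min(n_bursts_a, n_bursts_b)
  if (denom == 0) return(NA_real_)
  nrow(pairs) / denom
}

#' Onset lead/lag ratios of coincident bursts
#'
#' Compares the first-spike times of each coincident pair. A leads when its
#' onset is strictly earlier; exact onset ties form their own category.
#'
#' @param pairs result of [coincident_bursts()].
#' @return Named numeric vector `c(lead_a, lead_b, tie)`, summing to 1; all
#'   `NA` when there are no pairs.
#' @export
lead_lag <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0) return(c(lead_a = NA_real_, lead_b = NA_real_, tie = NA_real_))
  c(lead_a = sum(pairs$onset_a < pairs$onset_b) / n,
    lead_b = sum(pairs$onset_b < pairs$onset_a) / n,
    tie = sum(pairs$onset_a == pairs$onset_b) / n)
}

#' Spike-jitter surrogate trains
#'
#' Each surrogate displaces every spike independently by a uniform draw on
#' `[-half_width, +half_width]` (750 ms by default, the approximate duration
#' of a burst), clips to the recording span, and re-sorts. Spike count is
#' preserved exactly.
#'
#' @param train a [spike_train()].
#' @param half_width jitter half-width (s), default 0.75.
#' @param n number of surrogates, default 1000.
#' @param seed integer seed.
#' @return List of `n` [spike_train()]s.
#' @export
jitter_surrogates <- function(train, half_width = 0.75, n = 1000L, seed = NULL) {
  stopifnot(inherits(train, "spike_train"), half_width > 0, n >= 1)
  with_seed_or_not(seed, {
    lapply(seq_len(n), function(i) {
      t <- train$times + stats::runif(n_spikes(train), -half_width, half_width)
      t <- pmin(pmax(t, train$t_start), train$t_stop)
      spike_train(sort(t), t_start = train$t_start, t_stop = train$t_stop,
                  channel_id = train$channel_id, region = train$region,
                  layer = train$layer)
    })
  })
}

# Empirical percentile threshold (inverse-ECDF convention, quantile type 1).
empirical_percentile <- function(x, percentile) {
  stats::quantile(x, percentile / 100, type = 1, names = FALSE, na.rm = TRUE)
}

#' Full coincidence analysis of one electrode pair with a surrogate null
#'
#' Detects bursts on both trains, matches coincident bursts, computes the
#' coincidence ratio and onset lead/lag ratios, then builds a surrogate null
#' by spike-jittering the train with the lower burst count (the ratio's
#' denominator train), re-detecting bursts and re-matching for each
#' surrogate. Surrogate ratios are normalized by the observed pair's
#' denominator (the lower of the two observed burst counts), not by the
#' surrogate's own recomputed burst count: jitter at burst scale splits
#' bursts and inflates their number, and letting the denominator drift with
#' it would shift the null to a different scale than the observed ratio and
#' miscalibrate the test. The pair is flagged significant when the observed
#' ratio strictly exceeds the empirical `percentile`-th percentile of the
#' surrogate ratios.
#'
#' @param train_a,train_b [spike_train()]s covering the same recording span.
#' @param isi_max,min_spikes burst-detection parameters, see [detect_bursts()].
#' @param jitter_s surrogate jitter half-width (s), default 0.75.
#' @param n_surrogates number of surrogate trains, default 1000.
#' @param percentile significance percentile of the surrogate null, default 99.
#' @param seed integer seed for the surrogate jitter.
#' @param jitter_which which train to jitter: `"lower"` (fewer bursts,
#'   default), `"a"` or `"b"`.
#' @return An object of class `pair_coincidence`: list with `channel_a`,
#'   `channel_b`, `n_bursts_a`, `n_bursts_b`, `n_coincident`,
#'   `coincidence_ratio`, `lead_a`, `lead_b`, `tie`, `surrogate_ratios`,
#'   `surrogate_lead_a`, `threshold`, `significant`.
#' @export
pair_coincidence <- function(train_a, train_b, isi_max = 0.3, min_spikes = 3L,
                             jitter_s = 0.75, n_surrogates = 1000L,
                             percentile = 99, seed = NULL,
                             jitter_which = c("lower", "a", "b")) {
  jitter_which <- match.arg(jitter_which)
  ba <- detect_bursts(train_a, isi_max, min_spikes)
  bb <- detect_bursts(train_b, isi_max, min_spikes)
  pairs <- coincident_bursts(ba, bb)
  ratio <- coincidence_ratio(pairs, nrow(ba), nrow(bb))
  ll <- lead_lag(pairs)
  jit_a <- switch(jitter_which, lower = nrow(ba) <= nrow(bb), a = TRUE,
                  b = FALSE)
  jit_train <- if (jit_a) train_a else train_b
  fixed_bursts <- if (jit_a) bb else ba
  surr <- jitter_surrogates(jit_train, half_width = jitter_s,
                            n = n_surrogates, seed = seed)
  denom_obs <- min(nrow(ba), nrow(bb))
  surr_stats <- vapply(surr, function(st) {
    sb <- detect_bursts(st, isi_max, min_spikes)
    if (jit_a) {
      sp <- coincident_bursts(sb, fixed_bursts)
    } else {
      sp <- coincident_bursts(fixed_bursts, sb)
    }
    r <- if (denom_obs > 0) nrow(sp) / denom_obs else NA_real_
    c(r, lead_lag(sp)[["lead_a"]])
  }, numeric(2))
  thr <- empirical_percentile(surr_stats[1, ], percentile)
  structure(list(
    channel_a = train_a$channel_id, channel_b = train_b$channel_id,
    n_bursts_a = nrow(ba), n_bursts_b = nrow(bb), n_coincident = nrow(pairs),
    coincidence_ratio = ratio, lead_a = ll[["lead_a"]],
    lead_b = ll[["lead_b"]], tie = ll[["tie"]],
    surrogate_ratios = surr_stats[1, ], surrogate_lead_a = surr_stats[2, ],
    threshold = thr,
    significant = if (is.na(ratio)) NA else ratio > thr),
    class = "pair_coincidence")
}

#' @rdname pair_coincidence
#' @param x a `pair_coincidence`.
#' @param ... ignored.
#' @export
print.pair_coincidence <- function(x, ...) {
  cat(sprintf(
    "<pair_coincidence> %s vs %s: ratio %.3f (n = %d / bursts %d, %d)\n",
    x$channel_a, x$channel_b, x$coincidence_ratio, x$n_coincident,
    x$n_bursts_a, x$n_bursts_b))
  cat(sprintf("  lead A %.2f  lead B %.2f  tie %.2f | null p99 = %.3f -> %s\n",
              x$lead_a, x$lead_b, x$tie, x$threshold,
              if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' Significance of an observed coincidence ratio against surrogate ratios
#'
#' @param observed_ratio observed coincidence ratio.
#' @param surrogate_ratios numeric vector of surrogate coincidence ratios
#'   (at least 100).
#' @param percentile percentile of the null, default 99.
#' @return List with `threshold` (empirical percentile of the null) and
#'   `significant` (`TRUE` iff observed strictly exceeds it; `NA` when the
#'   observed ratio is undefined).
#' @export
coincidence_significance <- function(observed_ratio, surrogate_ratios,
                                     percentile = 99) {
  if (length(surrogate_ratios) < 100)
    stop("need at least 100 surrogate ratios")
  thr <- empirical_percentile(surrogate_ratios, percentile)
  list(threshold = thr,
       significant = if (is.na(observed_ratio)) NA else observed_ratio > thr)
}
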