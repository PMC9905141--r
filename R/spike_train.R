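#' Spike train container
#'
#' A `spike_train` holds the sorted spike times of one electrode together
#' with its channel metadata and the recording span. Times are in seconds.
#'
#' @param times numeric vector of spike times (seconds); sorted internally.
#' @param t_start,t_stop recording span (seconds); spikes must lie within.
#' @param channel_id character scalar identifying the electrode.
#' @param region cortical area label, typically one of `"S1Bf"`, `"M1"`, `"S2"`.
#' @param layer layer label, typically `"SP"` or `"L5/6"`.
#'
#' @return An object of class `spike_train`: a list with elements `times`,
#'   `t_start`, `t_stop`, `channel_id`, `region`, `layer`.
#' @examples
#' st <- spike_train(c(0.1, 0.4, 2.0), t_start = 0, t_stop = 10)
#' n_spikes(st)
#' @export
spike_train <- function(times, t_start = 0, t_stop = max(times, t_start),
                        channel_id = "ch1", region = NA_character_,
                        layer = NA_character_) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  times <- sort(times)
  stopifnot(is.numeric(t_start), is.numeric(t_stop), t_stop >= t_start)
  if (length(times) && (times[1] < t_start || times[length(times)] > t_stop))
    stop("spike times outside [t_start, t_stop]")
  structure(
    list(times = times, t_start = as.numeric(t_start),
         t_stop = as.numeric(t_stop), channel_id = as.character(channel_id),
         region = as.character(region), layer = as.character(layer)),
    class = "spike_train")
}

#' @rdname spike_train
#' @param x a `spike_train`.
#' @export
n_spikes <- function(x) length(x$times)

#' @rdname spike_train
#' @export
span_s <- function(x) x$t_stop - x$t_start

#' @param ... ignored.
#' @rdname spike_train
#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s [%s %s]: %d spikes over %.1f s\n",
              x$channel_id, x$region, x$layer, n_spikes(x), span_s(x)))
  invisible(x)
}

#' Read and write spike-train tables
#'
#' Spike tables are CSV files with mandatory header
#' `channel_id,region,layer,time_s`, one row per spike, times in seconds.
#'
#' @param path file path.
#' @param t_start,t_stop recording span applied to every train; when `NULL`
#'   the span is taken as `[0, max time]`.
#' @return `read_spike_csv()` returns a named list of `spike_train` objects
#'   (one per `channel_id`); `write_spike_csv()` returns `path` invisibly.
#' @export
read_spike_csv <- function(path, t_start = NULL, t_stop = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "region", "layer", "time_s")
  if (!all(need %in% names(df)))
    stop("spike CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_stop)) t_stop <- max(df$time_s, t_start)
  out <- lapply(split(df, df$channel_id), function(d) {
    spike_train(d$time_s, t_start = t_start, t_stop = t_stop,
                channel_id = d$channel_id[1], region = d$region[1],
                layer = d$layer[1])
  })
  out[order(names(out))]
}

#' @param trains a `spike_train` or list of them.
#' @rdname read_spike_csv
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  rows <- lapply(trains, function(st) {
    if (!n_spikes(st)) return(NULL)
    data.frame(channel_id = st$channel_id, region = st$region,
               layer = st$layer, time_s = st$times)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(channel_id = character(), region = character(),
                     layer = character(), time_s = numeric())
  df$time_s <- sprintf("%.6f", df$time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream label.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
# A NULL seed uses (and advances) the current RNG state.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
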