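#' Raw extracellular trace
#'
#' @param samples numeric voltage samples (any consistent unit).
#' @param sampling_rate sampling rate in Hz (20 kHz for the recordings this
#'   pipeline targets).
#' @param channel_id,region,layer channel metadata.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, sampling_rate, channel_id = "ch1",
                      region = NA_character_, layer = NA_character_) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 channel_id = channel_id, region = as.character(region),
                 layer = as.character(layer)), class = "raw_trace")
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase). MUA extraction uses the 200-5,000 Hz band.
#'
#' @param trace a [raw_trace()].
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @return A filtered [raw_trace()] of the same length and sampling rate.
#' @export
bandpass <- function(trace, low = 200, high = 5000) {
  stopifnot(inherits(trace, "raw_trace"))
  nyq <- trace$sampling_rate / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  out <- trace
  out$samples <- as.numeric(signal::filtfilt(bf, trace$samples))
  out
}

#' Baseline noise estimate from a spike-free interval
#'
#' Sample standard deviation of the (filtered) trace over a baseline
#' interval. If the interval's excess kurtosis is far above Gaussian
#' (kurtosis > 5) the interval likely contains spikes and a warning is
#' issued.
#'
#' @param trace a [raw_trace()] (normally band-passed first).
#' @param baseline_interval `c(t0, t1)` in seconds; must lie within the
#'   trace and be longer than 100 ms.
#' @return Scalar standard deviation.
#' @export
noise_sd <- function(trace, baseline_interval) {
  stopifnot(inherits(trace, "raw_trace"), length(baseline_interval) == 2)
  fs <- trace$sampling_rate
  t0 <- baseline_interval[1]; t1 <- baseline_interval[2]
  if (t1 <= t0) stop("empty baseline interval")
  if (t1 - t0 <= 0.1) stop("baseline interval must be longer than 100 ms")
  n <- length(trace$samples)
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(n, floor(t1 * fs))
  if (i0 >= i1) stop("baseline interval outside the trace")
  x <- trace$samples[i0:i1]
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 > 0) {
    kurt <- mean((x - m)^4) / s2^2
    if (kurt > 5)
      warning("baseline interval has heavy tails (kurtosis ",
              round(kurt, 1), "); it may contain spikes")
  }
  stats::sd(x)
}

#' Threshold-crossing spike detection
#'
#' Marks a spike at each negative-going crossing of `-k * sd` (extracellular
#' spikes are predominantly negative; set `polarity = "positive"` to flip).
#' The spike time is the first sample beyond threshold; subsequent crossings
#' within `dead_time` are suppressed.
#'
#' @param trace a band-passed [raw_trace()].
#' @param sd baseline standard deviation from [noise_sd()].
#' @param k threshold multiplier, default 5.
#' @param dead_time refractory suppression after a detection (s), default
#'   0.001.
#' @param polarity `"negative"` (default) or `"positive"` threshold.
#' @return A [spike_train()] spanning the trace duration.
#' @export
detect_spikes <- function(trace, sd, k = 5, dead_time = 0.001,
                          polarity = c("negative", "positive")) {
  stopifnot(inherits(trace, "raw_trace"), sd > 0, k > 0, dead_time >= 0)
  polarity <- match.arg(polarity)
  x <- trace$samples
  if (polarity == "positive") x <- -x
  thr <- -k * sd
  below <- x < thr
  crossing <- which(below & !c(FALSE, below[-length(below)]))
  if (length(crossing) > 1 && dead_time > 0) {
    dead_n <- dead_time * trace$sampling_rate
    keep <- logical(length(crossing))
    last <- -Inf
    for (i in seq_along(crossing)) {
      if (crossing[i] - last > dead_n) {
        keep[i] <- TRUE
        last <- crossing[i]
      }
    }
    crossing <- crossing[keep]
  }
  spike_train((crossing - 1) / trace$sampling_rate, t_start = 0,
              t_stop = length(x) / trace$sampling_rate,
              channel_id = trace$channel_id, region = trace$region,
              layer = trace$layer)
}
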