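# Independent oracles and small fixture builders used across the suite.

# Exhaustive maximal-run scan: walks the train spike by spike, growing a run
# while consecutive ISIs stay within isi_max, and emits the run if it holds
# at least min_spikes spikes. Deliberately a different algorithm from the
# package's vectorized run detection.
oracle_bursts <- function(times, isi_max = 0.3, min_spikes = 3) {
  n <- length(times)
  out <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) <= isi_max) j <- j + 1L
    if (j - i + 1L >= min_spikes)
      out <- rbind(out, c(first = i, last = j))
    i <- j + 1L
  }
  if (is.null(out))
    data.frame(first = integer(), last = integer())
  else as.data.frame(out)
}

# Homogeneous Poisson spike train.
poisson_train <- function(rate_hz, span_s, id = "p", seed = NULL,
                          region = NA, layer = NA) {
  gen <- function() {
    n <- stats::rpois(1, rate_hz * span_s)
    spike_train(sort(stats::runif(n, 0, span_s)), 0, span_s, id,
                region = region, layer = layer)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Exact two-sided signed-rank p-value by exhaustive enumeration of all 2^n
# sign patterns (for small n, no ties, no zeros).
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !any(duplicated(abs(d))))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% rk
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Planar fixture surfaces z = z0 over a lateral grid.
flat_surface <- function(z0, extent = 1000, n = 11) {
  g <- expand.grid(x = seq(0, extent, length.out = n),
                   y = seq(0, extent, length.out = n))
  fit_surface(data.frame(x = g$x, y = g$y, z = z0))
}
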