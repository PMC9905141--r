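#' Spike cross-correlogram between a reference and a target train
#'
#' Histograms all target-minus-reference spike-time differences with
#' `|difference| <= window` into bins of `bin_width`, centred on zero lag.
#' Positive lag means the target spike follows the reference spike. For a
#' train correlated against itself the zero-lag self-pairs are included
#' (autocorrelation convention); across distinct channels no self-pairs
#' arise.
#'
#' @param reference,target [spike_train()]s.
#' @param bin_width bin width (s), default 0.001.
#' @param window half-width of the lag range (s), default 0.05; the lag axis
#'   covers `[-window, +window]`.
#' @return An object of class `ccg`: list with `breaks` (bin edges, s),
#'   `lag` (bin centres, s), `counts`, `bin_width`, `window`,
#'   `reference_id`, `target_id`.
#' @export
compute_ccg <- function(reference, target, bin_width = 0.001, window = 0.05) {
  stopifnot(bin_width > 0, window >= bin_width)
  nb <- ceiling(window / bin_width - 0.5)
  breaks <- (seq_len(2 * nb + 2) - nb - 1.5) * bin_width  # zero-centred bins
  d <- pair_differences(reference$times, target$times, max(abs(breaks)))
  counts <- if (length(d)) {
    tabulate(findInterval(d, breaks, left.open = TRUE, rightmost.closed = TRUE),
             nbins = length(breaks) - 1L)
  } else integer(length(breaks) - 1L)
  structure(list(breaks = breaks, lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, bin_width = bin_width, window = window,
                 reference_id = reference$channel_id,
                 target_id = target$channel_id), class = "ccg")
}

# All target - reference differences with |d| <= window, both inputs sorted.
pair_differences <- function(ref, tgt, window) {
  if (!length(ref) || !length(tgt)) return(numeric())
  lo <- findInterval(ref - window, tgt, left.open = TRUE)      # exclusive low
  hi <- findInterval(ref + window, tgt)                        # inclusive high
  cnt <- hi - lo
  pos <- cnt > 0
  if (!any(pos)) return(numeric())
  tgt[sequence(cnt[pos], from = lo[pos] + 1L)] -
    rep(ref[pos], cnt[pos])
}

#' @rdname compute_ccg
#' @param x a `ccg`.
#' @param ... ignored.
#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> %s -> %s: %d bins of %.1f ms, %d pairs in +/-%.0f ms\n",
              x$reference_id, x$target_id, length(x$counts),
              x$bin_width * 1000, sum(x$counts), x$window * 1000))
  invisible(x)
}

# Kernel-smoothed joint-ISI sampling weights for dithering spike i along the
# anti-diagonal l + r = const. Precomputed once per train: a 2D histogram of
# the empirical (left ISI, right ISI) pairs blurred with a separable
# Gaussian kernel; weights for candidate shifts are looked up on this grid.
jisi_density_grid <- function(l, r, bandwidth, grid_step) {
  m_max <- max(c(l, r)) + 4 * bandwidth
  nb <- max(8L, ceiling(m_max / grid_step))
  edges <- seq(0, nb * grid_step, by = grid_step)
  il <- pmin(findInterval(l, edges, all.inside = TRUE), nb)
  ir <- pmin(findInterval(r, edges, all.inside = TRUE), nb)
  h <- matrix(0, nb, nb)
  for (k in seq_along(il)) h[il[k], ir[k]] <- h[il[k], ir[k]] + 1
  half <- max(1L, ceiling(3 * bandwidth / grid_step))
  kx <- stats::dnorm(seq(-half, half) * grid_step, sd = bandwidth)
  kx <- kx / sum(kx)
  conv1 <- function(x)  # zero-padded centred 1-D convolution
    as.numeric(stats::filter(c(numeric(half), x, numeric(half)), kx,
                             sides = 2))[(half + 1):(half + length(x))]
  h <- apply(h, 2, conv1)      # blur columns
  h <- t(apply(h, 1, conv1))   # blur rows
  list(density = h, step = grid_step, nb = nb)
}

jisi_lookup <- function(grid, l, r) {
  il <- pmin(pmax(ceiling(l / grid$step), 1L), grid$nb)
  ir <- pmin(pmax(ceiling(r / grid$step), 1L), grid$nb)
  grid$density[cbind(il, ir)]
}

#' Joint-ISI dithering surrogate trains
#'
#' Builds rate-preserving surrogates that destroy fine spike timing. Each
#' surrogate displaces every interior spike within the open interval spanned
#' by its two neighbours in the original train, so that the sum of its two
#' adjacent inter-spike intervals is conserved exactly (the move stays on
#' the anti-diagonal `l + r = const` of the joint-ISI plane). The new
#' position is drawn with probability proportional to the kernel-smoothed
#' empirical joint-ISI density evaluated along that anti-diagonal,
#' restricted to displacements of at most `dither_cap`; the displaced train
#' is then re-sorted (moves are bounded, so only near neighbours can ever
#' swap). First and last spikes never move and spike count is always
#' preserved.
#'
#' With fewer than 50 ISI pairs the empirical density is too sparse to
#' smooth and sampling falls back to uniform on the capped anti-diagonal
#' segment. Trains with fewer than 3 spikes are returned unchanged.
#'
#' @param train a [spike_train()].
#' @param n number of surrogates, default 1000.
#' @param dither_cap maximum displacement of a spike (s), default 0.025.
#' @param smoothing Gaussian kernel bandwidth for the joint-ISI density (s),
#'   default 0.005.
#' @param seed integer seed.
#' @return List of `n` [spike_train()]s.
#' @export
jisi_dither <- function(train, n = 1000L, dither_cap = 0.025,
                        smoothing = 0.005, seed = NULL) {
  stopifnot(inherits(train, "spike_train"), n >= 1, dither_cap > 0,
            smoothing > 0)
  t <- train$times
  ns <- length(t)
  mk <- function(times) spike_train(times, t_start = train$t_start,
                                    t_stop = train$t_stop,
                                    channel_id = train$channel_id,
                                    region = train$region, layer = train$layer)
  if (ns < 3) return(replicate(n, mk(t), simplify = FALSE))
  isi <- diff(t)
  l <- isi[-length(isi)]           # left ISI of interior spike i = 2..ns-1
  r <- isi[-1]                     # right ISI
  interior <- 2:(ns - 1)
  n_cand <- 41L                    # candidate shifts along the anti-diagonal
  use_density <- length(l) >= 50
  grid <- if (use_density)
    jisi_density_grid(l, r, bandwidth = smoothing,
                      grid_step = max(smoothing / 2, 1e-4))
  # Per interior spike: candidate shifts (bounded by cap and by neighbours)
  # and cumulative sampling weights. All fixed across surrogates because
  # dithered spikes keep their original neighbours.
  lo <- pmax(-l + 1e-9, -dither_cap)
  hi <- pmin(r - 1e-9, dither_cap)
  shift_mat <- matrix(0, length(interior), n_cand)
  cum_mat <- matrix(0, length(interior), n_cand)
  for (j in seq_along(interior)) {
    if (hi[j] <= lo[j]) { cum_mat[j, ] <- seq_len(n_cand); next }
    s <- seq(lo[j], hi[j], length.out = n_cand)
    shift_mat[j, ] <- s
    w <- if (use_density) jisi_lookup(grid, l[j] + s, r[j] - s) else rep(1, n_cand)
    if (!any(w > 0)) w <- rep(1, n_cand)
    cum_mat[j, ] <- cumsum(w)
  }
  tot <- cum_mat[, n_cand]
  n_int <- length(interior)
  with_seed_or_not(seed, {
    lapply(seq_len(n), function(k) {
      u <- stats::runif(n_int) * tot
      pick <- pmin(rowSums(cum_mat < u) + 1L, n_cand)
      t2 <- t
      t2[interior] <- t[interior] + shift_mat[cbind(seq_len(n_int), pick)]
      mk(sort(t2))
    })
  })
}

#' Per-bin CCG significance against dithered surrogates
#'
#' The per-bin threshold is the empirical `percentile`-th percentile of the
#' surrogate CCG counts; a bin is significant when the observed count
#' strictly exceeds its threshold. The summary additionally tests whether
#' significant bins cluster inside the monosynaptic analysis window
#' (5-15 ms by default) by comparing the fraction of significant bins
#' inside the window against the binomial expectation from the window's
#' share of bins.
#'
#' @param observed a `ccg` from [compute_ccg()].
#' @param surrogates list of `ccg`s computed with identical binning (built
#'   by dithering the target train, reference fixed); at least 100.
#' @param percentile null percentile, default 99.
#' @param analysis_window two positive lags (s) bounding the monosynaptic
#'   window, default `c(0.005, 0.015)`.
#' @return List with `lag` (bin centres), `threshold`, `significant`
#'   (logical mask), `n_significant`, `in_window` (logical: bin centre in
#'   the analysis window), `n_sig_in_window`, `cluster_p` (binomial p-value
#'   of the in-window concentration of significant bins; `NA` when no bin
#'   is significant).
#' @export
ccg_significance <- function(observed, surrogates, percentile = 99,
                             analysis_window = c(0.005, 0.015)) {
  if (length(surrogates) < 100) stop("need at least 100 surrogate CCGs")
  same <- vapply(surrogates, function(s)
    length(s$counts) == length(observed$counts) &&
      isTRUE(all.equal(s$breaks, observed$breaks)), logical(1))
  if (!all(same)) stop("surrogate CCGs must use identical binning")
  mat <- vapply(surrogates, function(s) as.numeric(s$counts),
                numeric(length(observed$counts)))
  thr <- apply(mat, 1, empirical_percentile, percentile = percentile)
  sig <- observed$counts > thr
  in_win <- observed$lag >= analysis_window[1] & observed$lag <= analysis_window[2]
  n_sig <- sum(sig)
  p_win <- mean(in_win)
  cluster_p <- if (n_sig > 0)
    stats::binom.test(sum(sig & in_win), n_sig, p_win,
                      alternative = "greater")$p.value
  else NA_real_
  list(lag = observed$lag, threshold = thr, significant = sig,
       n_significant = n_sig, in_window = in_win,
       n_sig_in_window = sum(sig & in_win), cluster_p = cluster_p)
}
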