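test_that("CCG histograms target-minus-reference differences", {
  r <- spike_train(c(0, 1), 0, 2)
  tg <- spike_train(c(0.010, 1.010), 0, 2)
  cc <- compute_ccg(r, tg, bin_width = 0.001, window = 0.05)
  i10 <- which(abs(cc$lag - 0.010) < 1e-9)
  expect_equal(cc$counts[i10], 2)
  expect_equal(sum(cc$counts), 2)  # cross-pairs at +/-990 ms fall outside
  # all-zero case
  cc0 <- compute_ccg(spike_train(numeric(), 0, 1), tg)
  expect_true(all(cc0$counts == 0))
})

test_that("CCG(A,B) at lag tau equals CCG(B,A) at -tau; pairs conserved", {
  a <- poisson_train(10, 60, "a", seed = 31)
  b <- poisson_train(12, 60, "b", seed = 32)
  ab <- compute_ccg(a, b)
  ba <- compute_ccg(b, a)
  expect_equal(ab$counts, rev(ba$counts))
  # pair-count conservation against direct enumeration over the bin range
  d <- as.vector(outer(b$times, a$times, "-"))
  expect_equal(sum(ab$counts), sum(abs(d) <= max(abs(ab$breaks))))
})

test_that("autocorrelation keeps self-pairs in the zero-lag bin", {
  st <- poisson_train(8, 30, "s", seed = 33)
  cc <- compute_ccg(st, st)
  expect_gte(cc$counts[which(abs(cc$lag) < 1e-12)], n_spikes(st))
})

test_that("jisi dithering conserves count, adjacent-ISI sums and order", {
  # wide-ISI train: all gaps exceed twice the dither cap, so no two spikes
  # can swap and the surrogate order maps one-to-one onto the original
  t <- cumsum(withr::with_seed(34, runif(300, 0.06, 0.14)))
  st <- spike_train(t, 0, max(t) + 0.1, "d")
  surr <- jisi_dither(st, n = 100, dither_cap = 0.025, seed = 35)
  expect_length(surr, 100)
  interior <- 2:(length(t) - 1)
  for (s in surr) {
    expect_equal(n_spikes(s), n_spikes(st))
    expect_false(is.unsorted(s$times))
    expect_lte(max(abs(s$times - t)), 0.025 + 1e-12)
    # endpoints fixed; every interior spike stays strictly between its
    # original neighbours, conserving its adjacent-ISI sum
    expect_identical(s$times[c(1, length(t))], t[c(1, length(t))])
    expect_true(all(s$times[interior] > t[interior - 1] &
                      s$times[interior] < t[interior + 1]))
    lr_new <- (s$times[interior] - t[interior - 1]) +
      (t[interior + 1] - s$times[interior])
    expect_equal(lr_new, t[interior + 1] - t[interior - 1], tolerance = 1e-12)
  }
  # dithering actually moves (nearly) all interior spikes
  moved <- vapply(surr, function(s) mean(abs(s$times - t)[interior] > 0),
                  numeric(1))
  expect_gt(mean(moved), 0.9)
  # on an irregular train, count and order still hold after re-sorting
  pp <- poisson_train(10, 60, "p", seed = 36)
  for (s in jisi_dither(pp, n = 20, seed = 37)) {
    expect_equal(n_spikes(s), n_spikes(pp))
    expect_false(is.unsorted(s$times))
    expect_lte(max(abs(sort(s$times) - pp$times)), 0.025 + 1e-12)
  }
})

test_that("jisi dithering preserves the ISI distribution (KS screen)", {
  ok <- 0
  for (k in 1:20) {
    st <- poisson_train(10, 100, "k", seed = 400 + k)
    surr <- jisi_dither(st, n = 5, seed = 500 + k)
    pooled <- unlist(lapply(surr, function(s) diff(s$times)))
    p <- suppressWarnings(stats::ks.test(diff(st$times), pooled))$p.value
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, 19)  # >= 95% of trains pass at alpha = 0.01
})

test_that("short trains are returned unchanged by the ditherer", {
  st <- spike_train(c(0.1, 0.5), 0, 1)
  surr <- jisi_dither(st, n = 3, seed = 1)
  for (s in surr) expect_identical(s$times, st$times)
})

test_that("a constructed +10 ms shift lights up the monosynaptic window", {
  ref <- poisson_train(10, 120, "r", seed = 41)
  tgt <- spike_train(ref$times + 0.010, 0, 120.1, "t")
  cc <- compute_ccg(ref, tgt)
  surr <- lapply(jisi_dither(tgt, n = 150, seed = 42),
                 function(s) compute_ccg(ref, s))
  sig <- ccg_significance(cc, surr)
  i10 <- which(abs(sig$lag - 0.010) < 1e-9)
  expect_true(sig$significant[i10])
  expect_gte(sig$n_sig_in_window, 1)
})

test_that("a monosynaptic-delay connection clusters inside the 5-15 ms window", {
  # delays spread over the physiological window elevate several bins, which
  # the clustering summary must pick up against the binomial expectation
  ref <- poisson_train(10, 120, "r", seed = 56)
  delays <- withr::with_seed(57, pmin(pmax(rnorm(n_spikes(ref), 0.010, 0.002),
                                           0.0055), 0.0145))
  tgt <- spike_train(ref$times + delays, 0, 120.1, "t")
  cc <- compute_ccg(ref, tgt)
  surr <- lapply(jisi_dither(tgt, n = 150, seed = 58),
                 function(s) compute_ccg(ref, s))
  sig <- ccg_significance(cc, surr)
  expect_gte(sig$n_sig_in_window, 3)
  expect_lt(sig$cluster_p, 0.01)
})

test_that("significance masks demand identical binning and >= 100 surrogates", {
  a <- poisson_train(5, 30, "a", seed = 43)
  b <- poisson_train(5, 30, "b", seed = 44)
  cc <- compute_ccg(a, b)
  surr <- lapply(jisi_dither(b, n = 100, seed = 45),
                 function(s) compute_ccg(a, s))
  expect_error(ccg_significance(cc, surr[1:50]), "100")
  bad <- lapply(jisi_dither(b, n = 100, seed = 46),
                function(s) compute_ccg(a, s, bin_width = 0.002))
  expect_error(ccg_significance(cc, bad), "binning")
  msk <- ccg_significance(compute_ccg(spike_train(numeric(), 0, 30), b), surr)
  expect_equal(msk$n_significant, 0)
  expect_true(is.na(msk$cluster_p))
})

test_that("injected synchrony raises the peak bin monotonically", {
  peak <- vapply(c(0, 0.3, 0.8), function(frac) {
    ref <- poisson_train(10, 120, "r", seed = 47)
    n_shared <- round(frac * n_spikes(ref))
    own <- poisson_train(10 * (1 - frac), 120, "t", seed = 48)
    tt <- withr::with_seed(49, sort(c(own$times,
      sample(ref$times, n_shared) + 0.010)))
    tgt <- spike_train(tt, 0, 121, "t")
    cc <- compute_ccg(ref, tgt)
    cc$counts[which(abs(cc$lag - 0.010) < 1e-9)]
  }, numeric(1))
  expect_true(all(diff(peak) > 0))
})
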