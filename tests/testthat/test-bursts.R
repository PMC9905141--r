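mk <- function(times, span = max(times, 1)) spike_train(times, 0, span)

test_that("burst detection follows the >=3 spikes / <=300 ms ISI rule", {
  b <- detect_bursts(mk(c(0, 0.1, 0.2)))
  expect_equal(nrow(b), 1)
  expect_equal(b$onset, 0)
  expect_equal(b$offset, 0.2)
  expect_equal(b$n_spikes, 3L)
  expect_equal(nrow(detect_bursts(mk(c(0, 0.5, 1.0)))), 0)
  # the boundary ISI of exactly 300 ms is inside the burst
  b3 <- detect_bursts(mk(c(0, 0.3, 0.6)))
  expect_equal(nrow(b3), 1)
  expect_equal(b3$n_spikes, 3L)
  expect_equal(nrow(detect_bursts(mk(c(0, 0.301, 0.6)))), 0)
  expect_equal(nrow(detect_bursts(spike_train(numeric(), 0, 1))), 0)
})

test_that("detected bursts match the exhaustive run-scan oracle", {
  for (k in 1:50) {
    st <- withr::with_seed(k, mk(sort(runif(50, 0, 30)), span = 30))
    got <- detect_bursts(st)
    want <- oracle_bursts(st$times)
    expect_equal(got$first_idx, want$first, info = paste("seed", k))
    expect_equal(got$last_idx, want$last, info = paste("seed", k))
    # maximality and disjointness
    if (nrow(got) > 1) expect_true(all(diff(got$onset) > 0))
    expect_true(all(got$offset >= got$onset))
  }
})

test_that("burst_stats reports occurrence, duration and intra-burst rate", {
  b <- detect_bursts(mk(c(0, 0.1, 0.2), span = 60))
  s <- burst_stats(b, 60)
  expect_equal(s$occurrence_per_min, 1)
  expect_equal(s$mean_intra_freq_hz, 10)  # (3 - 1) / 0.2 s
  expect_equal(s$mean_duration_ms, 200)
  empty <- burst_stats(detect_bursts(spike_train(numeric(), 0, 60)), 60)
  expect_equal(empty$occurrence_per_min, 0)
  expect_true(is.na(empty$mean_duration_ms))
})

test_that("coincidence uses the symmetric spike-in-interval rule", {
  a <- detect_bursts(mk(c(0, 0.2, 0.5)))
  b <- detect_bursts(mk(c(0.3, 0.55, 0.8)))
  pr <- coincident_bursts(a, b)  # spike 0.5 falls in [0.3, 0.8]
  expect_equal(nrow(pr), 1)
  far <- detect_bursts(mk(c(10, 10.2, 10.4)))
  expect_equal(nrow(coincident_bursts(a, far)), 0)
  # identical trains: every burst pairs with itself, ratio 1
  st <- withr::with_seed(1, mk(sort(runif(60, 0, 120)), 120))
  bb <- detect_bursts(st)
  self <- coincident_bursts(bb, bb)
  expect_equal(nrow(self), nrow(bb))
  expect_equal(coincidence_ratio(self, nrow(bb), nrow(bb)), 1)
})

test_that("coincidence ratio normalizes by the lower burst count", {
  a <- detect_bursts(mk(c(0, 0.1, 0.2, 5, 5.1, 5.2), 10))
  b <- detect_bursts(mk(c(0.15, 0.25, 0.35, 8, 8.1, 8.2), 10))
  pr <- coincident_bursts(a, b)
  expect_equal(nrow(pr), 1)
  expect_equal(coincidence_ratio(pr, 2, 2), 0.5)
  expect_equal(coincidence_ratio(pr[0, ], 2, 2), 0)
  expect_true(is.na(coincidence_ratio(pr[0, ], 0, 0)))
})

test_that("each burst joins at most one pair (greedy one-to-one matching)", {
  # one long A burst overlaps two B bursts: only one pair may form
  a <- detect_bursts(mk(seq(0, 2, by = 0.2), 10))
  b <- detect_bursts(mk(c(0.05, 0.15, 0.25, 1.5, 1.6, 1.7), 10))
  pr <- coincident_bursts(a, b)
  expect_equal(nrow(pr), 1)
  expect_false(any(duplicated(pr$idx_a)))
  expect_false(any(duplicated(pr$idx_b)))
})

test_that("lead/lag ratios partition coinciding pairs and sum to one", {
  a <- detect_bursts(mk(c(0, 0.1, 0.2, 5, 5.1, 5.2), 10))
  b <- detect_bursts(mk(c(0.1, 0.2, 0.3, 5.1, 5.2, 5.3), 10))
  ll <- lead_lag(coincident_bursts(a, b))
  expect_equal(ll, c(lead_a = 1, lead_b = 0, tie = 0))
  llt <- lead_lag(coincident_bursts(a, a))
  expect_equal(llt, c(lead_a = 0, lead_b = 0, tie = 1))
  expect_equal(sum(ll), 1)
  expect_true(all(is.na(lead_lag(coincident_bursts(a[0, ], b[0, ])))))
})

test_that("jitter surrogates preserve spike count and bound displacement", {
  st <- withr::with_seed(6, mk(sort(runif(200, 0, 300)), 300))
  surr <- jitter_surrogates(st, half_width = 0.75, n = 50, seed = 9)
  expect_length(surr, 50)
  for (s in surr[1:5]) {
    expect_equal(n_spikes(s), 200)
    expect_gte(min(s$times), 0)
    expect_lte(max(s$times), 300)
  }
  # support bound: per-spike displacement <= half-width (before re-sorting,
  # checked via optimal matching of sorted samples)
  d <- sort(surr[[1]]$times) - sort(st$times)
  expect_lte(max(abs(d)), 0.75 + 1e-12)
  # determinism
  surr2 <- jitter_surrogates(st, half_width = 0.75, n = 50, seed = 9)
  expect_identical(surr[[50]]$times, surr2[[50]]$times)
})

test_that("self-pair surrogate ratios fall below 1 under burst-scale jitter", {
  m <- burst_model(span_s = 900)
  st <- generate_burst_train(m, seed = 11)
  b <- detect_bursts(st)
  surr <- jitter_surrogates(st, half_width = 0.75, n = 100, seed = 12)
  ratios <- vapply(surr, function(s) {
    sb <- detect_bursts(s)
    coincidence_ratio(coincident_bursts(sb, b), nrow(sb), nrow(b))
  }, numeric(1))
  expect_lt(stats::quantile(ratios, 0.99, type = 1), 1)
})

test_that("pair significance flags constructed coupling, not chance", {
  # burst-scale jitter destroys alignment by fragmenting bursts below the
  # 3-spike rule; that requires bursts whose spike count is small relative
  # to the jitter span (with very dense long bursts the surrogate retains
  # alignment and the test is conservative by design)
  sparse <- function() burst_model(span_s = 600, spikes_nb_mu = 2,
                                   isi_mean_s = 0.04)
  ens <- generate_coupled_ensemble(
    list(A = sparse(), B = sparse()),
    list(coupling_spec("A", "B", 1, lag_mean_s = 0.1, lag_shape = Inf)),
    seed = 21)
  pc <- pair_coincidence(ens$A, ens$B, n_surrogates = 200, seed = 22)
  expect_true(pc$significant)
  expect_equal(length(pc$surrogate_ratios), 200)
  sig <- coincidence_significance(pc$coincidence_ratio, pc$surrogate_ratios)
  expect_equal(sig$significant, pc$significant)
  # an observed ratio below the surrogate median can never be flagged
  expect_false(coincidence_significance(
    stats::median(pc$surrogate_ratios) - 0.01, pc$surrogate_ratios)$significant)
  expect_error(coincidence_significance(0.5, runif(50)), "100")
})
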