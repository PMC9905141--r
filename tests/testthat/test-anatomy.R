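scheme_s1 <- layer_scheme("S1Bf")

test_that("layer schemes renormalize thickness and validate proportions", {
  expect_equal(sum(scheme_s1$thickness), 1)
  expect_equal(scheme_s1$thickness_raw,
               c(0.070, 0.245, 0.301, 0.263, 0.088))
  expect_equal(scheme_s1$neuron_proportion, c(0.06, 0.33, 0.24, 0.31, 0.06))
  expect_equal(scheme_s1$cum_depth,
               c(0, 0.0724, 0.3257, 0.6370, 0.9090, 1),
               tolerance = 1e-3)
  s2 <- layer_scheme("S2")
  expect_equal(s2$thickness_raw[4], 0.267)   # corrected L6 thickness
  s2v <- layer_scheme("S2", verbatim = TRUE)
  expect_equal(s2v$thickness_raw[4], 0.867)  # verbatim value stays loadable
  expect_error(layer_scheme(thickness = rep(0.2, 5),
                            neuron_proportion = rep(0.5, 5)), "sum to 1")
})

test_that("quadratic surface fitting is exact on quadratic data", {
  g <- expand.grid(x = seq(-50, 50, 10), y = seq(-50, 50, 10))
  flat <- fit_surface(data.frame(x = g$x, y = g$y, z = 100))
  expect_equal(flat$coef, c(100, 0, 0, 0, 0, 0), tolerance = 1e-8)
  expect_lt(flat$rms_residual, 1e-8)
  quad <- fit_surface(data.frame(x = g$x, y = g$y, z = g$x^2 / 1000))
  expect_equal(quad$coef[4], 1e-3, tolerance = 1e-6)
  expect_equal(surface_z(quad, 30, -20), 0.9, tolerance = 1e-6)
  expect_error(fit_surface(data.frame(x = 1:5, y = 1:5, z = 1:5)), "6 points")
  grid_line <- data.frame(x = 1:10, y = 2 * (1:10), z = 1:10)
  expect_error(fit_surface(grid_line), "rank")
})

test_that("point-to-surface distance matches a dense grid oracle", {
  plane <- flat_surface(0)
  expect_equal(point_surface_distance(plane, c(0, 0, 250)), 250)
  expect_equal(point_surface_distance(plane, c(10, 20, -5)), -5)
  g <- expand.grid(x = seq(0, 1000, 50), y = seq(0, 1000, 50))
  curved <- fit_surface(data.frame(x = g$x, y = g$y,
                                   z = 0.1 * g$x + 2e-4 * (g$x - 500)^2))
  pts <- withr::with_seed(51, cbind(runif(20, 200, 800), runif(20, 200, 800),
                                    runif(20, -50, 400)))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    d <- point_surface_distance(curved, p)
    gg <- expand.grid(x = seq(p[1] - 400, p[1] + 400, 1),
                      y = seq(p[2] - 400, p[2] + 400, 1))
    brute <- sqrt(min((gg$x - p[1])^2 + (gg$y - p[2])^2 +
                        (surface_z(curved, gg$x, gg$y) - p[3])^2))
    expect_equal(abs(d), brute, tolerance = 0.5)
  }
  on_surf <- c(300, 400, surface_z(curved, 300, 400))
  expect_lt(abs(point_surface_distance(curved, on_surf)), 1e-4)
})

test_that("normalized depth: planar closed form and boundary cells", {
  pial <- flat_surface(0); sp <- flat_surface(1000)
  cells <- data.frame(x = c(500, 500, 500), y = 500, z = c(250, 0, 1000))
  r <- normalized_depth(cells, pial, sp, scheme = scheme_s1)
  expect_equal(r$normalized_depth, c(0.25, 0, 1), tolerance = 1e-6)
  expect_equal(r$local_thickness, rep(1000, 3), tolerance = 1e-6)
  expect_equal(r$assigned_layer, c("CP", "MZ", "SP"))
})

test_that("normalized depth is invariant to translation and scaling", {
  g <- expand.grid(x = seq(0, 1000, 100), y = seq(0, 1000, 100))
  mkfit <- function(shift = c(0, 0, 0), scale = 1) {
    pz <- 1e-4 * (g$x - 500)^2
    list(pial = fit_surface(data.frame(x = scale * (g$x + shift[1]),
                                       y = scale * (g$y + shift[2]),
                                       z = scale * (pz + shift[3]))),
         sp = fit_surface(data.frame(x = scale * (g$x + shift[1]),
                                     y = scale * (g$y + shift[2]),
                                     z = scale * (pz + 900 + shift[3]))))
  }
  cell <- data.frame(x = 420, y = 510, z = 300)
  base <- mkfit()
  d0 <- normalized_depth(cell, base$pial, base$sp)$normalized_depth
  tr <- mkfit(shift = c(100, -50, 30))
  d1 <- normalized_depth(data.frame(x = 520, y = 460, z = 330),
                         tr$pial, tr$sp)$normalized_depth
  sc <- mkfit(scale = 2)
  d2 <- normalized_depth(data.frame(x = 840, y = 1020, z = 600),
                         sc$pial, sc$sp)$normalized_depth
  expect_equal(d1, d0, tolerance = 1e-6)
  expect_equal(d2, d0, tolerance = 1e-6)
})

test_that("assign_layer partitions [0,1] with half-open bins", {
  depths <- seq(0, 1, by = 0.001)
  lab <- assign_layer(depths, scheme_s1)
  expect_false(anyNA(lab))
  expect_equal(assign_layer(0, scheme_s1), "MZ")
  expect_equal(assign_layer(1, scheme_s1), "SP")
  # a depth exactly at a boundary belongs to the deeper layer
  b <- scheme_s1$cum_depth[3]  # CP/L5 boundary
  expect_equal(assign_layer(b, scheme_s1), "L5")
  expect_equal(assign_layer(b - 1e-9, scheme_s1), "CP")
  expect_error(assign_layer(1.2, scheme_s1), "0, 1")
})

test_that("layer proportions use truncated integer percentages", {
  labs <- rep(c("L6", "L5", "CP", "SP"), c(41, 37, 18, 15))
  lp <- layer_proportions(labs, scheme_s1)
  expect_equal(attr(lp, "total"), 111)
  expect_equal(lp$percent[match(c("L6", "L5", "CP", "SP"), lp$layer)],
               c(36L, 33L, 16L, 13L))
  one <- layer_proportions(rep("L5", 7), scheme_s1)
  expect_equal(one$percent[one$layer == "L5"], 100L)
  for (k in 1:20) {
    rnd <- withr::with_seed(600 + k,
      sample(scheme_s1$layers, 50, replace = TRUE))
    expect_lte(sum(layer_proportions(rnd, scheme_s1)$percent), 100)
  }
})

test_that("enrichment test: chi-square gate plus exact binomial follow-up", {
  # observed exactly proportional to expected -> statistic 0, p = 1
  p <- scheme_s1$neuron_proportion[-1] / sum(scheme_s1$neuron_proportion[-1])
  obs <- stats::setNames(round(p * 940), c("CP", "L5", "L6", "SP"))
  e0 <- enrichment_test(obs, scheme_s1)
  expect_lt(e0$chisq$statistic, 0.01)
  expect_gt(e0$chisq$p_value, 0.99)
  expect_null(e0$binomial)
  # two-sided exact binomial reference point: 8/10 against 0.5
  expect_equal(stats::binom.test(8, 10, 0.5)$p.value, 112 / 1024)
  # a strong L5 excess is flagged enriched
  skew <- c(CP = 100, L5 = 250, L6 = 100, SP = 50)
  e1 <- enrichment_test(skew, scheme_s1)
  expect_lt(e1$chisq$p_value, 0.05)
  row <- e1$binomial[e1$binomial$layer == "L5", ]
  expect_equal(row$direction, "enriched")
  expect_true(row$significant)
  expect_equal(e1$chisq$df, 3)
  expect_warning(enrichment_test(c(CP = 3, L5 = 2, L6 = 1, SP = 0),
                                 scheme_s1), "expected count")
  expect_error(enrichment_test(c(CP = 1, L5 = 1, L6 = 1, SP = 0), scheme_s1),
               "at least 5")
})

test_that("chi-square type-I rate is calibrated at alpha", {
  p <- scheme_s1$neuron_proportion[-1] / sum(scheme_s1$neuron_proportion[-1])
  rej <- withr::with_seed(61, {
    mean(vapply(1:1000, function(i) {
      obs <- stats::setNames(as.integer(stats::rmultinom(1, 300, p)),
                             c("CP", "L5", "L6", "SP"))
      enrichment_test(obs, scheme_s1)$chisq$p_value < 0.05
    }, logical(1)))
  })
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rej - 0.05), 3 * se + 0.01)  # + chi-square approximation slack
})
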