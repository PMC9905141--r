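#' Aggregate per-pair results into a labeled matrix
#'
#' Builds the familiar region+layer by region+layer summary matrix: each
#' cell holds the mean and SEM of a per-pair metric across slices (or
#' replicate pairs), together with the pooled number of coincident bursts.
#' The coincidence-ratio matrix is symmetric with a unit diagonal; the
#' lead-ratio matrix satisfies `M[i, j] + M[j, i] + tie = 1` per populated
#' cell.
#'
#' @param results list of `pair_coincidence` objects (possibly from several
#'   slices).
#' @param metric `"coincidence_ratio"` or `"lead"`; for `"lead"`, cell
#'   `[i, j]` holds the mean ratio of coincident bursts in which channel
#'   group `i` leads channel group `j`.
#' @param labels optional function mapping a `pair_coincidence` channel id
#'   to a group label; defaults to the id itself.
#' @return An object of class `pair_matrix`: list of matrices `mean`, `sem`,
#'   `n_pairs` (number of contributing electrode pairs) and `n_bursts`
#'   (pooled coincident bursts), plus `metric`. Empty cells are `NA`.
#' @export
aggregate_matrix <- function(results, metric = c("coincidence_ratio", "lead"),
                             labels = identity) {
  metric <- match.arg(metric)
  if (!length(results)) stop("need at least one pair result")
  recs <- list()
  for (r in results) {
    la <- labels(r$channel_a); lb <- labels(r$channel_b)
    if (metric == "coincidence_ratio") {
      v <- r$coincidence_ratio
      recs[[length(recs) + 1L]] <- list(la, lb, v, r$n_coincident)
      if (la != lb) recs[[length(recs) + 1L]] <- list(lb, la, v, r$n_coincident)
    } else {
      recs[[length(recs) + 1L]] <- list(la, lb, r$lead_a, r$n_coincident)
      if (la != lb) recs[[length(recs) + 1L]] <- list(lb, la, r$lead_b, r$n_coincident)
    }
  }
  labs <- unique(unlist(lapply(recs, function(x) c(x[[1]], x[[2]]))))
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  sem <- m; npair <- m; nburst <- m
  for (i in labs) for (j in labs) {
    vals <- unlist(lapply(recs, function(x)
      if (x[[1]] == i && x[[2]] == j) x[[3]] else NULL))
    ns <- unlist(lapply(recs, function(x)
      if (x[[1]] == i && x[[2]] == j) x[[4]] else NULL))
    vals <- vals[!is.na(vals)]
    if (length(vals)) {
      m[i, j] <- mean(vals)
      sem[i, j] <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0
      npair[i, j] <- length(vals)
      nburst[i, j] <- sum(ns)
    }
  }
  structure(list(mean = m, sem = sem, n_pairs = npair, n_bursts = nburst,
                 metric = metric), class = "pair_matrix")
}

#' @rdname aggregate_matrix
#' @param x a `pair_matrix`.
#' @param ... ignored.
#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %s (mean +/- SEM, pooled n of coincident bursts)\n",
              x$metric))
  labs <- rownames(x$mean)
  out <- matrix("", length(labs), length(labs), dimnames = list(labs, labs))
  for (i in labs) for (j in labs)
    out[i, j] <- if (is.na(x$mean[i, j])) "-" else
      sprintf("%.2f +/- %.2f (n = %d)", x$mean[i, j], x$sem[i, j],
              x$n_bursts[i, j])
  print(out, quote = FALSE)
  invisible(x)
}

#' Write a pair matrix as TSV
#'
#' One row/column per region+layer group; cells formatted
#' `mean +/- SEM (n = pooled bursts)`.
#'
#' @param x a `pair_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_matrix_tsv <- function(x, path) {
  labs <- rownames(x$mean)
  out <- matrix("", length(labs), length(labs), dimnames = list(labs, labs))
  for (i in labs) for (j in labs)
    out[i, j] <- if (is.na(x$mean[i, j])) "" else
      sprintf("%.3f +/- %.3f (n = %d)", x$mean[i, j], x$sem[i, j],
              x$n_bursts[i, j])
  utils::write.table(cbind(group = labs, out), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact signed-rank distribution for n at most 25 non-zero differences
#' (when there are no ties in the absolute differences), normal
#' approximation with continuity correction otherwise. All-zero differences
#' give p = 1.
#'
#' @param a,b paired samples of equal length, or `b = NULL` with `mu` to
#'   test `a` against a constant.
#' @param mu null location when `b` is `NULL`, default 0.
#' @return List with `statistic` (V), `p_value`, `n` (non-zero
#'   differences), `method`.
#' @export
wilcoxon_paired <- function(a, b = NULL, mu = 0) {
  if (!is.null(b)) {
    stopifnot(length(a) == length(b))
    d <- a - b
  } else d <- a - mu
  d <- d[!is.na(d)]
  nz <- sum(d != 0)
  if (nz == 0)
    return(list(statistic = 0, p_value = 1, n = 0, method = "all differences zero"))
  exact <- nz <= 25 && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = nz,
       method = if (exact) "exact" else "normal approximation")
}

#' Directionality report for a set of coupled electrode pairs
#'
#' Summarizes, per connection, the distribution of observed per-pair
#' lead ratios and of the matching surrogate lead ratios, and tests the
#' observed ratios against the chance level 0.5 with a Wilcoxon signed-rank
#' test. Stars: `*` p < 0.05, `**` p < 0.01.
#'
#' @param results list of `pair_coincidence` objects for one connection
#'   (e.g. all SP-to-L5/6 pairs across slices).
#' @param connection label for the report row.
#' @return One-row data frame: `connection`, `n_pairs`, `mean_lead_a`,
#'   `sem_lead_a`, `surrogate_mean_lead_a`, `wilcoxon_p`, `stars`. With
#'   fewer than 2 pairs the test columns are `NA` (descriptive only).
#' @export
directionality_report <- function(results, connection = "A->B") {
  leads <- vapply(results, function(r) r$lead_a, numeric(1))
  surr <- unlist(lapply(results, function(r) r$surrogate_lead_a))
  leads <- leads[!is.na(leads)]
  n <- length(leads)
  if (n >= 2) {
    wt <- wilcoxon_paired(leads, mu = 0.5)
    p <- wt$p_value
  } else p <- NA_real_
  data.frame(connection = connection, n_pairs = n,
             mean_lead_a = if (n) mean(leads) else NA_real_,
             sem_lead_a = if (n > 1) stats::sd(leads) / sqrt(n) else NA_real_,
             surrogate_mean_lead_a = mean(surr, na.rm = TRUE),
             wilcoxon_p = p,
             stars = if (is.na(p)) "" else if (p < 0.01) "**"
                     else if (p < 0.05) "*" else "ns")
}

#' Run the full synthetic pipeline from a configuration
#'
#' Executes simulate -> burst/coincidence analysis -> anatomy -> report and
#' writes every stage's outputs plus a manifest (parameter echo, seeds,
#' package version) under `outdir`. The configuration is a YAML file or an
#' equivalent nested list; see the bundled `demo_config.yaml` under
#' `inst/extdata` for the format and defaults.
#'
#' @param config path to a YAML file, or a list.
#' @param outdir output directory, created if needed.
#' @param seed integer seed overriding the config's seed.
#' @return Invisibly, a list with `coincidence` (pair matrix),
#'   `directionality`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = "neoconn_out", seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- cfg$seed %||% 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ep <- cfg$ephys %||% list()
  n_ch <- ep$n_channels %||% 4L
  ids <- paste0("ch", seq_len(n_ch))
  models <- stats::setNames(lapply(seq_len(n_ch), function(i)
    burst_model(span_s = ep$span_s %||% 600)), ids)
  couplings <- lapply(ep$couplings %||% list(), function(cp)
    coupling_spec(cp$source, cp$target, cp$prob,
                  lag_mean_s = cp$lag_mean_s %||% 0.15))
  trains <- stage("simulate-ephys",
                  generate_coupled_ensemble(models, couplings, seed = seed))
  write_spike_csv(trains, file.path(outdir, "spikes.csv"))

  ba <- cfg$bursts %||% list()
  pair_res <- list()
  combs <- utils::combn(ids, 2, simplify = FALSE)
  k <- 0L
  pair_res <- stage("coincidence", lapply(combs, function(pr) {
    k <<- k + 1L
    pair_coincidence(trains[[pr[1]]], trains[[pr[2]]],
                     isi_max = (ba$isi_max_ms %||% 300) / 1000,
                     min_spikes = ba$min_spikes %||% 3,
                     jitter_s = (ba$jitter_ms %||% 750) / 1000,
                     n_surrogates = ba$n_surrogates %||% 200,
                     percentile = ba$percentile %||% 99,
                     seed = sub_seed(seed, paste0("pair", k)))
  }))
  cmat <- aggregate_matrix(pair_res, "coincidence_ratio")
  lmat <- aggregate_matrix(pair_res, "lead")
  write_pair_matrix_tsv(cmat, file.path(outdir, "coincidence_matrix.tsv"))
  write_pair_matrix_tsv(lmat, file.path(outdir, "lead_matrix.tsv"))
  dir_rep <- directionality_report(pair_res, "all pairs")

  an <- cfg$anatomy %||% list()
  scheme <- layer_scheme(an$area %||% "S1Bf")
  spec <- volume_spec(area = scheme$area,
                      n_neurons = an$n_neurons %||% 2000,
                      backlabel_prob = unlist(an$backlabel_prob %||%
                                                c(0, 0.05, 0.05, 0.05, 0.05)))
  vol <- stage("simulate-anatomy",
               generate_cortical_volume(spec, scheme,
                                        seed = sub_seed(seed, "anatomy")))
  vol$cells <- sample_backlabeled(vol$cells, spec$backlabel_prob,
                                  scheme = scheme,
                                  seed = sub_seed(seed, "backlabel"))
  write_volume_csv(vol, file.path(outdir, "cells.csv"),
                   file.path(outdir, "surfaces.csv"))
  pial <- fit_surface(vol$pial_points)
  sp <- fit_surface(vol$sp_points)
  lab <- vol$cells[vol$cells$backlabeled == 1, ]
  lab <- stage("anatomy", normalized_depth(lab, pial, sp, scheme = scheme))
  utils::write.csv(lab, file.path(outdir, "cells_depth.csv"), row.names = FALSE)
  props <- layer_proportions(lab$assigned_layer[lab$valid], scheme)
  enr <- enrichment_test(props, scheme, alpha = an$alpha %||% 0.05)

  manifest <- list(package = "neoconn",
                   version = as.character(utils::packageVersion("neoconn")),
                   seed = seed, config = cfg,
                   n_channels = n_ch, n_pairs = length(pair_res),
                   n_cells = nrow(vol$cells), n_backlabeled = nrow(lab))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(
    chisq_p = enr$chisq$p_value,
    coincidence_mean = unname(cmat$mean[1, 2]),
    directionality = dir_rep), file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(coincidence = cmat, lead = lmat, directionality = dir_rep,
                 enrichment = enr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
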