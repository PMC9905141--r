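#' Laminar scheme: layer order, relative thickness, neuron proportions
#'
#' Bundled schemes for M1, S1Bf and S2 give, for each layer from pia to
#' white matter (MZ, CP, L5, L6, SP), its relative thickness and the
#' expected proportion of all neurons it contains. Relative thicknesses are
#' renormalized to sum exactly to 1 before use. The S2 scheme is available
#' in two variants: the default with the corrected L6 thickness (0.267) and
#' the verbatim one (0.867, an apparent transcription error in the source
#' counts).
#'
#' @param area `"M1"`, `"S1Bf"` or `"S2"`.
#' @param thickness,neuron_proportion optional numeric vectors overriding
#'   the bundled values (same length as `layers`).
#' @param layers layer labels, pia to white matter.
#' @param verbatim logical; for S2, load the verbatim thickness row instead
#'   of the typo-corrected default.
#' @return An object of class `layer_scheme`: list with `area`, `layers`,
#'   `thickness` (renormalized), `thickness_raw`, `neuron_proportion`,
#'   `cum_depth` (cumulative normalized-depth bin edges, starting at 0).
#' @examples
#' sc <- layer_scheme("S1Bf")
#' sc$cum_depth
#' @export
layer_scheme <- function(area = c("S1Bf", "M1", "S2"), thickness = NULL,
                         neuron_proportion = NULL,
                         layers = c("MZ", "CP", "L5", "L6", "SP"),
                         verbatim = FALSE) {
  if (is.null(thickness) || is.null(neuron_proportion)) {
    area <- match.arg(area)
    path <- system.file("extdata", "layer_schemes.yaml", package = "neoconn")
    tab <- yaml::read_yaml(path)
    layers <- tab$layers
    a <- tab$areas[[area]]
    if (is.null(thickness))
      thickness <- if (verbatim && !is.null(a$thickness_verbatim))
        a$thickness_verbatim else a$thickness
    if (is.null(neuron_proportion)) neuron_proportion <- a$neuron_proportion
  } else {
    area <- area[1]
  }
  thickness <- as.numeric(thickness)
  neuron_proportion <- as.numeric(neuron_proportion)
  stopifnot(length(thickness) == length(layers),
            length(neuron_proportion) == length(layers),
            all(thickness > 0), all(neuron_proportion >= 0))
  psum <- sum(neuron_proportion)
  if (abs(psum - 1) > 0.02)
    stop("expected neuron proportions must sum to 1 (got ", psum, ")")
  th <- thickness / sum(thickness)
  structure(list(area = area, layers = layers, thickness = th,
                 thickness_raw = thickness,
                 neuron_proportion = neuron_proportion,
                 cum_depth = c(0, cumsum(th))), class = "layer_scheme")
}

#' @rdname layer_scheme
#' @param x a `layer_scheme`.
#' @param ... ignored.
#' @export
print.layer_scheme <- function(x, ...) {
  cat(sprintf("<layer_scheme> %s\n", x$area))
  print(data.frame(layer = x$layers, rel_thickness = round(x$thickness, 4),
                   neuron_prop = x$neuron_proportion,
                   depth_lo = round(x$cum_depth[-length(x$cum_depth)], 4),
                   depth_hi = round(x$cum_depth[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' Least-squares quadratic surface fit
#'
#' Fits `z = c0 + c1 x + c2 y + c3 x^2 + c4 x y + c5 y^2` to a boundary
#' point cloud (pial or lower-subplate boundary) by ordinary least squares.
#'
#' @param points data frame or matrix with columns `x`, `y`, `z` (microns);
#'   at least 6 non-degenerate points.
#' @return An object of class `surface_model`: list with `coef` (length 6),
#'   `rms_residual` (microns), `bbox` (lateral bounding box).
#' @export
fit_surface <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(points))) {
    if (ncol(points) >= 3) names(points)[1:3] <- c("x", "y", "z")
    else stop("`points` needs columns x, y, z")
  }
  if (nrow(points) < 6) stop("need at least 6 points to fit a quadratic surface")
  X <- cbind(1, points$x, points$y, points$x^2, points$x * points$y, points$y^2)
  q <- qr(X)
  if (q$rank < 6)
    stop("rank-deficient design: boundary points do not determine a quadratic",
         " surface (are they collinear or on a line grid?)")
  cf <- qr.coef(q, points$z)
  res <- points$z - X %*% cf
  structure(list(coef = as.numeric(cf),
                 rms_residual = sqrt(mean(res^2)),
                 bbox = c(xmin = min(points$x), xmax = max(points$x),
                          ymin = min(points$y), ymax = max(points$y))),
            class = "surface_model")
}

#' @rdname fit_surface
#' @param surface a `surface_model`.
#' @param x,y lateral coordinates (microns), vectorized.
#' @return `surface_z()` returns the surface height `z` at `(x, y)`.
#' @export
surface_z <- function(surface, x, y) {
  cf <- surface$coef
  cf[1] + cf[2] * x + cf[3] * y + cf[4] * x^2 + cf[5] * x * y + cf[6] * y^2
}

#' @rdname fit_surface
#' @param ... ignored.
#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> z = %.3g %+.3g x %+.3g y %+.3g x2 %+.3g xy %+.3g y2 (rms %.2f um)\n",
              x$coef[1], x$coef[2], x$coef[3], x$coef[4], x$coef[5], x$coef[6],
              x$rms_residual))
  invisible(x)
}

# Nearest point on the surface to `p`; returns list(point, distance).
nearest_surface_point <- function(surface, p) {
  obj <- function(xy) {
    dz <- surface_z(surface, xy[1], xy[2]) - p[3]
    (xy[1] - p[1])^2 + (xy[2] - p[2])^2 + dz^2
  }
  opt <- stats::optim(c(p[1], p[2]), obj, method = "BFGS",
                      control = list(maxit = 200))
  if (opt$convergence != 0) {
    # dense-grid fallback around the lateral position
    warning("nearest-point search did not converge; using dense grid")
    g <- expand.grid(x = seq(p[1] - 500, p[1] + 500, by = 1),
                     y = seq(p[2] - 500, p[2] + 500, by = 1))
    d2 <- (g$x - p[1])^2 + (g$y - p[2])^2 +
      (surface_z(surface, g$x, g$y) - p[3])^2
    i <- which.min(d2)
    opt <- list(par = c(g$x[i], g$y[i]), value = d2[i])
  }
  q <- c(opt$par[1], opt$par[2], surface_z(surface, opt$par[1], opt$par[2]))
  list(point = q, distance = sqrt(opt$value))
}

#' Euclidean distance from a point to a fitted surface
#'
#' Minimal Euclidean distance, found numerically (BFGS over the lateral
#' coordinates with a dense-grid fallback). The distance is signed by side:
#' with `z` increasing from the pia down into the tissue, points below the
#' surface (larger `z` than the surface at their lateral position) are
#' positive and points above it are negative.
#'
#' @param surface a `surface_model`.
#' @param point numeric length-3 `(x, y, z)` in microns.
#' @return Signed scalar distance in microns (positive below the surface,
#'   i.e. deeper `z`; negative above).
#' @export
point_surface_distance <- function(surface, point) {
  stopifnot(length(point) == 3)
  np <- nearest_surface_point(surface, as.numeric(point))
  sgn <- if (point[3] >= surface_z(surface, point[1], point[2])) 1 else -1
  sgn * np$distance
}

#' Normalized cortical depth of labeled cells
#'
#' For each cell, the distance to the pial surface and the local cortical
#' thickness are measured along the direction from the cell's nearest point
#' on the pial surface through the cell (for a cell inside the cortex this
#' is the pial surface normal): the local thickness is the length of that
#' ray from the pial surface to the lower subplate surface, and the
#' normalized depth is `distance_to_pial / local_thickness` (0 at the pia,
#' 1 at the subplate-white matter boundary). Depths outside `[0, 1]` are
#' clipped, with the overshoot reported in `depth_raw`. The coordinate
#' convention has `z` increasing from the pia into the tissue.
#'
#' @param cells data frame with columns `x`, `y`, `z` (microns); other
#'   columns are carried through.
#' @param pial,sp `surface_model`s of the pial and lower-subplate
#'   boundaries; `sp` must lie below `pial` (larger `z`) at each cell.
#' @param scheme optional [layer_scheme()]; when given, an `assigned_layer`
#'   column is added via [assign_layer()].
#' @return `cells` with added columns `distance_to_pial`, `local_thickness`
#'   (microns), `depth_raw`, `normalized_depth` and `valid` (`FALSE` where
#'   the local thickness was not positive; such cells are excluded from
#'   downstream statistics), plus `assigned_layer` when `scheme` is given.
#' @export
normalized_depth <- function(cells, pial, sp, scheme = NULL) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("x", "y", "z") %in% names(cells)))
  n <- nrow(cells)
  d_pial <- numeric(n); thick <- numeric(n)
  for (i in seq_len(n)) {
    p <- c(cells$x[i], cells$y[i], cells$z[i])
    np <- nearest_surface_point(pial, p)
    d_pial[i] <- np$distance *
      (if (p[3] >= surface_z(pial, p[1], p[2])) 1 else -1)
    dir <- p - np$point
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-9) {
      # cell sits on the pial surface: use the surface normal there
      cf <- pial$coef
      gx <- cf[2] + 2 * cf[4] * p[1] + cf[5] * p[2]
      gy <- cf[3] + cf[5] * p[1] + 2 * cf[6] * p[2]
      dir <- c(-gx, -gy, 1)
      dir <- dir / sqrt(sum(dir^2)) * sign(1)  # pointing into the tissue
    } else {
      dir <- dir / nd * sign(d_pial[i])  # from the pia toward the cell
    }
    # length of the ray q + s*dir until it meets the lower SP surface
    f <- function(s) {
      q <- np$point + s * dir
      q[3] - surface_z(sp, q[1], q[2])
    }
    s_hi <- max(abs(d_pial[i]), 1) * 2 + 100
    tries <- 0
    while (f(s_hi) < 0 && tries < 20) { s_hi <- s_hi * 2; tries <- tries + 1 }
    thick[i] <- if (f(0) >= 0 || f(s_hi) < 0) NA_real_ else
      stats::uniroot(f, c(0, s_hi), tol = 1e-8)$root
  }
  cells$distance_to_pial <- d_pial
  cells$local_thickness <- thick
  cells$depth_raw <- d_pial / thick
  cells$valid <- !is.na(thick) & thick > 0
  over <- cells$valid & (cells$depth_raw < 0 | cells$depth_raw > 1)
  if (any(over))
    message(sum(over), " cell(s) outside [0, 1] normalized depth (max |overshoot| ",
            signif(max(abs(pmax(cells$depth_raw[over] - 1, 0 - cells$depth_raw[over]))), 3),
            "); clipped")
  cells$normalized_depth <- pmin(pmax(cells$depth_raw, 0), 1)
  cells$normalized_depth[!cells$valid] <- NA_real_
  if (!is.null(scheme))
    cells$assigned_layer <- assign_layer(cells$normalized_depth, scheme)
  cells
}

#' Assign a layer label from a normalized depth
#'
#' The renormalized cumulative layer thicknesses define half-open depth bins
#' `[c_{k-1}, c_k)` from the pia down; the last bin is closed at 1, so depth
#' 0 maps to MZ and depth 1 to SP. A depth exactly at an interior boundary
#' belongs to the deeper layer.
#'
#' @param depth numeric vector of normalized depths in \[0, 1\] (`NA`
#'   allowed).
#' @param scheme a [layer_scheme()].
#' @return Character vector of layer labels.
#' @export
assign_layer <- function(depth, scheme) {
  stopifnot(inherits(scheme, "layer_scheme"))
  ok <- !is.na(depth)
  if (any(depth[ok] < 0 | depth[ok] > 1)) stop("depth must be in [0, 1]")
  idx <- findInterval(depth, scheme$cum_depth, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(depth))
  out[ok] <- scheme$layers[idx[ok]]
  out
}

#' Per-layer counts and truncated percentages
#'
#' Counts cells per layer and reports each layer's percentage of the total
#' as `floor(100 * count / total)` — the truncation convention used when
#' such counts are reported in print (e.g. 41 of 111 prints as 36%).
#'
#' @param layers character vector of per-cell layer labels, or a data frame
#'   with an `assigned_layer` column (and optionally `backlabeled`).
#' @param scheme a [layer_scheme()] fixing the layer order.
#' @param backlabeled_only when `layers` is a data frame with a
#'   `backlabeled` column, restrict to backlabeled cells.
#' @param total denominator for the percentages; defaults to the number of
#'   tabulated cells. Published tables sometimes state a total that differs
#'   from the sum of the per-layer counts they print (e.g. cells that were
#'   recorded but not assigned); passing the stated total reproduces such
#'   percentages.
#' @return Data frame with `layer`, `count`, `percent` (truncated integer)
#'   and attribute `total`.
#' @export
layer_proportions <- function(layers, scheme, backlabeled_only = FALSE,
                              total = NULL) {
  if (is.data.frame(layers)) {
    df <- layers
    if (backlabeled_only) df <- df[as.logical(df$backlabeled), , drop = FALSE]
    layers <- df$assigned_layer
  }
  layers <- layers[!is.na(layers)]
  if (!length(layers)) stop("no cells to tabulate")
  cnt <- vapply(scheme$layers, function(l) sum(layers == l), integer(1))
  if (is.null(total)) total <- sum(cnt)
  stopifnot(total >= sum(cnt))
  out <- data.frame(layer = scheme$layers, count = as.integer(cnt),
                    percent = as.integer(floor(100 * cnt / total)))
  attr(out, "total") <- total
  out
}

#' Laminar enrichment test of backlabeled cells
#'
#' Tests whether backlabeled cells distribute across layers as expected
#' from the laminar neuron proportions. A chi-square goodness-of-fit test
#' is run over the included layers (MZ excluded by default, its expected
#' proportion renormalized away); if it rejects at `alpha`, each layer is
#' followed up with an exact two-sided binomial test of its observed count
#' against its expected proportion. No multiple-testing correction is
#' applied by default; set `p_adjust` to a [stats::p.adjust()] method to
#' turn it on.
#'
#' @param observed named integer vector of per-layer backlabeled counts, or
#'   a `layer_proportions()` result.
#' @param scheme a [layer_scheme()] providing expected neuron proportions.
#' @param exclude layers dropped before testing, default `"MZ"`.
#' @param alpha significance level gating the per-layer follow-up, default
#'   0.05.
#' @param p_adjust multiple-testing correction method for the per-layer
#'   p-values, default `"none"`.
#' @return An object of class `enrichment_result`: list with `layers`,
#'   `observed`, `expected_prop`, `expected_count`, `chisq` (`statistic`,
#'   `df`, `p_value`), `binomial` (data frame with per-layer `p_value` and
#'   `direction`), `total`, `alpha`. The `binomial` component is `NULL`
#'   when the chi-square test does not reject.
#' @export
enrichment_test <- function(observed, scheme, exclude = "MZ", alpha = 0.05,
                            p_adjust = "none") {
  if (is.data.frame(observed)) {
    cnt <- stats::setNames(observed$count, observed$layer)
  } else cnt <- observed
  if (is.null(names(cnt))) stop("observed counts must be named by layer")
  keep <- setdiff(scheme$layers, exclude)
  obs <- cnt[keep]
  obs[is.na(obs)] <- 0L
  total <- sum(obs)
  if (total < 5) stop("need at least 5 cells to test enrichment")
  p_exp <- scheme$neuron_proportion[match(keep, scheme$layers)]
  p_exp <- p_exp / sum(p_exp)
  exp_cnt <- total * p_exp
  if (any(exp_cnt < 1))
    warning("expected count below 1 in some layer; chi-square approximation",
            " is unreliable (consider an exact multinomial test)")
  cs <- suppressWarnings(stats::chisq.test(obs, p = p_exp))
  binom <- NULL
  if (cs$p.value < alpha) {
    pv <- vapply(seq_along(keep), function(i)
      stats::binom.test(obs[[i]], total, p_exp[i])$p.value, numeric(1))
    pv <- stats::p.adjust(pv, method = p_adjust)
    binom <- data.frame(
      layer = keep, observed = as.integer(obs),
      expected = exp_cnt, p_value = pv,
      direction = ifelse(obs > exp_cnt, "enriched",
                         ifelse(obs < exp_cnt, "depleted", "as expected")),
      significant = pv < alpha)
  }
  structure(list(layers = keep, observed = as.integer(obs),
                 expected_prop = p_exp, expected_count = exp_cnt,
                 chisq = list(statistic = unname(cs$statistic),
                              df = unname(cs$parameter),
                              p_value = cs$p.value),
                 binomial = binom, total = total, alpha = alpha),
            class = "enrichment_result")
}

#' @rdname enrichment_test
#' @param x an `enrichment_result`.
#' @param ... ignored.
#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d cells over %s\n", x$total,
              paste(x$layers, collapse = ", ")))
  cat(sprintf("  chi-square GoF: X2 = %.3f, df = %d, p = %.3g\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  if (!is.null(x$binomial)) {
    print(x$binomial, row.names = FALSE)
  } else cat("  no per-layer follow-up (chi-square not significant at alpha =",
             x$alpha, ")\n")
  invisible(x)
}
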