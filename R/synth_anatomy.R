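#' Specification of a synthetic cortical volume
#'
#' Describes an imaged cortical block by two analytic boundary surfaces —
#' pial on top, lower subplate boundary below — each a full quadratic
#' `z = c0 + c1 x + c2 y + c3 x^2 + c4 x y + c5 y^2` (microns; `z`
#' increases from the pia into the tissue), a lateral extent, a neuron
#' count and per-layer backlabeling probabilities. The pial surface must
#' lie strictly above (smaller `z` than) the subplate surface over the
#' whole lateral domain.
#'
#' @param area area label (`"S1Bf"`, `"M1"`, `"S2"`, ...).
#' @param extent_um lateral extent `c(x, y)` in microns.
#' @param pial_coef,sp_coef length-6 quadratic coefficient vectors of the
#'   two boundary surfaces. Defaults: a gently curved pia at about z = 0
#'   and a subplate boundary about `thickness_um` below it.
#' @param thickness_um mean cortical thickness used by the default
#'   surfaces, default 1000.
#' @param n_neurons number of neurons to place.
#' @param backlabel_prob per-layer backlabeling probabilities (MZ, CP, L5,
#'   L6, SP).
#' @return An object of class `volume_spec`.
#' @export
volume_spec <- function(area = "S1Bf", extent_um = c(1000, 1000),
                        pial_coef = c(0, 0, 0, 2e-5, 0, 1e-5),
                        sp_coef = NULL, thickness_um = 1000,
                        n_neurons = 1000,
                        backlabel_prob = c(0, 0.05, 0.05, 0.05, 0.05)) {
  if (is.null(sp_coef)) sp_coef <- pial_coef + c(thickness_um, 0, 0, 0, 0, 0)
  stopifnot(length(pial_coef) == 6, length(sp_coef) == 6, n_neurons > 0,
            all(backlabel_prob >= 0), all(backlabel_prob <= 1),
            all(extent_um > 0))
  spec <- structure(list(area = area, extent_um = extent_um,
                         pial_coef = pial_coef, sp_coef = sp_coef,
                         thickness_um = thickness_um,
                         n_neurons = as.integer(n_neurons),
                         backlabel_prob = backlabel_prob),
                    class = "volume_spec")
  g <- expand.grid(x = seq(0, extent_um[1], length.out = 21),
                   y = seq(0, extent_um[2], length.out = 21))
  if (any(quad_eval(sp_coef, g$x, g$y) <= quad_eval(pial_coef, g$x, g$y)))
    stop("pial surface must lie strictly above the subplate surface",
         " everywhere on the lateral domain")
  spec
}

quad_eval <- function(cf, x, y)
  cf[1] + cf[2] * x + cf[3] * y + cf[4] * x^2 + cf[5] * x * y + cf[6] * y^2

# Thickness along the inward pial normal at lateral position (x, y), and
# the unit normal itself. Used both to place synthetic cells at an exact
# true depth and as the geometric ground truth for recovery tests.
normal_thickness <- function(spec, x, y) {
  cf <- spec$pial_coef
  gx <- cf[2] + 2 * cf[4] * x + cf[5] * y
  gy <- cf[3] + cf[5] * x + 2 * cf[6] * y
  nrm <- cbind(-gx, -gy, 1) / sqrt(gx^2 + gy^2 + 1)
  z0 <- quad_eval(cf, x, y)
  thick <- vapply(seq_along(x), function(i) {
    f <- function(s) {
      px <- x[i] + s * nrm[i, 1]; py <- y[i] + s * nrm[i, 2]
      (z0[i] + s * nrm[i, 3]) - quad_eval(spec$sp_coef, px, py)
    }
    hi <- spec$thickness_um * 4 + 100
    stats::uniroot(f, c(0, hi), tol = 1e-9)$root
  }, numeric(1))
  list(normal = nrm, pial_z = z0, thickness = thick)
}

#' Generate a synthetic cortical volume with known laminar ground truth
#'
#' Places `n_neurons` somata in the volume: per-layer counts are drawn
#' multinomially from the scheme's expected neuron proportions, each
#' neuron's true normalized depth is uniform within its layer's depth bin,
#' and its 3D position lies on the inward pial normal at a uniform lateral
#' position, at that depth fraction of the local normal thickness. The two
#' boundary surfaces are sampled on a regular lateral grid, optionally with
#' isotropic Gaussian jitter.
#'
#' @param spec a [volume_spec()].
#' @param scheme a [layer_scheme()] giving layer order and expected
#'   proportions.
#' @param seed integer seed.
#' @param grid_n boundary-cloud grid resolution per axis, default 21.
#' @param surface_noise_um SD of Gaussian jitter added to boundary points,
#'   default 0 (noise-free surfaces).
#' @param margin_um lateral margin kept free of cells so that the
#'   nearest-point geometry never leaves the sampled domain, default 100.
#' @return List with `cells` (data frame: `cell_id`, `x`, `y`, `z`,
#'   `true_layer`, `true_depth`), `pial_points`, `sp_points` (data frames
#'   `x`, `y`, `z`).
#' @export
generate_cortical_volume <- function(spec, scheme, seed = NULL, grid_n = 21,
                                     surface_noise_um = 0, margin_um = 100) {
  stopifnot(inherits(spec, "volume_spec"), inherits(scheme, "layer_scheme"))
  with_seed_or_not(seed, {
    n <- spec$n_neurons
    counts <- as.integer(stats::rmultinom(1, n, scheme$neuron_proportion))
    true_layer <- rep(scheme$layers, counts)
    lo <- scheme$cum_depth[match(true_layer, scheme$layers)]
    hi <- scheme$cum_depth[match(true_layer, scheme$layers) + 1]
    depth <- stats::runif(n, lo, hi)
    x <- stats::runif(n, margin_um, spec$extent_um[1] - margin_um)
    y <- stats::runif(n, margin_um, spec$extent_um[2] - margin_um)
    geo <- normal_thickness(spec, x, y)
    d_um <- depth * geo$thickness
    cells <- data.frame(
      cell_id = seq_len(n),
      x = x + d_um * geo$normal[, 1],
      y = y + d_um * geo$normal[, 2],
      z = geo$pial_z + d_um * geo$normal[, 3],
      true_layer = true_layer, true_depth = depth)
    g <- expand.grid(x = seq(0, spec$extent_um[1], length.out = grid_n),
                     y = seq(0, spec$extent_um[2], length.out = grid_n))
    jit <- function(m) if (surface_noise_um > 0)
      m + stats::rnorm(length(m), sd = surface_noise_um) else m
    pial <- data.frame(x = jit(g$x), y = jit(g$y),
                       z = jit(quad_eval(spec$pial_coef, g$x, g$y)))
    sp <- data.frame(x = jit(g$x), y = jit(g$y),
                     z = jit(quad_eval(spec$sp_coef, g$x, g$y)))
    list(cells = cells, pial_points = pial, sp_points = sp)
  })
}

#' Flag backlabeled cells by per-layer Bernoulli draws
#'
#' Emulates retrograde labeling: each neuron is flagged backlabeled with
#' its layer's probability, independently across cells.
#'
#' @param cells data frame with a `true_layer` column (from
#'   [generate_cortical_volume()]).
#' @param probs named per-layer probabilities, or an unnamed vector in the
#'   scheme's layer order.
#' @param scheme a [layer_scheme()] (needed when `probs` is unnamed).
#' @param seed integer seed.
#' @return `cells` with an added integer `backlabeled` column (0/1).
#' @export
sample_backlabeled <- function(cells, probs, scheme = NULL, seed = NULL) {
  if (is.null(names(probs))) {
    if (is.null(scheme)) stop("unnamed `probs` needs a `scheme` for layer order")
    if (length(probs) != length(scheme$layers))
      stop("probability vector length must equal the number of layers")
    names(probs) <- scheme$layers
  }
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (!all(unique(cells$true_layer) %in% names(probs)))
    stop("missing probability for some layer")
  with_seed_or_not(seed, {
    p <- probs[cells$true_layer]
    cells$backlabeled <- as.integer(stats::runif(nrow(cells)) < p)
    cells
  })
}

#' Write / read synthetic-volume tables
#'
#' Cell clouds are CSVs with columns `cell_id, x_um, y_um, z_um, true_layer,
#' backlabeled`; boundary clouds are CSVs with `surface` (`pial` or `sp`),
#' `x_um, y_um, z_um`. A sidecar JSON stores all generator parameters.
#'
#' @param volume result of [generate_cortical_volume()] (with or without a
#'   `backlabeled` column added).
#' @param cells_path,surfaces_path,sidecar_path output files; `NULL` skips.
#' @param params list of generator parameters for the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_volume_csv <- function(volume, cells_path, surfaces_path,
                             sidecar_path = NULL, params = list()) {
  cells <- volume$cells
  df <- data.frame(cell_id = cells$cell_id, x_um = cells$x, y_um = cells$y,
                   z_um = cells$z, true_layer = cells$true_layer,
                   backlabeled = if ("backlabeled" %in% names(cells))
                     cells$backlabeled else NA_integer_)
  utils::write.csv(df, cells_path, row.names = FALSE, quote = FALSE)
  sf <- rbind(data.frame(surface = "pial", x_um = volume$pial_points$x,
                         y_um = volume$pial_points$y, z_um = volume$pial_points$z),
              data.frame(surface = "sp", x_um = volume$sp_points$x,
                         y_um = volume$sp_points$y, z_um = volume$sp_points$z))
  utils::write.csv(sf, surfaces_path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar_path))
    jsonlite::write_json(params, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(cells_path, surfaces_path, sidecar_path))
}

#' @rdname write_volume_csv
#' @export
read_volume_csv <- function(cells_path, surfaces_path) {
  cs <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  sf <- utils::read.csv(surfaces_path, stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = cs$cell_id, x = cs$x_um, y = cs$y_um,
                      z = cs$z_um, true_layer = cs$true_layer,
                      backlabeled = cs$backlabeled)
  list(cells = cells,
       pial_points = with(sf[sf$surface == "pial", ],
                          data.frame(x = x_um, y = y_um, z = z_um)),
       sp_points = with(sf[sf$surface == "sp", ],
                        data.frame(x = x_um, y = y_um, z = z_um)))
}
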