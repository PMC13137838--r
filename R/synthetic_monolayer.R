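# Synthetic confluent-monolayer generator. Cells are an anisotropic Voronoi
# tessellation of jittered-grid seed points; the junction marker is rendered
# as a Gaussian cross-profile band along the inter-cell borders, with optional
# Poisson shot noise and Gaussian read noise. Every output carries exact
# ground truth (labels, border skeleton, per-cell morphology).

#' Specification of a synthetic monolayer image
#'
#' Defines the geometry, optics and noise of a simulated junction-marker
#' (e.g. VE-cadherin) fluorescence image of a confluent endothelial
#' monolayer. Either `n_cells` or `density_cells_per_cm2` may be given; the
#' other is derived from the field area. The default density corresponds to
#' a confluent HUVEC culture (9e4 cells/cm^2).
#'
#' @param field_size_px integer pair, image size (rows, cols).
#' @param pixel_size_um pixel size, micrometres per pixel. The default
#'   (0.53 um/px on a 256 px field) reproduces a 135 um x 135 um high-
#'   magnification field of view.
#' @param n_cells number of cells; derived from the density when `NULL`.
#' @param density_cells_per_cm2 target cell density; derived from `n_cells`
#'   when that is given.
#' @param mean_aspect_ratio target mean cell elongation (>= 1).
#' @param orientation_mean_deg mean cell orientation, degrees CCW from the
#'   +x (column) axis, in [-90, 90).
#' @param orientation_concentration concentration of cell orientations about
#'   the mean; 0 = isotropic (uniform orientations), larger = tighter
#'   (angular SD approximately 45/concentration degrees).
#' @param junction_amplitude peak intensity of the junctional band (a.u.).
#' @param junction_sigma_px Gaussian cross-profile SD of the band, pixels.
#' @param background_level cytoplasmic background intensity (a.u.).
#' @param poisson_gain photons-per-count gain of the shot-noise model; 0
#'   disables shot noise.
#' @param gaussian_read_sigma SD of additive read noise (a.u.); 0 disables.
#' @param seed integer seed; every generator call is deterministic given the
#'   spec (including its seed).
#'
#' @return an object of class `monolayer_spec`.
#' @export
monolayer_spec <- function(field_size_px = c(256L, 256L),
                           pixel_size_um = 0.53,
                           n_cells = NULL,
                           density_cells_per_cm2 = 9e4,
                           mean_aspect_ratio = 1,
                           orientation_mean_deg = 0,
                           orientation_concentration = 0,
                           junction_amplitude = 100,
                           junction_sigma_px = 1.5,
                           background_level = 2,
                           poisson_gain = 1,
                           gaussian_read_sigma = 1,
                           seed = 1L) {
  stopifnot(length(field_size_px) == 2, all(field_size_px >= 16))
  check_positive(pixel_size_um, "pixel_size_um")
  if (mean_aspect_ratio < 1) stop("mean_aspect_ratio must be >= 1",
                                  call. = FALSE)
  check_nonneg(orientation_concentration, "orientation_concentration")
  check_positive(junction_amplitude, "junction_amplitude")
  check_positive(junction_sigma_px, "junction_sigma_px")
  check_nonneg(background_level, "background_level")
  check_nonneg(poisson_gain, "poisson_gain")
  check_nonneg(gaussian_read_sigma, "gaussian_read_sigma")
  area_cm2 <- prod(field_size_px) * pixel_size_um^2 * 1e-8
  if (is.null(n_cells)) {
    check_positive(density_cells_per_cm2, "density_cells_per_cm2")
    n_cells <- as.integer(round(density_cells_per_cm2 * area_cm2))
  } else {
    n_cells <- as.integer(n_cells)
    implied <- n_cells / area_cm2
    if (!missing(density_cells_per_cm2) &&
        abs(density_cells_per_cm2 * area_cm2 - n_cells) > 1)
      stop("density infeasible: n_cells and density_cells_per_cm2 disagree ",
           "by more than one cell over this field", call. = FALSE)
    density_cells_per_cm2 <- implied
  }
  if (n_cells < 2) stop("degenerate tessellation: need at least 2 cells",
                        call. = FALSE)
  if (n_cells > prod(field_size_px) / 16)
    stop("density infeasible: field too small for requested cell count",
         call. = FALSE)
  structure(list(field_size_px = as.integer(field_size_px),
                 pixel_size_um = pixel_size_um, n_cells = n_cells,
                 density_cells_per_cm2 = density_cells_per_cm2,
                 mean_aspect_ratio = mean_aspect_ratio,
                 orientation_mean_deg = wrap_angle_deg(orientation_mean_deg),
                 orientation_concentration = orientation_concentration,
                 junction_amplitude = junction_amplitude,
                 junction_sigma_px = junction_sigma_px,
                 background_level = background_level,
                 poisson_gain = poisson_gain,
                 gaussian_read_sigma = gaussian_read_sigma,
                 seed = as.integer(seed)),
            class = "monolayer_spec")
}

#' @export
print.monolayer_spec <- function(x, ...) {
  cat(sprintf(
    "<monolayer_spec> %d x %d px (%.3g um/px), %d cells (%.3g cells/cm^2)\n",
    x$field_size_px[1], x$field_size_px[2], x$pixel_size_um, x$n_cells,
    x$density_cells_per_cm2))
  cat(sprintf("  AR %.2f, orientation %.1f deg (conc %.2f), seed %d\n",
              x$mean_aspect_ratio, x$orientation_mean_deg,
              x$orientation_concentration, x$seed))
  invisible(x)
}

# Jittered-grid seed points for the tessellation, n x 2 (row, col), plus
# per-cell orientations (deg). Draws from the current RNG stream.
sample_seed_points <- function(spec) {
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  n <- spec$n_cells
  # grid dimensions proportional to the field aspect
  gr <- max(1L, as.integer(round(sqrt(n * nr / nc))))
  gc <- as.integer(ceiling(n / gr))
  while (gr * gc < n) gc <- gc + 1L
  cy <- (seq_len(gr) - 0.5) * nr / gr
  cx <- (seq_len(gc) - 0.5) * nc / gc
  pts <- as.matrix(expand.grid(row = cy, col = cx))
  jit_r <- stats::runif(nrow(pts), -0.35, 0.35) * nr / gr
  jit_c <- stats::runif(nrow(pts), -0.35, 0.35) * nc / gc
  pts <- pts + cbind(jit_r, jit_c)
  keep <- sample.int(nrow(pts), n)
  pts <- pts[keep, , drop = FALSE]
  pts[, 1] <- pmin(pmax(pts[, 1], 1), nr)
  pts[, 2] <- pmin(pmax(pts[, 2], 1), nc)
  theta <- if (spec$orientation_concentration <= 0)
    stats::runif(n, -90, 90)
  else
    wrap_angle_deg(stats::rnorm(n, spec$orientation_mean_deg,
                                45 / spec$orientation_concentration))
  list(points = pts, theta_deg = theta)
}

# Anisotropic Voronoi assignment: each seed carries its own elongation axis;
# distances are measured with the along-axis component shrunk by the stretch
# factor, which elongates cells along their axis by ~that factor.
voronoi_labels <- function(field_size_px, points, theta_deg, stretch) {
  nr <- field_size_px[1]; nc <- field_size_px[2]
  px_row <- matrix(seq_len(nr), nr, nc)
  px_col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  labels <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(points))) {
    dr <- px_row - points[i, 1]
    dc <- px_col - points[i, 2]
    dirv <- dir_to_rowcol(theta_deg[i])
    u <- (dr * dirv["drow"] + dc * dirv["dcol"]) / stretch
    v <- dr * dirv["dcol"] - dc * dirv["drow"]
    d2 <- u * u + v * v
    upd <- d2 < best
    best[upd] <- d2[upd]
    labels[upd] <- i
  }
  labels
}

# Render a junction-band image from a border mask: Gaussian cross-profile of
# the Euclidean distance to the nearest border pixel, plus background.
render_junction_band <- function(border, amplitude, sigma_px, background) {
  d <- EBImage::distmap(matrix(as.numeric(!border), nrow(border)),
                        metric = "euclidean")
  background + amplitude * exp(-d^2 / (2 * sigma_px^2))
}

apply_noise <- function(img, poisson_gain, read_sigma) {
  if (poisson_gain > 0)
    img <- matrix(stats::rpois(length(img), img / poisson_gain) * poisson_gain,
                  nrow(img))
  if (read_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, read_sigma), nrow(img))
  pmax(img, 0)
}

# Per-cell morphology table for a full label image (no 0 background).
ground_truth_morphology <- function(labels, pixel_size_um) {
  ids <- sort(unique(as.vector(labels)))
  nr <- nrow(labels); nc <- ncol(labels)
  rows <- lapply(ids, function(id) {
    mask <- labels == id
    me <- moment_ellipse(mask)
    on_edge <- any(mask[1, ]) || any(mask[nr, ]) || any(mask[, 1]) ||
      any(mask[, nc])
    data.frame(cell_id = id,
               area_um2 = sum(mask) * pixel_size_um^2,
               perimeter_um = chain_perimeter(mask) * pixel_size_um,
               centroid_row_um = me$centroid["row"] * pixel_size_um,
               centroid_col_um = me$centroid["col"] * pixel_size_um,
               aspect_ratio = me$ar,
               orientation_deg = me$orientation_deg,
               edge_cell = on_edge)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic monolayer frame with ground truth
#'
#' Renders one junction-marker frame from a [monolayer_spec()]: seeds an
#' anisotropic Voronoi tessellation, draws the junctional band as a Gaussian
#' cross-profile along the inter-cell borders, applies the noise model, and
#' returns the exact ground truth alongside the image. Deterministic: the
#' same spec (same seed) yields bit-identical output.
#'
#' @param spec a [monolayer_spec()].
#' @return a list with elements `series` (an [image_series] with one frame,
#'   channel `"junction"`) and `ground_truth` (list: `label_stack`,
#'   `border_stack`, `per_cell_morphology`, `per_frame_border_displacement_um`,
#'   `track_table`).
#' @export
generate_monolayer <- function(spec) {
  stopifnot(inherits(spec, "monolayer_spec"))
  with_stream(spec$seed, "generate_monolayer", {
    sp <- sample_seed_points(spec)
    labels <- voronoi_labels(spec$field_size_px, sp$points, sp$theta_deg,
                             spec$mean_aspect_ratio)
    border <- label_boundaries(labels)
    img <- render_junction_band(border, spec$junction_amplitude,
                                spec$junction_sigma_px, spec$background_level)
    img <- apply_noise(img, spec$poisson_gain, spec$gaussian_read_sigma)
    morph <- ground_truth_morphology(labels, spec$pixel_size_um)
    nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
    gt <- list(
      label_stack = array(labels, c(1L, nr, nc)),
      border_stack = array(border, c(1L, nr, nc)),
      per_cell_morphology = morph,
      per_frame_border_displacement_um = numeric(0),
      track_table = data.frame(
        track_id = morph$cell_id, frame = 1L,
        x_um = morph$centroid_col_um, y_um = morph$centroid_row_um))
    list(series = image_series(img, pixel_size_um = spec$pixel_size_um,
                               channel_names = "junction"),
         ground_truth = gt)
  })
}
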