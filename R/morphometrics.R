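# Per-cell morphometrics and intensity statistics: area, perimeter,
# ellipse-fit aspect ratio and orientation from second central moments,
# the junctional-band concentration statistic, per-cell total intensity,
# and monolayer density.

#' Per-cell morphology
#'
#' Area (pixel count x pixel area), perimeter (calibrated boundary chain
#' length), aspect ratio and orientation from the eigen-structure of the
#' second central moments of the filled cell label (AR =
#' sqrt(lambda_max / lambda_min), the major/minor axis ratio of the fitted
#' ellipse).
#'
#' @param seg a [segmentation_result()].
#' @param pixel_size_um pixel size (um/px).
#' @param include_edge_cells include cells touching the field edge; default
#'   `FALSE` because truncated geometry biases perimeter and aspect ratio.
#' @return data.frame: `cell_id`, `area_um2`, `perimeter_um`,
#'   `centroid_row_um`, `centroid_col_um`, `aspect_ratio`,
#'   `orientation_deg` (degrees CCW from +x, in [-90, 90)).
#' @export
cell_morphology <- function(seg, pixel_size_um = 1,
                            include_edge_cells = FALSE) {
  stopifnot(inherits(seg, "segmentation_result"))
  check_positive(pixel_size_um, "pixel_size_um")
  ids <- cell_ids(seg, interior_only = !include_edge_cells)
  if (length(ids) == 0)
    stop("no interior cells", call. = FALSE)
  rows <- lapply(ids, function(id) {
    mask <- seg$full_labels == id
    me <- moment_ellipse(mask)
    data.frame(cell_id = id,
               area_um2 = sum(mask) * pixel_size_um^2,
               perimeter_um = chain_perimeter(mask) * pixel_size_um,
               centroid_row_um = unname(me$centroid["row"]) * pixel_size_um,
               centroid_col_um = unname(me$centroid["col"]) * pixel_size_um,
               aspect_ratio = me$ar,
               orientation_deg = me$orientation_deg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Junctional-band concentration statistic
#'
#' The junctional ROI is the band extending `w_px` pixels on each side of
#' the segmentation line (border skeleton). The statistic is the integrated
#' intensity inside the ROI divided by the total cell border length, i.e. a
#' relative concentration of the marker at the junction.
#'
#' @param frame intensity matrix (same shape as the segmentation), or an
#'   [image_series].
#' @param seg a [segmentation_result()].
#' @param w_px band half-width, default 5 (an 11-px-wide ROI).
#' @param per_cell if `TRUE`, one row per (interior) cell, each using the
#'   skeleton pixels bounding that cell; otherwise one field-level row.
#' @param length_method `"pixels"` (skeleton pixel count, default) or
#'   `"chain"` (diagonal steps weighted sqrt(2)).
#' @param pixel_size_um optional; when given, `border_length` is also
#'   reported in um.
#' @return data.frame: `cell_id` (`NA` for field level), `band_halfwidth_px`,
#'   `integrated_intensity`, `border_length_px`, `relative_concentration`
#'   (= integrated intensity / border length), and `border_length_um` when
#'   calibrated.
#' @export
junctional_concentration <- function(frame, seg, w_px = 5, per_cell = FALSE,
                                     length_method = c("pixels", "chain"),
                                     pixel_size_um = NULL) {
  if (inherits(frame, "image_series")) frame <- get_frame(frame, 1, 1)
  length_method <- match.arg(length_method)
  stopifnot(inherits(seg, "segmentation_result"),
            all(dim(frame) == dim(seg$labels)))
  one <- function(cell_id) {
    skel <- if (is.na(cell_id)) seg$border_skeleton else
      cell_border_pixels(seg, cell_id)
    if (!any(skel)) stop("no border", call. = FALSE)
    bm <- if (is.na(cell_id)) band_mask(seg, w_px) else
      band_mask(seg, w_px, cell_id)
    len <- skeleton_length(skel, length_method)
    out <- data.frame(cell_id = cell_id, band_halfwidth_px = w_px,
                      integrated_intensity = sum(frame[bm]),
                      border_length_px = len,
                      relative_concentration = sum(frame[bm]) / len)
    if (!is.null(pixel_size_um))
      out$border_length_um <- len * pixel_size_um
    out
  }
  ids <- if (per_cell) cell_ids(seg, interior_only = TRUE) else NA_integer_
  out <- do.call(rbind, lapply(ids, one))
  rownames(out) <- NULL
  out
}

# Border length of a skeleton pixel set. "pixels": count (exact for the
# axis-aligned analytic case); "chain": edges of the 8-adjacency graph
# weighted 1 / sqrt(2), plus one (so a straight N-px line measures N).
skeleton_length <- function(skel, method = c("pixels", "chain")) {
  method <- match.arg(method)
  if (method == "pixels") return(sum(skel))
  nr <- nrow(skel); nc <- ncol(skel)
  straight <- sum(skel[-nr, ] & skel[-1, ]) + sum(skel[, -nc] & skel[, -1])
  diag <- sum(skel[-nr, -nc] & skel[-1, -1]) +
    sum(skel[-nr, -1] & skel[-1, -nc])
  straight + sqrt(2) * diag + 1
}

#' Per-cell total intensity paired with perimeter
#'
#' Sums the intensity of a channel over each cell label region and pairs it
#' with the cell perimeter, as in per-cell G-actin (DNase I) quantification.
#'
#' @param frame intensity matrix or [image_series].
#' @param seg a [segmentation_result()].
#' @param channel channel name recorded in the output.
#' @param pixel_size_um pixel size for the paired perimeter.
#' @param include_edge_cells include edge-touching cells; default `FALSE`.
#' @return data.frame: `cell_id`, `channel`, `total_intensity`,
#'   `perimeter_um`.
#' @export
cell_intensity <- function(frame, seg, channel = "ch1", pixel_size_um = 1,
                           include_edge_cells = FALSE) {
  if (inherits(frame, "image_series")) frame <- get_frame(frame, 1, 1)
  stopifnot(all(dim(frame) == dim(seg$labels)))
  morph <- cell_morphology(seg, pixel_size_um,
                           include_edge_cells = include_edge_cells)
  tot <- vapply(morph$cell_id,
                function(id) sum(frame[seg$full_labels == id]), numeric(1))
  data.frame(cell_id = morph$cell_id, channel = channel,
             total_intensity = tot, perimeter_um = morph$perimeter_um)
}

#' Monolayer density in cells per square centimetre
#'
#' Cells fully inside the field count 1; cells truncated by the field edge
#' count 1/2 (the standard edge correction for counting frames).
#'
#' @param seg a [segmentation_result()], or `NULL` for an empty field.
#' @param pixel_size_um pixel size (um/px).
#' @param field_size_px field size, needed only when `seg` is `NULL`.
#' @return density, cells/cm^2 (0 for an empty field).
#' @export
monolayer_density <- function(seg, pixel_size_um, field_size_px = NULL) {
  if (is.null(seg)) return(0)
  stopifnot(inherits(seg, "segmentation_result"))
  check_positive(pixel_size_um, "pixel_size_um")
  n_all <- max(seg$full_labels)
  n_edge <- length(seg$edge_cells)
  area_cm2 <- prod(dim(seg$labels)) * pixel_size_um^2 * 1e-8
  ((n_all - n_edge) + 0.5 * n_edge) / area_cm2
}
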