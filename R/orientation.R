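# Structure-tensor orientation analysis: per-pixel orientation and energy
# fields and the image-level "apparent coherency" in [0, 1] with its
# dominant direction, from single frames or time-lapse series.

#' Structure tensor of a frame
#'
#' Gaussian-derivative gradients (SD `gradient_sigma_px`), per-pixel outer
#' products, then Gaussian window smoothing (SD `window_sigma_px`).
#' Reflective padding at the image edge.
#'
#' @param frame intensity matrix (>= 16 x 16) or an [image_series].
#' @param gradient_sigma_px gradient scale, px; default 1.
#' @param window_sigma_px local-window scale, px; default 4.
#' @return list of class `structure_tensor` with matrices `jxx`, `jxy`,
#'   `jyy` (x = column axis, y = mathematical y = -row), and the two sigmas.
#' @export
structure_tensor <- function(frame, gradient_sigma_px = 1,
                             window_sigma_px = 4) {
  if (inherits(frame, "image_series")) frame <- get_frame(frame, 1, 1)
  stopifnot(is.matrix(frame))
  if (any(dim(frame) < 16)) stop("frame too small", call. = FALSE)
  if (window_sigma_px <= 0) stop("invalid window", call. = FALSE)
  check_positive(gradient_sigma_px, "gradient_sigma_px")
  g0 <- gauss_kernel_1d(gradient_sigma_px, 0)
  g1 <- gauss_kernel_1d(gradient_sigma_px, 1)
  gx <- conv_sep(frame, g0, g1)        # d/d(col)
  gr <- conv_sep(frame, g1, g0)        # d/d(row)
  gy <- -gr                            # math y axis points up
  gw <- gauss_kernel_1d(window_sigma_px, 0)
  structure(list(jxx = conv_sep(gx * gx, gw, gw),
                 jxy = conv_sep(gx * gy, gw, gw),
                 jyy = conv_sep(gy * gy, gw, gw),
                 gradient_sigma_px = gradient_sigma_px,
                 window_sigma_px = window_sigma_px),
            class = "structure_tensor")
}

# Orientation (deg, [-90, 90)) of the structure (minor eigenvector of the
# tensor = along the stripes); defined where the tensor is non-degenerate.
tensor_orientation_deg <- function(jxx, jxy, jyy) {
  # major eigenvector angle = 0.5 atan2(2 jxy, jxx - jyy); structure runs
  # perpendicular to the dominant gradient direction
  wrap_angle_deg(0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90)
}

#' Apparent coherency and dominant direction
#'
#' Image-level structure tensor = sum of the per-pixel tensors (energy
#' weighting; a margin of 3 window sigmas at the edge is excluded).
#' Coherency = (lambda1 - lambda2) / (lambda1 + lambda2) of that summed
#' tensor, in [0, 1]: 1 = strong uniform alignment along one dominant
#' direction, 0 = isotropic / random orientation (and 0 by convention for a
#' zero tensor, e.g. a constant image). The dominant direction is the
#' orientation of the structures (perpendicular to the principal gradient
#' eigenvector), degrees CCW from +x in [-90, 90).
#'
#' @param frame intensity matrix, [image_series] (all frames analyzed), or
#'   3D array (frames x rows x cols).
#' @param gradient_sigma_px,window_sigma_px see [structure_tensor()].
#' @param aggregation `"tensor_sum"` (default: eigen-analysis of the summed
#'   tensor) or `"mean_pixel"` (mean of per-pixel coherencies, energy
#'   weighted).
#' @return for a single frame, a list of class `orientation_analysis` with
#'   `coherency`, `dominant_direction_deg` (`NA` when coherency is 0),
#'   `energy`, `orientation_field_deg`, `energy_field`, and the parameters;
#'   for a series, a data.frame time course (`frame`, `coherency`,
#'   `dominant_direction_deg`, `energy`).
#' @export
apparent_coherency <- function(frame, gradient_sigma_px = 1,
                               window_sigma_px = 4,
                               aggregation = c("tensor_sum", "mean_pixel")) {
  aggregation <- match.arg(aggregation)
  if (inherits(frame, "image_series") || (is.array(frame) &&
                                          length(dim(frame)) == 3)) {
    arr <- if (inherits(frame, "image_series")) frame$data[[1]] else frame
    rows <- lapply(seq_len(dim(arr)[1]), function(k) {
      a <- apparent_coherency(matrix(arr[k, , ], dim(arr)[2], dim(arr)[3]),
                              gradient_sigma_px, window_sigma_px, aggregation)
      data.frame(frame = k, coherency = a$coherency,
                 dominant_direction_deg = a$dominant_direction_deg,
                 energy = a$energy)
    })
    return(do.call(rbind, rows))
  }
  st <- structure_tensor(frame, gradient_sigma_px, window_sigma_px)
  margin <- as.integer(ceiling(3 * window_sigma_px))
  nr <- nrow(frame); nc <- ncol(frame)
  ri <- (margin + 1):(nr - margin); ci <- (margin + 1):(nc - margin)
  if (length(ri) < 1 || length(ci) < 1) { ri <- seq_len(nr); ci <- seq_len(nc) }
  jxx <- st$jxx[ri, ci]; jxy <- st$jxy[ri, ci]; jyy <- st$jyy[ri, ci]
  energy_field <- jxx + jyy
  orient_field <- tensor_orientation_deg(jxx, jxy, jyy)
  # zero-tensor convention: a constant image (or pure floating-point
  # residue of one) carries no orientation signal
  scale <- diff(range(frame))
  if (scale == 0)
    return(structure(list(coherency = 0, dominant_direction_deg = NA_real_,
                          energy = 0,
                          orientation_field_deg = orient_field * NA,
                          energy_field = energy_field * 0,
                          gradient_sigma_px = gradient_sigma_px,
                          window_sigma_px = window_sigma_px,
                          aggregation = aggregation),
                     class = "orientation_analysis"))
  tr_eps <- length(energy_field) * (1e-10 * scale)^2
  if (aggregation == "tensor_sum") {
    sxx <- sum(jxx); sxy <- sum(jxy); syy <- sum(jyy)
    tr <- sxx + syy
    if (tr <= tr_eps) {
      coh <- 0; dom <- NA_real_
    } else {
      disc <- sqrt((sxx - syy)^2 + 4 * sxy^2)
      coh <- disc / tr
      dom <- if (coh == 0) NA_real_ else tensor_orientation_deg(sxx, sxy, syy)
    }
  } else {
    tr <- energy_field
    disc <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
    cfield <- ifelse(tr > tr_eps / length(tr), disc / tr, 0)
    coh <- if (sum(tr) <= tr_eps) 0 else sum(cfield * tr) / sum(tr)
    dom <- if (sum(tr) <= tr_eps) NA_real_ else
      tensor_orientation_deg(sum(jxx), sum(jxy), sum(jyy))
  }
  structure(list(coherency = coh, dominant_direction_deg = dom,
                 energy = sum(energy_field),
                 orientation_field_deg = orient_field,
                 energy_field = energy_field,
                 gradient_sigma_px = gradient_sigma_px,
                 window_sigma_px = window_sigma_px,
                 aggregation = aggregation),
            class = "orientation_analysis")
}

#' @export
print.orientation_analysis <- function(x, ...) {
  cat(sprintf("<orientation_analysis> coherency %.3f", x$coherency))
  if (!is.na(x$dominant_direction_deg))
    cat(sprintf(", dominant direction %.1f deg", x$dominant_direction_deg))
  cat(sprintf(" (grad sigma %g px, window sigma %g px)\n",
              x$gradient_sigma_px, x$window_sigma_px))
  invisible(x)
}
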