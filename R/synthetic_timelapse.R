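# Synthetic time-lapse of a monolayer under a programmed border motion.
# Motion acts on the tessellation seed points; per-frame steps have exactly
# the programmed magnitude, so the emitted ground-truth displacement is the
# program itself, not a noisy realisation of it.

#' Border motion program for synthetic time-lapses
#'
#' @param kind one of `"static"`, `"rigid_translation"`, `"border_jitter"`,
#'   `"intermediate_state"`. `static` keeps the tessellation fixed (only
#'   noise is regenerated per frame); `rigid_translation` moves all cells
#'   together; `border_jitter` moves each cell seed by a fixed-magnitude
#'   step in a random direction every frame; `intermediate_state` is
#'   `border_jitter` with the step magnitude reduced by
#'   `intermediate_reduction_fraction` inside a programmed frame window,
#'   emulating the transient shear-onset state in which junctional
#'   displacement drops by about 20%.
#' @param speed_um_per_min translation speed (rigid translation), um/min.
#' @param direction_deg translation direction, degrees CCW from +x.
#' @param jitter_amplitude_um per-frame step magnitude of each cell seed, um.
#' @param jitter_axis_deg axis of the oscillatory jitter, degrees CCW from
#'   +x; `NA` (default) draws a random axis per time-lapse.
#' @param intermediate_onset_frame,intermediate_release_frame first and last
#'   frame (inclusive) of the reduced-displacement window.
#' @param intermediate_reduction_fraction fractional reduction of the step
#'   magnitude inside the window; default 0.20.
#' @return an object of class `motion_program`.
#' @export
motion_program <- function(kind = c("static", "rigid_translation",
                                    "border_jitter", "intermediate_state"),
                           speed_um_per_min = 0,
                           direction_deg = 0,
                           jitter_amplitude_um = 0,
                           jitter_axis_deg = NA_real_,
                           intermediate_onset_frame = NA_integer_,
                           intermediate_release_frame = NA_integer_,
                           intermediate_reduction_fraction = 0.20) {
  kind <- match.arg(kind)
  check_nonneg(speed_um_per_min, "speed_um_per_min")
  check_nonneg(jitter_amplitude_um, "jitter_amplitude_um")
  if (intermediate_reduction_fraction < 0 || intermediate_reduction_fraction > 1)
    stop("intermediate_reduction_fraction must be in [0, 1]", call. = FALSE)
  if (kind == "intermediate_state" &&
      (is.na(intermediate_onset_frame) || is.na(intermediate_release_frame)))
    stop("intermediate_state needs onset and release frames", call. = FALSE)
  structure(list(kind = kind, speed_um_per_min = speed_um_per_min,
                 direction_deg = direction_deg,
                 jitter_amplitude_um = jitter_amplitude_um,
                 jitter_axis_deg = jitter_axis_deg,
                 intermediate_onset_frame = as.integer(intermediate_onset_frame),
                 intermediate_release_frame =
                   as.integer(intermediate_release_frame),
                 intermediate_reduction_fraction =
                   intermediate_reduction_fraction),
            class = "motion_program")
}

#' Generate a synthetic monolayer time-lapse with ground truth
#'
#' Frames share cell identity (each label is the same cell in every frame).
#' The per-transition true border displacement (um, between frame t and
#' t+1) is recorded in the ground truth; it is 0 everywhere for a static
#' program and exactly the programmed step magnitude otherwise.
#'
#' @param spec a [monolayer_spec()].
#' @param program a [motion_program()].
#' @param n_frames number of frames (>= 3).
#' @param frame_interval_min frame interval, minutes.
#' @return as [generate_monolayer()], with multi-frame stacks; ground truth
#'   additionally carries `per_frame_border_displacement_um` (length
#'   `n_frames - 1`) and a full `track_table`.
#' @export
generate_timelapse <- function(spec, program, n_frames,
                               frame_interval_min = 1) {
  stopifnot(inherits(spec, "monolayer_spec"),
            inherits(program, "motion_program"))
  if (n_frames < 3) stop("need at least 3 frames", call. = FALSE)
  if (frame_interval_min <= 0) stop("invalid calibration", call. = FALSE)
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  with_stream(spec$seed, "generate_timelapse", {
    sp <- sample_seed_points(spec)
    pts <- sp$points
    n <- spec$n_cells
    osc_axis <- if (is.na(program$jitter_axis_deg %||% NA_real_))
      stats::runif(1, 0, 2 * pi)
    else program$jitter_axis_deg * pi / 180
    labels <- array(0L, c(n_frames, nr, nc))
    borders <- array(FALSE, c(n_frames, nr, nc))
    frames <- array(0, c(n_frames, nr, nc))
    disp_um <- numeric(n_frames - 1L)
    tracks <- vector("list", n_frames)
    step_px_of <- function(t) {
      # step applied between frame t-1 and frame t, in px, n x 2 (row, col)
      if (program$kind == "static") return(matrix(0, n, 2))
      if (program$kind == "rigid_translation") {
        mag_px <- program$speed_um_per_min * frame_interval_min /
          spec$pixel_size_um
        dirv <- dir_to_rowcol(program$direction_deg)
        return(matrix(mag_px * dirv, n, 2, byrow = TRUE))
      }
      amp_um <- program$jitter_amplitude_um
      if (program$kind == "intermediate_state" &&
          t > program$intermediate_onset_frame &&
          t <= program$intermediate_release_frame)
        amp_um <- amp_um * (1 - program$intermediate_reduction_fraction)
      # oscillatory collective jitter: fixed-magnitude steps along one
      # random axis (drawn once per time-lapse), alternating in sign.
      # Borders translate coherently between two configurations, so every
      # transition has identical geometry: the per-frame true displacement
      # is exactly the programmed amplitude, a programmed fractional
      # reduction maps linearly onto measured rates, and cells do not
      # drift out of the field.
      sgn <- if (t %% 2 == 0) 1 else -1
      amp_px <- amp_um / spec$pixel_size_um
      matrix(sgn * c(amp_px * sin(osc_axis), amp_px * cos(osc_axis)),
             n, 2, byrow = TRUE)
    }
    for (t in seq_len(n_frames)) {
      if (t > 1) {
        st <- step_px_of(t)
        pts <- pts + st
        pts[, 1] <- pmin(pmax(pts[, 1], 1), nr)
        pts[, 2] <- pmin(pmax(pts[, 2], 1), nc)
        disp_um[t - 1L] <- mean(sqrt(rowSums(st^2))) * spec$pixel_size_um
      }
      lab <- voronoi_labels(spec$field_size_px, pts, sp$theta_deg,
                            spec$mean_aspect_ratio)
      bor <- label_boundaries(lab)
      img <- render_junction_band(bor, spec$junction_amplitude,
                                  spec$junction_sigma_px,
                                  spec$background_level)
      frames[t, , ] <- apply_noise(img, spec$poisson_gain,
                                   spec$gaussian_read_sigma)
      labels[t, , ] <- lab
      borders[t, , ] <- bor
      cent <- vapply(seq_len(n), function(i) {
        w <- which(lab == i, arr.ind = TRUE)
        if (nrow(w) == 0) c(NA_real_, NA_real_) else colMeans(w)
      }, numeric(2))
      tracks[[t]] <- data.frame(track_id = seq_len(n), frame = t,
                                x_um = cent[2, ] * spec$pixel_size_um,
                                y_um = cent[1, ] * spec$pixel_size_um)
    }
    gt <- list(label_stack = labels, border_stack = borders,
               per_cell_morphology =
                 ground_truth_morphology(matrix(labels[1, , ], nr, nc),
                                         spec$pixel_size_um),
               per_frame_border_displacement_um = disp_um,
               track_table = do.call(rbind, tracks),
               motion_program = program)
    list(series = image_series(frames, pixel_size_um = spec$pixel_size_um,
                               frame_interval = frame_interval_min,
                               frame_interval_unit = "min",
                               channel_names = "junction"),
         ground_truth = gt)
  })
}
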