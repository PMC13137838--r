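# Synthetic recoil curves, oriented textures and TER series: seeded fixtures
# with known ground truth for the recoil, orientation and dynamics stages.

#' Specification of a synthetic post-ablation recoil curve
#'
#' The noiseless curve follows the Kelvin-Voigt recoil model
#' L(t) = D (1 - exp(-t / tau)).
#'
#' @param D_um plateau displacement D (um), the force/elasticity ratio.
#' @param tau_s relaxation time tau (s); larger tau = lower pre-cut tension.
#' @param dt_s sampling interval (s); default 0.2 s (images every 200 ms).
#' @param duration_s total duration (s); must be >= 3 * dt_s.
#' @param noise_sigma_um SD of additive Gaussian measurement noise (um).
#' @param seed integer seed.
#' @return an object of class `recoil_spec`.
#' @export
recoil_spec <- function(D_um, tau_s, dt_s = 0.2, duration_s = 60,
                        noise_sigma_um = 0, seed = 1L) {
  check_positive(D_um, "D_um"); check_positive(tau_s, "tau_s")
  check_positive(dt_s, "dt_s"); check_positive(duration_s, "duration_s")
  check_nonneg(noise_sigma_um, "noise_sigma_um")
  if (duration_s < 3 * dt_s) stop("too few samples", call. = FALSE)
  structure(list(D_um = D_um, tau_s = tau_s, dt_s = dt_s,
                 duration_s = duration_s, noise_sigma_um = noise_sigma_um,
                 seed = as.integer(seed)),
            class = "recoil_spec")
}

#' Generate a recoil measurement from a recoil spec
#'
#' @param rs a [recoil_spec()].
#' @return a `recoil_measurement`: list with `t_s` (times, s, 0 at the cut)
#'   and `L_um` (displacement, um).
#' @export
generate_recoil_curve <- function(rs) {
  stopifnot(inherits(rs, "recoil_spec"))
  t_s <- seq(0, rs$duration_s, by = rs$dt_s)
  L <- rs$D_um * (1 - exp(-t_s / rs$tau_s))
  if (rs$noise_sigma_um > 0)
    L <- with_stream(rs$seed, "generate_recoil_curve",
                     L + stats::rnorm(length(L), 0, rs$noise_sigma_um))
  recoil_measurement(t_s, L)
}

#' Construct a recoil measurement
#'
#' @param t_s strictly increasing times (s), starting at the cut (t = 0).
#' @param L_um displacement relative to the pre-cut position (um).
#' @return an object of class `recoil_measurement`.
#' @export
recoil_measurement <- function(t_s, L_um) {
  stopifnot(length(t_s) == length(L_um), all(diff(t_s) > 0), all(t_s >= 0))
  structure(list(t_s = as.numeric(t_s), L_um = as.numeric(L_um)),
            class = "recoil_measurement")
}

#' Render a synthetic recoil movie
#'
#' Builds an image series of a tissue edge retracting after a simulated
#' ablation: before the cut the edge sits at `cut_col_px`; afterwards it
#' recoils along +x following the Kelvin-Voigt curve of the spec. The edge
#' cross-profile is a smooth sigmoid so sub-pixel tracking is meaningful.
#'
#' @param rs a [recoil_spec()].
#' @param size_px image size (rows, cols).
#' @param cut_col_px column of the cut / pre-cut edge position.
#' @param pixel_size_um spatial calibration (um/px).
#' @param n_pre_frames frames before the cut.
#' @param amplitude tissue intensity (a.u.).
#' @param edge_sigma_px softness of the edge profile.
#' @return list: `series` (an [image_series], frame interval `rs$dt_s` s),
#'   `cut_frame` (index of the cut), `true_edge_px` (edge column per frame).
#' @export
render_recoil_movie <- function(rs, size_px = c(32L, 128L), cut_col_px = 20,
                                pixel_size_um = 0.1, n_pre_frames = 5L,
                                amplitude = 100, edge_sigma_px = 1) {
  stopifnot(inherits(rs, "recoil_spec"))
  t_post <- seq(0, rs$duration_s, by = rs$dt_s)
  L_px <- rs$D_um * (1 - exp(-t_post / rs$tau_s)) / pixel_size_um
  edge <- c(rep(cut_col_px, n_pre_frames), cut_col_px + L_px)
  nr <- size_px[1]; nc <- size_px[2]
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  frames <- array(0, c(length(edge), nr, nc))
  for (f in seq_along(edge))
    frames[f, , ] <- amplitude / (1 + exp(-(cols - edge[f]) / edge_sigma_px))
  list(series = image_series(frames, pixel_size_um = pixel_size_um,
                             frame_interval = rs$dt_s,
                             frame_interval_unit = "s",
                             channel_names = "lifeact"),
       cut_frame = n_pre_frames + 1L,
       true_edge_px = edge)
}

#' Generate an oriented test texture
#'
#' `anisotropy = 1` gives a pure sinusoidal grating with stripes along
#' `theta_deg`; `anisotropy = 0` gives isotropic Gaussian-filtered noise;
#' intermediate values blend the two. `amplitude = 0` gives a constant
#' image (whose coherency is 0 by convention).
#'
#' @param theta_deg stripe direction, degrees CCW from +x, in [-90, 90).
#' @param anisotropy blend weight in [0, 1].
#' @param size_px integer pair (rows, cols), each >= 32.
#' @param seed integer seed (used for the noise component).
#' @param period_px grating period, pixels.
#' @param amplitude texture amplitude about the 0.5 mean level.
#' @return an [image_series] with one frame, channel `"texture"`.
#' @export
generate_oriented_texture <- function(theta_deg, anisotropy,
                                      size_px = c(128L, 128L), seed = 1L,
                                      period_px = 8, amplitude = 0.4) {
  stopifnot(length(size_px) == 2)
  if (any(size_px < 32)) stop("size must be at least 32 x 32", call. = FALSE)
  if (anisotropy < 0 || anisotropy > 1)
    stop("anisotropy must be in [0, 1]", call. = FALSE)
  nr <- size_px[1]; nc <- size_px[2]
  img <- matrix(0.5, nr, nc)
  if (amplitude > 0) {
    # stripes along theta: intensity varies along the normal direction
    dirv <- dir_to_rowcol(theta_deg)
    normal <- c(drow = dirv[["dcol"]], dcol = -dirv[["drow"]])
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    phase <- 2 * pi * (rr * normal[["drow"]] + cc * normal[["dcol"]]) /
      period_px
    grating <- cos(phase)
    noise <- with_stream(seed, "generate_oriented_texture", {
      w <- matrix(stats::rnorm(nr * nc), nr, nc)
      w <- gauss_smooth(w, period_px / 4)
      w / stats::sd(w)
    })
    img <- 0.5 + amplitude *
      (anisotropy * grating + (1 - anisotropy) * noise) / 2
  }
  image_series(pmax(img, 0), pixel_size_um = 1, channel_names = "texture")
}

#' Generate a synthetic TER time series
#'
#' Trans-endothelial electrical resistance fixtures sampled every 12 s:
#' `flat` (constant baseline), `transient_dip` (rapid drop with slow
#' recovery, as under acute ROCK inhibition), and `shear_rise` (saturating
#' rise whose normalized plateau is 1.30 x baseline, the barrier
#' strengthening observed under shear onset with ROCK inhibition).
#'
#' @param baseline_ohm baseline resistance (ohm), > 0.
#' @param effect `"flat"`, `"transient_dip"` or `"shear_rise"`.
#' @param n_points number of samples (>= 2).
#' @param seed integer seed (noise only).
#' @param noise_sigma_ohm SD of additive Gaussian noise (ohm); default 0.
#' @param dip_frame sample index of the dip minimum (transient_dip).
#' @param dip_fraction fractional depth of the dip; default 0.3.
#' @return a `ter_series`: list with `times_s`, `ter_ohm`.
#' @export
generate_ter_series <- function(baseline_ohm,
                                effect = c("flat", "transient_dip",
                                           "shear_rise"),
                                n_points = 100L, seed = 1L,
                                noise_sigma_ohm = 0,
                                dip_frame = NULL, dip_fraction = 0.3) {
  effect <- match.arg(effect)
  if (!is.numeric(baseline_ohm) || baseline_ohm <= 0)
    stop("invalid baseline", call. = FALSE)
  if (n_points < 2) stop("need at least 2 points", call. = FALSE)
  times_s <- (seq_len(n_points) - 1) * 12
  u <- times_s / max(times_s)
  ter <- switch(effect,
    flat = rep(baseline_ohm, n_points),
    transient_dip = {
      k <- dip_frame %||% max(2L, round(n_points / 4))
      w <- n_points / 10
      baseline_ohm * (1 - dip_fraction *
                        exp(-(seq_len(n_points) - k)^2 / (2 * w^2)))
    },
    shear_rise = baseline_ohm * (1 + 0.30 * (1 - exp(-6 * u))))
  if (noise_sigma_ohm > 0)
    ter <- with_stream(seed, "generate_ter_series",
                       ter + stats::rnorm(n_points, 0, noise_sigma_ohm))
  structure(list(times_s = times_s, ter_ohm = ter), class = "ter_series")
}
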