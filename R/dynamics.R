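# Time-resolved junction metrics: border-displacement rate
# d-mean(t)/(2*dt) from consecutive border skeletons, the reduced-
# displacement ("intermediate state") window detector, migration-track
# statistics, and TER normalization.

# Symmetric mean nearest-neighbour distance between two skeletons (px).
# Mean over pixels of A of the distance to the nearest pixel of B, averaged
# with the reverse direction; exact (chunked pairwise distances, no
# approximation). Edge-touching pixels are excluded to avoid boundary
# artifacts from cells entering/leaving the field.
skeleton_distance <- function(skel_a, skel_b, exclude_edge = TRUE) {
  stopifnot(all(dim(skel_a) == dim(skel_b)))
  trim <- function(s) {
    if (exclude_edge) {
      s[1, ] <- FALSE; s[nrow(s), ] <- FALSE
      s[, 1] <- FALSE; s[, ncol(s)] <- FALSE
    }
    s
  }
  A <- mask_coords(trim(skel_a)); B <- mask_coords(trim(skel_b))
  if (nrow(A) == 0 || nrow(B) == 0) stop("no borders", call. = FALSE)
  (mean(nn_dists(A, B)) + mean(nn_dists(B, A))) / 2
}

skel_of <- function(x) {
  if (inherits(x, "segmentation_result")) x$border_skeleton
  else if (is.logical(x) && is.matrix(x)) x
  else stop("expected a segmentation_result or logical matrix", call. = FALSE)
}

#' Border displacement at one time point
#'
#' d-mean(t) aggregates the distance between the border skeleton at time t
#' and each of its neighbouring frames (t - dt and t + dt); the average
#' junctional dynamic displacement rate is d-mean(t) / (2 dt). With the
#' default `aggregation = "sum"` the rate equals the single-step border
#' speed for rigid motion; `"mean"` halves it.
#'
#' @param seg_prev,seg_t,seg_next [segmentation_result()]s (or logical
#'   skeleton matrices) at t - dt, t, t + dt, same shape.
#' @param dt_min frame interval (min).
#' @param pixel_size_um pixel size (um/px).
#' @param aggregation `"sum"` (default) or `"mean"` of the two neighbour
#'   distances.
#' @return list: `d_mean_um`, `rate_um_per_min`.
#' @export
border_displacement <- function(seg_prev, seg_t, seg_next, dt_min,
                                pixel_size_um = 1,
                                aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  check_positive(dt_min, "dt_min")
  check_positive(pixel_size_um, "pixel_size_um")
  d1 <- skeleton_distance(skel_of(seg_t), skel_of(seg_prev))
  d2 <- skeleton_distance(skel_of(seg_t), skel_of(seg_next))
  d_mean_px <- if (aggregation == "sum") d1 + d2 else (d1 + d2) / 2
  d_mean_um <- d_mean_px * pixel_size_um
  list(d_mean_um = d_mean_um, rate_um_per_min = d_mean_um / (2 * dt_min))
}

#' Border-displacement time series
#'
#' Applies [border_displacement()] over a sliding three-frame window of a
#' segmentation stack and detects the largest contiguous reduced-
#' displacement window: frames whose rate falls below
#' (1 - reduction/2) x the pre-window baseline (the midpoint threshold for
#' a programmed fractional reduction `reduction`).
#'
#' @param seg_stack list of [segmentation_result()]s (or logical skeleton
#'   matrices), >= 3 frames.
#' @param dt_min frame interval (min).
#' @param pixel_size_um pixel size (um/px).
#' @param aggregation see [border_displacement()].
#' @param reduction fractional displacement reduction the detector is looking
#'   for; default 0.20 (the intermediate-state effect size).
#' @return object of class `border_displacement_series`: data.frame `series`
#'   (`frame`, `time_min`, `d_mean_um`, `rate_um_per_min`; rate `NA` at the
#'   first and last frame) plus `intermediate_window` (integer frames, may
#'   be empty) and `baseline_rate_um_per_min`.
#' @export
displacement_timeseries <- function(seg_stack, dt_min, pixel_size_um = 1,
                                    aggregation = c("sum", "mean"),
                                    reduction = 0.20) {
  aggregation <- match.arg(aggregation)
  n <- length(seg_stack)
  if (n < 3) stop("insufficient frames", call. = FALSE)
  rate <- rep(NA_real_, n)
  d_mean <- rep(NA_real_, n)
  for (t in 2:(n - 1)) {
    bd <- border_displacement(seg_stack[[t - 1]], seg_stack[[t]],
                              seg_stack[[t + 1]], dt_min, pixel_size_um,
                              aggregation)
    rate[t] <- bd$rate_um_per_min
    d_mean[t] <- bd$d_mean_um
  }
  win <- detect_reduced_window(rate, reduction)
  structure(list(
    series = data.frame(frame = seq_len(n), time_min = (seq_len(n) - 1) * dt_min,
                        d_mean_um = d_mean, rate_um_per_min = rate),
    intermediate_window = win$window,
    baseline_rate_um_per_min = win$baseline),
    class = "border_displacement_series")
}

#' @export
print.border_displacement_series <- function(x, ...) {
  r <- x$series$rate_um_per_min
  cat(sprintf(
    "<border_displacement_series> %d frames, median rate %.3g um/min\n",
    nrow(x$series), stats::median(r, na.rm = TRUE)))
  if (length(x$intermediate_window))
    cat(sprintf("  reduced-displacement window: frames %d-%d\n",
                min(x$intermediate_window), max(x$intermediate_window)))
  invisible(x)
}

# Change-point fit of a two-level step model: the rate is a baseline
# outside one contiguous window and reduced inside it. All contiguous
# windows (length >= 3, leaving >= 2 frames outside) are scanned for the
# largest reduction evidence (a Welch-like statistic); the best window is
# accepted if its fitted reduction is at least half of `reduction`.
detect_reduced_window <- function(rate, reduction = 0.20) {
  ok <- which(!is.na(rate))
  n <- length(ok)
  if (n < 5) return(list(window = integer(0), baseline = NA_real_))
  r <- rate[ok]
  cs <- cumsum(r)
  tot <- cs[n]
  best_score <- -Inf; best <- integer(0); best_baseline <- NA_real_
  best_drop <- 0
  for (a in 1:(n - 2)) {
    for (b in (a + 2):n) {
      len_in <- b - a + 1L
      len_out <- n - len_in
      if (len_out < 2) next
      s_in <- cs[b] - if (a > 1) cs[a - 1] else 0
      m_in <- s_in / len_in
      m_out <- (tot - s_in) / len_out
      score <- (m_out - m_in) * sqrt(1 / (1 / len_in + 1 / len_out))
      if (score > best_score) {
        best_score <- score
        best <- ok[a:b]
        best_baseline <- m_out
        best_drop <- if (m_out > 0) 1 - m_in / m_out else 0
      }
    }
  }
  if (length(best) == 0 || best_drop < reduction / 2)
    return(list(window = integer(0), baseline = best_baseline))
  list(window = best, baseline = best_baseline)
}

#' Migration-track metrics
#'
#' Velocity, accumulated distance (total path length) and Euclidean
#' distance (start to end) of a centroid track.
#'
#' @param positions n x 2 matrix or data.frame of (x, y) positions in um,
#'   ordered in time.
#' @param dt_min time between consecutive positions (min), or a vector of
#'   times (min) of length n.
#' @return list of class `migration_track`: `accumulated_distance_um`,
#'   `euclidean_distance_um`, `velocity_um_per_min`, `elapsed_min`.
#' @export
migration_metrics <- function(positions, dt_min) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("degenerate track", call. = FALSE)
  steps <- diff(positions)
  acc <- sum(sqrt(rowSums(steps^2)))
  euc <- sqrt(sum((positions[nrow(positions), ] - positions[1, ])^2))
  elapsed <- if (length(dt_min) == 1) (nrow(positions) - 1) * dt_min
  else diff(range(dt_min))
  structure(list(accumulated_distance_um = acc,
                 euclidean_distance_um = euc,
                 velocity_um_per_min = acc / elapsed,
                 elapsed_min = elapsed),
            class = "migration_track")
}

#' Migration metrics for a track table
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt_min frame interval (min).
#' @return data.frame, one row per track.
#' @export
migration_metrics_table <- function(tracks, dt_min) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  ids <- sort(unique(tracks$track_id))
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    m <- migration_metrics(tr[, c("x_um", "y_um")], dt_min)
    data.frame(track_id = id,
               velocity_um_per_min = m$velocity_um_per_min,
               accumulated_distance_um = m$accumulated_distance_um,
               euclidean_distance_um = m$euclidean_distance_um)
  })
  do.call(rbind, rows)
}

#' Normalize a TER series to its value at time zero
#'
#' TER(t) / TER(t = 0), the standard normalization of trans-endothelial
#' resistance recordings; reports the minimum and its time.
#'
#' @param ter a `ter_series` (see [generate_ter_series()]) or a list with
#'   `times_s` and `ter_ohm`.
#' @param t0_index index of time zero (treatment), default 1.
#' @return a `ter_series` with added `normalized`, `t0_index`,
#'   `min_normalized`, `min_time_s`, `max_normalized`, `max_time_s`.
#' @export
normalize_ter <- function(ter, t0_index = 1L) {
  stopifnot(!is.null(ter$times_s), !is.null(ter$ter_ohm))
  if (t0_index < 1 || t0_index > length(ter$ter_ohm))
    stop("t0_index out of range", call. = FALSE)
  if (ter$ter_ohm[t0_index] <= 0) stop("invalid baseline", call. = FALSE)
  norm <- ter$ter_ohm / ter$ter_ohm[t0_index]
  ter$normalized <- norm
  ter$t0_index <- as.integer(t0_index)
  ter$min_normalized <- min(norm)
  ter$min_time_s <- ter$times_s[which.min(norm)]
  ter$max_normalized <- max(norm)
  ter$max_time_s <- ter$times_s[which.max(norm)]
  class(ter) <- "ter_series"
  ter
}
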