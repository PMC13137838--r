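# Laser-ablation recoil analysis: kymograph extraction along a scan line,
# sub-pixel edge tracking of the retracting tissue after the cut, and
# Kelvin-Voigt fitting L(t) = D (1 - exp(-t / tau)). D is the
# force/elasticity ratio (plateau displacement); tau is the relaxation
# time, with smaller tau indicating higher pre-cut tension.

#' Extract a kymograph along a scan line
#'
#' Per frame, intensity is sampled at unit spacing along the line by
#' bilinear interpolation and averaged across `width_px` perpendicular
#' offsets. Columns are frames, rows are positions along the line.
#'
#' @param series an [image_series].
#' @param line numeric vector `c(row0, col0, row1, col1)` (pixels, 1-based).
#' @param width_px number of perpendicular samples to average (odd).
#' @param channel channel to sample.
#' @return matrix (space x time) of class `kymograph`, with attributes
#'   `spacing_px` (distance between rows, px), `pixel_size_um`,
#'   `frame_interval`, `frame_interval_unit`.
#' @export
extract_kymograph <- function(series, line, width_px = 1, channel = 1) {
  stopifnot(inherits(series, "image_series"), length(line) == 4)
  arr <- series$data[[channel]]
  n_frames <- dim(arr)[1]
  if (n_frames < 2) stop("need at least 2 frames", call. = FALSE)
  p0 <- line[1:2]; p1 <- line[3:4]
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("invalid line", call. = FALSE)
  n_samp <- as.integer(floor(len)) + 1L
  tdir <- (p1 - p0) / len                       # along-line unit (row, col)
  ndir <- c(-tdir[2], tdir[1])                  # perpendicular unit
  offs <- seq_len(width_px) - (width_px + 1) / 2
  s <- seq(0, n_samp - 1L)
  kymo <- matrix(0, n_samp, n_frames)
  for (f in seq_len(n_frames)) {
    frame <- matrix(arr[f, , ], dim(arr)[2], dim(arr)[3])
    acc <- numeric(n_samp)
    for (o in offs) {
      rr <- p0[1] + s * tdir[1] + o * ndir[1]
      cc <- p0[2] + s * tdir[2] + o * ndir[2]
      acc <- acc + bilinear_sample(frame, rr, cc)
    }
    kymo[, f] <- acc / length(offs)
  }
  structure(kymo, class = c("kymograph", "matrix"),
            spacing_px = 1, pixel_size_um = series$pixel_size_um,
            frame_interval = series$frame_interval,
            frame_interval_unit = series$frame_interval_unit)
}

# Bilinear interpolation of frame at fractional (row, col); clamped at the
# border.
bilinear_sample <- function(frame, rr, cc) {
  nr <- nrow(frame); nc <- ncol(frame)
  rr <- pmin(pmax(rr, 1), nr); cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- rr - r0; fc <- cc - c0
  i00 <- frame[cbind(r0, c0)];     i01 <- frame[cbind(r0, c0 + 1)]
  i10 <- frame[cbind(r0 + 1, c0)]; i11 <- frame[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

#' Track the recoiling edge in a kymograph
#'
#' For every post-cut frame, the edge position is the first spatial sample,
#' scanning from the cut point outward, where the intensity rises through
#' half of the local pre-cut plateau (sub-pixel by linear interpolation).
#' Displacement is reported relative to the edge position at the cut frame.
#'
#' @param kymo a `kymograph` from [extract_kymograph()], or a plain
#'   space x time matrix.
#' @param cut_frame frame index of the cut (displacement zero here).
#' @param cut_pos_px position of the cut along the line (row index of the
#'   kymograph); default 1 (scan starts at the cut point).
#' @param pixel_size_um spatial calibration of a kymograph row; taken from
#'   the kymograph attributes when present.
#' @param dt_s frame interval in seconds; default 0.2 s (200 ms capture),
#'   or taken from the kymograph attributes.
#' @return a [recoil_measurement()] (`t_s`, `L_um`), with the tracked raw
#'   edge positions (px) as attribute `edge_px`.
#' @export
track_recoil <- function(kymo, cut_frame, cut_pos_px = 1,
                         pixel_size_um = NULL, dt_s = NULL) {
  spacing <- attr(kymo, "spacing_px") %||% 1
  pixel_size_um <- pixel_size_um %||% attr(kymo, "pixel_size_um") %||% 1
  if (is.null(dt_s)) {
    fi <- attr(kymo, "frame_interval")
    un <- attr(kymo, "frame_interval_unit")
    dt_s <- if (is.null(fi)) 0.2 else if (identical(un, "min")) fi * 60 else fi
  }
  km <- unclass(kymo)
  n_frames <- ncol(km)
  if (cut_frame < 1 || cut_frame > n_frames - 1)
    stop("cut_frame outside the series", call. = FALSE)
  pre <- km[, seq_len(cut_frame), drop = FALSE]
  plateau <- stats::median(apply(pre, 1, stats::median)[
    seq(cut_pos_px, nrow(km))])
  half <- plateau / 2
  edge_of <- function(col) {
    v <- km[, col]
    idx <- seq(cut_pos_px, nrow(km))
    above <- v[idx] >= half
    k <- which(above)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1) return(idx[1])
    i1 <- idx[k - 1]; i2 <- idx[k]
    i1 + (half - v[i1]) / (v[i2] - v[i1]) * (i2 - i1)
  }
  frames <- seq(cut_frame, n_frames)
  edge <- vapply(frames, edge_of, numeric(1))
  if (anyNA(edge)) {
    bad <- frames[which(is.na(edge))[1]]
    stop(sprintf("edge lost at frame %d (last valid frame %d)", bad,
                 bad - 1L), call. = FALSE)
  }
  L_um <- (edge - edge[1]) * spacing * pixel_size_um
  m <- recoil_measurement((frames - cut_frame) * dt_s, L_um)
  attr(m, "edge_px") <- edge
  m
}

# Profiled least squares for L(t) = D (1 - exp(-t / tau)): for fixed tau the
# optimal D is linear; tau is found by 1D minimization of the profiled SSE.
kv_profile <- function(t_s, L_um) {
  sse_of <- function(log_tau) {
    g <- 1 - exp(-t_s / exp(log_tau))
    sg2 <- sum(g * g)
    if (sg2 == 0) return(sum(L_um^2))
    D <- sum(L_um * g) / sg2
    if (D <= 0) return(sum(L_um^2))
    sum((L_um - D * g)^2)
  }
  D0 <- max(L_um)
  tau0 <- if (D0 > 0) {
    k <- which(L_um >= (1 - exp(-1)) * D0)[1]
    if (is.na(k) || t_s[k] <= 0) max(t_s) / 3 else t_s[k]
  } else max(t_s) / 3
  lo <- log(max(tau0 / 100, min(t_s[t_s > 0]) / 10))
  hi <- log(100 * max(tau0, max(t_s)))
  opt <- stats::optimize(sse_of, c(lo, hi), tol = 1e-12)
  # guard against boundary or local issues with a few bracketed restarts
  for (w in c(0.5, 2, 8)) {
    o2 <- stats::optimize(sse_of, opt$minimum + c(-w, w), tol = 1e-12)
    if (o2$objective < opt$objective) opt <- o2
  }
  tau <- exp(opt$minimum)
  g <- 1 - exp(-t_s / tau)
  D <- sum(L_um * g) / sum(g * g)
  list(D = D, tau = tau, sse = opt$objective,
       converged = D > 0 && opt$minimum > lo + 1e-9 && opt$minimum < hi - 1e-9)
}

#' Fit the Kelvin-Voigt recoil model
#'
#' Nonlinear least squares of L(t) = D (1 - exp(-t / tau)) to a recoil
#' measurement, via profiled least squares (D is profiled out analytically;
#' tau is found by bounded 1D minimization initialized at the time where the
#' displacement first reaches (1 - 1/e) of its maximum). Optionally a
#' seeded residual-resampling bootstrap yields 95% confidence intervals.
#'
#' Interpretation: larger tau = slower recoil = lower pre-cut junctional
#' tension; D is the plateau displacement (force/elasticity ratio).
#'
#' @param m a [recoil_measurement()], or a data.frame with columns `t_s`,
#'   `L_um`.
#' @param bootstrap_n number of bootstrap resamples (0 = none).
#' @param seed seed for the bootstrap.
#' @return an object of class `kelvin_voigt_fit`: `D_um`, `tau_s`, `sse`,
#'   `r_squared`, `converged`, `ci_D`, `ci_tau` (95% percentile intervals,
#'   `NULL` without bootstrap), `data`.
#' @export
fit_kelvin_voigt <- function(m, bootstrap_n = 0, seed = 1L) {
  if (is.data.frame(m)) m <- recoil_measurement(m$t_s, m$L_um)
  stopifnot(inherits(m, "recoil_measurement"))
  t_s <- m$t_s; L <- m$L_um
  if (length(t_s) < 5) stop("insufficient data: need at least 5 samples",
                            call. = FALSE)
  fit <- kv_profile(t_s, L)
  if (!fit$converged)
    stop("fit failed: no interior optimum (D = ", format(fit$D),
         ", tau = ", format(fit$tau), ")", call. = FALSE)
  if (max(t_s) < fit$tau)
    warning("recoil curve spans less than one fitted tau; ",
            "estimates may be poorly constrained")
  pred <- fit$D * (1 - exp(-t_s / fit$tau))
  ss_tot <- sum((L - mean(L))^2)
  r2 <- if (ss_tot > 0) 1 - fit$sse / ss_tot else NA_real_
  ci_D <- ci_tau <- NULL
  if (bootstrap_n > 0) {
    res <- L - pred
    boots <- with_stream(seed, "fit_kelvin_voigt_bootstrap", {
      vapply(seq_len(bootstrap_n), function(b) {
        Lb <- pred + sample(res, length(res), replace = TRUE)
        fb <- kv_profile(t_s, Lb)
        c(fb$D, fb$tau)
      }, numeric(2))
    })
    ci_D <- unname(stats::quantile(boots[1, ], c(0.025, 0.975)))
    ci_tau <- unname(stats::quantile(boots[2, ], c(0.025, 0.975)))
  }
  structure(list(D_um = fit$D, tau_s = fit$tau, sse = fit$sse,
                 r_squared = r2, converged = fit$converged,
                 ci_D = ci_D, ci_tau = ci_tau,
                 data = data.frame(t_s = t_s, L_um = L)),
            class = "kelvin_voigt_fit")
}

#' @export
print.kelvin_voigt_fit <- function(x, ...) {
  cat("Kelvin-Voigt recoil fit: L(t) = D (1 - exp(-t/tau))\n")
  cat(sprintf("  D   = %.4g um%s\n", x$D_um,
              if (!is.null(x$ci_D)) sprintf("  [95%% CI %.4g, %.4g]",
                                            x$ci_D[1], x$ci_D[2]) else ""))
  cat(sprintf("  tau = %.4g s%s\n", x$tau_s,
              if (!is.null(x$ci_tau)) sprintf("   [95%% CI %.4g, %.4g]",
                                              x$ci_tau[1], x$ci_tau[2])
              else ""))
  cat(sprintf("  n = %d, SSE = %.4g, R^2 = %.4f\n", nrow(x$data), x$sse,
              x$r_squared))
  invisible(x)
}

#' @export
summary.kelvin_voigt_fit <- function(object, ...) {
  print(object)
  cat("  interpretation: smaller tau indicates higher pre-cut tension\n")
  invisible(object)
}

#' @export
coef.kelvin_voigt_fit <- function(object, ...) {
  c(D_um = object$D_um, tau_s = object$tau_s)
}

#' @export
fitted.kelvin_voigt_fit <- function(object, ...) {
  object$D_um * (1 - exp(-object$data$t_s / object$tau_s))
}

#' @export
residuals.kelvin_voigt_fit <- function(object, ...) {
  object$data$L_um - fitted(object)
}

#' @export
predict.kelvin_voigt_fit <- function(object, newdata = NULL, ...) {
  t_s <- if (is.null(newdata)) object$data$t_s else
    if (is.data.frame(newdata)) newdata$t_s else as.numeric(newdata)
  object$D_um * (1 - exp(-t_s / object$tau_s))
}

#' @export
plot.kelvin_voigt_fit <- function(x, ...) {
  graphics::plot(x$data$t_s, x$data$L_um, pch = 16, cex = 0.5,
                 xlab = "time after cut (s)", ylab = "displacement (um)",
                 main = "Kelvin-Voigt recoil fit", ...)
  tt <- seq(0, max(x$data$t_s), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red", lwd = 2)
  graphics::abline(h = x$D_um, lty = 2, col = "grey50")
  invisible(x)
}
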