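# Synthetic monolayer, time-lapse, recoil, texture and TER generators:
# determinism, ground-truth consistency, and the analytic properties the
# downstream stages rely on.

quiet_spec <- function(...) {
  monolayer_spec(poisson_gain = 0, gaussian_read_sigma = 0, ...)
}

test_that("monolayer generation is deterministic and seed-sensitive", {
  spec <- monolayer_spec(n_cells = 20, seed = 1)
  a <- generate_monolayer(spec)
  b <- generate_monolayer(spec)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$ground_truth$label_stack, b$ground_truth$label_stack)
  c_ <- generate_monolayer(monolayer_spec(n_cells = 20, seed = 2))
  expect_false(identical(a$series$data, c_$series$data))
})

test_that("ground truth has the requested cells and consistent borders", {
  sim <- generate_monolayer(quiet_spec(n_cells = 20, seed = 3))
  lab <- matrix(sim$ground_truth$label_stack[1, , ], 256)
  expect_identical(sort(unique(as.vector(lab))), 1:20)
  border <- matrix(sim$ground_truth$border_stack[1, , ], 256)
  # independent re-derivation of the boundary pixels
  expect_identical(border, oracle_boundaries(lab))
  # every border pixel touches >= 2 labels in its 8-neighbourhood
  w <- which(border, arr.ind = TRUE)
  for (k in sample(nrow(w), 200)) {
    i <- w[k, 1]; j <- w[k, 2]
    nb <- lab[max(1, i - 1):min(256, i + 1), max(1, j - 1):min(256, j + 1)]
    expect_gte(length(unique(as.vector(nb))), 2)
  }
})

test_that("spec validation enforces density/cell-count consistency", {
  expect_error(monolayer_spec(n_cells = 1), "degenerate tessellation")
  expect_error(monolayer_spec(field_size_px = c(32, 32), pixel_size_um = 0.5,
                              density_cells_per_cm2 = 5e7),
               "density infeasible")
  expect_error(monolayer_spec(n_cells = 40, density_cells_per_cm2 = 9e4),
               "density infeasible")
  # derived n_cells matches density x area within one cell
  spec <- monolayer_spec(density_cells_per_cm2 = 9e4)
  area_cm2 <- prod(spec$field_size_px) * spec$pixel_size_um^2 * 1e-8
  expect_lte(abs(spec$n_cells - 9e4 * area_cm2), 1)
})

test_that("noise-free band rendering integrates to amplitude*sigma*sqrt(2pi)", {
  skel <- matrix(FALSE, 64, 200)
  skel[32, ] <- TRUE
  img <- junctiondyn:::render_junction_band(skel, amplitude = 50,
                                           sigma_px = 2, background = 0)
  # per-column cross-profile integral, away from the ends
  sums <- colSums(img[, 20:180])
  expect_lt(max(abs(sums - 50 * 2 * sqrt(2 * pi))) / (50 * 2 * sqrt(2 * pi)),
            0.02)
})

test_that("static time-lapse is motion-free; translation has exact steps", {
  spec <- quiet_spec(n_cells = 12, field_size_px = c(128L, 128L),
                     pixel_size_um = 0.5, seed = 4)
  st <- generate_timelapse(spec, motion_program("static"), 5)
  expect_identical(st$ground_truth$per_frame_border_displacement_um,
                   rep(0, 4))
  for (t in 2:5) expect_identical(st$series$data[[1]][t, , ],
                                  st$series$data[[1]][1, , ])
  tr <- generate_timelapse(spec,
                           motion_program("rigid_translation",
                                          speed_um_per_min = 0.5), 5,
                           frame_interval_min = 1)
  expect_equal(tr$ground_truth$per_frame_border_displacement_um,
               rep(0.5, 4), tolerance = 1e-12)
  expect_error(generate_timelapse(spec, motion_program("static"), 5,
                                  frame_interval_min = 0),
               "invalid calibration")
  expect_error(generate_timelapse(spec, motion_program("static"), 2),
               "at least 3 frames")
})

test_that("intermediate state reduces true displacement by the programmed fraction", {
  spec <- quiet_spec(n_cells = 12, field_size_px = c(128L, 128L), seed = 5)
  prog <- motion_program("intermediate_state", jitter_amplitude_um = 1,
                         intermediate_onset_frame = 5,
                         intermediate_release_frame = 10,
                         intermediate_reduction_fraction = 0.20)
  sim <- generate_timelapse(spec, prog, 15)
  d <- sim$ground_truth$per_frame_border_displacement_um
  inside <- d[5:9]     # transitions into frames 6..10
  outside <- d[-(5:9)]
  expect_equal(mean(inside) / mean(outside), 0.80, tolerance = 0.02)
})

test_that("recoil curves follow the Kelvin-Voigt model exactly when noiseless", {
  rs <- recoil_spec(D_um = 2, tau_s = 15, dt_s = 0.2, duration_s = 60)
  m <- generate_recoil_curve(rs)
  expect_equal(m$L_um[1], 0)
  expect_equal(m$L_um[m$t_s == 15], 2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(m$L_um, 2 * (1 - exp(-m$t_s / 15)), tolerance = 1e-15)
  expect_error(recoil_spec(2, 15, dt_s = 1, duration_s = 2),
               "too few samples")
})

test_that("recoil noise is centred on the noiseless model", {
  rs <- recoil_spec(2, 15, 0.2, 60, noise_sigma_um = 0.1, seed = 7)
  m <- generate_recoil_curve(rs)
  resid <- m$L_um - 2 * (1 - exp(-m$t_s / 15))
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * 0.1 / sqrt(n))
  # seeded: reproducible
  expect_identical(m$L_um, generate_recoil_curve(rs)$L_um)
})

test_that("TER presets have the programmed shapes", {
  flat <- normalize_ter(generate_ter_series(800, "flat", 50))
  expect_equal(flat$normalized, rep(1, 50))
  rise <- normalize_ter(generate_ter_series(800, "shear_rise", 200))
  expect_equal(rise$max_normalized, 1.30, tolerance = 0.01)
  dip <- normalize_ter(generate_ter_series(800, "transient_dip", 100,
                                           dip_frame = 30))
  expect_equal(which.min(dip$normalized), 30)
  expect_error(generate_ter_series(-5, "flat"), "invalid baseline")
})

test_that("oriented textures span the coherency range", {
  expect_error(generate_oriented_texture(0, 1, size_px = c(16, 16)),
               "at least 32")
  expect_error(generate_oriented_texture(0, 1.5), "anisotropy")
  flat <- generate_oriented_texture(0, 1, amplitude = 0)
  expect_equal(apparent_coherency(get_frame(flat))$coherency, 0)
})

test_that("coherency is monotone in orientation concentration", {
  # cells elongated at AR 3 with tightening orientation spread; rendered
  # noise-free so the ordering is driven by geometry alone
  for (seed in 1:10) {
    coh <- vapply(c(0, 2, 8), function(conc) {
      spec <- quiet_spec(n_cells = 36, field_size_px = c(192L, 192L),
                         mean_aspect_ratio = 3,
                         orientation_concentration = conc, seed = seed)
      apparent_coherency(get_frame(generate_monolayer(spec)$series),
                         window_sigma_px = 6)$coherency
    }, numeric(1))
    expect_true(all(diff(coh) > 0),
                info = sprintf("seed %d: %s", seed,
                               paste(round(coh, 3), collapse = " ")))
  }
})

test_that("aligned elongated monolayers read out their programmed direction", {
  spec <- quiet_spec(n_cells = 16, field_size_px = c(128L, 128L),
                     mean_aspect_ratio = 3, orientation_mean_deg = 0,
                     orientation_concentration = 10, seed = 2)
  a <- apparent_coherency(get_frame(generate_monolayer(spec)$series),
                          window_sigma_px = 8)
  expect_gt(a$coherency, 0.5)
  expect_lt(abs(a$dominant_direction_deg - 0), 5)
})
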