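# Per-cell shape and intensity statistics.

# helper: embed a mask as cell 2 inside a background cell 1
seg_from_mask <- function(mask, pad = 10) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(1L, nr + 2 * pad, nc + 2 * pad)
  lab[(pad + 1):(pad + nr), (pad + 1):(pad + nc)][mask] <- 2L
  segmentation_result(lab)
}

morph_of_mask <- function(mask) {
  m <- cell_morphology(seg_from_mask(mask), pixel_size_um = 1)
  m[m$cell_id == 2, ]
}

test_that("digital disk: near-unit aspect ratio, perimeter near 2*pi*r", {
  m <- morph_of_mask(disk_mask(101, 51, 51, 40))
  expect_lte(m$aspect_ratio, 1.05)
  expect_lt(abs(m$perimeter_um - 2 * pi * 40) / (2 * pi * 40), 0.03)
  expect_equal(m$area_um2, sum(disk_mask(101, 51, 51, 40)))
})

test_that("axis-aligned rectangle: AR 2, orientation 0", {
  mask <- matrix(FALSE, 60, 100)
  mask[11:50, 11:90] <- TRUE   # 40 rows x 80 cols
  m <- morph_of_mask(mask)
  expect_equal(m$aspect_ratio, 2.00, tolerance = 0.02)
  expect_equal(m$orientation_deg, 0)
})

test_that("rotated ellipse: AR and orientation recovered, matching the moment oracle", {
  th <- 30 * pi / 180
  mask <- outer(seq_len(161), seq_len(161), function(i, j) {
    x <- j - 81; y <- -(i - 81)
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    (u / 40)^2 + (v / 20)^2 <= 1
  })
  m <- morph_of_mask(mask)
  expect_equal(m$aspect_ratio, 2.0, tolerance = 0.05)
  expect_lt(abs(m$orientation_deg - 30), 2)
  o <- oracle_moments(mask)
  expect_equal(m$aspect_ratio, o$ar, tolerance = 1e-9)
  expect_equal(m$orientation_deg, o$orientation, tolerance = 1e-9)
})

test_that("aspect ratio is exactly invariant under 90-degree rotation", {
  mask <- matrix(FALSE, 80, 80); mask[21:60, 31:50] <- TRUE
  mask[25:30, 33:44] <- FALSE  # make it asymmetric
  m1 <- morph_of_mask(mask)
  m2 <- morph_of_mask(t(mask)[ncol(mask):1, ])  # rotate 90 deg
  expect_equal(m1$aspect_ratio, m2$aspect_ratio, tolerance = 1e-12)
  shift <- (m2$orientation_deg - m1$orientation_deg) %% 180
  expect_true(min(abs(shift - 90), abs(shift - 90 + 180)) < 1e-9)
  expect_equal(m1$perimeter_um, m2$perimeter_um, tolerance = 1e-12)
})

test_that("morphology respects the isoperimetric bound with discretization slack", {
  sim <- generate_monolayer(monolayer_spec(n_cells = 20, seed = 5,
                                           poisson_gain = 0,
                                           gaussian_read_sigma = 0))
  seg <- segmentation_result(matrix(sim$ground_truth$label_stack[1, , ], 256))
  m <- cell_morphology(seg, pixel_size_um = 0.53)
  expect_true(all(m$aspect_ratio >= 1))
  expect_true(all(m$area_um2 > 0))
  expect_true(all(m$perimeter_um >= 2 * sqrt(pi * m$area_um2) * 0.95))
})

test_that("junctional concentration: analytic band case and exact homogeneity", {
  lab <- matrix(1L, 64, 64); lab[33:64, ] <- 2L
  seg <- segmentation_result(lab)
  f <- matrix(3, 64, 64)
  jc <- junctional_concentration(f, seg, w_px = 5)
  expect_equal(jc$relative_concentration, 11 * 3)
  expect_equal(junctional_concentration(matrix(0, 64, 64),
                                        seg)$relative_concentration, 0)
  # homogeneity: scaling intensities scales the statistic exactly
  set.seed(11)
  fr <- matrix(runif(64 * 64), 64)
  a <- junctional_concentration(fr, seg)$relative_concentration
  b <- junctional_concentration(5 * fr, seg)$relative_concentration
  expect_identical(b, 5 * a)
})

test_that("junctional concentration equals a brute-force pixel loop", {
  sim <- generate_monolayer(monolayer_spec(n_cells = 12, seed = 6,
                                           field_size_px = c(128L, 128L),
                                           junction_sigma_px = 2))
  seg <- segmentation_result(matrix(sim$ground_truth$label_stack[1, , ], 128))
  f <- get_frame(sim$series)
  jc <- junctional_concentration(f, seg, w_px = 5, per_cell = TRUE)
  for (k in seq_len(min(3, nrow(jc)))) {
    id <- jc$cell_id[k]
    cb <- which(junctiondyn:::cell_border_pixels(seg, id), arr.ind = TRUE)
    s <- 0
    for (i in seq_len(128)) for (j in seq_len(128)) {
      d2 <- min((cb[, 1] - i)^2 + (cb[, 2] - j)^2)
      if (d2 <= 25) s <- s + f[i, j]
    }
    expect_equal(jc$integrated_intensity[k], s, tolerance = 1e-9)
    expect_equal(jc$relative_concentration[k], s / nrow(cb),
                 tolerance = 1e-9)
  }
})

test_that("field-level band intensity is bounded by the per-cell sum", {
  sim <- generate_monolayer(monolayer_spec(n_cells = 12, seed = 7,
                                           field_size_px = c(128L, 128L)))
  lab <- matrix(sim$ground_truth$label_stack[1, , ], 128)
  seg <- segmentation_result(lab)
  f <- get_frame(sim$series)
  field <- junctional_concentration(f, seg, w_px = 3)$integrated_intensity
  # include edge cells so the whole border is covered
  per_all <- sum(vapply(cell_ids(seg), function(id)
    sum(f[band_mask(seg, 3, id)]), numeric(1)))
  expect_lte(field, per_all + 1e-9)
  # each band pixel is claimed by the >= 2 cells sharing its border, plus a
  # third at tri-cellular vertices; 3x is the hard ceiling
  expect_lte(per_all, 3 * field + 1e-9)
  expect_gte(per_all, 1.8 * field)
})

test_that("cell intensity sums the label region and pairs with perimeter", {
  sim <- generate_monolayer(monolayer_spec(n_cells = 12, seed = 8,
                                           field_size_px = c(128L, 128L),
                                           poisson_gain = 0,
                                           gaussian_read_sigma = 0))
  seg <- segmentation_result(matrix(sim$ground_truth$label_stack[1, , ], 128))
  ci <- cell_intensity(matrix(4, 128, 128), seg, pixel_size_um = 1)
  areas <- vapply(ci$cell_id, function(id) sum(seg$full_labels == id),
                  numeric(1))
  expect_equal(ci$total_intensity, 4 * areas)
  expect_equal(cell_intensity(matrix(0, 128, 128), seg)$total_intensity,
               rep(0, nrow(ci)))
  # programmed intensity proportional to perimeter -> rank correlation 1
  m <- cell_morphology(seg, 1)
  f2 <- matrix(0, 128, 128)
  for (id in m$cell_id)
    f2[seg$full_labels == id] <- m$perimeter_um[m$cell_id == id] /
      sum(seg$full_labels == id)
  ci2 <- cell_intensity(f2, seg, pixel_size_um = 1)
  expect_equal(cor(ci2$total_intensity, ci2$perimeter_um,
                   method = "spearman"), 1)
})

test_that("monolayer density uses the half-weight edge correction", {
  # the half-weighting of edge cells assumes the field is a window cut from
  # a larger monolayer, so segment a central crop of a larger synthetic
  # field: crop-edge cells then genuinely continue outside the window
  sim <- generate_monolayer(monolayer_spec(field_size_px = c(512L, 512L),
                                           density_cells_per_cm2 = 9e4,
                                           poisson_gain = 0,
                                           gaussian_read_sigma = 0,
                                           seed = 9))
  full <- matrix(sim$ground_truth$label_stack[1, , ], 512)
  crop <- full[65:448, 65:448]
  seg <- segmentation_result(crop)
  d <- monolayer_density(seg, 0.53)
  expect_lt(abs(d - 9e4) / 9e4, 0.10)
  n_all <- max(seg$full_labels); n_edge <- length(seg$edge_cells)
  area <- 384^2 * 0.53^2 * 1e-8
  expect_equal(d, (n_all - 0.5 * n_edge) / area)
  expect_equal(monolayer_density(NULL, 0.53), 0)
})
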