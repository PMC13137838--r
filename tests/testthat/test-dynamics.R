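# Border-displacement dynamics, migration metrics and TER normalization.

test_that("identical borders give zero displacement rate", {
  s <- line_skel(40, 40, 20)
  bd <- border_displacement(s, s, s, dt_min = 1)
  expect_equal(bd$rate_um_per_min, 0)
})

test_that("rigid translation of a straight border gives the exact rate", {
  delta <- 3
  bd <- border_displacement(line_skel(40, 40, 10), line_skel(40, 40, 13),
                            line_skel(40, 40, 16), dt_min = 2,
                            pixel_size_um = 0.5)
  expect_equal(bd$d_mean_um, 2 * delta * 0.5)
  expect_equal(bd$rate_um_per_min, delta * 0.5 / 2)
  # mean aggregation halves the rate
  bdm <- border_displacement(line_skel(40, 40, 10), line_skel(40, 40, 13),
                             line_skel(40, 40, 16), dt_min = 2,
                             pixel_size_um = 0.5, aggregation = "mean")
  expect_equal(bdm$rate_um_per_min, bd$rate_um_per_min / 2)
})

test_that("skeleton distance matches the exhaustive pairwise oracle", {
  set.seed(42)
  for (rep in 1:5) {
    a <- matrix(FALSE, 40, 40); b <- matrix(FALSE, 40, 40)
    a[cbind(sample(2:39, 60, TRUE), sample(2:39, 60, TRUE))] <- TRUE
    b[cbind(sample(2:39, 60, TRUE), sample(2:39, 60, TRUE))] <- TRUE
    expect_equal(junctiondyn:::skeleton_distance(a, b, exclude_edge = FALSE),
                 oracle_skeleton_distance(a, b), tolerance = 1e-9)
    # symmetry
    expect_equal(junctiondyn:::skeleton_distance(a, b, exclude_edge = FALSE),
                 junctiondyn:::skeleton_distance(b, a, exclude_edge = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("displacement series is time-reversal symmetric", {
  skels <- lapply(c(5, 8, 9, 13, 18), function(cc) line_skel(32, 32, cc))
  fwd <- displacement_timeseries(skels, dt_min = 1)
  rev_ <- displacement_timeseries(rev(skels), dt_min = 1)
  expect_equal(fwd$series$rate_um_per_min,
               rev(rev_$series$rate_um_per_min))
  expect_error(displacement_timeseries(skels[1:2], 1),
               "insufficient frames")
})

test_that("pixel-size scaling propagates exactly", {
  s1 <- line_skel(40, 40, 10); s2 <- line_skel(40, 40, 12)
  s3 <- line_skel(40, 40, 14)
  a <- border_displacement(s1, s2, s3, 1, pixel_size_um = 1)
  b <- border_displacement(s1, s2, s3, 1, pixel_size_um = 3)
  expect_equal(b$rate_um_per_min, 3 * a$rate_um_per_min)
  expect_equal(b$d_mean_um, 3 * a$d_mean_um)
})

test_that("static synthetic time-lapse yields zero rates and no window", {
  spec <- monolayer_spec(n_cells = 12, field_size_px = c(96L, 96L),
                         poisson_gain = 0, gaussian_read_sigma = 0, seed = 2)
  sim <- generate_timelapse(spec, motion_program("static"), 6)
  skels <- lapply(1:6, function(t)
    matrix(sim$ground_truth$border_stack[t, , ], 96))
  bd <- displacement_timeseries(skels, dt_min = 1)
  expect_equal(bd$series$rate_um_per_min[2:5], rep(0, 4))
  expect_length(bd$intermediate_window, 0)
})

test_that("migration metrics reproduce analytic paths", {
  m <- migration_metrics(rbind(c(0, 0), c(3, 4)), dt_min = 1)
  expect_equal(m$accumulated_distance_um, 5)
  expect_equal(m$euclidean_distance_um, 5)
  expect_equal(m$velocity_um_per_min, 5)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  ms <- migration_metrics(sq, dt_min = 1)
  expect_equal(ms$accumulated_distance_um, 40)
  expect_equal(ms$euclidean_distance_um, 0)
  expect_error(migration_metrics(rbind(c(0, 0)), 1), "degenerate track")
})

test_that("random-walk metrics match a step-summing oracle", {
  set.seed(99)
  ang <- runif(100, 0, 2 * pi)
  pos <- rbind(c(0, 0), cbind(cumsum(cos(ang)), cumsum(sin(ang))))
  m <- migration_metrics(pos, dt_min = 1)
  expect_equal(m$accumulated_distance_um, 100, tolerance = 1e-9)
  oracle_acc <- 0
  for (i in 2:nrow(pos))
    oracle_acc <- oracle_acc + sqrt(sum((pos[i, ] - pos[i - 1, ])^2))
  expect_equal(m$accumulated_distance_um, oracle_acc, tolerance = 1e-12)
  expect_equal(m$euclidean_distance_um,
               sqrt(sum(pos[101, ]^2)), tolerance = 1e-12)
})

test_that("accumulated >= euclidean with equality only for co-directional paths", {
  steps <- expand.grid(dx1 = -1:1, dy1 = -1:1, dx2 = -1:1, dy2 = -1:1)
  for (k in seq_len(nrow(steps))) {
    s <- steps[k, ]
    if (all(s[c(1, 2)] == 0) || all(s[c(3, 4)] == 0)) next
    pos <- rbind(c(0, 0), c(s$dx1, s$dy1), c(s$dx1 + s$dx2, s$dy1 + s$dy2))
    m <- migration_metrics(pos, 1)
    expect_gte(m$accumulated_distance_um, m$euclidean_distance_um - 1e-12)
    collinear <- s$dx1 * s$dy2 - s$dy1 * s$dx2 == 0 &&
      s$dx1 * s$dx2 + s$dy1 * s$dy2 >= 0
    if (abs(m$accumulated_distance_um - m$euclidean_distance_um) < 1e-12)
      expect_true(collinear)
    if (collinear)
      expect_equal(m$accumulated_distance_um, m$euclidean_distance_um,
                   tolerance = 1e-12)
  }
})

test_that("track tables are processed per track", {
  tracks <- data.frame(track_id = rep(1:2, each = 3), frame = rep(1:3, 2),
                       x_um = c(0, 3, 3, 0, 0, 5), y_um = c(0, 4, 4, 0, 0, 0))
  mm <- migration_metrics_table(tracks, dt_min = 2)
  expect_equal(mm$accumulated_distance_um, c(5, 5))
  expect_equal(mm$velocity_um_per_min, c(5 / 4, 5 / 4))
})

test_that("TER normalization divides by the value at time zero", {
  ter <- list(times_s = c(0, 12, 24), ter_ohm = 800 * c(1, 0.8, 1.3))
  n <- normalize_ter(ter)
  expect_equal(n$normalized, c(1, 0.8, 1.3))
  expect_equal(which.min(n$normalized), 2)
  expect_equal(n$normalized[n$t0_index], 1)
  const <- normalize_ter(list(times_s = 0:4, ter_ohm = rep(650, 5)))
  expect_equal(const$normalized, rep(1, 5))
  expect_error(normalize_ter(list(times_s = 0:1, ter_ohm = c(0, 1))),
               "invalid baseline")
})
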