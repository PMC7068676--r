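test_that("axial sampling spans the uniform-to-point-mass range", {
  expect_error(sample_axial_angle(30, -1), "kappa")
  # zero-dispersion limit: the capped concentration returns the mean exactly
  expect_equal(sample_axial_angle(30, 1e8, 5), rep(30, 5))
  expect_equal(sample_axial_angle(190, 1e9), 10)

  # kappa = 0: uniform on [0, 180) (Kolmogorov-Smirnov distance < 0.02)
  set.seed(100)
  u <- sample_axial_angle(77, 0, 10000)
  expect_true(all(u >= 0 & u < 180))
  ks <- suppressWarnings(ks.test(u, "punif", 0, 180))
  expect_lt(ks$statistic, 0.02)

  # concentrated draws scatter tightly around the mean axis
  set.seed(101)
  tight <- sample_axial_angle(150, 200, 2000)
  expect_lt(max(axial_delta(tight, 150)), 20)
  expect_lt(axial_delta(axial_order(tight)$mean_axis_deg, 150), 1)

  # fixed seed gives an identical draw sequence
  set.seed(55); a <- sample_axial_angle(60, 4, 50)
  set.seed(55); b <- sample_axial_angle(60, 4, 50)
  expect_identical(a, b)
})

test_that("rasterized fibers are 1-pixel-wide 8-connected chains", {
  h5 <- rasterize_fiber(c(10, 10), 0, 5, c(30, 30))
  expect_equal(nrow(h5), 5L)
  expect_true(all(h5[, "y"] == 10L))
  expect_equal(sort(h5[, "x"]), 8:12)

  v5 <- rasterize_fiber(c(10, 10), 90, 5, c(30, 30))
  expect_equal(nrow(v5), 5L)
  expect_true(all(v5[, "x"] == 10L))

  d5 <- rasterize_fiber(c(10, 10), 45, 5, c(30, 30))
  a <- orientation_angle(central_moments(d5))
  expect_lt(axial_delta(a$angle_deg, 45), 2)

  expect_error(rasterize_fiber(c(5, 5), 0, 1, c(20, 20)), "length")

  # 8-connectivity and no duplicate pixels, at arbitrary angles/centers
  set.seed(61)
  for (i in 1:40) {
    px <- rasterize_fiber(runif(2, 20, 60), runif(1, 0, 180),
                          round(runif(1, 5, 40)), c(80, 80))
    expect_equal(anyDuplicated(paste(px[, 1], px[, 2])), 0L)
    steps <- abs(diff(px[, "x"])) <= 1 & abs(diff(px[, "y"])) <= 1
    expect_true(all(steps))
  }

  # clipping: a fiber centered near the border loses out-of-bounds pixels
  clipped <- rasterize_fiber(c(1, 1), 0, 11, c(20, 20))
  expect_true(all(clipped[, "x"] >= 0))
  expect_lt(nrow(clipped), 11L)
})

test_that("field generation is bit-reproducible and honors empty specs", {
  spec <- synthetic_field_spec(
    width = 150, height = 150, n_sections = 3,
    clusters = list(cluster_spec(25, 10, 20, c(12, 12, 138, 138)),
                    cluster_spec(100, 10, 20, c(12, 12, 138, 138))),
    seed = 9, allow_crossings = TRUE)
  f1 <- generate_field(spec)
  f2 <- generate_field(spec)
  expect_identical(f1$stack$planes, f2$stack$planes)
  expect_identical(f1$truth, f2$truth)

  none <- generate_field(synthetic_field_spec(
    width = 50, height = 50, n_sections = 2,
    clusters = list(cluster_spec(10, 5, 0, c(5, 5, 45, 45))), seed = 1))
  expect_equal(nrow(none$truth), 0L)
  expect_true(all(vapply(none$stack$planes, sum, numeric(1)) == 0))

  expect_error(synthetic_field_spec(width = 100, height = 100,
    clusters = list(cluster_spec(10, 5, 5, c(0, 0, 120, 50)))), "bounds")
  expect_error(cluster_spec(10, 5, 5, c(50, 0, 10, 50)), "region")
  expect_error(cluster_spec(10, 5, 5, c(0, 0, 10, 10), length_range = c(1, 5)),
               "length_range")
})

test_that("a cluster's fibers are stable when other clusters change", {
  base <- synthetic_field_spec(
    width = 200, height = 200, n_sections = 2,
    clusters = list(cluster_spec(25, 50, 15, c(12, 12, 90, 188))),
    seed = 17, allow_crossings = TRUE)
  more <- synthetic_field_spec(
    width = 200, height = 200, n_sections = 2,
    clusters = list(cluster_spec(25, 50, 15, c(12, 12, 90, 188)),
                    cluster_spec(160, 50, 15, c(110, 12, 188, 188))),
    seed = 17, allow_crossings = TRUE)
  t1 <- generate_field(base)$truth
  t2 <- generate_field(more)$truth
  expect_equal(t1$true_angle_deg, t2$true_angle_deg[t2$cluster == 1])
  expect_equal(t1$center_x, t2$center_x[t2$cluster == 1])
})

test_that("infeasible packing raises a generation error", {
  cramped <- synthetic_field_spec(
    width = 40, height = 40, n_sections = 1,
    clusters = list(cluster_spec(0, 5, 200, c(5, 5, 34, 34),
                                 length_range = c(10, 20))),
    seed = 2, allow_crossings = FALSE)
  expect_error(generate_field(cramped), "drop rate")
})

test_that("non-crossing fields are recovered fiber-for-fiber", {
  f <- generate_field(synthetic_field_spec(
    width = 400, height = 400, n_sections = 4,
    clusters = list(cluster_spec(30, 1e8, 50, c(25, 25, 375, 375))),
    seed = 30, allow_crossings = FALSE))
  m <- orientation_map(f$stack)
  expect_equal(length(m$segments), nrow(f$truth))
  r <- recovery_report(f$truth, m)
  expect_equal(r$match_rate, 1.0)
  # zero-dispersion field: every recovered angle reflects only rasterization
  # error, empirically below 5 degrees for 10-40 px fibers, mean well under 1
  expect_lt(r$max_abs_angle_err_deg, 5)
  expect_lt(r$mean_abs_angle_err_deg, 1)
})

test_that("recovery matches by geometry, not by segment labels", {
  f <- generate_field(synthetic_field_spec(
    width = 200, height = 200, n_sections = 2,
    clusters = list(cluster_spec(75, 40, 25, c(15, 15, 185, 185))),
    seed = 44, allow_crossings = FALSE))
  m <- orientation_map(f$stack)
  r0 <- recovery_report(f$truth, m)
  shuffled <- m
  set.seed(1)
  shuffled$segments <- sample(m$segments)
  for (i in seq_along(shuffled$segments))
    shuffled$segments[[i]]$segment_id <- i
  r1 <- recovery_report(f$truth, shuffled)
  expect_equal(r1$match_rate, r0$match_rate)
  expect_equal(r1$mean_abs_angle_err_deg, r0$mean_abs_angle_err_deg)
  expect_equal(r1$per_cluster$err_deg, r0$per_cluster$err_deg)
  expect_error(recovery_report(f$truth[0, ], m), "empty")
})

test_that("crossing stress: branch removal multiplies segments but keeps the modes", {
  f <- generate_field(synthetic_field_spec(
    width = 300, height = 300, n_sections = 2,
    clusters = list(cluster_spec(30, 100, 80, c(20, 20, 280, 280)),
                    cluster_spec(120, 100, 80, c(20, 20, 280, 280))),
    seed = 66, allow_crossings = TRUE))
  m <- orientation_map(f$stack, min_segment_length = 5)
  expect_gt(length(m$segments), nrow(f$truth))
  h <- angular_histogram(m)
  top2 <- sort(order(h$counts, decreasing = TRUE)[1:2] - 1L)
  expect_equal(top2, c(5L, 21L))  # 30 / 5.625 -> bin 5; 120 / 5.625 -> bin 21
})

test_that("ground-truth tables round-trip through text files", {
  f <- generate_field(synthetic_field_spec(
    width = 100, height = 100, n_sections = 2,
    clusters = list(cluster_spec(10, 20, 10, c(10, 10, 90, 90))), seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(f$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$true_angle_deg, f$truth$true_angle_deg)
  expect_equal(back$fiber_id, f$truth$fiber_id)
})

test_that("field specifications round-trip through config files", {
  spec <- two_cluster_field(seed = 23L, n_fibers = 7L, kappa = 12.5)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_field_spec(spec, path)
  back <- read_field_spec(path)
  expect_equal(back, spec)
  f1 <- generate_field(spec)
  f2 <- generate_field(back)
  expect_identical(f1$stack$planes, f2$stack$planes)
})
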