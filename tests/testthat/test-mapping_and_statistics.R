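test_that("binary projection is the per-pixel maximum over selected planes", {
  p1 <- line_plane(20, 20, 4, 2, 10)
  p2 <- line_plane(20, 20, 14, 5, 10)
  st <- trace_stack(list(p1, p2))
  expect_identical(project_binary(st), pmax(p1, p2))
  # idempotence: identical plane repeated
  st2 <- trace_stack(list(p1, p1, p1))
  expect_identical(project_binary(st2), p1)
  expect_identical(project_binary(st, z_range = c(0, 0)), p1)
  expect_error(project_binary(st, z_range = c(1, 0)), "z_range")
  expect_error(project_binary(st, z_range = c(0, 5)), "z_range")
})

test_that("map projection contains exactly the retained segment pixels", {
  f <- generate_field(synthetic_field_spec(
    width = 150, height = 150, n_sections = 3,
    clusters = list(cluster_spec(20, 4, 20, c(12, 12, 138, 138))),
    seed = 33, allow_crossings = TRUE))
  m <- orientation_map(f$stack)
  proj <- project_binary(m)
  union_px <- matrix(0L, 150, 150)
  for (s in m$segments)
    union_px[cbind(s$pixels[, "y"] + 1L, s$pixels[, "x"] + 1L)] <- 1L
  expect_identical(proj, union_px)
  # and it is a subset of the raw stack projection
  expect_true(all(proj <= project_binary(f$stack)))
})

test_that("the hue LUT is a monotone rainbow with distinct entries", {
  lut <- hue_lut(32)
  expect_equal(lut$n_bins, 32L)
  expect_equal(anyDuplicated(lut$hex), 0L)
  expect_true(all(diff(lut$hues) > 0))
  expect_equal(lut$hues[1], 0)
  expect_equal(lut$hues[32], 300)
  strip <- lut_ruler(lut, height = 3, px_per_bin = 2)
  expect_equal(dim(strip), c(3, 64, 3))
  expect_error(hue_lut(0), "n_bins")
})

test_that("rendered projections paint segments by bin color with topmost overlap", {
  h <- line_plane(20, 40, 5, 4, 12)          # horizontal, bin 0
  v <- matrix(0L, 20, 40); v[3:14, 31] <- 1L # vertical, 90 deg -> bin 16
  m <- orientation_map(trace_stack(list(pmax(h, v))))
  lut <- hue_lut(32)
  img <- render_colored_projection(m, lut)
  cols <- unique(apply(matrix(img, ncol = 3), 1, paste, collapse = ","))
  cols <- setdiff(cols, "0,0,0")
  expect_setequal(cols, apply(lut$rgb[c(1, 17), ], 1, paste, collapse = ","))
  # all pixels of the horizontal segment carry lut[bin 0]
  expect_true(all(img[6, 5:16, 1] == lut$rgb[1, 1] &
                  img[6, 5:16, 2] == lut$rgb[1, 2] &
                  img[6, 5:16, 3] == lut$rgb[1, 3]))

  # overlap in projection: the topmost (largest plane index) wins
  a <- line_plane(10, 20, 4, 2, 12)
  b <- matrix(0L, 10, 20); b[2:9, 8] <- 1L  # crosses `a` at (7, 4)
  m2 <- orientation_map(trace_stack(list(a, b)))
  img2 <- render_colored_projection(m2)
  expect_equal(as.numeric(img2[5, 8, ]), as.numeric(lut$rgb[17, ]))

  # degenerate segments are painted the reserved gray
  pl <- line_plane(15, 15, 2, 2, 8); pl[10, 10] <- 1L
  m3 <- orientation_map(trace_stack(list(pl)), min_segment_length = 1)
  img3 <- render_colored_projection(m3)
  expect_equal(as.numeric(img3[10, 10, ]), rep(0.5, 3))

  expect_error(render_colored_projection(m, hue_lut(16)), "configuration")
})

test_that("angular histograms count segments or pixels per bin", {
  planes <- list(line_plane(30, 30, 3, 2, 8),
                 line_plane(30, 30, 13, 2, 8),
                 line_plane(30, 30, 23, 2, 8))
  m <- orientation_map(trace_stack(planes))
  h <- angular_histogram(m)
  expect_equal(h$counts[1], 3)
  expect_equal(sum(h$counts), 3)
  expect_equal(h$total, length(m$segments) - m$n_degenerate)

  # per-pixel weighting of one 10-pixel segment at 45 degrees -> bin 8
  d <- matrix(0L, 15, 15)
  d[cbind(1:10, 1:10)] <- 1L
  md <- orientation_map(trace_stack(list(d)))
  hp <- angular_histogram(md, "pixel")
  expect_equal(hp$counts[9], 10)
  expect_equal(sum(hp$counts), 10)

  empty <- orientation_map(trace_stack(list(matrix(0L, 8, 8))))
  expect_true(all(angular_histogram(empty)$counts == 0))
})

test_that("the nematic order parameter hits its analytic limits", {
  expect_equal(axial_order(rep(37, 5))$order_parameter, 1)
  expect_equal(axial_order(rep(37, 5))$mean_axis_deg, 37)
  orth <- axial_order(c(0, 90))
  expect_lt(orth$order_parameter, 1e-12)
  expect_true(is.na(orth$mean_axis_deg))
  set.seed(8)
  expect_lt(axial_order(runif(10000, 0, 180))$order_parameter, 0.05)
  expect_error(axial_order(numeric(0)), "angles")
  expect_error(axial_order(NA_real_), "angles")
})

test_that("S is rotation-invariant and the mean axis shifts by the rotation", {
  set.seed(21)
  ang <- sample_axial_angle(40, 6, 200)
  base <- axial_order(ang)
  for (phi in c(13.7, 90, 145)) {
    rot <- axial_order((ang + phi) %% 180)
    expect_equal(rot$order_parameter, base$order_parameter, tolerance = 1e-12)
    expect_lt(axial_delta(rot$mean_axis_deg, base$mean_axis_deg + phi), 1e-9)
  }
  # relabeling (permutation) leaves S unchanged
  perm <- axial_order(sample(ang))
  expect_equal(perm$order_parameter, base$order_parameter, tolerance = 1e-12)
})

test_that("pixel weighting emphasises long segments", {
  long <- line_plane(40, 60, 5, 2, 50)                  # 0 deg, 50 px
  short <- matrix(0L, 40, 60); short[20:29, 30] <- 1L   # 90 deg, 10 px
  m <- orientation_map(trace_stack(list(pmax(long, short))))
  s_seg <- axial_order(m, "segment")$order_parameter
  s_px <- axial_order(m, "pixel")$order_parameter
  expect_lt(s_seg, 1e-12)       # equal weights, orthogonal pair cancels
  expect_equal(s_px, 40 / 60)   # |50 - 10| / (50 + 10)
})

test_that("condition comparison reports Delta S and rejects bin mismatches", {
  f <- generate_field(synthetic_field_spec(
    width = 150, height = 150, n_sections = 2,
    clusters = list(cluster_spec(10, 50, 30, c(12, 12, 138, 138))),
    seed = 3))
  m <- orientation_map(f$stack)
  same <- compare_conditions(m, m)
  expect_equal(same$delta_S, 0)
  # ordered vs isotropic: Delta S approaches 1 (the isotropic S shrinks
  # as 1/sqrt(n), so a few hundred fibers pin it near zero)
  fo <- generate_field(synthetic_field_spec(
    width = 400, height = 400, n_sections = 4,
    clusters = list(cluster_spec(55, 1e8, 200, c(25, 25, 375, 375))),
    seed = 4))
  fi <- generate_field(synthetic_field_spec(
    width = 400, height = 400, n_sections = 4,
    clusters = list(cluster_spec(0, 0, 200, c(25, 25, 375, 375))),
    seed = 5))
  cmp <- compare_conditions(orientation_map(fo$stack),
                            orientation_map(fi$stack))
  expect_gt(cmp$delta_S, 0.85)
  m16 <- orientation_map(f$stack, n_bins = 16)
  expect_error(compare_conditions(m, m16), "n_bins")
})

test_that("distinct rendered colors equal occupied histogram bins", {
  set.seed(77)
  for (rep in 1:3) {
    f <- generate_field(synthetic_field_spec(
      width = 200, height = 200, n_sections = 3,
      clusters = list(cluster_spec(runif(1, 0, 180), 20, 40,
                                   c(15, 15, 185, 185))),
      seed = 760 + rep, allow_crossings = TRUE))
    m <- orientation_map(f$stack)
    lut <- hue_lut(m$n_bins)
    img <- render_colored_projection(m, lut)
    cols <- setdiff(unique(apply(matrix(img, ncol = 3), 1,
                                 paste, collapse = ",")), "0,0,0")
    occupied <- which(angular_histogram(m)$counts > 0)
    want <- apply(lut$rgb[occupied, , drop = FALSE], 1, paste, collapse = ",")
    if (m$n_degenerate > 0) want <- c(want, "0.5,0.5,0.5")
    expect_setequal(cols, want)
  }
})

test_that("histogram and image files are written readably", {
  f <- generate_field(synthetic_field_spec(
    width = 120, height = 120, n_sections = 2,
    clusters = list(cluster_spec(140, 30, 20, c(12, 12, 108, 108))),
    seed = 6))
  m <- orientation_map(f$stack)
  hpath <- withr::local_tempfile(fileext = ".tsv")
  write_histogram(angular_histogram(m), hpath)
  back <- read.delim(hpath)
  expect_equal(nrow(back), 32L)
  expect_equal(sum(back$count), length(m$segments) - m$n_degenerate)
  ppath <- withr::local_tempfile(fileext = ".png")
  write_projection_png(render_colored_projection(m), ppath)
  expect_equal(dim(png::readPNG(ppath))[1:2], c(120L, 120L))
  tpath <- withr::local_tempfile(fileext = ".tif")
  write_projection_tiff(project_binary(m), tpath)
  expect_equal(dim(tiff::readTIFF(tpath)), c(120L, 120L))
})
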