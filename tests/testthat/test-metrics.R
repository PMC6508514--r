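test_that("total length converts the pixel count with the calibration", {
  m <- matrix(FALSE, 30, 40)
  m[10, 3:22] <- TRUE  # 20 px line
  sk <- skeleton_from_mask(m, pixel_size = 0.2)
  expect_equal(total_length(sk), 20 * 0.2 / 1000)

  empty <- skeleton_from_mask(matrix(FALSE, 10, 10))
  expect_identical(total_length(empty), 0)

  sk$pixel_size_xy <- NA_real_
  expect_error(total_length(sk), "calibration")
})

test_that("mean intensity is the arithmetic mean over skeleton pixels", {
  m <- matrix(FALSE, 10, 10); m[5, 3:5] <- TRUE
  sk <- skeleton_from_mask(m, intensities = c(10, 20, 30))
  expect_equal(as.numeric(mean_intensity(sk)), 20)

  empty <- skeleton_from_mask(matrix(FALSE, 5, 5))
  mi <- mean_intensity(empty)
  expect_true(is.na(mi))
  expect_identical(attr(mi, "reason"), "empty_skeleton")
})

test_that("skewness matches the population-moment definition and its edge cases", {
  expect_equal(as.numeric(intensity_skewness(c(10, 20, 30))), 0)
  expect_gt(as.numeric(intensity_skewness(c(1, 1, 1, 1, 100))), 0)

  # degenerate inputs are flagged, not zeroed
  expect_identical(attr(intensity_skewness(c(5, 5, 5, 5)), "reason"),
                   "constant_intensity")
  expect_identical(attr(intensity_skewness(c(1, 2)), "reason"), "too_few_pixels")

  set.seed(41)
  x <- stats::rexp(1000, rate = 1 / 50)
  expect_equal(as.numeric(intensity_skewness(x)), oracle_skewness(x),
               tolerance = 1e-12)
})

test_that("skewness is invariant under affine intensity maps with a > 0", {
  set.seed(42)
  x <- stats::rlnorm(500, 5, 0.6)
  s0 <- as.numeric(intensity_skewness(x))
  for (ab in list(c(3.5, 0), c(1, 120), c(0.02, -1))) {
    expect_equal(as.numeric(intensity_skewness(ab[1] * x + ab[2])), s0,
                 tolerance = 1e-9)
  }
})

test_that("pair orientation counts match an exhaustive all-pairs loop", {
  horiz <- mask_from_pixels(cbind(5, 3:12))
  expect_identical(pair_orientation_counts(horiz),
                   c(n0 = 9, n45 = 0, n90 = 0, n135 = 0))

  stair <- mask_from_pixels(cbind(12:3, 3:12))  # up-right diagonal
  expect_identical(pair_orientation_counts(stair),
                   c(n0 = 0, n45 = 9, n90 = 0, n135 = 0))

  set.seed(7)
  for (i in 1:25) {
    m <- matrix(stats::runif(15 * 15) < 0.2, 15, 15)
    expect_identical(unname(pair_orientation_counts(m)) * 1,
                     unname(oracle_pair_counts(m)) * 1)
  }
})

test_that("parallelness follows the printed contrast formula", {
  expect_equal(as.numeric(parallelness(c(n0 = 9, n45 = 0, n90 = 0, n135 = 0))), 1)
  expect_equal(as.numeric(parallelness(c(n0 = 5, n45 = 5, n90 = 5, n135 = 5))), 0)
  expect_equal(as.numeric(parallelness(c(n0 = 3, n45 = 1, n90 = 7, n135 = 2))), 5 / 13)
  expect_identical(attr(parallelness(c(n0 = 0, n45 = 0, n90 = 0, n135 = 0)), "reason"),
                   "no_pairs")
  set.seed(11)
  for (i in 1:20) {
    cts <- c(n0 = sample(0:9, 1), n45 = sample(0:9, 1),
             n90 = sample(0:9, 1), n135 = sample(0:9, 1))
    if (sum(cts) == 0) next
    expect_equal(as.numeric(parallelness(cts)), oracle_parallelness(cts),
                 tolerance = 1e-12)
  }
})

test_that("axial mean uses the doubled-angle construction", {
  expect_equal(as.numeric(axial_mean(c(40, 40, 40))), 40)
  # axial wrap: 10 and 170 average to 0, not 90
  expect_equal(as.numeric(axial_mean(c(10, 170))), 0, tolerance = 1e-9)
  expect_identical(attr(axial_mean(c(0, 90)), "reason"), "balanced_orientation")
  expect_identical(attr(axial_mean(numeric(0)), "reason"), "no_pairs")
})

test_that("mean fiber angle recovers straight-line orientations", {
  horiz <- mask_from_pixels(cbind(5, 3:12))
  expect_equal(as.numeric(mean_fiber_angle(horiz)), 0)
  vert <- mask_from_pixels(cbind(3:12, 5))
  expect_equal(as.numeric(mean_fiber_angle(vert)), 90)
  stair <- mask_from_pixels(cbind(12:3, 3:12))
  expect_equal(as.numeric(mean_fiber_angle(stair)), 45)
  expect_identical(attr(mean_fiber_angle(matrix(FALSE, 4, 4)), "reason"), "no_pairs")
})

test_that("delta theta implements the piecewise rule verbatim", {
  expect_equal(delta_theta(30, 30), 0)
  expect_equal(delta_theta(10, 120), 20)   # |d| = 110 > 90 -> 110 - 90
  expect_equal(delta_theta(0, 90), 90)     # boundary of the first branch
  set.seed(13)
  for (i in 1:50) {
    tp <- stats::runif(1, 0, 180); tc <- stats::runif(1, 0, 180)
    expect_equal(delta_theta(tp, tc), oracle_delta_theta(tp, tc), tolerance = 1e-12)
  }
})

test_that("compute_all is consistent with the individual metric operations", {
  set.seed(3)
  m <- mask_from_pixels(cbind(8, 3:14), nr = 24, nc = 24)
  ints <- stats::rlnorm(sum(m), 6, 0.4)
  sk <- skeleton_from_mask(m, intensities = ints)
  region <- load_or_segment_region(
    projection_image(matrix(1, 24, 24) + 0, 0.2),
    mask = ellipse_mask(24, 24, 10, 8))
  out <- compute_all(sk, region, cell_id = "unit")

  expect_equal(out$total_length_mm, total_length(sk))
  expect_equal(out$mean_intensity, as.numeric(mean_intensity(sk)))
  expect_equal(out$skewness, as.numeric(intensity_skewness(sk)))
  expect_equal(out$parallelness, as.numeric(parallelness(sk)))
  expect_equal(out$theta_cellulose, as.numeric(mean_fiber_angle(sk)))
  expect_equal(out$delta_theta,
               delta_theta(region$theta_protoplast, out$theta_cellulose))
  expect_equal(out$stddev_per_mean, out$sigma / out$mean_intensity)

  df <- as.data.frame(out)
  expect_identical(names(df),
                   c("cell_id", "shape_class", "aspect_ratio", "theta_protoplast",
                     "i_nPix", "total_length_mm", "total_length_corrected_mm",
                     "i_mean", "i_stddevPerMean", "i_skewness",
                     "n0", "n45", "n90", "n135",
                     "a_normAvgRad", "a_avgTheta", "delta_theta_deg",
                     "missing_reason"))
})

test_that("an empty skeleton yields zero length and flagged missing metrics", {
  sk <- skeleton_from_mask(matrix(FALSE, 24, 24))
  region <- load_or_segment_region(
    projection_image(matrix(1, 24, 24) + 0, 0.2),
    mask = ellipse_mask(24, 24, 10, 8))
  out <- compute_all(sk, region)
  expect_identical(out$total_length_mm, 0)
  expect_true(is.na(out$mean_intensity))
  expect_true(is.na(out$skewness))
  expect_true(is.na(out$parallelness))
  expect_match(out$missing_reason, "empty_skeleton")
  df <- as.data.frame(out)
  expect_true(is.na(df$i_mean) && is.na(df$a_avgTheta))
})

test_that("metrics transform correctly under joint 90-degree rotation", {
  set.seed(23)
  sc <- generate_scene(scene_params(seed = 77, image_size = 160L, n_fibers = 15L))
  proj <- max_intensity_projection(sc$stack)
  skel <- extract_skeleton(proj)
  region <- load_or_segment_region(proj, scene_cell_mask(sc))
  msk <- mask_skeleton(skel, region)
  m0 <- compute_all(msk, region)

  # rotate the extracted skeleton and the mask together as data
  rot_mask <- rotate90(msk$skeleton)
  rot_ref <- rotate90(msk$reference)
  sk_r <- prune_skeleton(rot_mask, msk$shave_len, msk$del_len, rot_ref,
                         msk$pixel_size_xy)
  region_r <- load_or_segment_region(
    projection_image(rotate90(proj$pixels), proj$pixel_size_xy),
    mask = rotate90(region$mask))
  m1 <- compute_all(sk_r, region_r)

  expect_equal(m1$parallelness, m0$parallelness, tolerance = 1e-12)
  # the axial angular offset is rotation-invariant by construction (the
  # verbatim piecewise rule is not, when the 180-degree wrap moves a
  # difference across its 90-degree breakpoint)
  expect_equal(m1$delta_theta_axial, m0$delta_theta_axial, tolerance = 1e-6)
  expect_equal((m1$theta_cellulose - m0$theta_cellulose) %% 180, 90,
               tolerance = 1e-6)
  expect_identical(m1$n_cellulose, m0$n_cellulose)
})
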