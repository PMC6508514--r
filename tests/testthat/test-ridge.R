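test_that("ridge parameter validation enforces the documented domains", {
  p <- ridge_params()
  expect_identical(p$giws_iter, 8L)
  expect_identical(p$mdnms_len, 7L)
  expect_identical(p$pickup, "above")
  expect_identical(p$shave_len, 5L)
  expect_identical(p$del_len, 5L)
  expect_error(ridge_params(mdnms_len = 6), "odd")
  expect_error(ridge_params(giws_iter = -1), "giws_iter")
  expect_error(ridge_params(shave_len = -2), "shave_len")
})

test_that("smoothing: identity at zero iterations, constants fixed, peaks spread", {
  set.seed(2)
  img <- projection_image(matrix(stats::runif(400) * 100, 20, 20), 0.2)
  expect_identical(smooth_giws(img, 0)$pixels, img$pixels)

  cst <- projection_image(matrix(42, 16, 16) + 0, 0.2)
  expect_equal(smooth_giws(cst, 8)$pixels, cst$pixels, tolerance = 1e-9)

  peak <- matrix(0, 21, 21); peak[11, 11] <- 1000
  sm <- smooth_giws(projection_image(peak, 0.2), 8)$pixels
  expect_lt(sm[11, 11], 1000)                  # peak strictly decreased
  expect_gt(sm[11, 12], 0)                     # mass spread to neighbours
  expect_true(all(sm >= 0) && max(sm) <= 1000) # bounded by input range
})

test_that("oriented line response matches the exhaustive per-pixel oracle", {
  p <- ridge_params(mdnms_len = 5L)
  set.seed(3)
  img <- matrix(stats::runif(15 * 15) * 100, 15, 15)
  resp <- mdnms_line_response(projection_image(img, 0.2), p)
  oracle <- oracle_line_response(img, 5L, resp$angles)
  for (d in seq_along(resp$angles))
    expect_equal(resp$per_direction[[d]], oracle[, , d], tolerance = 1e-12)
  expect_equal(resp$response, apply(oracle, c(1, 2), max), tolerance = 1e-12)
})

test_that("ideal thin lines respond at full strength along their direction", {
  p <- ridge_params()
  img <- matrix(0, 31, 31); img[16, 5:27] <- 500   # horizontal line
  resp <- mdnms_line_response(projection_image(img, 0.2), p)
  expect_equal(resp$response[16, 16], 500)          # kernel fully on the line
  expect_equal(resp$angles[resp$direction[16, 16]], 0)
  # rotate by 90 degrees: vertical line picks the 90-degree direction
  respv <- mdnms_line_response(projection_image(t(img), 0.2), p)
  expect_equal(respv$angles[respv$direction[16, 16]], 90)
})

test_that("pickup = below extracts dark lines on a bright background", {
  img <- matrix(800, 31, 31); img[16, 5:27] <- 100
  sk <- extract_skeleton(projection_image(img, 0.2),
                         ridge_params(giws_iter = 2L, pickup = "below"))
  expect_gt(sum(sk$skeleton[16, 8:24]), 10)
  expect_equal(sum(sk$skeleton[-16, ]), 0)
})

test_that("non-maximum suppression reduces a bright band to its centerline", {
  p <- ridge_params(giws_iter = 0L)
  img <- matrix(0, 31, 41)
  img[15, 5:37] <- 300; img[16, 5:37] <- 600; img[17, 5:37] <- 300
  resp <- mdnms_line_response(projection_image(img, 0.2), p)
  cand <- non_maximum_suppression(resp)
  expect_true(all(which(cand, arr.ind = TRUE)[, 1] == 16))  # centre row only
  expect_gt(sum(cand[16, ]), 20)

  # constant image: no strict maxima anywhere
  rc <- mdnms_line_response(projection_image(matrix(5, 20, 20) + 0, 0.2), p)
  expect_equal(sum(non_maximum_suppression(rc)), 0)
})

test_that("both centerlines survive where two lines cross", {
  p <- ridge_params(giws_iter = 1L)
  img <- matrix(0, 41, 41)
  img[21, 4:38] <- 1000                            # bright horizontal
  img[4:38, 21] <- pmax(img[4:38, 21], 500)        # dimmer vertical
  sk <- extract_skeleton(projection_image(img, 0.2), p)
  horiz <- mask_from_pixels(cbind(21, 8:34), 41, 41)
  vert <- mask_from_pixels(cbind(8:34, 21), 41, 41)
  expect_gt(coverage_1px(horiz, sk$skeleton), 0.9)
  expect_gt(coverage_1px(vert, sk$skeleton), 0.9)
})

test_that("pruning shaves short spurs and deletes small components", {
  # 50-px line with a 3-px spur: spur goes, line stays
  m <- matrix(FALSE, 60, 60)
  m[30, 5:54] <- TRUE
  m[cbind(29:27, 20:22)] <- TRUE
  sk <- prune_skeleton(m, shave_len = 5L, del_len = 5L, pixel_size_xy = 0.2)
  expect_true(all(sk$skeleton[30, 5:54]))
  expect_equal(sum(sk$skeleton), 50)

  # isolated 4-px blob deleted at del_len = 5
  b <- matrix(FALSE, 20, 20); b[cbind(c(5, 5, 6, 6), c(5, 6, 5, 7))] <- TRUE
  expect_equal(sum(prune_skeleton(b, 5L, 5L)$skeleton), 0)

  # empty input is a valid empty skeleton
  e <- prune_skeleton(matrix(FALSE, 10, 10), 5L, 5L)
  expect_equal(sum(e$skeleton), 0)
  expect_length(e$intensities, 0)
})

test_that("pruning matches a literal-loop shave-then-delete reference", {
  set.seed(17)
  for (i in 1:30) {
    raw <- matrix(stats::runif(20 * 20) < 0.25, 20, 20)
    thin <- fibrilquant:::.thin_mask(raw)
    shave <- sample(0:6, 1); del <- sample(0:6, 1)
    got <- prune_skeleton(thin, shave, del)$skeleton
    want <- oracle_prune(thin, shave, del)
    expect_identical(got, want)
  }
})

test_that("extraction is deterministic, scale-invariant and stays one pixel wide", {
  sc <- generate_scene(scene_params(seed = 31, image_size = 160L, n_fibers = 12L))
  proj <- max_intensity_projection(sc$stack)
  s1 <- extract_skeleton(proj)
  s2 <- extract_skeleton(proj)
  expect_identical(s1$skeleton, s2$skeleton)       # no RNG in this path

  s3 <- extract_skeleton(projection_image(proj$pixels * 4.2, proj$pixel_size_xy))
  expect_identical(s3$skeleton, s1$skeleton)       # relative threshold

  # one-pixel width: no fully-foreground 2x2 block
  M <- s1$skeleton * 1
  blocks <- M[-nrow(M), -ncol(M)] + M[-1, -ncol(M)] + M[-nrow(M), -1] + M[-1, -1]
  expect_equal(sum(blocks == 4), 0)

  # blank image gives an empty skeleton
  expect_equal(sum(extract_skeleton(projection_image(matrix(0, 64, 64), 0.2))$skeleton), 0)
})

test_that("rotating the image by 90 degrees rotates the skeleton with it", {
  sc <- generate_scene(scene_params(seed = 8, image_size = 160L, n_fibers = 12L))
  proj <- max_intensity_projection(sc$stack)
  s0 <- extract_skeleton(proj)
  sr <- extract_skeleton(projection_image(rotate90(proj$pixels), proj$pixel_size_xy))
  agree <- mean(rotate90(s0$skeleton) == sr$skeleton)
  # thinning sub-passes are directional, so covariance is near- but not
  # bit-exact
  expect_gt(agree, 0.98)
  expect_lt(abs(sum(s0$skeleton) - sum(sr$skeleton)) / sum(s0$skeleton), 0.03)
})
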