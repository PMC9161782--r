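# Feature matching, robust similarity estimation, stack registration.

make_pair <- function(tf, seed = 5) {
  sc <- fixture_scene()
  tfs <- rep(list(similarity_transform()), length(mihc_panel()) + 1)
  tfs[[2]] <- tf
  r <- render_round_images(sc, round_transforms = tfs, seed = seed)
  list(fixed = r$rounds[[1]], moving = r$rounds[[2]], rendered = r)
}

test_that("an image matched against itself has zero offset", {
  r <- fixture_rendered()
  cc <- detect_and_match_features(r$rounds[[1]], r$rounds[[1]])
  expect_gte(nrow(cc), 10)
  expect_lt(median(abs(cc$x_fixed - cc$x_moving)), 1)
  expect_lt(median(abs(cc$y_fixed - cc$y_moving)), 1)
})

test_that("a pure translation is recovered by the matcher", {
  pair <- make_pair(similarity_transform(1, 0, 12, -7))
  cc <- detect_and_match_features(pair$fixed, pair$moving)
  # transform maps moving -> fixed: fixed = moving + (12, -7)
  expect_lt(abs(median(cc$x_fixed - cc$x_moving) - 12), 1)
  expect_lt(abs(median(cc$y_fixed - cc$y_moving) + 7), 1)
})

test_that("featureless images raise an insufficient-features error", {
  flat <- array(0.5, c(80, 80, 3))
  expect_error(detect_and_match_features(flat, flat),
               class = "mihc_insufficient_features")
})

test_that("similarity estimation is exact on noiseless correspondences", {
  set.seed(42)
  pts <- cbind(runif(20, 0, 200), runif(20, 0, 200))
  # identity
  cc_id <- tibble::tibble(x_fixed = pts[, 1], y_fixed = pts[, 2],
                          x_moving = pts[, 1], y_moving = pts[, 2])
  tf0 <- estimate_similarity(cc_id, ransac = FALSE)
  expect_equal(tf0$scale, 1, tolerance = 1e-12)
  expect_equal(tf0$angle, 0, tolerance = 1e-12)
  expect_equal(unname(tf0$translation), c(0, 0), tolerance = 1e-12)

  tf_true <- similarity_transform(1.02, 3 * pi / 180, 10, -5)
  mapped <- tf_apply(tf_true, pts)
  cc <- tibble::tibble(x_fixed = mapped[, 1], y_fixed = mapped[, 2],
                       x_moving = pts[, 1], y_moving = pts[, 2])
  tf <- estimate_similarity(cc, ransac = FALSE)
  expect_equal(tf$scale, 1.02, tolerance = 1e-6)
  expect_equal(tf$angle, 3 * pi / 180, tolerance = 1e-6)
  expect_equal(unname(tf$translation), c(10, -5), tolerance = 1e-6)
})

test_that("gross outliers are rejected by the consensus fit", {
  set.seed(7)
  pts <- cbind(runif(20, 0, 200), runif(20, 0, 200))
  tf_true <- similarity_transform(1.02, 3 * pi / 180, 10, -5)
  mapped <- tf_apply(tf_true, pts)
  out_pts <- cbind(runif(6, 0, 200), runif(6, 0, 200))
  cc <- tibble::tibble(
    x_fixed = c(mapped[, 1], out_pts[, 1] + runif(6, 40, 90)),
    y_fixed = c(mapped[, 2], out_pts[, 2] - runif(6, 40, 90)),
    x_moving = c(pts[, 1], out_pts[, 1]),
    y_moving = c(pts[, 2], out_pts[, 2]))
  tf <- estimate_similarity(cc, seed = 3)
  expect_lt(attr(tf, "rms"), 0.5)
  pred <- tf_apply(tf, pts)
  expect_lt(sqrt(mean((pred - mapped)^2)), 0.5)
})

test_that("degenerate correspondence geometry errors out", {
  line <- tibble::tibble(x_fixed = 1:5, y_fixed = 2 * (1:5),
                         x_moving = 1:5, y_moving = 2 * (1:5))
  expect_error(estimate_similarity(line), "degenerate")
  expect_error(estimate_similarity(line[1:2, ]), "at least 3")
})

test_that("registering a rendered stack recovers the planted transforms", {
  sc <- fixture_scene()
  n_round <- length(mihc_panel()) + 1
  tfs <- rep(list(similarity_transform()), n_round)
  tfs[[2]] <- similarity_transform(1.02, 3 * pi / 180, 10, -5)
  tfs[[5]] <- similarity_transform(0.99, -2 * pi / 180, -6, 4)
  r <- render_round_images(sc, round_transforms = tfs, seed = 5)
  stack <- register_stack(r$rounds, reference_round = 0, seed = 1)
  cb <- stack$crop_box
  corners <- cbind(cb[c("xmin", "xmax", "xmax", "xmin")],
                   cb[c("ymin", "ymin", "ymax", "ymax")])
  for (ri in c(2, 5)) {
    est <- stack$transforms[[as.character(ri - 1)]]
    # composition of estimate with true inverse should be near identity
    dev <- tf_apply(est, tf_apply(tf_invert(tfs[[ri]]), corners)) - corners
    expect_lt(max(sqrt(rowSums(dev^2))), 2)
  }
  # all rasters share the cropped shape
  dims <- vapply(stack$marker_rasters, dim, numeric(2))
  expect_true(all(dims[1, ] == nrow(stack$nuclear)))
  expect_true(all(dims[2, ] == ncol(stack$nuclear)))
})

test_that("warping by the estimated transform restores correlation", {
  # same stain content in both frames: round 1 rendered with and without
  # the planted misalignment
  sc <- fixture_scene()
  tf_true <- similarity_transform(1.01, 2 * pi / 180, 6, -3)
  tfs <- rep(list(similarity_transform()), length(mihc_panel()) + 1)
  r_id <- fixture_rendered()
  tfs[[2]] <- tf_true
  r_tf <- render_round_images(sc, round_transforms = tfs, seed = 5)
  fixed <- r_id$rounds[[2]]
  moving <- r_tf$rounds[[2]]
  cc <- detect_and_match_features(fixed, moving)
  tf <- estimate_similarity(cc, seed = 1)
  warped <- warp_image(moving$rgb, tf, fill = 1)
  g_f <- 1 - apply(fixed$rgb, c(1, 2), mean)
  g_w <- 1 - apply(warped, c(1, 2), mean)
  inner <- 30:(nrow(g_f) - 30)
  ncc <- cor(as.vector(g_f[inner, inner]), as.vector(g_w[inner, inner]))
  expect_gte(ncc, 0.95)
})

test_that("registration is idempotent", {
  pair <- make_pair(similarity_transform(1.01, 1.5 * pi / 180, 5, 3))
  cc <- detect_and_match_features(pair$fixed, pair$moving)
  tf <- estimate_similarity(cc, seed = 1)
  warped <- structure(list(roi_id = pair$moving$roi_id, round_index = 1,
                           marker = pair$moving$marker,
                           rgb = warp_image(pair$moving$rgb, tf, fill = 1),
                           pixel_size_um = pair$moving$pixel_size_um),
                      class = "mihc_round")
  cc2 <- detect_and_match_features(pair$fixed, warped)
  tf2 <- estimate_similarity(cc2, seed = 1)
  corners <- cbind(c(0, 200, 200, 0), c(0, 0, 200, 200))
  dev <- tf_apply(tf2, corners) - corners
  expect_lt(max(sqrt(rowSums(dev^2))), 0.5)
})

test_that("crop box pixels map inside every source round", {
  sc <- fixture_scene()
  n_round <- length(mihc_panel()) + 1
  tfs <- rep(list(similarity_transform()), n_round)
  tfs[[3]] <- similarity_transform(1.015, 2.5 * pi / 180, 8, -6)
  r <- render_round_images(sc, round_transforms = tfs, seed = 5)
  stack <- register_stack(r$rounds, reference_round = 0, seed = 1)
  cb <- stack$crop_box
  corners <- cbind(cb[c("xmin", "xmax", "xmax", "xmin")],
                   cb[c("ymin", "ymin", "ymax", "ymax")])
  H <- dim(r$rounds[[1]]$rgb)[1]; W <- dim(r$rounds[[1]]$rgb)[2]
  for (key in names(stack$transforms)) {
    src <- tf_apply(tf_invert(stack$transforms[[key]]), corners)
    expect_true(all(src[, 1] >= -0.51 & src[, 1] <= W - 0.49 &
                      src[, 2] >= -0.51 & src[, 2] <= H - 0.49),
                info = paste("round", key))
  }
})

test_that("single-round and malformed stacks are handled", {
  r <- fixture_rendered()
  stack <- register_stack(r$rounds[1], reference_round = 0)
  tf <- stack$transforms[["0"]]
  expect_equal(tf$scale, 1)
  expect_equal(unname(stack$crop_box),
               c(0, ncol(stack$nuclear) - 1, 0, nrow(stack$nuclear) - 1))
  bad <- r$rounds[1:2]
  bad[[2]]$pixel_size_um <- 0.5
  expect_error(register_stack(bad, 0), "pixel size")
})

test_that("transforms survive a JSON round trip", {
  tfs <- list("0" = similarity_transform(),
              "1" = similarity_transform(1.02, 3 * pi / 180, 10, -5))
  f <- tempfile(fileext = ".json")
  write_transforms(tfs, 0, f)
  back <- read_transforms(f)
  expect_equal(back$reference_round, 0)
  expect_equal(back$transforms[["1"]]$scale, 1.02, tolerance = 1e-12)
  expect_equal(back$transforms[["1"]]$angle, 3 * pi / 180,
               tolerance = 1e-12)
})
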