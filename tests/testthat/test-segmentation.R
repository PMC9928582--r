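test_that("x-y binning averages blocks and rescales spacing", {
  set.seed(42)
  img <- voxel_image(array(runif(40 * 40 * 5), c(40, 40, 5)),
                     c(0.648, 0.648, 1.25))
  b <- bin_xy(img, 2)
  expect_equal(b$spacing, c(1.296, 1.296, 1.25))
  expect_equal(dim(b$data), c(20L, 20L, 5L))
  expect_equal(b$data[1, 1, 1], mean(img$data[1:2, 1:2, 1]))
  # factor 1 is the identity
  expect_identical(bin_xy(img, 1), img)
  # a constant image stays constant under any factor
  cimg <- voxel_image(array(7, c(12, 12, 3)), rep(1, 3))
  expect_true(all(bin_xy(cimg, 3)$data == 7))
  expect_error(bin_xy(img, 0), "factor")
  # non-divisible dims are cropped with a message
  img2 <- voxel_image(array(runif(9 * 9 * 2), c(9, 9, 2)), rep(1, 3))
  expect_message(b2 <- bin_xy(img2, 2), "cropping")
  expect_equal(dim(b2$data), c(4L, 4L, 2L))
})

test_that("Otsu separates a two-delta histogram and rejects constants", {
  y <- voxel_image(array(rep(c(10, 200), 500), c(10, 10, 10)), rep(1, 3))
  thr <- otsu_threshold(y$data)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  mk <- otsu_mask(y)
  expect_identical(unname(mk$labels > 0), unname(y$data >= thr))
  expect_equal(mk$provenance$threshold, thr)
  # inverted contrast with the polarity flag gives the complement
  mk2 <- otsu_mask(voxel_image(250 - y$data, rep(1, 3)), polarity = "dark")
  expect_identical(mk2$labels > 0, mk$labels > 0)
  expect_error(otsu_mask(voxel_image(array(5, c(4, 4, 4)), rep(1, 3))),
               "no threshold")
})

test_that("volume-wise Otsu agrees with the EBImage reference", {
  skip_if_not_installed("EBImage")
  set.seed(5)
  x <- c(rnorm(4000, 30, 6), rnorm(1000, 180, 12))
  x <- pmin(pmax(x, 0), 255)
  ours <- otsu_threshold(x, nbins = 256)
  ref <- EBImage::otsu(EBImage::Image(matrix(x / 255, 50, 100)),
                       range = c(0, 1), levels = 256) * 255
  # thresholds may sit anywhere inside an empty histogram valley (argmax
  # ties); the foreground assignment must agree exactly
  expect_identical(x >= ours, x >= ref)
})

test_that("Otsu masks are invariant under increasing affine intensity maps", {
  vx <- cached("noisy_sphere_seg", voxelize(synthetic_scene(
    shape_spec("sphere", R = 20), voxel_spacing = rep(2, 3),
    noise_sd = 8, seed = 7)))
  m1 <- otsu_mask(vx$apical)
  img2 <- vx$apical
  img2$data <- 2.5 * img2$data + 40
  m2 <- otsu_mask(img2)
  expect_identical(m1$labels, m2$labels)
})

test_that("multi-Otsu matches exact multilevel images and a brute-force oracle", {
  # tri-level image, classes = 3, lowest threshold -> {100, 200} foreground
  x <- voxel_image(array(rep(c(0, 100, 200), c(500, 300, 200)), c(10, 10, 10)),
                   rep(1, 3))
  m3 <- multiotsu_mask(x, classes = 3, take = "lowest")
  expect_identical(unname(m3$labels > 0), unname(x$data >= 100))
  # quad-level image, classes = 4, highest threshold -> {240} foreground
  x4 <- voxel_image(array(rep(c(0, 80, 160, 240), 250), c(10, 10, 10)),
                    rep(1, 3))
  m4 <- multiotsu_mask(x4, classes = 4, take = "highest")
  expect_identical(unname(m4$labels > 0), unname(x4$data == 240))

  # oracle: exhaustive search over a small histogram in plain R
  set.seed(9)
  y <- sample(c(rnorm(300, 10, 2), rnorm(300, 50, 4), rnorm(200, 120, 6)))
  nb <- 32L
  h <- hist(y, breaks = seq(min(y), max(y), length.out = nb + 1), plot = FALSE)
  cnt <- as.numeric(h$counts); mid <- h$mids
  best <- -Inf; best_t <- NULL
  for (t1 in 1:(nb - 2)) for (t2 in (t1 + 1):(nb - 1)) {
    sp <- list(1:t1, (t1 + 1):t2, (t2 + 1):nb)
    v <- sum(vapply(sp, function(ix) {
      w <- sum(cnt[ix]); if (w == 0) return(0)
      mu <- sum(cnt[ix] * mid[ix]) / w
      w * mu^2
    }, numeric(1)))
    if (v > best) { best <- v; best_t <- c(t1, t2) }
  }
  oracle <- h$breaks[best_t + 1]
  ours <- multiotsu_thresholds(y, classes = 3, nbins = nb)
  expect_equal(ours, oracle)
})

test_that("apical multi-Otsu isolates the bright shell over dim tissue", {
  vx <- cached("actin_sphere", voxelize(synthetic_scene(
    shape_spec("sphere", R = 25), voxel_spacing = rep(1.5, 3),
    noise_sd = 4, seed = 2, apical_style = "actin")))
  mk <- multiotsu_mask(vx$apical, classes = 4, take = "highest")
  # the mask must be the thin shell: its voxel count is close to the
  # shell volume 4*pi*R^2*2w, far below the enclosed lumen volume
  nvox <- sum(mk$labels > 0)
  shell_vox <- 4 * pi * 25^2 * 2 * 1.5 / 1.5^3
  expect_lt(abs(nvox / shell_vox - 1), 0.35)
  # and the filled shell recovers the lumen solid
  lum <- lumen_solid(mk)
  vol <- sum(lum$labels > 0) * 1.5^3
  expect_lt(abs(vol / (4 / 3 * pi * 25^3) - 1), 0.05)
})

test_that("noiseless sphere mask volume converges to the analytic volume", {
  errs <- vapply(c(5, 2.5, 1.25), function(sp) {
    vx <- voxelize(synthetic_scene(shape_spec("sphere", R = 50),
                                   voxel_spacing = rep(sp, 3)))
    mk <- lumen_solid(otsu_mask(vx$apical))
    abs(sum(mk$labels > 0) * sp^3 / (4 / 3 * pi * 50^3) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))        # monotone error decrease
  expect_lt(errs[3], 0.02)
})

test_that("shrinkage correction scales by dimension and refuses reapplication", {
  expect_equal(unname(apply_shrinkage_correction(60.3, 0.603)), 100,
               ignore_attr = TRUE)
  expect_equal(unname(apply_shrinkage_correction(0.603^3 * 500, 0.603,
                                                 kind = "volume")), 500,
               ignore_attr = TRUE)
  x1 <- apply_shrinkage_correction(10, 1)
  expect_equal(as.numeric(x1), 10)
  df <- data.frame(V = 0.603^3, A = 0.603^2, M = 0.603, v = 0.5, g = 1L)
  cd <- apply_shrinkage_correction(df, 0.603)
  expect_equal(cd$V, 1); expect_equal(cd$A, 1); expect_equal(cd$M, 1)
  expect_equal(cd$v, 0.5)                 # dimensionless untouched
  expect_error(apply_shrinkage_correction(cd, 0.603), "already applied")
  expect_error(apply_shrinkage_correction(1, 1.5), "factor")
})
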