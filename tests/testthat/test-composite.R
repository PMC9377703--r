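test_that("contour rasterization draws a circle of the right length", {
  dense <- make_analytic_shape("ring", n = 90L, R = 8, rho = 1, z = 0)
  ct <- slice_contour(dense, 0, n_theta = 180L) # closed, radius ~ 7
  img <- rasterize_contour(ct, size = 128L, extent = 20)
  n_px <- sum(img$values > 0)
  expected <- 2 * pi * 7 / img$scale
  expect_gt(n_px, 0.8 * expected)
  expect_lt(n_px, 1.2 * expected)

  # doubling the resolution roughly doubles the drawn pixel count
  img2 <- rasterize_contour(ct, size = 256L, extent = 20)
  ratio <- sum(img2$values > 0) / n_px
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)

  # an all-open contour rasterizes to an empty image
  empty <- structure(list(z = 0, theta = c(45, 135, 225, 315),
                          radius = rep(NA_real_, 4), closed = FALSE),
                     class = "PoreContour")
  expect_equal(sum(rasterize_contour(empty, 64L, 20)$values), 0)

  expect_error(rasterize_contour(ct, size = 64L, extent = 10), "smaller")
})

test_that("mean condensation is the exact, order-invariant average", {
  set.seed(7)
  imgs <- lapply(1:4, function(i) {
    raster_image(matrix(runif(64), 8, 8), scale = 1)
  })
  avg <- condense_stack(imgs, mode = "mean")
  manual <- (imgs[[1]]$values + imgs[[2]]$values + imgs[[3]]$values +
             imgs[[4]]$values) / 4
  expect_identical(avg$values, manual)
  perm <- condense_stack(imgs[c(3, 1, 4, 2)], mode = "mean")
  expect_identical(perm$values, avg$values)

  # idempotent on identical stacks
  same <- condense_stack(rep(imgs[1], 5), mode = "mean")
  expect_equal(same$values, imgs[[1]]$values)

  zeros <- raster_image(matrix(0, 4, 4), 1)
  ones <- raster_image(matrix(1, 4, 4), 1)
  half <- condense_stack(list(zeros, ones), mode = "mean")
  expect_true(all(half$values == 0.5))
})

test_that("over-compositing with full opacity is pixelwise max on binary images", {
  set.seed(11)
  bins <- lapply(1:3, function(i) {
    raster_image(matrix(as.numeric(runif(100) > 0.6), 10, 10), scale = 0.5)
  })
  over <- condense_stack(bins, mode = "over", alpha = 1)
  pmax_all <- pmax(bins[[1]]$values, bins[[2]]$values, bins[[3]]$values)
  expect_equal(over$values, pmax_all)
  # order dependence with partial opacity is allowed; values stay in [0,1]
  o2 <- condense_stack(bins, mode = "over", alpha = 0.3)
  expect_true(all(o2$values >= 0 & o2$values <= 1))
  expect_error(condense_stack(bins, mode = "over", alpha = 0), "alpha")
  shrunk <- raster_image(matrix(0, 4, 4), 0.5)
  expect_error(condense_stack(list(bins[[1]], shrunk)), "shape")
})

test_that("motion averaging blurs along the motion direction", {
  mk_frame <- function(x) {
    molecular_assembly(data.frame(
      serial = 1L, element = "C", x = x, y = 0, z = 0, radius = 1.5,
      chain = "A", resno = 1L, resid = "SYN"))
  }
  # one static atom: peak at the projected position
  still <- motion_average(trajectory_stack(list(mk_frame(2))),
                          view_axis = "z", size = 64L, extent = 16,
                          splat_sigma = 1)
  peak <- which(still$values == max(still$values), arr.ind = TRUE)[1, ]
  px <- still$origin[1] + (peak["col"] - 1) * still$scale
  py <- still$origin[2] + (peak["row"] - 1) * still$scale
  expect_lt(abs(px - 2), still$scale)
  expect_lt(abs(py - 0), still$scale)

  # uniform translation along x: second moment larger along x than y
  moving <- trajectory_stack(lapply(seq(-4, 4, length.out = 9), mk_frame))
  img <- motion_average(moving, view_axis = "z", size = 64L, extent = 16,
                        splat_sigma = 1)
  xs <- img$origin[1] + (seq_len(img$width) - 1) * img$scale
  ys <- img$origin[2] + (seq_len(img$height) - 1) * img$scale
  w <- img$values / sum(img$values)
  mx <- sum(t(w) * xs); my <- sum(w * ys)
  var_x <- sum(t(w) * (xs - mx)^2)
  var_y <- sum(w * (ys - my)^2)
  expect_gt(var_x, var_y)

  # duplicated frames change nothing (mean idempotence)
  twice <- trajectory_stack(list(mk_frame(2), mk_frame(2)))
  once <- trajectory_stack(list(mk_frame(2)))
  expect_equal(motion_average(twice, size = 32L, extent = 16)$values,
               motion_average(once, size = 32L, extent = 16)$values)

  # motion blur cannot exceed any single frame's peak (un-normalized)
  frame_peaks <- sapply(moving$frames, function(fr) {
    max(motion_average(trajectory_stack(list(fr)), size = 64L, extent = 16,
                       splat_sigma = 1, normalize = FALSE)$values)
  })
  blur_peak <- max(motion_average(moving, size = 64L, extent = 16,
                                  splat_sigma = 1, normalize = FALSE)$values)
  expect_lte(blur_peak, max(frame_peaks) + 1e-12)

  expect_error(motion_average(once, size = 0L, extent = 16), "size")
  expect_error(motion_average(once, size = 32L, extent = 16,
                              splat_sigma = 0), "sigma")
})

test_that("raster export round-trips values", {
  img <- raster_image(matrix(seq(0, 1, length.out = 36), 6, 6), scale = 2)
  prefix <- tempfile()
  files <- export_raster(img, prefix)
  expect_true(all(file.exists(files)))
  back <- channelkit:::read_tsv_matrix(paste0(prefix, ".tsv"))
  expect_identical(unname(back), img$values)
})
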