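# Raster condensation: overlay a time series of pore contours with
# transparency, and produce motion-averaged stills from trajectories (motion
# blur). Images are plain numeric matrices in [0, 1] with a physical scale.

#' Construct a raster image
#'
#' `values[iy, ix]` covers the point
#' `(origin[1] + (ix-1)*scale, origin[2] + (iy-1)*scale)`: the y coordinate
#' grows with the row index (mathematical orientation); PNG export flips rows
#' into screen orientation.
#'
#' @param values numeric matrix with entries in \[0, 1\].
#' @param scale Angstrom per pixel (> 0).
#' @param origin xy position (A) of the centre of pixel (1, 1).
#' @return object of class `RasterImage`.
#' @export
raster_image <- function(values, scale, origin = c(0, 0)) {
  stopifnot(is.matrix(values), scale > 0, length(origin) == 2L)
  if (any(values < 0 | values > 1)) stop("raster values must lie in [0, 1]")
  structure(list(values = values, scale = scale, origin = as.numeric(origin),
                 width = ncol(values), height = nrow(values)),
            class = "RasterImage")
}

#' @export
print.RasterImage <- function(x, ...) {
  cat(sprintf("RasterImage: %d x %d px, %.3f A/px, %d nonzero\n",
              x$width, x$height, x$scale, sum(x$values > 0)))
  invisible(x)
}

# integer (Bresenham) line rasterization; returns matrix updated in place
draw_line_px <- function(m, x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  repeat {
    if (x0 >= 1L && x0 <= ncol(m) && y0 >= 1L && y0 <= nrow(m)) m[y0, x0] <- 1
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  m
}

#' Rasterize a pore contour
#'
#' Converts the polar boundary samples to xy and draws line segments between
#' consecutive closed-sector samples (value 1 on a 0 background, integer line
#' rasterization). Open sectors leave gaps; the wrap-around segment is drawn
#' when both end samples are closed. The image is a square of `size` pixels
#' spanning `extent` Angstrom, centred on the axis.
#'
#' @param contour a [slice_contour()] result.
#' @param size image side length in pixels (>= 8).
#' @param extent physical side length (A); must cover the contour.
#' @return a [raster_image()].
#' @export
rasterize_contour <- function(contour, size = 256L, extent) {
  stopifnot(inherits(contour, "PoreContour"), size >= 8L, extent > 0)
  rmax <- suppressWarnings(max(contour$radius, na.rm = TRUE))
  if (is.finite(rmax) && 2 * rmax > extent) {
    stop(sprintf("extent %.2f A is smaller than the contour diameter %.2f A",
                 extent, 2 * rmax))
  }
  scale <- extent / size
  origin <- c(-extent / 2 + scale / 2, -extent / 2 + scale / 2)
  m <- matrix(0, size, size)
  th <- contour$theta * pi / 180
  closed_i <- which(!is.na(contour$radius))
  if (length(closed_i) > 0L) {
    px <- round((contour$radius * cos(th) - origin[1]) / scale) + 1L
    py <- round((contour$radius * sin(th) - origin[2]) / scale) + 1L
    n <- length(contour$theta)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (!is.na(contour$radius[i]) && !is.na(contour$radius[j])) {
        m <- draw_line_px(m, px[i], py[i], px[j], py[j])
      }
    }
  }
  raster_image(m, scale, origin)
}

#' Condense an image stack into one still
#'
#' `mode = "mean"` takes the pixelwise arithmetic mean (uniform transparency
#' 1/T; order-independent). `mode = "over"` composites the frames in order
#' with opacity `alpha`, starting from black:
#' `out <- out * (1 - alpha * I_t) + alpha * I_t` -- later frames dominate,
#' matching how transparent prints stack physically.
#'
#' @param images list of `RasterImage` with identical shape and scale.
#' @param mode `"mean"` (default) or `"over"`.
#' @param alpha opacity in (0, 1\] for `"over"`.
#' @return a `RasterImage`.
#' @export
condense_stack <- function(images, mode = c("mean", "over"), alpha = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.list(images), length(images) >= 1L)
  lapply(images, function(im) stopifnot(inherits(im, "RasterImage")))
  ref <- images[[1]]
  for (im in images) {
    if (im$width != ref$width || im$height != ref$height ||
        im$scale != ref$scale) {
      stop("all images must share shape and scale")
    }
  }
  out <- if (mode == "mean") {
    Reduce(`+`, lapply(images, `[[`, "values")) / length(images)
  } else {
    if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
    acc <- matrix(0, ref$height, ref$width)
    for (im in images) {
      acc <- acc * (1 - alpha * im$values) + alpha * im$values
    }
    acc
  }
  raster_image(pmin(pmax(out, 0), 1), ref$scale, ref$origin)
}

#' Motion-averaged still of a trajectory
#'
#' Projects every frame's atom centres orthographically along `view_axis`,
#' splats each as a normalized 2D Gaussian of width `splat_sigma`, and
#' averages the frames with uniform weight -- a motion-blur still in which
#' fast-moving parts smear and stationary parts stay crisp. Projection
#' planes: view `z` -> (x, y), view `x` -> (y, z), view `y` -> (x, z).
#'
#' @param stack a [trajectory_stack()].
#' @param view_axis `"z"`, `"x"` or `"y"`.
#' @param size image side length in pixels.
#' @param extent physical side length (A), centred on the origin.
#' @param splat_sigma Gaussian width (A, > 0).
#' @param normalize max-normalize the final image to \[0, 1\] (default). With
#'   `FALSE` the raw frame-averaged intensity is returned (clamped to 1 only
#'   if it exceeds it), useful for comparing absolute intensities across
#'   stacks.
#' @return a `RasterImage`.
#' @export
motion_average <- function(stack, view_axis = c("z", "x", "y"), size = 128L,
                           extent = 50, splat_sigma = 1, normalize = TRUE) {
  view_axis <- match.arg(view_axis)
  stopifnot(inherits(stack, "TrajectoryStack"))
  if (size < 1L) stop("image size must be positive")
  if (splat_sigma <= 0) stop("splat_sigma must be > 0")
  scale <- extent / size
  grid <- -extent / 2 + scale / 2 + (seq_len(size) - 1L) * scale
  pick <- switch(view_axis, z = c(1L, 2L), x = c(2L, 3L), y = c(1L, 3L))
  amp <- 1 / (2 * pi * splat_sigma^2)
  acc <- matrix(0, size, size)
  for (fr in stack$frames) {
    xy <- coords(fr)[, pick, drop = FALSE]
    # separable Gaussian: image contribution = Gy %*% t(Gx)
    gx <- exp(-outer(grid, xy[, 1L], `-`)^2 / (2 * splat_sigma^2))
    gy <- exp(-outer(grid, xy[, 2L], `-`)^2 / (2 * splat_sigma^2))
    acc <- acc + amp * (gy %*% t(gx))
  }
  acc <- acc / length(stack$frames)
  if (normalize) {
    mx <- max(acc)
    if (mx > 0) acc <- acc / mx
  } else {
    acc <- pmin(acc, 1)
  }
  raster_image(acc, scale, c(-extent / 2 + scale / 2, -extent / 2 + scale / 2))
}

#' Export a raster image as PNG and TSV
#'
#' `<prefix>.png` is an 8-bit grayscale image (linear mapping of \[0, 1\],
#' rows flipped into screen orientation); `<prefix>.tsv` dumps the raw value
#' matrix.
#'
#' @param image a `RasterImage`.
#' @param path_prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
export_raster <- function(image, path_prefix) {
  stopifnot(inherits(image, "RasterImage"))
  f_tsv <- paste0(path_prefix, ".tsv")
  f_png <- paste0(path_prefix, ".png")
  write_tsv_matrix(image$values, f_tsv)
  write_gray_png(image$values[rev(seq_len(image$height)), , drop = FALSE], f_png)
  invisible(c(f_tsv, f_png))
}
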