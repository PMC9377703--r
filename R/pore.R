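# Pore geometry along the channel axis. The pore radius at height z is the
# radius of the largest probe sphere centred ON the axis at (0,0,z) that
# clashes with no atom: r(z) = max(0, min_i(||c_i - (0,0,z)|| - rho_i)).
# This deterministic on-axis definition matches axis-slice illustrations;
# off-axis probe relaxation (as in Monte-Carlo pore finders) is future work.

#' Pore radius at a height on the axis
#'
#' @param assembly canonical-frame `MolecularAssembly` with radii.
#' @param z height (A).
#' @return list with `radius` (A, >= 0) and `blocked` (TRUE when the axis
#'   point itself lies inside an atom, in which case radius is 0).
#' @export
pore_radius_at <- function(assembly, z) {
  stopifnot(inherits(assembly, "MolecularAssembly"))
  rad <- assembly$atoms$radius
  if (any(is.na(rad))) stop("atoms lack radii; run assign_radii() first")
  xyz <- coords(assembly)
  d <- sqrt(xyz[, 1L]^2 + xyz[, 2L]^2 + (xyz[, 3L] - z)^2) - rad
  m <- min(d)
  list(radius = max(0, m), blocked = m < 0)
}

#' Axial pore radius profile
#'
#' Evaluates [pore_radius_at()] on an even grid of heights including both
#' endpoints. The profile is 1-Lipschitz in z by construction (it is a
#' minimum of unit-slope distance functions).
#'
#' @param assembly canonical-frame `MolecularAssembly` with radii.
#' @param z_min,z_max height range (A), `z_min < z_max`.
#' @param n_samples number of evenly spaced samples (>= 2).
#' @return object of class `PoreProfile`: data.frame-like list with `z`,
#'   `radius`, `blocked`.
#' @export
radius_profile <- function(assembly, z_min, z_max, n_samples = 101L) {
  stopifnot(z_min < z_max, n_samples >= 2L)
  zs <- seq(z_min, z_max, length.out = n_samples)
  res <- lapply(zs, function(z) pore_radius_at(assembly, z))
  structure(list(z = zs,
                 radius = vapply(res, `[[`, numeric(1), "radius"),
                 blocked = vapply(res, `[[`, logical(1), "blocked")),
            class = "PoreProfile")
}

#' @export
print.PoreProfile <- function(x, ...) {
  cat(sprintf("PoreProfile: %d samples, z in [%.2f, %.2f] A, min radius %.3f A\n",
              length(x$z), min(x$z), max(x$z), min(x$radius)))
  invisible(x)
}

#' Pore boundary contour at one height
#'
#' For each theta-bin centre, casts an inner-mode radial ray from the axis at
#' height `z` and records the distance to the first sphere entry -- the pore
#' wall. Rays escaping between subunits are open sectors (radius NA), which
#' are legal values; only a blocked axis point (inside an atom) is an error,
#' since no contour exists there.
#'
#' @param assembly canonical-frame `MolecularAssembly` with radii.
#' @param z slice height (A).
#' @param n_theta number of azimuth samples (>= 3).
#' @return object of class `PoreContour`: `z`, `theta` (degrees, bin
#'   centres), `radius` (A, NA = open sector), `closed` (no open sectors).
#' @export
slice_contour <- function(assembly, z, n_theta = 180L) {
  stopifnot(n_theta >= 3L)
  pr <- pore_radius_at(assembly, z)
  if (pr$blocked) {
    stop(sprintf("axis point at z = %.3f is inside an atom; contour undefined", z))
  }
  theta <- (seq_len(n_theta) - 0.5) * 360 / n_theta
  radius <- vapply(theta, function(th) {
    hit <- cast_radial_ray(assembly, z, th, side = "inner")
    if (hit$hit) hit$radius else NA_real_
  }, numeric(1))
  structure(list(z = z, theta = theta, radius = radius,
                 closed = !anyNA(radius)),
            class = "PoreContour")
}

#' @export
print.PoreContour <- function(x, ...) {
  cat(sprintf("PoreContour at z = %.2f A: %d rays, %s (%d open)\n",
              x$z, length(x$theta), if (x$closed) "closed" else "open",
              sum(is.na(x$radius))))
  invisible(x)
}

#' Detect pore constrictions
#'
#' Finds strict local minima of the unblocked radius samples (interior
#' samples only; a flat plateau counts once, at its leftmost sample) and
#' returns the `k` narrowest, sorted by radius ascending (ties broken by
#' lower z). These are the reference heights (n1, n2, ...) used to place
#' contour slices; the narrowest is the gate candidate.
#'
#' @param profile a [radius_profile()] result.
#' @param k number of constrictions to return (>= 1); fewer are returned when
#'   fewer minima exist.
#' @return object of class `ConstrictionSet`: data.frame with `z` and
#'   `radius`.
#' @export
find_constrictions <- function(profile, k = 4L) {
  stopifnot(inherits(profile, "PoreProfile"), k >= 1L)
  ok <- !profile$blocked
  zs <- profile$z[ok]
  rr <- profile$radius[ok]
  n <- length(rr)
  if (n < 3L) stop("no interior local minimum found")
  minima_z <- numeric(0); minima_r <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && rr[j + 1L] == rr[i]) j <- j + 1L # plateau run [i, j]
    if (j <= n - 1L && rr[i - 1L] > rr[i] && rr[j + 1L] > rr[i]) {
      minima_z <- c(minima_z, zs[i]) # leftmost sample of the plateau
      minima_r <- c(minima_r, rr[i])
    }
    i <- j + 1L
  }
  if (length(minima_r) == 0L) stop("no interior local minimum found")
  ord <- order(minima_r, minima_z)
  take <- ord[seq_len(min(k, length(ord)))]
  structure(data.frame(z = minima_z[take], radius = minima_r[take]),
            class = c("ConstrictionSet", "data.frame"))
}

#' Track the constriction across trajectory frames
#'
#' For each frame, profiles the pore inside `z_window` and records the
#' minimum radius and its height -- the time series of the gate aperture.
#'
#' @param stack a [trajectory_stack()] of canonical-frame assemblies.
#' @param z_window numeric `c(z_lo, z_hi)` (A), `z_lo < z_hi`.
#' @param n_samples profile resolution per frame.
#' @return data.frame with `frame` (1-based), `z`, `radius`.
#' @export
track_constriction <- function(stack, z_window, n_samples = 101L) {
  stopifnot(inherits(stack, "TrajectoryStack"),
            length(z_window) == 2L, z_window[1] < z_window[2])
  rows <- lapply(seq_along(stack$frames), function(k) {
    pf <- radius_profile(stack$frames[[k]], z_window[1], z_window[2], n_samples)
    i <- which.min(pf$radius) # ties resolve to the lowest z
    data.frame(frame = k, z = pf$z[i], radius = pf$radius[i])
  })
  do.call(rbind, rows)
}

#' Write a pore profile as TSV
#'
#' Columns `z`, `radius`, `blocked` with a header line.
#'
#' @param profile a `PoreProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pore_profile <- function(profile, path) {
  stopifnot(inherits(profile, "PoreProfile"))
  writeLines(c("z\tradius\tblocked",
               sprintf("%.17g\t%.17g\t%d", profile$z, profile$radius,
                       as.integer(profile$blocked))), path)
  invisible(path)
}

#' Write a pore contour as TSV
#'
#' Columns `theta`, `radius`, `open` (1 for open sectors, radius NA).
#'
#' @param contour a `PoreContour`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  stopifnot(inherits(contour, "PoreContour"))
  writeLines(c("theta\tradius\topen",
               sprintf("%.17g\t%s\t%d", contour$theta,
                       ifelse(is.na(contour$radius), "NA",
                              sprintf("%.17g", contour$radius)),
                       as.integer(is.na(contour$radius)))), path)
  invisible(path)
}
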