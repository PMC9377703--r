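# Canonical cylindrical frame: channel axis -> z, membrane mid-plane -> z = 0,
# azimuth reference -> +x. All downstream modules (explode, panorama, pore)
# assume assemblies have been passed through align_to_axis().

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Deterministic sign convention: component along z must be >= 0; exact ties
# fall through to +x, then +y preference.
canonical_axis_sign <- function(v, tol = 1e-9) {
  if (v[3] > tol) return(v)
  if (v[3] < -tol) return(-v)
  if (v[1] > tol) return(v)
  if (v[1] < -tol) return(-v)
  if (v[2] >= 0) v else -v
}

derive_azimuth_ref <- function(axis) {
  for (cand in list(c(1, 0, 0), c(0, 1, 0))) {
    proj <- cand - sum(cand * axis) * axis
    if (sqrt(sum(proj^2)) > 1e-9) return(normalize3(proj))
  }
  stop("cannot derive an azimuth reference") # unreachable for a unit axis
}

#' Construct a symmetry frame
#'
#' A `SymmetryFrame` is the canonical cylindrical coordinate system of a
#' channel: an origin on the axis, the unit axis direction (sign
#' canonicalized so it points towards +z), and a unit azimuth reference
#' perpendicular to the axis defining theta = 0.
#'
#' @param origin 3-vector (Angstrom).
#' @param axis 3-vector, normalized internally; sign flipped so that the axis
#'   points towards +z (ties prefer +x, then +y).
#' @param azimuth_ref optional 3-vector; projected off the axis and
#'   normalized. Default: projection of (1,0,0), falling back to (0,1,0).
#' @return object of class `SymmetryFrame`.
#' @export
symmetry_frame <- function(origin = c(0, 0, 0), axis = c(0, 0, 1),
                           azimuth_ref = NULL) {
  stopifnot(length(origin) == 3L, length(axis) == 3L, all(is.finite(origin)))
  axis <- canonical_axis_sign(normalize3(axis))
  ref <- if (is.null(azimuth_ref)) {
    derive_azimuth_ref(axis)
  } else {
    proj <- azimuth_ref - sum(azimuth_ref * axis) * axis
    normalize3(proj)
  }
  structure(list(origin = as.numeric(origin), axis = axis, azimuth_ref = ref),
            class = "SymmetryFrame")
}

#' @export
print.SymmetryFrame <- function(x, ...) {
  cat(sprintf("SymmetryFrame: origin (%.3f, %.3f, %.3f), axis (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

is_canonical_frame <- function(frame, tol = 1e-9) {
  inherits(frame, "SymmetryFrame") &&
    all(abs(frame$origin) <= tol) &&
    all(abs(frame$axis - c(0, 0, 1)) <= tol) &&
    all(abs(frame$azimuth_ref - c(1, 0, 0)) <= tol)
}

#' Principal (gyration) axis of an assembly
#'
#' Detects the channel axis from the eigendecomposition of the coordinate
#' covariance (gyration) tensor: the axis is the eigenvector whose eigenvalue
#' is most distinct (largest minimum separation from the other two). This
#' works for both prolate (tall cylinder) and oblate (flat ring) assemblies.
#'
#' @param assembly a `MolecularAssembly` with at least 3 non-collinear atoms.
#' @return a [symmetry_frame()] with origin at the centroid.
#' @export
inertia_axis <- function(assembly) {
  xyz <- coords(assembly)
  if (nrow(xyz) < 3L) stop("need at least 3 atoms")
  ctr <- colMeans(xyz)
  d <- sweep(xyz, 2L, ctr)
  cv <- crossprod(d) / nrow(d)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values # descending
  scale <- max(ev[1], .Machine$double.eps)
  if ((ev[1] - ev[3]) / scale < 1e-6) {
    stop("no distinct axis: gyration tensor is degenerate (all eigenvalues equal)")
  }
  if (ev[2] / scale < 1e-12) stop("atoms are collinear: axis frame undefined")
  sep <- c(ev[1] - ev[2],                     # distinctness of the largest
           min(ev[1] - ev[2], ev[2] - ev[3]), # of the middle
           ev[2] - ev[3])                     # of the smallest
  pick <- which.max(sep) # ties resolve to the larger eigenvalue
  symmetry_frame(origin = ctr, axis = eg$vectors[, pick])
}

#' Symmetry axis from subunit centroids
#'
#' For a cyclic (C_n) oligomer the subunit centroids lie on a ring; the
#' channel axis is the normal of the least-squares plane through them. This is
#' the preferred detector for ring-shaped channels whose gyration tensor can
#' be oblate or ambiguous.
#'
#' @param assembly a `MolecularAssembly`.
#' @param partition a [partition_subunits()] result with >= 3 groups whose
#'   centroids are not collinear.
#' @return a [symmetry_frame()] with origin at the mean subunit centroid.
#' @export
cyclic_axis <- function(assembly, partition) {
  stopifnot(inherits(partition, "SubunitPartition"))
  if (length(partition$groups) < 3L) {
    stop("cyclic axis needs at least 3 subunits (got ",
         length(partition$groups), ")")
  }
  xyz <- coords(assembly)
  ctrs <- t(vapply(partition$groups,
                   function(idx) colMeans(xyz[idx, , drop = FALSE]),
                   numeric(3)))
  mu <- colMeans(ctrs)
  d <- sweep(ctrs, 2L, mu)
  cv <- crossprod(d) / nrow(d)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values
  if (ev[2] / max(ev[1], .Machine$double.eps) < 1e-9) {
    stop("subunit centroids are collinear: plane fit undefined")
  }
  symmetry_frame(origin = mu, axis = eg$vectors[, 3L]) # smallest eigenvalue = normal
}

#' Align a stack (or assembly) into the canonical frame
#'
#' Applies the rigid transform taking `frame$origin` to the global origin,
#' `frame$axis` to (0,0,1) and `frame$azimuth_ref` to (1,0,0). The same
#' transform is applied to every frame of a stack, so trajectories stay
#' mutually registered. Pairwise distances are preserved exactly (pure
#' rotation + translation).
#'
#' @param stack a [trajectory_stack()] or single [molecular_assembly()].
#' @param frame a [symmetry_frame()].
#' @return object of the same class as `stack`, transformed.
#' @export
align_to_axis <- function(stack, frame) {
  stopifnot(inherits(frame, "SymmetryFrame"))
  rot <- rbind(frame$azimuth_ref,
               cross3(frame$axis, frame$azimuth_ref),
               frame$axis)
  move <- function(assembly) {
    xyz <- sweep(coords(assembly), 2L, frame$origin) %*% t(rot)
    set_coords(assembly, xyz)
  }
  if (inherits(stack, "MolecularAssembly")) return(move(stack))
  stopifnot(inherits(stack, "TrajectoryStack"))
  stack$frames <- lapply(stack$frames, move)
  stack
}
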