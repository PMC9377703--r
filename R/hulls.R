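# Geometric abstraction of subunits: sample the van-der-Waals surface, take
# the convex hull, then coarsen it by shortest-edge collapse. The result is a
# small watertight envelope per subunit, the "simple geometric elements"
# representation of the assembly.

#' Sample quasi-uniform points on a subunit's atomic surface
#'
#' Places `points_per_atom` points on each atom sphere using a Fibonacci
#' lattice (deterministic, no RNG) and discards points buried strictly inside
#' another atom of the same subunit. Concentric identical atoms keep their
#' points (a point on the boundary of a sphere is not inside it).
#'
#' @param assembly a `MolecularAssembly` with radii assigned.
#' @param subunit integer vector of atom indices (default: all atoms).
#' @param points_per_atom integer >= 1.
#' @return numeric m x 3 matrix of surface points (Angstrom).
#' @export
sample_surface_points <- function(assembly, subunit = NULL, points_per_atom = 30L) {
  stopifnot(inherits(assembly, "MolecularAssembly"), points_per_atom >= 1L)
  if (is.null(subunit)) subunit <- seq_len(nrow(assembly$atoms))
  if (length(subunit) == 0L) stop("empty subunit")
  xyz <- coords(assembly)[subunit, , drop = FALSE]
  rad <- assembly$atoms$radius[subunit]
  if (any(is.na(rad))) stop("atoms lack radii; run assign_radii() first")
  m <- as.integer(points_per_atom)
  # Fibonacci sphere directions, identical for every atom
  i <- seq_len(m) - 0.5
  zs <- 1 - 2 * i / m
  phi <- pi * (3 - sqrt(5)) * (seq_len(m) - 1)
  rho <- sqrt(pmax(0, 1 - zs^2))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), zs)

  n_at <- length(subunit)
  pts <- matrix(0, n_at * m, 3L)
  owner <- rep(seq_len(n_at), each = m)
  for (a in seq_len(n_at)) {
    pts[((a - 1L) * m + 1L):(a * m), ] <-
      dirs * rad[a] + matrix(xyz[a, ], m, 3L, byrow = TRUE)
  }
  keep <- rep(TRUE, nrow(pts))
  for (a in seq_len(n_at)) {
    d2 <- (pts[, 1L] - xyz[a, 1L])^2 + (pts[, 2L] - xyz[a, 2L])^2 +
      (pts[, 3L] - xyz[a, 3L])^2
    keep <- keep & (owner == a | d2 >= (rad[a] - 1e-9)^2)
  }
  pts[keep, , drop = FALSE]
}

#' Build a convex hull envelope
#'
#' Computes the convex hull of a point set as a closed, outward-oriented
#' triangulation.
#'
#' @param points numeric m x 3 matrix (>= 4 affinely independent points).
#' @param subunit_label label carried into the hull object.
#' @return object of class `AbstractHull` with `vertices` (V x 3 matrix),
#'   `faces` (F x 3 matrix of 1-based vertex indices) and `subunit_label`.
#' @export
build_hull <- function(points, subunit_label = "") {
  h <- chull3d(points)
  structure(list(vertices = h$vertices, faces = h$faces,
                 subunit_label = subunit_label),
            class = "AbstractHull")
}

#' @export
print.AbstractHull <- function(x, ...) {
  cat(sprintf("AbstractHull%s: %d vertices, %d faces, volume %.2f A^3\n",
              if (nzchar(x$subunit_label)) paste0(" [", x$subunit_label, "]") else "",
              nrow(x$vertices), nrow(x$faces), hull_volume(x)))
  invisible(x)
}

#' Enclosed volume of a hull
#'
#' @param hull an `AbstractHull`.
#' @return signed volume (A^3); positive for outward-oriented meshes.
#' @export
hull_volume <- function(hull) {
  stopifnot(inherits(hull, "AbstractHull"))
  mesh_volume(hull$vertices, hull$faces)
}

#' Check that a hull is a closed watertight mesh
#'
#' @param hull an `AbstractHull`.
#' @return TRUE when every edge borders exactly 2 faces, V - E + F = 2 and
#'   the signed volume is positive.
#' @export
hull_is_watertight <- function(hull) {
  stopifnot(inherits(hull, "AbstractHull"))
  mesh_is_watertight(hull$vertices, hull$faces) && hull_volume(hull) > 0
}

#' Coarsen a hull to a target vertex count
#'
#' Iteratively collapses the shortest edge of the mesh to its midpoint
#' (recomputing candidate edges after every collapse) until at most
#' `target_vertices` vertices survive, then re-convexifies the surviving
#' vertex set to restore a closed hull. Midpoint collapse can move the
#' envelope slightly in either direction; the volume change stays small for
#' round shapes but is not one-sided.
#'
#' @param hull an `AbstractHull`.
#' @param target_vertices integer >= 4.
#' @return the coarsened `AbstractHull`.
#' @export
decimate_hull <- function(hull, target_vertices) {
  stopifnot(inherits(hull, "AbstractHull"))
  if (target_vertices < 4L) stop("target_vertices must be >= 4")
  verts <- hull$vertices
  faces <- hull$faces
  if (nrow(verts) <= target_vertices) return(hull)
  while (nrow(verts) > target_vertices) {
    ed <- mesh_edges(faces)
    len2 <- rowSums((verts[ed[, 1L], , drop = FALSE] -
                     verts[ed[, 2L], , drop = FALSE])^2)
    e <- ed[which.min(len2), ]
    mid <- (verts[e[1L], ] + verts[e[2L], ]) / 2
    # merge e[2] into e[1], move to midpoint, drop degenerate faces
    verts[e[1L], ] <- mid
    faces[faces == e[2L]] <- e[1L]
    degenerate <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    faces <- faces[!degenerate, , drop = FALSE]
    # compact vertex indices
    keep <- sort(unique(as.vector(faces)))
    remap <- integer(nrow(verts)); remap[keep] <- seq_along(keep)
    verts <- verts[keep, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3L)
  }
  h <- chull3d(verts)
  structure(list(vertices = h$vertices, faces = h$faces,
                 subunit_label = hull$subunit_label),
            class = "AbstractHull")
}

#' Abstract every subunit of an assembly into a hull
#'
#' Convenience pipeline: surface sampling, convex hull, optional decimation,
#' one hull per partition group.
#'
#' @param assembly a `MolecularAssembly` with radii.
#' @param partition a [partition_subunits()] result.
#' @param points_per_atom surface sampling density.
#' @param target_vertices optional decimation target (NULL = keep full hull).
#' @return list of `AbstractHull`, one per subunit, in label order.
#' @export
abstract_subunits <- function(assembly, partition, points_per_atom = 30L,
                              target_vertices = NULL) {
  stopifnot(inherits(partition, "SubunitPartition"))
  hulls <- lapply(names(partition$groups), function(lab) {
    pts <- sample_surface_points(assembly, partition$groups[[lab]],
                                 points_per_atom)
    h <- build_hull(pts, subunit_label = lab)
    if (!is.null(target_vertices)) h <- decimate_hull(h, target_vertices)
    h
  })
  names(hulls) <- names(partition$groups)
  hulls
}

#' Write hulls as a Wavefront OBJ file
#'
#' One named object (`o` line) per hull; vertex indices are 1-based and global
#' across objects, per the OBJ convention.
#'
#' @param hulls a single `AbstractHull` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(hulls, path) {
  if (inherits(hulls, "AbstractHull")) hulls <- list(hulls)
  lines <- character(0)
  offset <- 0L
  for (k in seq_along(hulls)) {
    h <- hulls[[k]]
    stopifnot(inherits(h, "AbstractHull"))
    lab <- if (nzchar(h$subunit_label)) h$subunit_label else paste0("hull_", k)
    lines <- c(lines, paste("o", lab),
               sprintf("v %.6f %.6f %.6f",
                       h$vertices[, 1L], h$vertices[, 2L], h$vertices[, 3L]),
               sprintf("f %d %d %d",
                       h$faces[, 1L] + offset, h$faces[, 2L] + offset,
                       h$faces[, 3L] + offset))
    offset <- offset + nrow(h$vertices)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Wavefront OBJ file written by [write_mesh()]
#'
#' @param path OBJ path.
#' @return list of `AbstractHull`, one per `o` group.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  tag <- substr(lines, 1L, 2L)
  verts_all <- do.call(rbind, lapply(strsplit(lines[tag == "v "], "\\s+"),
                                     function(p) as.numeric(p[2:4])))
  hulls <- list()
  cur_label <- NULL; cur_faces <- list()
  flush <- function() {
    if (is.null(cur_label) || length(cur_faces) == 0L) return()
    f <- do.call(rbind, cur_faces)
    used <- sort(unique(as.vector(f)))
    remap <- integer(max(used)); remap[used] <- seq_along(used)
    hulls[[cur_label]] <<- structure(
      list(vertices = verts_all[used, , drop = FALSE],
           faces = matrix(remap[f], ncol = 3L),
           subunit_label = cur_label),
      class = "AbstractHull")
  }
  for (ln in lines) {
    if (startsWith(ln, "o ")) {
      flush()
      cur_label <- sub("^o ", "", ln); cur_faces <- list()
    } else if (startsWith(ln, "f ")) {
      cur_faces[[length(cur_faces) + 1L]] <-
        as.integer(strsplit(ln, "\\s+")[[1]][2:4])
    }
  }
  flush()
  hulls
}
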