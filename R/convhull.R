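# Incremental 3D convex hull (randomized-incremental without conflict graph).
# Faces are stored as ordered vertex triples, oriented counter-clockwise seen
# from outside (outward normals). Visibility tolerance scales with the point
# cloud extent so the hull is robust for coordinates of any magnitude.

chull3d <- function(pts, tol = 1e-9) {
  stopifnot(is.matrix(pts), ncol(pts) == 3L)
  pts <- pts[!duplicated(round(pts, 12L)), , drop = FALSE]
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs at least 4 distinct points")
  extent <- max(apply(pts, 2L, function(v) diff(range(v))))
  if (extent < tol) stop("degenerate point set: all points coincide")
  eps <- tol * max(extent, 1)

  # --- initial simplex from extreme points ---------------------------------
  cand <- unique(c(apply(pts, 2L, which.min), apply(pts, 2L, which.max)))
  best <- c(cand[1L], cand[2L]); bd <- -1
  for (i in cand) for (j in cand) {
    d <- sum((pts[i, ] - pts[j, ])^2)
    if (d > bd) { bd <- d; best <- c(i, j) }
  }
  i1 <- best[1L]; i2 <- best[2L]
  if (bd < eps^2) stop("degenerate point set")
  dir12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  crossm <- cbind(rel[, 2L] * dir12[3L] - rel[, 3L] * dir12[2L],
                  rel[, 3L] * dir12[1L] - rel[, 1L] * dir12[3L],
                  rel[, 1L] * dir12[2L] - rel[, 2L] * dir12[1L])
  line_d <- sqrt(rowSums(crossm^2)) / sqrt(sum(dir12^2))
  i3 <- which.max(line_d)
  if (line_d[i3] < eps) stop("degenerate point set: points are collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  plane_d <- rel %*% nrm / sqrt(sum(nrm^2))
  i4 <- which.max(abs(plane_d))
  if (abs(plane_d[i4]) < eps) stop("degenerate point set: points are coplanar")
  interior <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient_face <- function(f) {
    nv <- cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
    if (sum(nv * (pts[f[1L], ] - interior)) < 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- t(apply(faces, 1L, orient_face))
  face_geom <- function(faces) {
    v1 <- pts[faces[, 1L], , drop = FALSE]
    e1 <- pts[faces[, 2L], , drop = FALSE] - v1
    e2 <- pts[faces[, 3L], , drop = FALSE] - v1
    nm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
                e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
                e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
    nm <- nm / sqrt(rowSums(nm^2))
    list(normals = nm, offsets = rowSums(nm * v1))
  }
  geom <- face_geom(faces)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    sd <- geom$normals %*% pts[p, ] - geom$offsets
    vis <- which(sd > eps)
    if (length(vis) == 0L) next
    vf <- faces[vis, , drop = FALSE]
    ed <- rbind(vf[, c(1L, 2L)], vf[, c(2L, 3L)], vf[, c(3L, 1L)])
    key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    horizon <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1L, orient_face))
    faces <- rbind(faces[-vis, , drop = FALSE], newf)
    geom <- face_geom(faces)
  }

  used <- sort(unique(as.vector(faces)))
  remap <- integer(n); remap[used] <- seq_along(used)
  list(vertices = pts[used, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3L))
}

# unique undirected edges of a triangle mesh, as a 2-column index matrix
mesh_edges <- function(faces) {
  ed <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  ed <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  unique(ed)
}

# every undirected edge must border exactly two faces, and V - E + F = 2
mesh_is_watertight <- function(vertices, faces) {
  ed <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  counts <- table(key)
  all(counts == 2L) &&
    (nrow(vertices) - length(counts) + nrow(faces)) == 2L
}

# signed volume of a closed oriented mesh (positive when outward-oriented)
mesh_volume <- function(vertices, faces) {
  v1 <- vertices[faces[, 1L], , drop = FALSE]
  v2 <- vertices[faces[, 2L], , drop = FALSE]
  v3 <- vertices[faces[, 3L], , drop = FALSE]
  sum(v1[, 1L] * (v2[, 2L] * v3[, 3L] - v2[, 3L] * v3[, 2L]) -
      v1[, 2L] * (v2[, 1L] * v3[, 3L] - v2[, 3L] * v3[, 1L]) +
      v1[, 3L] * (v2[, 1L] * v3[, 2L] - v2[, 2L] * v3[, 1L])) / 6
}

# max signed distance of query points outside the hull (<= 0 means inside)
mesh_signed_outside <- function(vertices, faces, query) {
  v1 <- vertices[faces[, 1L], , drop = FALSE]
  e1 <- vertices[faces[, 2L], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3L], , drop = FALSE] - v1
  nm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nm <- nm / sqrt(rowSums(nm^2))
  offs <- rowSums(nm * v1)
  apply(query %*% t(nm) - matrix(offs, nrow(query), length(offs), byrow = TRUE),
        1L, max)
}
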