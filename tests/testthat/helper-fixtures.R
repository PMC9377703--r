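# Shared fixtures, all generated in code (no data files).

# small clean pentamer: 5 x 40 atoms, no noise
small_pentamer <- function(...) {
  make_cyclic_assembly(synthetic_spec(atoms_per_subunit = 40L, ...))
}

# full-size pentamer matching the default study conditions: 5 x 200 atoms
full_pentamer <- function(...) {
  make_cyclic_assembly(synthetic_spec(...))
}

# a minimal hand-written single-model PDB file; returns its path
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  C   ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  N   ALA A   1       4.000   5.000   6.000  1.00  0.00           N",
    "ATOM      3  O   ALA A   2       7.000   8.000   9.000  1.00  0.00           O",
    "END"), path)
  path
}

# pairwise distance matrix of selected atoms
pair_dists <- function(assembly, idx = NULL) {
  xyz <- coords(assembly)
  if (!is.null(idx)) xyz <- xyz[idx, , drop = FALSE]
  as.matrix(dist(xyz))
}

# minimum distance between atoms of two fragments
min_gap <- function(assembly, idx_a, idx_b) {
  xa <- coords(assembly)[idx_a, , drop = FALSE]
  xb <- coords(assembly)[idx_b, , drop = FALSE]
  min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)))
}

# rotation matrix about z (degrees)
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rotate_assembly_z <- function(assembly, deg) {
  set_coords(assembly, coords(assembly) %*% t(rot_z(deg)))
}

# independent pore oracle: binary search on the probe radius with an explicit
# all-atom clash test (never calls the min-of-distances formula)
pore_radius_oracle <- function(assembly, z, r_max = 100, tol = 1e-9) {
  xyz <- coords(assembly)
  rad <- assembly$atoms$radius
  clashes <- function(r) {
    any(sqrt(xyz[, 1]^2 + xyz[, 2]^2 + (xyz[, 3] - z)^2) < r + rad)
  }
  if (clashes(0)) return(list(radius = 0, blocked = TRUE))
  lo <- 0; hi <- r_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (clashes(mid)) hi <- mid else lo <- mid
  }
  list(radius = lo, blocked = FALSE)
}

# random small assembly for oracle comparisons
random_assembly <- function(n_atoms, seed) {
  set.seed(seed)
  atoms <- data.frame(
    serial = seq_len(n_atoms), element = "C",
    x = runif(n_atoms, -10, 10), y = runif(n_atoms, -10, 10),
    z = runif(n_atoms, -10, 10),
    radius = runif(n_atoms, 0.8, 2.5),
    chain = "A", resno = seq_len(n_atoms), resid = "RND",
    property = NA_real_, stringsAsFactors = FALSE)
  molecular_assembly(atoms)
}
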