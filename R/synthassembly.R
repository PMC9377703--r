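# Deterministic synthetic fixtures with analytic ground truth: C_n ring
# assemblies modelled loosely on a pentameric channel (a wall of atom columns
# around a central pore, narrowing at two built-in constriction heights),
# gating-twist trajectories that rotate the extracellular half and dilate the
# gate, and simple analytic shapes (sphere, cylinder shell, ring of spheres)
# for closed-form checks.

# run expr with a private RNG stream; the caller's .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic cyclic assembly
#'
#' Defaults describe a pentamer at roughly the scale of a small pentameric
#' channel: 5 subunits on a 16 A ring, 200 atoms each, spanning a 20 A
#' height (membrane plus a short extracellular stretch). The `wall_column`
#' template narrows at two built-in heights, z = -0.4 * height and
#' z = +0.3 * height (inner radii 0.5 and 0.35 x `ring_radius`), giving the
#' assembly an hourglass pore whose constriction radii are known in closed
#' form; the narrower (+z) one is the gate tracked by twist trajectories.
#'
#' @param n_subunits number of subunits (>= 1; >= 3 for axis detection).
#' @param ring_radius ring radius of the subunit centres (A).
#' @param subunit_template `"wall_column"` (pore-forming wall) or
#'   `"sphere_cluster"` (blob, for axis tests).
#' @param atoms_per_subunit atoms per subunit (a multiple of 4 for
#'   `wall_column`).
#' @param atom_radius sphere radius of every atom (A).
#' @param height vertical extent of the assembly (A).
#' @param twist_deg total gating twist of the z > 0 half (degrees).
#' @param pore_open_frac fractional radial dilation of the gate over a
#'   trajectory, in \[0, 1\].
#' @param noise_sigma isotropic Gaussian coordinate noise (A).
#' @param seed RNG seed for the noise (and cluster template) stream.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_subunits = 5L, ring_radius = 16,
                           subunit_template = c("wall_column", "sphere_cluster"),
                           atoms_per_subunit = 200L, atom_radius = 1.7,
                           height = 20, twist_deg = 15, pore_open_frac = 0.3,
                           noise_sigma = 0, seed = 1L) {
  subunit_template <- match.arg(subunit_template)
  stopifnot(n_subunits >= 1L, ring_radius > 0, atoms_per_subunit >= 1L,
            atom_radius > 0, height > 0, pore_open_frac >= 0,
            pore_open_frac <= 1, noise_sigma >= 0)
  structure(list(n_subunits = as.integer(n_subunits),
                 ring_radius = ring_radius,
                 subunit_template = subunit_template,
                 atoms_per_subunit = as.integer(atoms_per_subunit),
                 atom_radius = atom_radius, height = height,
                 twist_deg = twist_deg, pore_open_frac = pore_open_frac,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# wall radius profile r(z): ring_radius with two Gaussian narrowings
wall_radius_fun <- function(spec) {
  z1 <- -0.4 * spec$height; r1 <- 0.50 * spec$ring_radius
  z2 <- 0.3 * spec$height; r2 <- 0.35 * spec$ring_radius
  w <- spec$height / 10
  list(
    fun = function(z) {
      spec$ring_radius -
        (spec$ring_radius - r1) * exp(-((z - z1) / w)^2) -
        (spec$ring_radius - r2) * exp(-((z - z2) / w)^2)
    },
    z1 = z1, z2 = z2, w = w
  )
}

# template subunit for chain A (sector centred on azimuth 0), plus metadata
build_template <- function(spec) {
  n <- spec$atoms_per_subunit
  if (spec$subunit_template == "wall_column") {
    n_az <- 4L
    if (n %% n_az != 0L) {
      stop("atoms_per_subunit must be a multiple of 4 for the wall_column template")
    }
    n_z <- n %/% n_az
    z_levels <- seq(-spec$height / 2, spec$height / 2, length.out = n_z)
    wall <- wall_radius_fun(spec)
    # snap the two constriction heights onto exact z levels
    z1 <- z_levels[which.min(abs(z_levels - wall$z1))]
    z2 <- z_levels[which.min(abs(z_levels - wall$z2))]
    sector <- 2 * pi / spec$n_subunits
    az <- ((seq_len(n_az) - 0.5) / n_az - 0.5) * sector
    g <- expand.grid(az = az, z = z_levels) # z varies slowest: level blocks
    r <- wall$fun(g$z)
    list(xyz = cbind(r * cos(g$az), r * sin(g$az), g$z),
         z_levels = z_levels, level_radii = wall$fun(z_levels),
         z_key = z2, z_other = z1, gate_width = wall$w)
  } else {
    sigma <- spec$height / 6
    xyz <- with_private_seed(spec$seed + 1L, {
      matrix(stats::rnorm(3L * n, sd = sigma), ncol = 3L)
    })
    xyz[, 1L] <- xyz[, 1L] + spec$ring_radius
    list(xyz = xyz, z_levels = NULL, level_radii = NULL,
         z_key = NA_real_, z_other = NA_real_, gate_width = NA_real_)
  }
}

rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

# closed-form on-axis pore radius of the discrete wall construction, with
# optional per-level radial dilation factors
wall_pore_radius <- function(z, z_levels, level_radii, atom_radius,
                             dilation = 1) {
  rl <- level_radii * dilation
  min(sqrt(rl^2 + (z_levels - z)^2)) - atom_radius
}

#' Generate a cyclic (C_n) synthetic assembly
#'
#' Builds one template subunit, copies it by rotations of 360/n degrees about
#' the z axis (chains A, B, C, ...), optionally adds isotropic Gaussian
#' coordinate noise (seeded, reproducible), and returns the assembly together
#' with its partition and a ground-truth record: the true axis, the subunit
#' centroids, and -- for the `wall_column` template -- the built-in
#' constriction heights and on-axis pore radii in closed form.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `assembly`, `partition`, `ground_truth`.
#' @export
make_cyclic_assembly <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  tmpl <- build_template(spec)
  n_sub <- spec$n_subunits
  n_at <- spec$atoms_per_subunit
  xyz <- do.call(rbind, lapply(seq_len(n_sub) - 1L, function(k) {
    tmpl$xyz %*% t(rotz(360 * k / n_sub))
  }))
  centroids <- t(vapply(seq_len(n_sub) - 1L, function(k) {
    colMeans(tmpl$xyz %*% t(rotz(360 * k / n_sub)))
  }, numeric(3)))
  if (spec$noise_sigma > 0) {
    xyz <- xyz + with_private_seed(spec$seed, {
      matrix(stats::rnorm(length(xyz), sd = spec$noise_sigma), ncol = 3L)
    })
  }
  n_total <- n_sub * n_at
  atoms <- data.frame(
    serial = seq_len(n_total), element = "C",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    radius = spec$atom_radius,
    chain = rep(LETTERS[seq_len(n_sub)], each = n_at),
    resno = rep(seq_len(n_at), times = n_sub),
    resid = "SYN", property = NA_real_,
    stringsAsFactors = FALSE
  )
  assembly <- molecular_assembly(atoms, label = sprintf("C%d synthetic", n_sub))
  partition <- partition_subunits(assembly, "by_chain")
  gt <- list(axis = c(0, 0, 1), origin = c(0, 0, 0),
             subunit_centroids = centroids)
  if (spec$subunit_template == "wall_column") {
    cz <- c(tmpl$z_key, tmpl$z_other)
    cr <- vapply(cz, wall_pore_radius, numeric(1),
                 z_levels = tmpl$z_levels, level_radii = tmpl$level_radii,
                 atom_radius = spec$atom_radius)
    ord <- order(cr)
    gt$constrictions <- data.frame(z = cz[ord], radius = cr[ord])
    gt$z_key <- tmpl$z_key
    gt$gate_width <- tmpl$gate_width
    gt$z_levels <- tmpl$z_levels
    gt$level_radii <- tmpl$level_radii
  }
  list(assembly = assembly, partition = partition, ground_truth = gt)
}

#' Generate a gating-twist trajectory
#'
#' Frame t (t = 0 ... n_frames-1, s = t/(n_frames-1)) applies two motions to
#' the base assembly: the extracellular half (z > 0) rotates about the axis
#' by `twist_deg * s`, and the gate region dilates radially by a factor
#' `1 + pore_open_frac * s * exp(-((z - z_key)/w)^2)`, linearly opening the
#' pore. Frame 0 is the untwisted assembly. The returned stack carries a
#' `ground_truth` attribute with the per-frame gate height and on-axis
#' radius computed from the construction in closed form.
#'
#' @param spec a [synthetic_spec()] with the `wall_column` template.
#' @param n_frames number of frames (>= 2).
#' @return a [trajectory_stack()] with attribute `ground_truth` (data.frame
#'   `frame`, `z`, `radius`) and attribute `partition`.
#' @export
make_twist_trajectory <- function(spec, n_frames = 8L) {
  stopifnot(inherits(spec, "SyntheticSpec"), n_frames >= 2L)
  if (spec$subunit_template != "wall_column") {
    stop("twist trajectories need the wall_column template (pore ground truth)")
  }
  base <- make_cyclic_assembly(spec)
  gt <- base$ground_truth
  xyz0 <- coords(base$assembly)
  w <- gt$gate_width
  frames <- vector("list", n_frames)
  gt_rows <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    s <- t / (n_frames - 1)
    dil <- 1 + spec$pore_open_frac * s * exp(-((xyz0[, 3L] - gt$z_key) / w)^2)
    xyz <- cbind(xyz0[, 1L] * dil, xyz0[, 2L] * dil, xyz0[, 3L])
    upper <- xyz[, 3L] > 0
    xyz[upper, ] <- xyz[upper, , drop = FALSE] %*% t(rotz(spec$twist_deg * s))
    fr <- set_coords(base$assembly, xyz)
    fr$frame_index <- t
    frames[[t + 1L]] <- fr
    level_dil <- 1 + spec$pore_open_frac * s *
      exp(-((gt$z_levels - gt$z_key) / w)^2)
    gt_rows[[t + 1L]] <- data.frame(
      frame = t + 1L, z = gt$z_key,
      radius = wall_pore_radius(gt$z_key, gt$z_levels, gt$level_radii,
                                spec$atom_radius, dilation = level_dil))
  }
  stack <- trajectory_stack(frames, frame_times = seq_len(n_frames) - 1)
  attr(stack, "ground_truth") <- do.call(rbind, gt_rows)
  attr(stack, "partition") <- base$partition
  stack
}

#' Generate an analytic test shape
#'
#' \describe{
#'   \item{sphere}{a single atom of radius `R` at `center`.}
#'   \item{cylinder_shell}{`n_rings` stacked dense rings of `atoms_per_ring`
#'     small atoms (radius `rho`) at cylinder radius `R` spanning `height`.}
#'   \item{ring}{`n` atoms of radius `rho` on a circle of radius `R` in the
#'     plane `z`.}
#' }
#'
#' @param kind `"sphere"`, `"cylinder_shell"` or `"ring"`.
#' @param R principal radius (A).
#' @param rho atom radius for shell/ring members (A).
#' @param n number of atoms in a `ring`.
#' @param z plane height for a `ring` (A).
#' @param height,n_rings,atoms_per_ring cylinder shell geometry.
#' @param center sphere centre.
#' @return a `MolecularAssembly`.
#' @export
make_analytic_shape <- function(kind = c("sphere", "cylinder_shell", "ring"),
                                R = 10, rho = 0.5, n = 10L, z = 0,
                                height = 20, n_rings = 41L,
                                atoms_per_ring = 72L, center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  stopifnot(R > 0, rho > 0)
  xyz <- switch(kind,
    sphere = matrix(center, 1L, 3L),
    ring = {
      th <- 2 * pi * (seq_len(n) - 1L) / n
      cbind(R * cos(th), R * sin(th), rep(z, n))
    },
    cylinder_shell = {
      zs <- seq(-height / 2, height / 2, length.out = n_rings)
      th <- 2 * pi * (seq_len(atoms_per_ring) - 1L) / atoms_per_ring
      g <- expand.grid(th = th, z = zs)
      cbind(R * cos(g$th), R * sin(g$th), g$z)
    })
  radius <- if (kind == "sphere") R else rho
  atoms <- data.frame(
    serial = seq_len(nrow(xyz)), element = "C",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    radius = radius, chain = "A", resno = seq_len(nrow(xyz)),
    resid = "SYN", property = NA_real_, stringsAsFactors = FALSE
  )
  molecular_assembly(atoms, label = kind)
}
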