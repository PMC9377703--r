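# 360-degree panorama unrolling: a virtual ray caster sits on the channel
# axis and spins about it, recording where each horizontal ray meets the
# van-der-Waals surface. The hit radii over (theta, z) form a flat 2D map of
# the roughly cylindrical protein surface -- the molecular analogue of a
# spinning panoramic camera.

# vectorized ray-sphere intersection against all atoms of an assembly;
# returns entry/exit distances (NA where the ray misses an atom)
ray_sphere_hits <- function(xyz, rad, origin, direction) {
  oc <- sweep(xyz, 2L, origin)
  b <- oc %*% direction
  disc <- b^2 - (rowSums(oc^2) - rad^2)
  ok <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  t_in <- ifelse(ok, b - sq, NA_real_)
  t_out <- ifelse(ok, b + sq, NA_real_)
  list(t_in = as.numeric(t_in), t_out = as.numeric(t_out))
}

#' Cast one radial ray from the channel axis
#'
#' The ray starts at (0, 0, `z`) and travels horizontally along
#' (cos theta, sin theta, 0). `side = "inner"` returns the first sphere entry
#' (the lumen-facing wall, as seen by a camera on the axis); `side = "outer"`
#' returns the last sphere exit (the outer silhouette surface). Only
#' intersections at positive ray parameter count.
#'
#' @param assembly a `MolecularAssembly` in the canonical frame, radii
#'   assigned.
#' @param z height of the ray origin (A).
#' @param theta azimuth in degrees (0 along +x, counterclockwise seen from
#'   +z).
#' @param side `"outer"` (default) or `"inner"`.
#' @return list with `hit` (logical), and when `hit`: `radius` (A) and
#'   `atom` (index of the hit atom).
#' @export
cast_radial_ray <- function(assembly, z, theta, side = c("outer", "inner")) {
  side <- match.arg(side)
  stopifnot(inherits(assembly, "MolecularAssembly"))
  rad <- assembly$atoms$radius
  if (any(is.na(rad))) stop("atoms lack radii; run assign_radii() first")
  th <- theta * pi / 180
  hits <- ray_sphere_hits(coords(assembly), rad,
                          origin = c(0, 0, z),
                          direction = c(cos(th), sin(th), 0))
  sel <- select_hit(hits, side)
  if (is.null(sel)) return(list(hit = FALSE))
  list(hit = TRUE, radius = sel$radius, atom = sel$atom)
}

# pick the surface hit among positive ray parameters: inner = smallest
# positive root (first boundary crossing ahead of the origin), outer =
# largest positive root (last exit). Entry roots behind the origin (ray
# starting inside a sphere) never count.
select_hit <- function(hits, side) {
  tt <- c(hits$t_in, hits$t_out)
  tt[!is.na(tt) & tt <= 0] <- NA_real_
  if (all(is.na(tt))) return(NULL)
  k <- if (side == "inner") which.min(tt) else which.max(tt)
  n <- length(hits$t_in)
  list(radius = tt[k], atom = ((k - 1L) %% n) + 1L)
}

#' Unroll a surface onto a (theta, z) panorama map
#'
#' Casts one radial ray per (theta-bin centre, z-bin centre) and collects hit
#' radii, the hit atoms' painted properties, and a miss mask.
#'
#' @param assembly canonical-frame `MolecularAssembly` with radii.
#' @param theta_bins,z_bins grid resolution (>= 1 each).
#' @param z_range numeric `c(z_min, z_max)` (A), `z_min < z_max`.
#' @param side `"outer"` (silhouette) or `"inner"` (lumen wall).
#' @return object of class `PanoramaMap`: matrices `radii`, `properties`,
#'   `mask` of shape theta_bins x z_bins (theta bin k covers
#'   \[(k-1), k) * 360/theta_bins degrees; z rows analogous), plus the grid
#'   descriptors.
#' @export
unroll_surface <- function(assembly, theta_bins, z_bins, z_range,
                           side = c("outer", "inner")) {
  side <- match.arg(side)
  stopifnot(inherits(assembly, "MolecularAssembly"),
            theta_bins >= 1L, z_bins >= 1L,
            length(z_range) == 2L, z_range[1] < z_range[2])
  rad <- assembly$atoms$radius
  if (any(is.na(rad))) stop("atoms lack radii; run assign_radii() first")
  xyz <- coords(assembly)
  prop <- assembly$atoms$property
  prop[is.na(prop)] <- 0
  dtheta <- 360 / theta_bins
  theta_centers <- (seq_len(theta_bins) - 0.5) * dtheta
  dz <- (z_range[2] - z_range[1]) / z_bins
  z_centers <- z_range[1] + (seq_len(z_bins) - 0.5) * dz
  radii <- matrix(NA_real_, theta_bins, z_bins)
  props <- matrix(0, theta_bins, z_bins)
  mask <- matrix(TRUE, theta_bins, z_bins)
  for (it in seq_len(theta_bins)) {
    th <- theta_centers[it] * pi / 180
    d <- c(cos(th), sin(th), 0)
    for (iz in seq_len(z_bins)) {
      sel <- select_hit(ray_sphere_hits(xyz, rad, c(0, 0, z_centers[iz]), d),
                        side)
      if (!is.null(sel)) {
        radii[it, iz] <- sel$radius
        props[it, iz] <- prop[sel$atom]
        mask[it, iz] <- FALSE
      }
    }
  }
  structure(list(theta_bins = as.integer(theta_bins),
                 z_bins = as.integer(z_bins),
                 z_range = as.numeric(z_range),
                 theta_centers = theta_centers, z_centers = z_centers,
                 radii = radii, properties = props, mask = mask,
                 side = side),
            class = "PanoramaMap")
}

#' @export
print.PanoramaMap <- function(x, ...) {
  cat(sprintf("PanoramaMap (%s): %d theta x %d z bins, z in [%.1f, %.1f] A, %.1f%% masked\n",
              x$side, x$theta_bins, x$z_bins, x$z_range[1], x$z_range[2],
              100 * mean(x$mask)))
  invisible(x)
}

#' Export a panorama map as TSV matrices and a grayscale PNG
#'
#' Writes `<prefix>_radii.tsv` and `<prefix>_properties.tsv` (rows = theta
#' bins, columns = z bins, masked cells as NA) and `<prefix>.png`, an 8-bit
#' grayscale image of the radii min-max normalized over unmasked cells
#' (masked pixels black; a constant map renders white). In the PNG, theta
#' increases rightward and z upward.
#'
#' @param map a `PanoramaMap`.
#' @param path_prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
export_panorama <- function(map, path_prefix) {
  stopifnot(inherits(map, "PanoramaMap"))
  if (all(map$mask)) stop("cannot export an all-masked panorama (no surface hits)")
  f_rad <- paste0(path_prefix, "_radii.tsv")
  f_prop <- paste0(path_prefix, "_properties.tsv")
  f_png <- paste0(path_prefix, ".png")
  write_tsv_matrix(map$radii, f_rad)
  write_tsv_matrix(map$properties, f_prop)
  vals <- map$radii[!map$mask]
  lo <- min(vals); hi <- max(vals)
  norm <- if (hi - lo < .Machine$double.eps * max(abs(hi), 1)) {
    ifelse(map$mask, 0, 1) # zero dynamic range maps to white
  } else {
    ifelse(map$mask, 0, (map$radii - lo) / (hi - lo))
  }
  norm[is.na(norm)] <- 0
  # PNG layout: columns = theta (rightward), rows = z (upward)
  img <- t(norm)[rev(seq_len(map$z_bins)), , drop = FALSE]
  write_gray_png(img, f_png)
  invisible(c(f_rad, f_prop, f_png))
}
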