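# Exploded views: subunits translated radially away from the symmetry axis,
# vertically across the membrane plane, or both. Fragments are translated,
# never rotated, so every fragment remains rigid.

#' Compute an exploded-view layout
#'
#' Builds per-fragment rigid translation vectors for an exploded view of an
#' oligomeric assembly:
#' \describe{
#'   \item{radial}{one fragment per subunit, translated by `radial_offset`
#'     along the unit vector from the axis to the subunit centroid (projected
#'     into the plane perpendicular to the axis).}
#'   \item{vertical}{each subunit is split at the membrane plane
#'     `z = split_z` into an upper and a lower fragment, translated by
#'     +/- `vertical_gap`/2 along the axis (an empty half is omitted).}
#'   \item{combined}{both translations summed per fragment.}
#' }
#' Offsets are absolute distances in Angstrom, so gaps are predictable across
#' differently sized assemblies.
#'
#' @param assembly a `MolecularAssembly` in the canonical frame (or in the
#'   frame given by `frame`).
#' @param partition a [partition_subunits()] result.
#' @param frame a [symmetry_frame()]; default is the canonical frame.
#' @param mode `"radial"`, `"vertical"` or `"combined"`.
#' @param radial_offset radial separation (A, >= 0).
#' @param vertical_gap total vertical separation (A, >= 0).
#' @param split_z height of the splitting plane along the axis (A); default 0,
#'   the membrane mid-plane.
#' @return object of class `ExplosionLayout`: `fragments` is a named list of
#'   `list(atoms = <indices>, translation = <3-vector>)`.
#' @export
compute_layout <- function(assembly, partition, frame = symmetry_frame(),
                           mode = c("radial", "vertical", "combined"),
                           radial_offset = 0, vertical_gap = 0, split_z = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(assembly, "MolecularAssembly"),
            inherits(partition, "SubunitPartition"),
            inherits(frame, "SymmetryFrame"),
            radial_offset >= 0, vertical_gap >= 0)
  xyz <- coords(assembly)
  axis <- frame$axis
  fragments <- list()
  for (lab in names(partition$groups)) {
    idx <- partition$groups[[lab]]
    sub_xyz <- xyz[idx, , drop = FALSE]
    radial_vec <- c(0, 0, 0)
    if (mode %in% c("radial", "combined")) {
      ctr <- colMeans(sub_xyz) - frame$origin
      perp <- ctr - sum(ctr * axis) * axis
      pn <- sqrt(sum(perp^2))
      if (pn < 1e-6) {
        stop("subunit '", lab, "' has its centroid on the axis; ",
             "radial explosion direction is undefined")
      }
      radial_vec <- as.numeric(radial_offset * perp / pn)
    }
    if (mode == "radial") {
      fragments[[lab]] <- list(atoms = idx, translation = radial_vec)
    } else {
      h <- (sub_xyz - matrix(frame$origin, nrow(sub_xyz), 3, byrow = TRUE)) %*% axis
      upper <- idx[h > split_z]
      lower <- idx[h <= split_z]
      if (length(upper) > 0L) {
        fragments[[paste0(lab, ".upper")]] <-
          list(atoms = upper, translation = radial_vec + (vertical_gap / 2) * axis)
      }
      if (length(lower) > 0L) {
        fragments[[paste0(lab, ".lower")]] <-
          list(atoms = lower, translation = radial_vec - (vertical_gap / 2) * axis)
      }
    }
  }
  structure(list(fragments = fragments, mode = mode,
                 radial_offset = radial_offset, vertical_gap = vertical_gap,
                 split_z = split_z),
            class = "ExplosionLayout")
}

#' @export
print.ExplosionLayout <- function(x, ...) {
  cat(sprintf("ExplosionLayout (%s): %d fragment(s), radial %.2f A, vertical %.2f A\n",
              x$mode, length(x$fragments), x$radial_offset, x$vertical_gap))
  invisible(x)
}

#' Apply an exploded-view layout
#'
#' Rigidly translates each fragment by its layout vector. Atom ordering is
#' unchanged; intra-fragment geometry is preserved exactly.
#'
#' @param assembly the `MolecularAssembly` the layout was computed for.
#' @param layout an [compute_layout()] result.
#' @return the exploded `MolecularAssembly`.
#' @export
apply_layout <- function(assembly, layout) {
  stopifnot(inherits(assembly, "MolecularAssembly"),
            inherits(layout, "ExplosionLayout"))
  xyz <- coords(assembly)
  n <- nrow(xyz)
  for (frag in layout$fragments) {
    if (any(frag$atoms < 1L | frag$atoms > n)) {
      stop("layout fragment indexes atoms outside the assembly")
    }
    xyz[frag$atoms, ] <- sweep(xyz[frag$atoms, , drop = FALSE], 2L,
                               frag$translation, `+`)
  }
  set_coords(assembly, xyz)
}

#' Scale a layout for explosion animation ramps
#'
#' @param layout an `ExplosionLayout`.
#' @param t interpolation parameter in \[0, 1\]: 0 collapses all translations
#'   to zero, 1 returns the layout unchanged.
#' @return the scaled `ExplosionLayout`.
#' @export
interpolate_layout <- function(layout, t) {
  stopifnot(inherits(layout, "ExplosionLayout"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
    stop("t must be a single value in [0, 1]")
  }
  layout$fragments <- lapply(layout$fragments, function(frag) {
    frag$translation <- frag$translation * t
    frag
  })
  layout
}

#' Serialize a layout as JSON
#'
#' Writes the fragment translations (label -> 3-vector, Angstrom) plus the
#' generating mode and parameters, for consumption by external renderers.
#'
#' @param layout an `ExplosionLayout`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "ExplosionLayout"))
  obj <- list(
    mode = layout$mode,
    radial_offset = layout$radial_offset,
    vertical_gap = layout$vertical_gap,
    split_z = layout$split_z,
    fragments = lapply(layout$fragments, function(frag) {
      list(n_atoms = length(frag$atoms), translation = frag$translation)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
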