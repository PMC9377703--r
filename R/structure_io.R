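# Atom tables are plain data.frames with columns:
#   serial, element, x, y, z, radius, chain, resno, resid, property
# Coordinates are in Angstrom throughout the package.

#' Construct a molecular assembly
#'
#' A `MolecularAssembly` bundles an atom table with a frame index and a free
#' text label. It is the basic container every geometric operation consumes:
#' one assembly is one structure (or one frame of a trajectory stack).
#'
#' @param atoms data.frame with columns `serial`, `element`, `x`, `y`, `z`,
#'   `radius`, `chain`, `resno`, `resid` and optionally `property` (a unitless
#'   per-atom scalar used for surface painting). Coordinates and radii in
#'   Angstrom.
#' @param frame_index integer frame number (0-based, 0 for single structures).
#' @param label free-text description.
#' @return object of class `MolecularAssembly`.
#' @export
molecular_assembly <- function(atoms, frame_index = 0L, label = "") {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "element", "x", "y", "z", "radius", "chain", "resno", "resid")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("assembly must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique within a frame")
  if (any(!is.na(atoms$radius) & atoms$radius <= 0)) stop("atom radii must be > 0")
  if (is.null(atoms$property)) atoms$property <- NA_real_
  structure(
    list(atoms = atoms, frame_index = as.integer(frame_index), label = label),
    class = "MolecularAssembly"
  )
}

#' @export
print.MolecularAssembly <- function(x, ...) {
  cat(sprintf(
    "MolecularAssembly: %d atoms, %d chain(s), frame %d%s\n",
    nrow(x$atoms), length(unique(x$atoms$chain)), x$frame_index,
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param assembly a `MolecularAssembly`.
#' @return numeric n x 3 matrix of coordinates (Angstrom).
#' @export
coords <- function(assembly) {
  stopifnot(inherits(assembly, "MolecularAssembly"))
  as.matrix(assembly$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#'
#' @param assembly a `MolecularAssembly`.
#' @param xyz n x 3 numeric matrix.
#' @return the assembly with updated coordinates.
#' @export
set_coords <- function(assembly, xyz) {
  stopifnot(inherits(assembly, "MolecularAssembly"),
            is.matrix(xyz), ncol(xyz) == 3L, nrow(xyz) == nrow(assembly$atoms))
  assembly$atoms$x <- xyz[, 1]
  assembly$atoms$y <- xyz[, 2]
  assembly$atoms$z <- xyz[, 3]
  assembly
}

#' Construct a trajectory stack
#'
#' A `TrajectoryStack` is an ordered list of frames (each a
#' [molecular_assembly()]) with identical atom count and ordering, standing in
#' for a molecular dynamics trajectory. Multi-model PDB files map one MODEL to
#' one frame.
#'
#' @param frames list of `MolecularAssembly` objects.
#' @param frame_times optional numeric vector of times (arbitrary units),
#'   strictly increasing.
#' @return object of class `TrajectoryStack`.
#' @export
trajectory_stack <- function(frames, frame_times = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  lapply(frames, function(f) stopifnot(inherits(f, "MolecularAssembly")))
  n0 <- nrow(frames[[1]]$atoms)
  s0 <- frames[[1]]$atoms$serial
  for (f in frames) {
    if (nrow(f$atoms) != n0 || !identical(f$atoms$serial, s0)) {
      stop("all frames must share atom count and ordering")
    }
  }
  if (!is.null(frame_times)) {
    stopifnot(length(frame_times) == length(frames))
    if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  }
  structure(list(frames = frames, frame_times = frame_times),
            class = "TrajectoryStack")
}

#' @export
print.TrajectoryStack <- function(x, ...) {
  cat(sprintf("TrajectoryStack: %d frame(s) x %d atoms\n",
              length(x$frames), nrow(x$frames[[1]]$atoms)))
  invisible(x)
}

#' @export
length.TrajectoryStack <- function(x) length(x$frames)

#' Bundled van der Waals radius table
#'
#' Standard van der Waals radii (Bondi set) in Angstrom, used to assign a
#' sphere radius to each atom before any surface, panorama or pore operation.
#'
#' @return named numeric vector, element symbol (upper case) -> radius (A).
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, HE = 1.40, LI = 1.82, BE = 1.53, B = 1.92, C = 1.70,
    N = 1.55, O = 1.52, F = 1.47, NE = 1.54, "NA" = 2.27, MG = 1.73,
    AL = 1.84, SI = 2.10, P = 1.80, S = 1.80, CL = 1.75, AR = 1.88,
    K = 2.75, CA = 2.31, MN = 2.05, FE = 2.04, CO = 2.00, NI = 1.63,
    CU = 1.40, ZN = 1.39, BR = 1.85, I = 1.98)
}

#' Assign per-atom sphere radii
#'
#' Looks each atom's element symbol up in a named radius table. Unknown
#' elements never fail: they receive `default_radius` and are counted in the
#' attached report (`attr(result, "radius_report")`); a warning summarises the
#' count.
#'
#' @param assembly a `MolecularAssembly`.
#' @param radius_set named numeric vector (element -> radius, Angstrom);
#'   defaults to [default_vdw_radii()]. A single unnamed value is used as a
#'   uniform radius for all atoms.
#' @param default_radius radius (A) for elements absent from the table.
#' @param warn emit a warning when unknown elements are present.
#' @return the assembly with `radius` filled; attribute `radius_report` holds
#'   `n_unknown` and the unknown element symbols.
#' @export
assign_radii <- function(assembly, radius_set = default_vdw_radii(),
                         default_radius = 1.5, warn = TRUE) {
  stopifnot(inherits(assembly, "MolecularAssembly"))
  ele <- toupper(trimws(assembly$atoms$element))
  if (length(radius_set) == 1L && is.null(names(radius_set))) {
    assembly$atoms$radius <- rep(as.numeric(radius_set), length(ele))
    attr(assembly, "radius_report") <- list(n_unknown = 0L, elements = character(0))
    return(assembly)
  }
  r <- unname(radius_set[ele])
  unknown <- is.na(r)
  r[unknown] <- default_radius
  assembly$atoms$radius <- r
  report <- list(n_unknown = sum(unknown), elements = unique(ele[unknown]))
  attr(assembly, "radius_report") <- report
  if (warn && report$n_unknown > 0L) {
    warning(sprintf("%d atom(s) with unknown element (%s) assigned default radius %.2f A",
                    report$n_unknown, paste(report$elements, collapse = ","),
                    default_radius))
  }
  assembly
}

#' Read an atomic structure or trajectory stack from PDB
#'
#' Parses fixed-column ATOM/HETATM records via \pkg{bio3d}. MODEL/ENDMDL
#' blocks become trajectory frames; a file without MODEL records yields a
#' single-frame stack. Alternate locations keep the first conformer; CONECT
#' records are ignored. Radii are assigned from [default_vdw_radii()]
#' (unknown elements degrade to the default radius); the B-factor column is
#' imported as the per-atom `property`.
#'
#' @param path PDB file path.
#' @param model_policy `"all"` (one frame per MODEL) or `"first"`.
#' @return a [trajectory_stack()].
#' @export
read_structure <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("cannot read structure: no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = (model_policy == "all"),
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) {
    stop("no ATOM/HETATM records in ", path)
  }
  a <- pdb$atom
  chain <- a$chain
  chain[is.na(chain)] <- " "
  ele <- a$elesy
  # fall back to first letter of the atom name when the element column is blank
  blank <- is.na(ele) | !nzchar(trimws(ele))
  ele[blank] <- substr(trimws(a$elety[blank]), 1L, 1L)
  base_atoms <- data.frame(
    serial = a$eleno, element = trimws(ele),
    x = a$x, y = a$y, z = a$z,
    radius = NA_real_,
    chain = chain, resno = a$resno, resid = a$resid,
    property = a$b,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- if (model_policy == "all") nrow(xyz) else 1L
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    at <- base_atoms
    m <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    if (nrow(m) != nrow(at)) stop("inconsistent atom count across MODEL records")
    at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
    fr <- molecular_assembly(at, frame_index = k - 1L, label = basename(path))
    frames[[k]] <- assign_radii(fr, warn = FALSE)
  }
  trajectory_stack(frames)
}

#' Write a structure or trajectory stack to PDB
#'
#' Emits standard fixed-column ATOM records; multi-frame stacks are wrapped in
#' MODEL/ENDMDL blocks. With `property_to_bfactor = TRUE` the per-atom
#' `property` is written into the B-factor column (the de-facto convention for
#' painting scalars onto structures in molecular viewers), clamped to the
#' printable range of the column.
#'
#' @param stack a [trajectory_stack()] or single [molecular_assembly()].
#' @param path output file path.
#' @param property_to_bfactor write `property` into the B-factor column.
#' @return `path`, invisibly.
#' @export
write_structure <- function(stack, path, property_to_bfactor = FALSE) {
  if (inherits(stack, "MolecularAssembly")) stack <- trajectory_stack(list(stack))
  stopifnot(inherits(stack, "TrajectoryStack"))
  a <- stack$frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(stack$frames, function(f) as.vector(t(coords(f)))))
  if (any(xyz < -999.999) || any(xyz > 9999.999)) {
    stop("coordinates exceed the fixed-column width of the PDB format")
  }
  b <- if (property_to_bfactor) {
    p <- a$property
    p[is.na(p)] <- 0
    pmin(pmax(p, -99.99), 999.99)
  } else rep(0, nrow(a))
  chain <- a$chain
  chain[chain == " "] <- NA
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = rep("ATOM", nrow(a)),
    eleno = a$serial, elety = a$element,
    resid = a$resid, chain = chain, resno = a$resno,
    o = rep(1, nrow(a)), b = b, elesy = a$element
  )
  invisible(path)
}

#' Partition an assembly into subunits
#'
#' Groups atoms into the subunits used by explosion, hull abstraction and
#' cyclic axis detection. Pentameric channels such as GLIC partition naturally
#' by chain into their five identical subunits.
#'
#' @param assembly a `MolecularAssembly`.
#' @param mode `"by_chain"` (group by chain identifier) or `"single"` (one
#'   group covering all atoms).
#' @return object of class `SubunitPartition`: list with `groups` (named list
#'   of atom index vectors, labels sorted lexicographically) and `mode`.
#' @export
partition_subunits <- function(assembly, mode = c("by_chain", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assembly, "MolecularAssembly"))
  n <- nrow(assembly$atoms)
  groups <- if (mode == "single") {
    list(all = seq_len(n))
  } else {
    g <- split(seq_len(n), assembly$atoms$chain)
    g[order(names(g))]
  }
  structure(list(groups = groups, mode = mode), class = "SubunitPartition")
}

#' @export
print.SubunitPartition <- function(x, ...) {
  cat(sprintf("SubunitPartition (%s): %d group(s) [%s]\n", x$mode,
              length(x$groups), paste(names(x$groups), collapse = ", ")))
  invisible(x)
}

#' Paint a per-residue property table onto an assembly
#'
#' Reads a TSV table with columns `chain`, `resno`, `value` and assigns
#' `value` to every atom matching (chain, residue index). Atoms without a
#' match keep their current property.
#'
#' @param assembly a `MolecularAssembly`.
#' @param path TSV file with header `chain  resno  value`.
#' @return the assembly with `property` updated.
#' @export
read_property_table <- function(assembly, path) {
  stopifnot(inherits(assembly, "MolecularAssembly"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chain", "resno", "value") %in% names(tab)))
  key <- paste(assembly$atoms$chain, assembly$atoms$resno)
  idx <- match(key, paste(tab$chain, tab$resno))
  hit <- !is.na(idx)
  assembly$atoms$property[hit] <- tab$value[idx[hit]]
  assembly
}
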