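# Topology and Trajectory containers.
#
# A topology is a flat atom table plus derived residue/segment views; this
# mirrors how MD analysis tools index selections. Coordinates are Angstrom,
# residue numbering is 1-based, the membrane normal is z and the bilayer
# centre sits near z = 0 by convention.

#' Bundled element masses and van der Waals radii
#'
#' Minimal lookup used when a structure file carries no per-atom masses or
#' radii (the PDB format does not). Masses in amu, radii in Angstrom.
#'
#' @return data.frame with columns `element`, `mass`, `vdw_radius`.
#' @export
element_table <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "P", "S", "MG", "NA", "CL", "K"),
    mass = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06,
             24.305, 22.990, 35.45, 39.098),
    vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.73, 2.27, 1.75, 2.75),
    stringsAsFactors = FALSE
  )
}

#' Construct a topology
#'
#' @param atoms data.frame with columns `atom_id` (1-based, contiguous),
#'   `name`, `element`, `mass` (amu), `charge` (e), `vdw_radius` (Angstrom),
#'   `res_id` (1-based), `res_name`, `seg_name`, `role`. Optional columns:
#'   `body` (sub-body tag for ligand/lipid node splitting), `eps`, `sigma`
#'   (Lennard-Jones parameters, kcal/mol and Angstrom).
#' @return object of class `abc_topology`.
#' @export
new_topology <- function(atoms) {
  req <- c("atom_id", "name", "element", "mass", "charge", "vdw_radius",
           "res_id", "res_name", "seg_name", "role")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("topology atoms missing columns: ",
                         paste(miss, collapse = ", "))
  if (!("body" %in% names(atoms))) atoms$body <- NA_character_
  if (!("eps" %in% names(atoms))) atoms$eps <- NA_real_
  if (!("sigma" %in% names(atoms))) atoms$sigma <- NA_real_
  atoms <- atoms[order(atoms$atom_id), , drop = FALSE]
  rownames(atoms) <- NULL
  top <- structure(list(atoms = atoms, n_atoms = nrow(atoms)),
                   class = "abc_topology")
  validate_topology(top)
  top
}

#' Validate topology invariants
#'
#' Checks atom-id uniqueness/contiguity, positive masses, non-negative
#' van der Waals radii, residue membership and that every residue belongs
#' to at most one segment.
#'
#' @param top an `abc_topology`.
#' @return the topology, invisibly; stops on violation.
#' @export
validate_topology <- function(top) {
  a <- top$atoms
  if (anyDuplicated(a$atom_id))
    stop("parse error: duplicated atom ids: ",
         paste(unique(a$atom_id[duplicated(a$atom_id)]), collapse = ", "))
  if (!identical(as.integer(a$atom_id), seq_len(nrow(a))))
    stop("atom ids must be contiguous 1..N")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    stop("masses must be positive")
  if (any(!is.finite(a$vdw_radius)) || any(a$vdw_radius < 0))
    stop("vdw radii must be non-negative")
  if (anyNA(a$res_id)) stop("every atom must belong to a residue")
  segs <- unique(a[, c("res_id", "seg_name")])
  if (anyDuplicated(segs$res_id))
    stop("a residue belongs to more than one segment")
  invisible(top)
}

#' @export
print.abc_topology <- function(x, ...) {
  a <- x$atoms
  cat("abc_topology:", x$n_atoms, "atoms,",
      length(unique(a$res_id)), "residues,",
      length(unique(a$seg_name)), "segments\n")
  cat("  roles:", paste(sort(unique(a$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Residue table of a topology
#' @param top an `abc_topology`.
#' @return data.frame with one row per residue.
#' @export
residues <- function(top) {
  a <- top$atoms
  unique(a[, c("res_id", "res_name", "seg_name", "role")])
}

#' Atom indices of a residue set
#'
#' @param top an `abc_topology`.
#' @param res_ids integer residue ids.
#' @param atoms `"all"` for every atom, `"ca"` for pseudo/real C-alpha
#'   atoms, `"backbone"` for CA/N/C/O, `"heavy"` to drop hydrogens.
#' @return integer atom indices.
#' @export
atom_indices <- function(top, res_ids, atoms = c("all", "ca", "backbone", "heavy")) {
  atoms <- match.arg(atoms)
  a <- top$atoms
  sel <- a$res_id %in% res_ids
  sel <- switch(atoms,
    all = sel,
    ca = sel & a$name == "CA",
    backbone = sel & a$name %in% c("CA", "N", "C", "O"),
    heavy = sel & a$element != "H")
  which(sel)
}

#' Construct a trajectory
#'
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`,
#'   Angstrom.
#' @param box per-frame orthorhombic box lengths: length-3 vector (recycled)
#'   or `n_frames` x 3 matrix; `NULL` for no periodic box.
#' @param frame_time time between stored frames, ps.
#' @return object of class `abc_trajectory`.
#' @export
new_trajectory <- function(coords, box = NULL, frame_time = 100) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  nf <- dim(coords)[3]
  if (!is.null(box)) {
    if (is.vector(box)) box <- matrix(box, nf, 3, byrow = TRUE)
    if (any(box <= 0)) stop("box lengths must be positive")
    if (nrow(box) != nf) stop("box rows must match frame count")
  }
  structure(list(coords = coords, box = box, frame_time = frame_time,
                 n_frames = nf, n_atoms = dim(coords)[1]),
            class = "abc_trajectory")
}

#' @export
print.abc_trajectory <- function(x, ...) {
  cat("abc_trajectory:", x$n_frames, "frames x", x$n_atoms,
      "atoms;", x$frame_time, "ps/frame\n")
  invisible(x)
}

#' Extract one frame as an N x 3 matrix
#' @param traj an `abc_trajectory`.
#' @param i frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > traj$n_frames) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

frame_box <- function(traj, i) {
  if (is.null(traj$box)) NULL else traj$box[i, ]
}
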