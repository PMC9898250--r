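# Structure and trajectory file IO.
#
# Reading goes through bio3d's PDB parser; writing of (multi-model) PDB is
# done here because trajectory-style multi-model output is not covered by
# bio3d's single-model writer. Partial charges survive a round trip by
# being stored in the B-factor column (the PDB format has no charge field);
# this is documented behaviour, not a convention of the format.

#' Read a structure file
#'
#' Parses a PDB file into a topology plus the first model's coordinates.
#' Role tags default to `"unassigned"`; selection roles are supplied
#' separately by a selection scheme (see [parse_selection_scheme()]).
#' Masses and van der Waals radii come from [element_table()]; partial
#' charges are recovered from the B-factor column.
#'
#' @param path file path.
#' @param format only `"pdb"` is supported.
#' @return list with `topology` (an `abc_topology`), `coords` (N x 3,
#'   Angstrom) and `box` (length-3 or `NULL`).
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (anyDuplicated(at$eleno))
    stop("parse error: duplicated atom serial in ", path, " (serial ",
         paste(unique(at$eleno[duplicated(at$eleno)]), collapse = ", "), ")")
  elem <- toupper(trimws(at$elesy))
  elem[is.na(elem) | elem == ""] <- toupper(substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1))
  et <- element_table()
  m <- match(elem, et$element)
  if (anyNA(m))
    stop("element lookup error: no mass/radius for element(s): ",
         paste(unique(elem[is.na(m)]), collapse = ", "))
  resfac <- match(paste(at$resno, at$chain), unique(paste(at$resno, at$chain)))
  atoms <- data.frame(
    atom_id = seq_len(nrow(at)),
    name = trimws(at$elety),
    element = elem,
    mass = et$mass[m],
    charge = ifelse(is.na(at$b), 0, at$b),
    vdw_radius = et$vdw_radius[m],
    res_id = resfac,
    res_name = trimws(at$resid),
    seg_name = "unassigned",
    role = "unassigned",
    stringsAsFactors = FALSE
  )
  top <- new_topology(atoms)
  coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  list(topology = top, coords = coords, box = read_cryst1(path))
}

read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 200), value = TRUE)
  if (!length(ln)) return(NULL)
  as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24), substr(ln[1], 25, 33)))
}

#' Read a multi-model PDB as a trajectory
#'
#' @param path multi-model PDB file.
#' @param topology the matching `abc_topology` (atom counts must agree).
#' @param stride keep every `stride`-th frame starting at the first;
#'   `frame_time` is scaled accordingly.
#' @param frame_time time between stored models in the file, ps.
#' @return an `abc_trajectory`.
#' @export
read_trajectory <- function(path, topology, stride = 1, frame_time = 100) {
  if (!is.numeric(stride) || length(stride) != 1 || stride < 1 ||
      stride != round(stride))
    stop("stride must be a positive integer")
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_file <- ncol(xyz) / 3
  if (n_file != topology$n_atoms)
    stop("shape error: file has ", n_file, " atoms but topology has ",
         topology$n_atoms)
  keep <- seq(1, nrow(xyz), by = stride)
  coords <- array(0, c(topology$n_atoms, 3, length(keep)))
  for (k in seq_along(keep))
    coords[, , k] <- matrix(xyz[keep[k], ], ncol = 3, byrow = TRUE)
  box <- read_cryst1(path)
  new_trajectory(coords, box = box, frame_time = frame_time * stride)
}

#' Write a (multi-model) PDB
#'
#' One MODEL block per frame; partial charges are written into the
#' B-factor column so that [read_structure()] can recover them.
#'
#' @param top an `abc_topology`.
#' @param coords N x 3 matrix or N x 3 x F array, Angstrom.
#' @param path output path.
#' @param box optional orthorhombic box lengths for a CRYST1 record.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(top, coords, path, box = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  a <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1], box[2], box[3], 90, 90, 90), con)
  nf <- dim(coords)[3]
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$atom_id %% 100000, name4, substr(a$res_name, 1, 3), "A",
      a$res_id %% 10000,
      coords[, 1, f], coords[, 2, f], coords[, 3, f],
      1.00, a$charge, a$element)
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#' @param traj an `abc_trajectory`.
#' @param top matching `abc_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, top, path) {
  box <- if (is.null(traj$box)) NULL else traj$box[1, ]
  write_pdb(top, traj$coords, path, box = box)
}
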