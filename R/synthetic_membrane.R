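# Synthetic membranes and ligand pseudo-molecules.
#
# Lipids are geometric stand-ins: a phosphate-like head bead, two
# all-trans tails with explicit hydrogens, and a tunable fraction of
# carbons whose C-H vectors are drawn isotropically. The analytic order
# parameter of the ensemble is -0.5 * p where p is the fraction of
# membrane-plane C-H vectors, so the target |S_CD| level maps to
# p = level / 0.5 exactly.

#' Specification for a synthetic membrane
#'
#' @param composition named fractions over species `pc`, `pe`, `sterol`
#'   (must sum to 1).
#' @param n_per_leaflet lipids per leaflet.
#' @param tail_length carbons per tail.
#' @param order target `|S_CD|` level in `[0, 0.5]` (0.5 = all-trans
#'   membrane-normal tails, 0 = isotropic C-H vectors).
#' @param box orthorhombic box, Angstrom; `NULL` sizes xy automatically at
#'   64 Angstrom^2 per lipid.
#' @param head_z leaflet head-bead height above the bilayer centre.
#' @param seed RNG seed.
#' @return list of class `membrane_spec`.
#' @export
membrane_spec <- function(composition = c(pc = 0.5, pe = 0.25, sterol = 0.25),
                          n_per_leaflet = 64, tail_length = 8, order = 0.3,
                          box = NULL, head_z = 19, seed = 1) {
  if (abs(sum(composition) - 1) > 1e-6) stop("composition must sum to 1")
  if (n_per_leaflet <= 0) stop("lipid count must be positive")
  if (order < 0 || order > 0.5) stop("order level must lie in [0, 0.5]")
  if (is.null(box)) {
    l <- ceiling(sqrt(n_per_leaflet * 64))
    box <- c(l, l, 80)
  }
  if (n_per_leaflet * 60 > box[1] * box[2])
    stop("packing error: box too small for requested lipid count at 60 A^2/lipid")
  structure(list(composition = composition, n_per_leaflet = n_per_leaflet,
                 tail_length = tail_length, order = order, box = box,
                 head_z = head_z, seed = seed),
            class = "membrane_spec")
}

species_counts <- function(fracs, n) {
  cnt <- floor(fracs * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(fracs * n - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  cnt
}

#' Build a synthetic bilayer
#'
#' @param spec a [membrane_spec()].
#' @param seed overrides the spec seed if given.
#' @return list with `topology`, `coords` and `spec`.
#' @export
make_membrane <- function(spec = membrane_spec(), seed = NULL) {
  stopifnot(inherits(spec, "membrane_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  n <- spec$n_per_leaflet
  g <- ceiling(sqrt(n))
  dx <- spec$box[1] / g; dy <- spec$box[2] / g
  p_perp <- spec$order / 0.5

  rows <- list(); coords <- list(); res_counter <- 0L

  add_lipid <- function(x, y, s, resname) {
    res_counter <<- res_counter + 1L
    nm <- "P"; el <- "P"; bd <- "head"
    xyz <- matrix(c(x, y, s * spec$head_z), 1, 3)
    for (tail in c("A", "B")) {
      toff <- if (tail == "A") -0.9 else 0.9
      for (k in seq_len(spec$tail_length)) {
        cpos <- c(x + toff, y, s * (spec$head_z - 1 - 1.27 * k))
        if (stats::runif(1) < p_perp) {
          al <- stats::runif(1, 0, 2 * pi)
          h1 <- cpos + 1.09 * c(cos(al), sin(al), 0)
          h2 <- cpos + 1.09 * c(cos(al + 2 * pi / 3), sin(al + 2 * pi / 3), 0)
        } else {
          rv <- function() {
            v <- stats::rnorm(3); 1.09 * v / sqrt(sum(v^2))
          }
          h1 <- cpos + rv(); h2 <- cpos + rv()
        }
        nm <- c(nm, paste0("C", k, tail), paste0("H", k, tail, "1"),
                paste0("H", k, tail, "2"))
        el <- c(el, "C", "H", "H")
        bd <- c(bd, rep(paste0("tail_", tolower(tail)), 3))
        xyz <- rbind(xyz, cpos, h1, h2)
      }
    }
    rows[[length(rows) + 1]] <<- data.frame(
      name = nm, element = el, mass = element_table()$mass[
        match(el, element_table()$element)],
      charge = 0, vdw_radius = element_table()$vdw_radius[
        match(el, element_table()$element)],
      res_id = res_counter, res_name = resname, seg_name = resname,
      role = "lipid", body = bd, stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- xyz
  }

  add_sterol <- function(x, y, s) {
    res_counter <<- res_counter + 1L
    ang <- 2 * pi * (0:4) / 5
    ring <- cbind(x + 1.2 * cos(ang), y + 1.2 * sin(ang),
                  s * (spec$head_z - 4))
    xyz <- rbind(c(x, y, s * (spec$head_z - 1)), ring,
                 c(x, y, s * (spec$head_z - 7)),
                 c(x, y, s * (spec$head_z - 10)))
    nm <- c("O3", paste0("R", 1:5), "C15", "C17")
    el <- c("O", rep("C", 7))
    rows[[length(rows) + 1]] <<- data.frame(
      name = nm, element = el, mass = element_table()$mass[
        match(el, element_table()$element)],
      charge = 0, vdw_radius = element_table()$vdw_radius[
        match(el, element_table()$element)],
      res_id = res_counter, res_name = "CHL", seg_name = "CHL",
      role = "sterol", body = "sterol", stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- xyz
  }

  fr <- c(pc = 0, pe = 0, sterol = 0)
  fr[names(spec$composition)] <- spec$composition
  for (s in c(1, -1)) {
    cnt <- species_counts(fr, n)
    species <- sample(rep(c("PCL", "PEL", "CHL"), cnt))
    for (k in seq_len(n)) {
      x <- (((k - 1) %% g) + 0.5) * dx
      y <- ((k - 1) %/% g + 0.5) * dy
      if (species[k] == "CHL") add_sterol(x, y, s)
      else add_lipid(x, y, s, species[k])
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  top <- new_topology(atoms)
  list(topology = top, coords = do.call(rbind, coords), spec = spec)
}

#' Build a ligand pseudo-molecule
#'
#' Sub-body tagging mirrors the coarse node model used for allosteric
#' networks: ATP-like ligands split into purine, ribose and triphosphate;
#' LTX-like (leukotriene-like amphiphile) into glutathione, tail and acid;
#' sterol-like molecules form a single body.
#'
#' @param kind one of `"atp_like"`, `"ltx_like"`, `"sterol_like"`.
#' @param pose position of the ligand origin, length-3, Angstrom.
#' @return list with `atoms` (topology fragment, local 1-based ids),
#'   `coords`, `donors` (data.frame of donor-heavy/hydrogen local indices),
#'   `acceptors` (local indices) and `rings` (named list of ring-atom
#'   index vectors).
#' @export
make_ligand <- function(kind = c("atp_like", "ltx_like", "sterol_like"),
                        pose = c(0, 0, 0)) {
  kind <- match.arg(kind)
  hexagon <- function(center, r = 1.4) {
    ang <- 2 * pi * (0:5) / 6
    cbind(center[1] + r * cos(ang), center[2] + r * sin(ang), center[3])
  }
  if (kind == "atp_like") {
    ring <- hexagon(pose)
    rib <- sweep(rbind(c(2.5, 0, 0), c(3.5, 0.8, 0), c(3.5, -0.8, 0),
                       c(4.5, 0, 0)), 2, pose, `+`)
    ho2 <- rib[4, ] + c(0.7, 0.7, 0)
    tp <- sweep(rbind(c(6, 0, 0), c(7.5, 0, 0), c(9, 0, 0), c(10, 0.8, 0)),
                2, pose, `+`)
    xyz <- rbind(ring, rib, ho2, tp)
    atoms <- data.frame(
      name = c("N1", "C2", "N3", "C4", "C5", "C6",
               "C1'", "C2'", "C3'", "O2'", "HO2",
               "PA", "PB", "PG", "O3G"),
      element = c("N", "C", "N", "C", "C", "C", "C", "C", "C", "O", "H",
                  "P", "P", "P", "O"),
      charge = c(rep(0, 11), -1, -1, -1, 0),
      body = c(rep("purine", 6), rep("ribose", 5), rep("triphosphate", 4)),
      res_name = "ATP", role = "ligand", stringsAsFactors = FALSE)
    donors <- data.frame(d = 10, h = 11)
    acceptors <- c(1, 3, 15)
    rings <- list(purine = 1:6)
  } else if (kind == "ltx_like") {
    glu <- sweep(rbind(c(0, 0, 0), c(1.4, 0.5, 0), c(2.3, -0.6, 0),
                       c(1.2, 1.9, 0)), 2, pose, `+`)
    hn <- glu[1, ] + c(-0.9, 0.5, 0)
    tail <- sweep(cbind(3 + 1.3 * (1:6), rep(-1.2, 6), rep(0, 6)), 2, pose, `+`)
    acid <- sweep(rbind(c(11.5, -1.2, 0), c(12.5, -0.5, 0)), 2, pose, `+`)
    xyz <- rbind(glu, hn, tail, acid)
    atoms <- data.frame(
      name = c("N", "CA", "SG", "O", "HN", paste0("C", 1:6), "C7", "OXT"),
      element = c("N", "C", "S", "O", "H", rep("C", 7), "O"),
      charge = c(rep(0, 12), -1),
      body = c(rep("glutathione", 5), rep("tail", 6), rep("acid", 2)),
      res_name = "LTX", role = "ligand", stringsAsFactors = FALSE)
    donors <- data.frame(d = 1, h = 5)
    acceptors <- c(4, 14)
    rings <- list()
  } else {
    ang <- 2 * pi * (0:4) / 5
    ring <- cbind(pose[1] + 1.2 * cos(ang), pose[2] + 1.2 * sin(ang),
                  pose[3] - 3)
    xyz <- rbind(pose + c(0, 0, 0), pose + c(0.7, 0, 0.7), ring,
                 pose + c(0, 0, -6))
    atoms <- data.frame(
      name = c("O3", "HO3", paste0("R", 1:5), "C17"),
      element = c("O", "H", rep("C", 6)),
      charge = 0,
      body = "sterol",
      res_name = "CHL", role = "sterol", stringsAsFactors = FALSE)
    donors <- data.frame(d = 1, h = 2)
    acceptors <- 1
    rings <- list(sterol = 3:7)
  }
  et <- element_table()
  atoms$mass <- et$mass[match(atoms$element, et$element)]
  atoms$vdw_radius <- et$vdw_radius[match(atoms$element, et$element)]
  atoms$eps <- ifelse(atoms$element == "H", 0, 0.1)
  atoms$sigma <- ifelse(atoms$element == "H", 1, 3)
  atoms$res_id <- 1L
  atoms$seg_name <- atoms$res_name
  atoms$atom_id <- seq_len(nrow(atoms))
  list(atoms = atoms, coords = xyz, donors = donors, acceptors = acceptors,
       rings = rings)
}

#' Merge systems into one topology and frame
#'
#' Re-indexes atom and residue ids so that independently built parts
#' (transporter, membrane, ligands) can be analysed as one system.
#'
#' @param ... parts, each a list with `topology` (or `atoms`) and `coords`.
#' @return list with `topology`, `coords` and `offsets` (per-part first
#'   atom/residue id).
#' @export
merge_systems <- function(...) {
  parts <- list(...)
  rows <- list(); coords <- list()
  atom_off <- 0L; res_off <- 0L
  offsets <- data.frame(part = seq_along(parts), first_atom = NA_integer_,
                        first_res = NA_integer_)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    a <- if (!is.null(p$topology)) p$topology$atoms else p$atoms
    a$atom_id <- a$atom_id + atom_off
    a$res_id <- a$res_id + res_off
    offsets$first_atom[k] <- atom_off + 1L
    offsets$first_res[k] <- res_off + 1L
    atom_off <- max(a$atom_id); res_off <- max(a$res_id)
    rows[[k]] <- a
    coords[[k]] <- p$coords
  }
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(a) {
    for (cc in setdiff(cols, names(a))) a[[cc]] <- NA
    a[, cols]
  })
  list(topology = new_topology(do.call(rbind, rows)),
       coords = do.call(rbind, coords), offsets = offsets)
}
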