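# ABC conformational descriptors.
#
# Definitions follow the standard ABC structural parameters: the IC angle
# measures the intracellular opening between the two transmembrane
# half-groups seen from the extracellular region's centre of mass; the EC
# angle measures the extracellular opening seen from the NBD pair; the NBD
# distance/twist describe the nucleotide-binding-domain dimer geometry
# (twist as a signed dihedral over lobe COMs about the NBD1->NBD2 axis).

#' Centre of mass of an atom set
#'
#' @param frame N x 3 coordinate matrix.
#' @param idx atom indices.
#' @param masses per-atom masses (full length N or length of `idx`); when
#'   `NULL` or `mass_weighted = FALSE` the unweighted mean is returned.
#' @param mass_weighted use masses.
#' @return length-3 point, Angstrom.
#' @export
center_of_mass <- function(frame, idx, masses = NULL, mass_weighted = TRUE) {
  if (!length(idx)) stop("argument error: empty atom set")
  x <- frame[idx, , drop = FALSE]
  if (!mass_weighted || is.null(masses)) return(colMeans(x))
  m <- if (length(masses) == nrow(frame)) masses[idx] else masses
  colSums(x * m) / sum(m)
}

group_com <- function(frame, top, scheme, name, mass_weighted = TRUE,
                      atoms = "all") {
  idx <- atom_indices(top, scheme_group(scheme, name), atoms = atoms)
  if (!length(idx)) stop("scheme group '", name, "' selects no atoms")
  center_of_mass(frame, idx, masses = top$atoms$mass,
                 mass_weighted = mass_weighted)
}

#' Intracellular opening angle
#'
#' Angle between the vectors from the COM of the whole extracellular
#' region to the COMs of the two intracellular TMH half-groups
#' (TMH1,2,3,6,10,11 vs TMH4,5,7,8,9,12).
#'
#' @param frame N x 3 coordinates.
#' @param top an `abc_topology`.
#' @param scheme an `abc_scheme` providing `ec_whole`, `ic_half_a`,
#'   `ic_half_b`.
#' @param mass_weighted COMs mass-weighted (default) or geometric.
#' @return angle in degrees.
#' @export
ic_angle <- function(frame, top, scheme, mass_weighted = TRUE) {
  e <- group_com(frame, top, scheme, "ec_whole", mass_weighted)
  a <- group_com(frame, top, scheme, "ic_half_a", mass_weighted)
  b <- group_com(frame, top, scheme, "ic_half_b", mass_weighted)
  angle_between(a - e, b - e)
}

#' Extracellular opening angle and EC distance
#'
#' Angle between vectors from the COM of both NBDs to the COMs of the two
#' extracellular TMH half-groups (TMH1,2,9,10,11,12 vs TMH3,4,5,6,7,8);
#' the EC distance is the distance between those two half-group COMs.
#'
#' @inheritParams ic_angle
#' @return list with `angle` (degrees) and `distance` (Angstrom).
#' @export
ec_angle_and_distance <- function(frame, top, scheme, mass_weighted = TRUE) {
  n <- group_com(frame, top, scheme, "nbd_both", mass_weighted)
  a <- group_com(frame, top, scheme, "ec_half_a", mass_weighted)
  b <- group_com(frame, top, scheme, "ec_half_b", mass_weighted)
  list(angle = angle_between(a - n, b - n), distance = vec_norm(a - b))
}

#' NBD distance and rocking-twist
#'
#' Distance between the two NBD centres of mass, and the signed dihedral
#' COM(nbd1_lobe)-COM(nbd1)-COM(nbd2)-COM(nbd2_lobe) describing the
#' relative rotation of the NBDs about their connecting axis.
#'
#' @inheritParams ic_angle
#' @return list with `distance` (Angstrom) and `twist` (degrees in
#'   `(-180, 180]`).
#' @export
nbd_distance_and_twist <- function(frame, top, scheme, mass_weighted = TRUE) {
  c1 <- group_com(frame, top, scheme, "nbd1", mass_weighted)
  c2 <- group_com(frame, top, scheme, "nbd2", mass_weighted)
  l1 <- group_com(frame, top, scheme, "nbd1_lobe", mass_weighted)
  l2 <- group_com(frame, top, scheme, "nbd2_lobe", mass_weighted)
  list(distance = vec_norm(c2 - c1),
       twist = dihedral_angle(l1, c1, c2, l2))
}

#' Walker-A glycine / ABC-signature serine distances
#'
#' C-alpha to C-alpha distances of the two composite nucleotide-binding
#' sites' anchor pairs, under the minimal-image convention.
#'
#' @inheritParams ic_angle
#' @param box orthorhombic box for minimal image, or `NULL`.
#' @return named numeric: `d_gs_nbs1`, `d_gs_nbs2` (Angstrom).
#' @export
nbs_gs_distances <- function(frame, top, scheme, box = NULL) {
  one <- function(group) {
    res <- scheme_group(scheme, group)
    if (length(res) != 2) stop("group '", group, "' must name two residues")
    ca <- vapply(res, function(r) {
      idx <- atom_indices(top, r, atoms = "ca")
      if (!length(idx))
        stop("topology error: residue ", r, " has no CA atom")
      idx[1]
    }, integer(1))
    vec_norm(min_image(frame[ca[1], ] - frame[ca[2], ], box))
  }
  c(d_gs_nbs1 = one("nbs1_gs"), d_gs_nbs2 = one("nbs2_gs"))
}

#' Helix tilt angle against a reference normal
#'
#' Principal axis of the helix C-alpha cloud (largest-variance
#' eigenvector), oriented IC->EC by the first-to-last C-alpha vector, then
#' folded into `[0, 90]` degrees against the normal.
#'
#' @param frame N x 3 coordinates.
#' @param top an `abc_topology`.
#' @param res_ids residues of the helix (>= 4 C-alpha atoms).
#' @param normal reference bilayer normal (default +z).
#' @return tilt in degrees in `[0, 90]`.
#' @export
helix_tilt <- function(frame, top, res_ids, normal = c(0, 0, 1)) {
  idx <- atom_indices(top, res_ids, atoms = "ca")
  if (length(idx) < 4) stop("helix needs >= 4 CA atoms")
  x <- frame[idx, , drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  if (ev$values[1] < 1e-10) stop("degenerate helix: coincident CA atoms")
  axis <- ev$vectors[, 1]
  if (sum(axis * (x[nrow(x), ] - x[1, ])) < 0) axis <- -axis
  ang <- angle_between(axis, normal)
  if (ang > 90) ang <- 180 - ang
  ang
}

#' Rigid superposition and RMSD
#'
#' Kabsch least-squares fit of `mobile` onto `ref` over `fit_idx`
#' (proper rotation enforced), returning the RMSD after the fit.
#'
#' @param mobile,ref N x 3 coordinate matrices.
#' @param fit_idx atoms used for fitting and RMSD (default all).
#' @return list with `R`, `t`, `rmsd` and superposed `coords`.
#' @export
superpose_and_rmsd <- function(mobile, ref, fit_idx = NULL) {
  superpose_kabsch(mobile, ref, fit_idx)
}

#' Root-mean-square fluctuations
#'
#' Each frame is superposed (single pass) onto the trajectory-average
#' structure using the alignment set, then
#' RMSF_i = sqrt(mean |r_i - <r_i>|^2) per atom.
#'
#' @param traj an `abc_trajectory` (>= 2 frames).
#' @param atom_idx atoms to report (default all).
#' @param align_idx atoms used for the superposition (default `atom_idx`).
#' @return numeric RMSF per atom, Angstrom.
#' @export
rmsf <- function(traj, atom_idx = NULL, align_idx = NULL) {
  if (traj$n_frames < 2) stop("rmsf needs >= 2 frames")
  if (is.null(atom_idx)) atom_idx <- seq_len(traj$n_atoms)
  if (is.null(align_idx)) align_idx <- atom_idx
  avg <- apply(traj$coords, c(1, 2), mean)
  fitted <- array(0, c(length(atom_idx), 3, traj$n_frames))
  for (f in seq_len(traj$n_frames)) {
    fit <- superpose_kabsch(get_frame(traj, f), avg, align_idx)
    fitted[, , f] <- fit$coords[atom_idx, , drop = FALSE]
  }
  mu <- apply(fitted, c(1, 2), mean)
  dev2 <- sweep(fitted, c(1, 2), mu)^2
  sqrt(apply(dev2, 1, mean) * 3)
}

#' Principal component analysis of the ABC core
#'
#' PCA of the Cartesian covariance of the ABC core (backbone atoms of
#' TMH1-12, NBD1 and NBD2), after superposing every frame on the core's
#' trajectory average. Reports explained-variance fractions and the
#' per-domain share of each component (squared loadings summed over TMD1 =
#' TMH1-6, TMD2 = TMH7-12, NBD1, NBD2).
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param scheme an `abc_scheme` with `tmh<k>` and `nbd1`/`nbd2` groups.
#' @param n_components components to report.
#' @param atoms atom selection within core residues (default backbone).
#' @param align superpose every frame on the core average first (set
#'   `FALSE` for frames already aligned).
#' @return list of class `abc_pca`: `explained` (fractions), `loadings`,
#'   `domain_contrib` (components x domains matrix, rows sum to 1),
#'   `atom_idx`.
#' @export
pca_abc_core <- function(traj, top, scheme, n_components = 5,
                         atoms = "backbone", align = TRUE) {
  tmh <- lapply(1:12, function(h) scheme_group(scheme, paste0("tmh", h)))
  dom_res <- list(TMD1 = sort(unlist(tmh[1:6])),
                  TMD2 = sort(unlist(tmh[7:12])),
                  NBD1 = scheme_group(scheme, "nbd1"),
                  NBD2 = scheme_group(scheme, "nbd2"))
  core_res <- sort(unique(unlist(dom_res)))
  idx <- atom_indices(top, core_res, atoms = atoms)
  avg <- apply(traj$coords[idx, , , drop = FALSE], c(1, 2), mean)
  mat <- matrix(0, traj$n_frames, 3 * length(idx))
  for (f in seq_len(traj$n_frames)) {
    x <- get_frame(traj, f)[idx, , drop = FALSE]
    if (align) x <- superpose_kabsch(x, avg)$coords
    mat[f, ] <- as.vector(t(x))
  }
  pc <- stats::prcomp(mat, center = TRUE)
  lambda <- pc$sdev^2
  rank_ <- sum(lambda > 1e-12 * lambda[1])
  if (n_components > rank_) {
    warning("n_components exceeds rank (", rank_, "); truncated")
    n_components <- rank_
  }
  explained <- lambda / sum(lambda)
  atom_dom <- rep(NA_character_, length(idx))
  res_of <- top$atoms$res_id[idx]
  for (dn in names(dom_res)) atom_dom[res_of %in% dom_res[[dn]]] <- dn
  contrib <- matrix(0, n_components, length(dom_res),
                    dimnames = list(paste0("PC", seq_len(n_components)),
                                    names(dom_res)))
  for (k in seq_len(n_components)) {
    w2 <- pc$rotation[, k]^2
    per_atom <- colSums(matrix(w2, nrow = 3))
    for (dn in names(dom_res))
      contrib[k, dn] <- sum(per_atom[atom_dom == dn])
    contrib[k, ] <- contrib[k, ] / sum(contrib[k, ])
  }
  structure(list(explained = explained[seq_len(n_components)],
                 explained_all = explained,
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 domain_contrib = contrib, atom_idx = idx),
            class = "abc_pca")
}

#' Per-frame descriptor series
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param scheme an `abc_scheme`.
#' @param replica replica label stored with the series.
#' @param gs include Walker-A/signature distances (needs `nbs1_gs`,
#'   `nbs2_gs` groups).
#' @return data.frame with one row per frame: `frame`, `time_ps`,
#'   `ic_angle`, `ec_angle`, `ec_distance`, `nbd_distance`, `nbd_twist`
#'   and optionally `d_gs_nbs1`, `d_gs_nbs2`.
#' @export
descriptor_series <- function(traj, top, scheme, replica = 1L, gs = TRUE) {
  nf <- traj$n_frames
  out <- data.frame(replica = replica, frame = seq_len(nf),
                    time_ps = (seq_len(nf) - 1) * traj$frame_time,
                    ic_angle = NA_real_, ec_angle = NA_real_,
                    ec_distance = NA_real_, nbd_distance = NA_real_,
                    nbd_twist = NA_real_)
  if (gs) { out$d_gs_nbs1 <- NA_real_; out$d_gs_nbs2 <- NA_real_ }
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    out$ic_angle[f] <- ic_angle(fr, top, scheme)
    ec <- ec_angle_and_distance(fr, top, scheme)
    out$ec_angle[f] <- ec$angle; out$ec_distance[f] <- ec$distance
    nb <- nbd_distance_and_twist(fr, top, scheme)
    out$nbd_distance[f] <- nb$distance; out$nbd_twist[f] <- nb$twist
    if (gs) {
      d <- nbs_gs_distances(fr, top, scheme, box = frame_box(traj, f))
      out$d_gs_nbs1[f] <- d[1]; out$d_gs_nbs2[f] <- d[2]
    }
  }
  out
}

#' Project structures and trajectories into the ABC descriptor space
#'
#' Computes the descriptor vector (IC angle, EC angle, NBD distance, NBD
#' twist) for each labelled reference structure and, optionally, for every
#' frame of a trajectory, returning one table for joint plotting.
#'
#' @param structures list of entries `list(label =, class =, frame =,
#'   topology =, scheme =)`; entries without a scheme are skipped with a
#'   warning.
#' @param traj optional `abc_trajectory` projected alongside.
#' @param top,scheme topology and scheme for `traj`.
#' @param traj_label label for trajectory rows.
#' @return data.frame with columns `label`, `class`, `ic_angle`,
#'   `ec_angle`, `nbd_distance`, `nbd_twist`.
#' @export
project_reference_space <- function(structures = list(), traj = NULL,
                                    top = NULL, scheme = NULL,
                                    traj_label = "trajectory") {
  rows <- list()
  for (s in structures) {
    if (is.null(s$scheme)) {
      warning("structure '", s$label, "' has no scheme; skipped")
      next
    }
    ec <- ec_angle_and_distance(s$frame, s$topology, s$scheme)
    nb <- nbd_distance_and_twist(s$frame, s$topology, s$scheme)
    rows[[length(rows) + 1]] <- data.frame(
      label = s$label, class = if (is.null(s$class)) NA else s$class,
      ic_angle = ic_angle(s$frame, s$topology, s$scheme),
      ec_angle = ec$angle, nbd_distance = nb$distance,
      nbd_twist = nb$twist, stringsAsFactors = FALSE)
  }
  if (!is.null(traj)) {
    ds <- descriptor_series(traj, top, scheme, gs = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      label = traj_label, class = "trajectory",
      ic_angle = ds$ic_angle, ec_angle = ds$ec_angle,
      nbd_distance = ds$nbd_distance, nbd_twist = ds$nbd_twist,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(label = character(), class = character(),
                      ic_angle = numeric(), ec_angle = numeric(),
                      nbd_distance = numeric(), nbd_twist = numeric()))
  do.call(rbind, rows)
}
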