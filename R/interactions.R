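# Hydrogen bonds, ligand-site non-bonded potentials and pi-stacking.

#' Detect hydrogen bonds along a trajectory
#'
#' A bond is present in a frame iff the heavy-donor to acceptor distance
#' is at most `d_cut` AND the donor-H...acceptor angle (vertex at the
#' hydrogen) is at least `a_cut`. Fractions are reported per
#' donor/acceptor pair over frames; replicas should be analysed
#' independently and combined with [aggregate_replicas()].
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param donors data.frame with columns `d` (heavy donor atom id) and
#'   `h` (its hydrogen atom id); donors without hydrogens are skipped
#'   with a message.
#' @param acceptors acceptor atom ids.
#' @param d_cut distance cutoff, Angstrom.
#' @param a_cut minimum angle, degrees.
#' @param replica replica label.
#' @return data.frame with `donor`, `h`, `acceptor`, `fraction`,
#'   `replica` (pairs with zero fraction included).
#' @export
detect_hbonds <- function(traj, top, donors, acceptors, d_cut = 3.5,
                          a_cut = 120, replica = 1L) {
  keep <- !is.na(donors$h)
  if (any(!keep)) message(sum(!keep), " donor(s) without hydrogen skipped")
  donors <- donors[keep, , drop = FALSE]
  pairs <- expand.grid(di = seq_len(nrow(donors)), a = acceptors)
  pairs <- pairs[donors$d[pairs$di] != pairs$a, , drop = FALSE]
  cnt <- numeric(nrow(pairs))
  for (f in seq_len(traj$n_frames)) {
    fr <- get_frame(traj, f)
    bx <- frame_box(traj, f)
    for (p in seq_len(nrow(pairs))) {
      d_at <- donors$d[pairs$di[p]]; h_at <- donors$h[pairs$di[p]]
      a_at <- pairs$a[p]
      dv <- min_image(fr[a_at, ] - fr[d_at, ], bx)
      if (vec_norm(dv) > d_cut) next
      v1 <- min_image(fr[d_at, ] - fr[h_at, ], bx)
      v2 <- min_image(fr[a_at, ] - fr[h_at, ], bx)
      if (angle_between(v1, v2) >= a_cut) cnt[p] <- cnt[p] + 1
    }
  }
  data.frame(donor = donors$d[pairs$di], h = donors$h[pairs$di],
             acceptor = pairs$a, fraction = cnt / traj$n_frames,
             replica = replica)
}

#' Single-configuration H-bond decision
#'
#' @param d_a heavy-donor to acceptor distance, Angstrom.
#' @param angle donor-H...acceptor angle at the hydrogen, degrees.
#' @param d_cut,a_cut cutoffs.
#' @return logical.
#' @export
hbond_present <- function(d_a, angle, d_cut = 3.5, a_cut = 120) {
  d_a <= d_cut & angle >= a_cut
}

#' Derive donor-hydrogen pairs and acceptors from geometry
#'
#' Pairs every hydrogen with the nearest heavy atom of the same residue
#' within 1.2 Angstrom; acceptors are all N/O heavy atoms.
#'
#' @param top an `abc_topology`.
#' @param frame N x 3 coordinates.
#' @return list with `donors` (data.frame d, h) and `acceptors`.
#' @export
find_hbond_candidates <- function(top, frame) {
  a <- top$atoms
  hs <- which(a$element == "H")
  d <- integer(0); h <- integer(0)
  for (hi in hs) {
    cand <- which(a$res_id == a$res_id[hi] & a$element != "H")
    if (!length(cand)) next
    dist <- sqrt(rowSums(sweep(frame[cand, , drop = FALSE], 2,
                               frame[hi, ])^2))
    if (min(dist) <= 1.2) { d <- c(d, cand[which.min(dist)]); h <- c(h, hi) }
  }
  list(donors = data.frame(d = d, h = h),
       acceptors = which(a$element %in% c("N", "O")))
}

#' Coulomb and Lennard-Jones interaction energy series
#'
#' Per frame, sums over inter-selection atom pairs within the cutoff
#' (minimal image, plain truncation):
#' Coulomb k_e q_i q_j / (eps_r r_ij) with k_e = 332.06
#' kcal mol^-1 Angstrom e^-2, and LJ 4 eps_ij ((sigma/r)^12 - (sigma/r)^6)
#' under Lorentz-Berthelot combination of per-atom `eps`/`sigma`.
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology` with `charge` and (for LJ) `eps`, `sigma`.
#' @param sel_a,sel_b disjoint atom-index selections.
#' @param dielectric relative dielectric eps_r.
#' @param cutoff pair cutoff, Angstrom.
#' @return data.frame with `frame`, `coulomb`, `vdw` (kcal/mol) plus
#'   attributes `mean_coulomb`, `mean_vdw`.
#' @export
interaction_energy <- function(traj, top, sel_a, sel_b, dielectric = 1,
                               cutoff = 10) {
  a <- top$atoms
  if (length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint")
  need <- c(sel_a, sel_b)
  bad <- need[is.na(a$eps[need]) | is.na(a$sigma[need])]
  if (length(bad))
    stop("missing LJ parameters for atoms: ", paste(bad, collapse = ", "))
  ke <- 332.06
  qa <- a$charge[sel_a]; qb <- a$charge[sel_b]
  ea <- a$eps[sel_a]; eb <- a$eps[sel_b]
  sa <- a$sigma[sel_a]; sb <- a$sigma[sel_b]
  eij <- sqrt(outer(ea, eb))
  sij <- outer(sa, sb, `+`) / 2
  qq <- outer(qa, qb)
  out <- data.frame(frame = seq_len(traj$n_frames), coulomb = 0, vdw = 0)
  for (f in seq_len(traj$n_frames)) {
    fr <- get_frame(traj, f)
    bx <- frame_box(traj, f)
    r <- matrix(0, length(sel_a), length(sel_b))
    for (j in seq_along(sel_b)) {
      dv <- sweep(fr[sel_a, , drop = FALSE], 2, fr[sel_b[j], ])
      dv <- min_image(dv, bx)
      r[, j] <- sqrt(rowSums(dv^2))
    }
    ok <- r <= cutoff & r > 1e-9
    out$coulomb[f] <- sum(ke * qq[ok] / (dielectric * r[ok]))
    sr6 <- (sij[ok] / r[ok])^6
    out$vdw[f] <- sum(4 * eij[ok] * (sr6^2 - sr6))
  }
  attr(out, "mean_coulomb") <- mean(out$coulomb)
  attr(out, "mean_vdw") <- mean(out$vdw)
  out
}

#' Ring-centroid (pi-stacking) distance series
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param ring_a,ring_b atom indices of the two rings (>= 5 heavy atoms
#'   each).
#' @return data.frame with `frame`, `distance` plus attributes `mean`,
#'   `sd`.
#' @export
pi_stacking <- function(traj, top, ring_a, ring_b) {
  a <- top$atoms
  ring_a <- ring_a[a$element[ring_a] != "H"]
  ring_b <- ring_b[a$element[ring_b] != "H"]
  if (length(ring_a) < 5 || length(ring_b) < 5)
    stop("ring atoms missing: each ring needs >= 5 heavy atoms")
  out <- data.frame(frame = seq_len(traj$n_frames), distance = NA_real_)
  for (f in seq_len(traj$n_frames)) {
    fr <- get_frame(traj, f)
    out$distance[f] <- vec_norm(colMeans(fr[ring_a, , drop = FALSE]) -
                                colMeans(fr[ring_b, , drop = FALSE]))
  }
  attr(out, "mean") <- mean(out$distance)
  attr(out, "sd") <- stats::sd(out$distance)
  out
}
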