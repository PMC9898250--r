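# Synthetic pseudo-transporters and trajectories with known ground truth.
#
# These generators place centre-of-mass targets analytically so that the
# descriptor layer must recover prescribed IC/EC angles, NBD distance and
# NBD rocking-twist exactly in the noise-free limit. Pseudo-atoms carry a
# uniform mass of 12 amu so mass-weighted and geometric COMs coincide,
# isolating descriptor math from mass bookkeeping.

#' Specification for a synthetic pseudo-transporter
#'
#' @param ic_angle target intracellular opening angle, degrees in `[0, 180)`.
#' @param ec_angle target extracellular opening angle, degrees in `[0, 180)`.
#' @param nbd_distance target distance between the two NBD centres of mass,
#'   Angstrom.
#' @param nbd_twist target NBD rocking-twist (signed dihedral), degrees in
#'   `(-180, 180]`.
#' @param helix_len residues per transmembrane helix (even, >= 8).
#' @param noise_sigma isotropic Gaussian positional noise added to the
#'   built frame, Angstrom (0 = exact geometry).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @param box orthorhombic box lengths, Angstrom.
#' @return list of class `transporter_spec`.
#' @export
transporter_spec <- function(ic_angle = 30, ec_angle = 10, nbd_distance = 40,
                             nbd_twist = 60, helix_len = 24,
                             noise_sigma = 0, seed = 1,
                             box = c(150, 150, 200)) {
  if (ic_angle < 0 || ic_angle >= 180 || ec_angle < 0 || ec_angle >= 180)
    stop("angles must lie in [0, 180)")
  if (nbd_distance <= 0) stop("nbd_distance must be positive")
  if (nbd_twist <= -180 || nbd_twist > 180)
    stop("nbd_twist must lie in (-180, 180]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (helix_len < 8 || helix_len %% 2 != 0)
    stop("helix_len must be an even integer >= 8")
  structure(list(ic_angle = ic_angle, ec_angle = ec_angle,
                 nbd_distance = nbd_distance, nbd_twist = nbd_twist,
                 helix_len = helix_len, noise_sigma = noise_sigma,
                 seed = seed, box = box),
            class = "transporter_spec")
}

#' Ideal alpha-helix backbone
#'
#' Pseudo-C-alpha trace with 1.5 Angstrom rise and 100 degrees twist per
#' residue on a 2.3 Angstrom radius, plus two backbone dummy atoms per
#' residue placed symmetrically along the axis (so each residue's centroid
#' is its C-alpha position).
#'
#' @param n_res number of residues (>= 4).
#' @param origin helix start, length-3.
#' @param axis helix axis direction (any non-zero vector).
#' @param seed unused; accepted for generator API uniformity.
#' @param rise,twist_deg,radius helix geometry parameters.
#' @param dummies include the two backbone dummy atoms per residue.
#' @return list with `ca` (n x 3 C-alpha coordinates), `coords` (all atoms),
#'   `names` (atom names) and `res_local` (1-based residue index per atom).
#' @export
make_helix <- function(n_res, origin = c(0, 0, 0), axis = c(0, 0, 1),
                       seed = NULL, rise = 1.5, twist_deg = 100,
                       radius = 2.3, dummies = TRUE) {
  if (n_res < 4) stop("n_res must be >= 4")
  u <- unit_vec(axis)  # errors on zero axis
  k <- 0:(n_res - 1)
  phi <- twist_deg * pi / 180 * k
  local <- cbind(radius * cos(phi), radius * sin(phi), rise * k)
  rot <- rotation_from_to(c(0, 0, 1), u)
  ca <- local %*% t(rot)
  ca <- sweep(ca, 2, origin, `+`)
  if (!dummies) {
    return(list(ca = ca, coords = ca, names = rep("CA", n_res),
                res_local = seq_len(n_res)))
  }
  n <- nrow(ca)
  coords <- matrix(0, 3 * n, 3)
  nm <- character(3 * n); rl <- integer(3 * n)
  for (i in seq_len(n)) {
    r0 <- (i - 1) * 3
    coords[r0 + 1, ] <- ca[i, ]
    coords[r0 + 2, ] <- ca[i, ] - 0.6 * u
    coords[r0 + 3, ] <- ca[i, ] + 0.6 * u
    nm[r0 + (1:3)] <- c("CA", "N", "C")
    rl[r0 + (1:3)] <- i
  }
  list(ca = ca, coords = coords, names = nm, res_local = rl)
}

# hexagon offsets (xy plane) summing exactly to zero -- used to spread six
# helices of a half-group around the group's COM target
hex_offsets <- function(rho = 8) {
  j <- 0:5
  cbind(rho * cos(pi * j / 3), rho * sin(pi * j / 3), 0)
}

#' Build a synthetic pseudo-transporter
#'
#' Twelve pseudo-TMHs (tagged TMH1-12 with IC and EC segments), two
#' pseudo-NBD point clouds with lobe sub-tags, Walker-A/signature anchor
#' residues, an L0-like linker and four coupling-helix stubs, placed so
#' that the descriptor layer recovers the spec's IC angle, EC angle, NBD
#' distance and NBD twist exactly (machine precision) when
#' `noise_sigma = 0`.
#'
#' @param spec a [transporter_spec()].
#' @return list with `topology`, `coords` (the built frame), `scheme`
#'   (matching `abc_scheme`), and `measured` (descriptor values of the
#'   noise-free frame).
#' @export
make_transporter <- function(spec = transporter_spec()) {
  stopifnot(inherits(spec, "transporter_spec"))
  z_ec <- 20; z_ic <- -20; z_nbd <- -45
  i_off <- (z_ec - z_ic) * tan(spec$ic_angle / 2 * pi / 180)
  e_off <- (z_ec - z_nbd) * tan(spec$ec_angle / 2 * pi / 180)
  d <- spec$nbd_distance
  if (2 * i_off + 20 > spec$box[1] || 2 * e_off + 20 > spec$box[1] ||
      d + 30 > spec$box[1])
    stop("construction error: target geometry does not fit the box")

  ic_targets <- matrix(0, 12, 3); ec_targets <- matrix(0, 12, 3)
  hx <- hex_offsets(8)
  for (j in 1:6) {
    ic_targets[IC_HALF_A[j], ] <- c(-i_off, 0, z_ic) + hx[j, ]
    ic_targets[IC_HALF_B[j], ] <- c(+i_off, 0, z_ic) + hx[j, ]
    ec_targets[EC_HALF_A[j], ] <- c(-e_off, 0, z_ec) + hx[j, ]
    ec_targets[EC_HALF_B[j], ] <- c(+e_off, 0, z_ec) + hx[j, ]
  }

  rows <- list(); coords <- list()
  res_counter <- 0L
  groups <- list()
  n2 <- spec$helix_len / 2

  add_segment <- function(helix, center, seg, role, resname) {
    # translate so the centroid of all atoms lands exactly on `center`
    shift <- center - colMeans(helix$coords)
    xyz <- sweep(helix$coords, 2, shift, `+`)
    ids <- res_counter + helix$res_local
    res_counter <<- res_counter + max(helix$res_local)
    rows[[length(rows) + 1]] <<- data.frame(
      name = helix$names, element = "C", mass = 12, charge = 0,
      vdw_radius = 1.7, res_id = ids, res_name = resname,
      seg_name = seg, role = role, stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- xyz
    unique(ids)
  }

  for (h in 1:12) {
    u <- unit_vec(ec_targets[h, ] - ic_targets[h, ])
    seg <- paste0("TMH", h)
    ric <- add_segment(make_helix(n2, axis = u), ic_targets[h, ],
                       seg, "tmh", "ALA")
    rec <- add_segment(make_helix(n2, axis = u), ec_targets[h, ],
                       seg, "tmh", "ALA")
    groups[[paste0("tmh", h, "_ic")]] <- ric
    groups[[paste0("tmh", h, "_ec")]] <- rec
    groups[[paste0("tmh", h)]] <- c(ric, rec)
  }

  # NBDs: two lobes of four 2-atom residues each, atom offsets in +/- pairs
  # so lobe COM and NBD COM are exact
  c1 <- c(-d / 2, 0, z_nbd); c2 <- c(d / 2, 0, z_nbd)
  phi <- spec$nbd_twist * pi / 180
  w1 <- 6 * c(0, 1, 0)
  w2 <- 6 * c(0, cos(phi), sin(phi))
  lobe_offsets <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(1.2, 1.2, 1.2))
  add_lobe <- function(lc, seg) {
    ids <- integer(0)
    for (j in 1:4) {
      res_counter <<- res_counter + 1L
      rows[[length(rows) + 1]] <<- data.frame(
        name = c("CA", "N"), element = "C", mass = 12, charge = 0,
        vdw_radius = 1.7, res_id = res_counter, res_name = "ASP",
        seg_name = seg, role = "nbd", stringsAsFactors = FALSE)
      coords[[length(coords) + 1]] <<- rbind(lc + lobe_offsets[j, ],
                                             lc - lobe_offsets[j, ])
      ids <- c(ids, res_counter)
    }
    ids
  }
  n1a <- add_lobe(c1 + w1, "NBD1"); n1b <- add_lobe(c1 - w1, "NBD1")
  n2a <- add_lobe(c2 + w2, "NBD2"); n2b <- add_lobe(c2 - w2, "NBD2")
  groups$nbd1 <- c(n1a, n1b); groups$nbd2 <- c(n2a, n2b)
  groups$nbd1_lobe <- n1a; groups$nbd2_lobe <- n2a

  # Walker-A glycine / ABC-signature serine anchor residues (single CA),
  # kept outside the nbd groups so NBD COMs stay exact
  add_anchor <- function(pos, resname) {
    res_counter <<- res_counter + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      name = "CA", element = "C", mass = 12, charge = 0, vdw_radius = 1.7,
      res_id = res_counter, res_name = resname, seg_name = "NBS",
      role = "anchor", stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- matrix(pos, 1, 3)
    res_counter
  }
  gly1 <- add_anchor(c1 + c(0, 2, 4), "GLY")
  ser2 <- add_anchor(c2 + c(0, 2, 4), "SER")
  ser1 <- add_anchor(c1 + c(0, -2, 4), "SER")
  gly2 <- add_anchor(c2 + c(0, -2, 4), "GLY")
  groups$nbs1_gs <- c(gly1, ser2)
  groups$nbs2_gs <- c(ser1, gly2)
  groups$nbs1_residues <- c(gly1, ser2, n1a[1], n2a[1])
  groups$nbs2_residues <- c(ser1, gly2, n1b[1], n2b[1])

  groups$l0 <- add_segment(make_helix(6, axis = c(1, 0, 0)),
                           c(0, 18, -28), "L0", "l0", "ALA")
  ch_pos <- rbind(c(14, 14, -30), c(-14, 14, -30),
                  c(14, -14, -30), c(-14, -14, -30))
  ch_names <- c("ch_2_3", "ch_4_5", "ch_8_9", "ch_10_11")
  ch_segs <- c("CH23", "CH45", "CH89", "CH1011")
  for (k in 1:4)
    groups[[ch_names[k]]] <- add_segment(make_helix(4, axis = c(0, 1, 0)),
                                         ch_pos[k, ], ch_segs[k], "ch", "ALA")

  # substrate-binding pocket: EC-ward residues of three IC half-segments
  pocket <- c(tail(groups$tmh6_ic, 2), tail(groups$tmh7_ic, 2),
              tail(groups$tmh11_ic, 2))
  groups$binding_pocket_residues <- sort(pocket)

  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  top <- new_topology(atoms)
  xyz <- do.call(rbind, coords)

  scheme <- structure(derive_composite_groups(groups), class = "abc_scheme")
  validate_scheme(scheme, top)

  measured <- list(
    ic_angle = ic_angle(xyz, top, scheme),
    ec = ec_angle_and_distance(xyz, top, scheme),
    nbd = nbd_distance_and_twist(xyz, top, scheme))
  measured <- list(ic_angle = measured$ic_angle,
                   ec_angle = measured$ec$angle,
                   ec_distance = measured$ec$distance,
                   nbd_distance = measured$nbd$distance,
                   nbd_twist = measured$nbd$twist)

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$noise_sigma),
                        nrow(xyz), 3)
  }
  list(topology = top, coords = xyz, scheme = scheme, spec = spec,
       measured = measured)
}

#' Draw a synthetic trajectory from a state mixture
#'
#' Frames are drawn i.i.d. from the supplied conformational states with
#' the given weights; every atom then receives isotropic Gaussian noise of
#' sd `noise_sigma`. Atom sets listed in `correlated_modes` instead receive
#' a shared latent Gaussian displacement constructed so the Pearson
#' correlation of their per-frame fluctuations equals `rho` in expectation
#' (negative `rho` anti-correlates the pair).
#'
#' @param states list of N x 3 coordinate matrices (one per state).
#' @param n_frames number of frames to draw.
#' @param noise_sigma per-atom isotropic displacement sd, Angstrom.
#' @param correlated_modes list of `list(i =, j =, rho =)` with atom-index
#'   vectors `i`, `j` and target correlation `rho` in `[-1, 1]`.
#' @param seed RNG seed (all randomness is derived from it).
#' @param weights state weights (>= 0, normalised internally); default
#'   uniform.
#' @param box optional box lengths.
#' @param frame_time ps per frame.
#' @return an `abc_trajectory` with an extra element `state_id` giving the
#'   generating state of each frame.
#' @export
make_trajectory <- function(states, n_frames, noise_sigma = 0,
                            correlated_modes = NULL, seed = 1,
                            weights = NULL, box = NULL, frame_time = 100) {
  if (!is.list(states) || !length(states))
    stop("argument error: empty state list")
  if (is.null(weights)) weights <- rep(1, length(states))
  if (length(weights) != length(states) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  weights <- weights / sum(weights)
  for (m in correlated_modes)
    if (abs(m$rho) > 1) stop("|rho| must be <= 1")
  n_atoms <- nrow(states[[1]])
  set.seed(seed)
  sid <- sample.int(length(states), n_frames, replace = TRUE, prob = weights)
  s_arr <- array(unlist(states), c(n_atoms, 3, length(states)))
  coords <- s_arr[, , sid, drop = FALSE]
  if (noise_sigma > 0) {
    noise <- array(stats::rnorm(n_atoms * 3 * n_frames, sd = noise_sigma),
                   c(n_atoms, 3, n_frames))
    for (m in correlated_modes) {
      r <- abs(m$rho); sgn <- if (m$rho >= 0) 1 else -1
      z <- matrix(stats::rnorm(3 * n_frames, sd = noise_sigma), 3, n_frames)
      ei <- matrix(stats::rnorm(3 * n_frames, sd = noise_sigma), 3, n_frames)
      ej <- matrix(stats::rnorm(3 * n_frames, sd = noise_sigma), 3, n_frames)
      di <- sqrt(r) * z + sqrt(1 - r) * ei
      dj <- sgn * sqrt(r) * z + sqrt(1 - r) * ej
      for (f in seq_len(n_frames)) {
        noise[m$i, , f] <- matrix(di[, f], length(m$i), 3, byrow = TRUE)
        noise[m$j, , f] <- matrix(dj[, f], length(m$j), 3, byrow = TRUE)
      }
    }
    coords <- coords + noise
  }
  traj <- new_trajectory(coords, box = box, frame_time = frame_time)
  traj$state_id <- sid
  traj
}
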