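# Lipid-structure analyses: order parameters, 2D densities, occupancy
# hotspots, thickness fields and a simplified continuum deformation
# energy.

lipid_residues <- function(top, species) {
  r <- residues(top)
  r$res_id[r$res_name %in% species]
}

head_marker_atoms <- function(top, species = c("PCL", "PEL")) {
  a <- top$atoms
  marker <- ifelse(a$res_name == "CHL", "O3", "P")
  which(a$res_name %in% species & a$name == marker)
}

#' Lipid tail order parameters S_CD
#'
#' S_CD(k) = <(3 cos^2 theta - 1)/2> over frames, lipids and the hydrogen
#' atoms of carbon k, with theta the angle between the C-H vector and the
#' membrane normal (z). Carbons without hydrogens are skipped with a
#' message.
#'
#' @param traj an `abc_trajectory` (a single N x 3 frame is also accepted).
#' @param top an `abc_topology`.
#' @param species lipid residue name(s), e.g. `"PCL"`.
#' @param tail `"sn1"` (tail A) or `"sn2"` (tail B).
#' @return data.frame with `carbon`, `s_cd`, `n_samples`.
#' @export
order_parameters <- function(traj, top, species = "PCL",
                             tail = c("sn1", "sn2")) {
  tail <- match.arg(tail)
  suf <- if (tail == "sn1") "A" else "B"
  if (is.matrix(traj)) traj <- new_trajectory(traj)
  a <- top$atoms
  lip <- a$res_name %in% species
  carbons <- sort(unique(as.integer(sub(paste0("^C([0-9]+)", suf, "$"), "\\1",
    a$name[lip & grepl(paste0("^C[0-9]+", suf, "$"), a$name)]))))
  out <- data.frame(carbon = carbons, s_cd = NA_real_, n_samples = 0L)
  for (ci in seq_along(carbons)) {
    k <- carbons[ci]
    cidx <- which(lip & a$name == paste0("C", k, suf))
    hs <- lapply(1:2, function(hn)
      which(lip & a$name == paste0("H", k, suf, hn)))
    if (!length(cidx) || !any(lengths(hs) > 0)) {
      message("carbon ", k, " has no hydrogens; skipped")
      next
    }
    num <- 0; cnt <- 0L
    for (f in seq_len(traj$n_frames)) {
      fr <- get_frame(traj, f)
      for (h in hs) {
        if (!length(h)) next
        # hydrogens are emitted alongside their carbon per residue, so
        # matching by residue order is exact
        o <- match(a$res_id[cidx], a$res_id[h])
        v <- fr[h[o], , drop = FALSE] - fr[cidx, , drop = FALSE]
        cz <- v[, 3] / sqrt(rowSums(v^2))
        num <- num + sum((3 * cz^2 - 1) / 2)
        cnt <- cnt + length(cz)
      }
    }
    out$s_cd[ci] <- num / cnt
    out$n_samples[ci] <- cnt
  }
  out[!is.na(out$s_cd), , drop = FALSE]
}

#' Leaflet-resolved 2D lipid density
#'
#' Time-averaged xy histogram of a species' head-marker atom (phosphate
#' bead for phospholipids, hydroxyl bead for sterols), normalised per
#' Angstrom^2 per frame, so the grid integral equals the mean molecule
#' count per frame.
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param species residue name(s).
#' @param leaflet `"upper"` (marker z above the bilayer centre) or
#'   `"lower"`.
#' @param box xy box lengths; defaults to the trajectory box.
#' @param spacing grid spacing, Angstrom.
#' @param center bilayer centre z.
#' @return list with `x`, `y` (cell centres), `density` (counts/A^2/frame)
#'   and `integral`.
#' @export
density_2d <- function(traj, top, species, leaflet = c("upper", "lower"),
                       box = NULL, spacing = 2, center = NULL) {
  leaflet <- match.arg(leaflet)
  if (is.null(box)) {
    if (is.null(traj$box)) stop("box required")
    box <- traj$box[1, 1:2]
  }
  if (is.null(center)) center <- bilayer_center(get_frame(traj, 1), top)
  marker <- head_marker_atoms(top, species)
  nx <- max(2, ceiling(box[1] / spacing)); ny <- max(2, ceiling(box[2] / spacing))
  grid <- matrix(0, nx, ny)
  if (!length(marker)) {
    warning("species ", paste(species, collapse = ","), " absent; empty grid")
  } else {
    for (f in seq_len(traj$n_frames)) {
      fr <- get_frame(traj, f)
      sel <- if (leaflet == "upper") fr[marker, 3] > center else fr[marker, 3] <= center
      xy <- fr[marker[sel], 1:2, drop = FALSE]
      xy[, 1] <- xy[, 1] %% box[1]; xy[, 2] <- xy[, 2] %% box[2]
      i <- pmin(nx, 1 + floor(xy[, 1] / box[1] * nx))
      j <- pmin(ny, 1 + floor(xy[, 2] / box[2] * ny))
      for (kk in seq_along(i)) grid[i[kk], j[kk]] <- grid[i[kk], j[kk]] + 1
    }
  }
  cell <- (box[1] / nx) * (box[2] / ny)
  dens <- grid / (cell * traj$n_frames)
  list(x = (seq_len(nx) - 0.5) * box[1] / nx,
       y = (seq_len(ny) - 0.5) * box[2] / ny,
       density = dens, integral = sum(dens) * cell)
}

#' Lipid occupancy hotspots around a protein selection
#'
#' For each lipid/sterol molecule, the fraction of frames with any heavy
#' atom within `cutoff` of the protein selection; molecules are reported
#' as hotspot sites at each threshold together with the protein residues
#' they touch.
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param species residue name(s) of the lipids scored.
#' @param protein_idx atom indices of the protein selection.
#' @param cutoff heavy-atom contact cutoff, Angstrom.
#' @param thresholds occupancy thresholds reported.
#' @return data.frame with `res_id`, `species`, `fraction`,
#'   `at_50`/`at_80`-style logical columns per threshold, `residues`
#'   (touched protein residues, comma-separated).
#' @export
occupancy_hotspots <- function(traj, top, species, protein_idx,
                               cutoff = 6, thresholds = c(0.5, 0.8)) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- top$atoms
  lips <- lipid_residues(top, species)
  pro <- protein_idx[a$element[protein_idx] != "H"]
  out <- data.frame(res_id = lips,
                    species = a$res_name[match(lips, a$res_id)],
                    fraction = 0, residues = "", stringsAsFactors = FALSE)
  for (li in seq_along(lips)) {
    lidx <- which(a$res_id == lips[li] & a$element != "H")
    hit <- 0L; touched <- integer(0)
    for (f in seq_len(traj$n_frames)) {
      fr <- get_frame(traj, f)
      bx <- frame_box(traj, f)
      d <- proxy_min_dists(fr[lidx, , drop = FALSE],
                           fr[pro, , drop = FALSE], bx)
      if (any(d <= cutoff)) {
        hit <- hit + 1L
        touched <- union(touched, a$res_id[pro[d <= cutoff]])
      }
    }
    out$fraction[li] <- hit / traj$n_frames
    out$residues[li] <- paste(sort(touched), collapse = ",")
  }
  for (t in thresholds)
    out[[paste0("at_", round(100 * t))]] <- out$fraction >= t
  out[out$fraction > 0, , drop = FALSE]
}

# per-column minimum distance from set A (rows) to each atom of B
proxy_min_dists <- function(a_xyz, b_xyz, box = NULL) {
  out <- numeric(nrow(b_xyz))
  for (j in seq_len(nrow(b_xyz))) {
    d <- sweep(a_xyz, 2, b_xyz[j, ])
    d <- min_image(d, box)
    out[j] <- sqrt(min(rowSums(d^2)))
  }
  out
}

#' Membrane thickness field
#'
#' Per xy-cell distance between the mean head-marker z surfaces of the
#' two leaflets, time-averaged; cells with an empty leaflet are
#' interpolated from neighbours and flagged.
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param box xy box lengths (default: trajectory box).
#' @param spacing grid spacing, Angstrom.
#' @param center bilayer centre z.
#' @return list with `x`, `y`, `thickness` (matrix, Angstrom),
#'   `interpolated` (logical matrix) and `mean` (area-weighted scalar).
#' @export
thickness_map <- function(traj, top, box = NULL, spacing = 4, center = NULL) {
  if (is.null(box)) {
    if (is.null(traj$box)) stop("box required")
    box <- traj$box[1, 1:2]
  }
  marker <- head_marker_atoms(top, c("PCL", "PEL"))
  if (!length(marker)) stop("no phospholipid head markers")
  if (is.null(center)) center <- bilayer_center(get_frame(traj, 1), top)
  nx <- max(2, ceiling(box[1] / spacing)); ny <- max(2, ceiling(box[2] / spacing))
  zsum <- array(0, c(nx, ny, 2)); cnt <- array(0, c(nx, ny, 2))
  for (f in seq_len(traj$n_frames)) {
    fr <- get_frame(traj, f)
    z <- fr[marker, 3]
    xy <- fr[marker, 1:2, drop = FALSE]
    xy[, 1] <- xy[, 1] %% box[1]; xy[, 2] <- xy[, 2] %% box[2]
    i <- pmin(nx, 1 + floor(xy[, 1] / box[1] * nx))
    j <- pmin(ny, 1 + floor(xy[, 2] / box[2] * ny))
    lf <- ifelse(z > center, 1, 2)
    for (k in seq_along(i)) {
      zsum[i[k], j[k], lf[k]] <- zsum[i[k], j[k], lf[k]] + z[k]
      cnt[i[k], j[k], lf[k]] <- cnt[i[k], j[k], lf[k]] + 1
    }
  }
  if (all(cnt[, , 1] == 0) || all(cnt[, , 2] == 0))
    stop("a leaflet is empty")
  up <- zsum[, , 1] / cnt[, , 1]; lo <- zsum[, , 2] / cnt[, , 2]
  th <- up - lo
  bad <- !is.finite(th)
  if (any(bad)) {
    fill <- th
    for (i in which(bad)) {
      ii <- ((i - 1) %% nx) + 1; jj <- ((i - 1) %/% nx) + 1
      nb <- c()
      for (di in -1:1) for (dj in -1:1) {
        ai <- ((ii + di - 1) %% nx) + 1; aj <- ((jj + dj - 1) %% ny) + 1
        if (is.finite(th[ai, aj])) nb <- c(nb, th[ai, aj])
      }
      fill[i] <- if (length(nb)) mean(nb) else mean(th[is.finite(th)])
    }
    th <- fill
  }
  list(x = (seq_len(nx) - 0.5) * box[1] / nx,
       y = (seq_len(ny) - 0.5) * box[2] / ny,
       thickness = th, interpolated = bad, mean = mean(th))
}

#' Continuum membrane deformation free energy
#'
#' Simplified two-term elastic functional over the thickness deviation
#' u = (h - h0)/2:
#' dG = integral of (K_A/2)(2u/h0)^2 + (K_C/2)(laplacian u)^2 dA,
#' evaluated with periodic central differences; the flat reference
#' contributes zero, so a flat field gives dG = 0 and any non-flat field
#' a positive cost. Comparative (system minus reference) conventions that
#' yield negative deformation energies are left to the caller.
#'
#' @param thickness nx x ny thickness field, Angstrom (>= 4 cells/side).
#' @param h0 reference (unperturbed) thickness, Angstrom.
#' @param k_a area-compressibility modulus, energy/Angstrom^2 (default
#'   0.6 kcal mol^-1 A^-2).
#' @param k_c bending modulus, energy (default 12 kcal mol^-1).
#' @param dx,dy grid spacings, Angstrom.
#' @return list with `dG`, `compression`, `bending` (energy units).
#' @export
deformation_energy <- function(thickness, h0, k_a = 0.6, k_c = 12,
                               dx = 1, dy = 1) {
  if (nrow(thickness) < 4 || ncol(thickness) < 4)
    stop("grid too coarse: need >= 4 cells per side")
  if (k_a <= 0 || k_c <= 0) stop("moduli must be positive")
  u <- (thickness - h0) / 2
  lap <- (rbind(u[-1, ], u[1, , drop = FALSE]) +
          rbind(u[nrow(u), , drop = FALSE], u[-nrow(u), ]) - 2 * u) / dx^2 +
         (cbind(u[, -1], u[, 1, drop = FALSE]) +
          cbind(u[, ncol(u), drop = FALSE], u[, -ncol(u)]) - 2 * u) / dy^2
  da <- dx * dy
  comp <- sum((k_a / 2) * (2 * u / h0)^2) * da
  bend <- sum((k_c / 2) * lap^2) * da
  list(dG = comp + bend, compression = comp, bending = bend)
}
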