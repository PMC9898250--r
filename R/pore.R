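# Translocation-pathway radius profiles.
#
# A Hole-style re-implementation: per z-slab the largest sphere centre in
# the membrane plane maximising min_i(|c - r_i| - vdW_i) over atoms within
# a slab window, found by a deterministic multi-start pattern search
# seeded from the previous slab's centre (reproducibility preferred over
# the original simulated-annealing search).

slab_radius_fn <- function(atoms_xyz, vdw, z) {
  function(xy) {
    d <- sqrt((atoms_xyz[, 1] - xy[1])^2 + (atoms_xyz[, 2] - xy[2])^2 +
              (atoms_xyz[, 3] - z)^2)
    min(d - vdw)
  }
}

pattern_search <- function(f, start, step = 2, tol = 1e-4, max_iter = 200) {
  x <- start; fx <- f(x)
  it <- 0
  while (step > tol && it < max_iter) {
    it <- it + 1
    moved <- FALSE
    for (d in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
      cand <- x + d; fc <- f(cand)
      if (fc > fx + 1e-12) { x <- cand; fx <- fc; moved <- TRUE }
    }
    if (!moved) step <- step / 2
  }
  list(x = x, value = fx)
}

#' Pore radius profile of one frame
#'
#' @param frame N x 3 coordinates.
#' @param top an `abc_topology` supplying van der Waals radii (falling
#'   back to [element_table()] where absent).
#' @param atom_idx atoms forming the pore wall (default: all heavy atoms).
#' @param axis_point (x, y) seed for the pore axis at the first slab.
#' @param z_range z interval scanned (bilayer-centred), Angstrom.
#' @param z_step slab spacing, Angstrom.
#' @param max_radius search cap; slabs with no atoms (or radius reaching
#'   the cap) are flagged `capped`.
#' @param slab_halfwidth half-width of the atom-inclusion window per slab.
#' @return data.frame with `z`, `radius`, `x`, `y`, `capped`.
#' @export
pore_profile <- function(frame, top, atom_idx = NULL, axis_point = c(0, 0),
                         z_range = c(-30, 30), z_step = 1, max_radius = 15,
                         slab_halfwidth = 7.5) {
  if (is.null(atom_idx)) atom_idx <- which(top$atoms$element != "H")
  if (!length(atom_idx)) stop("no pore-wall atoms")
  xyz <- frame[atom_idx, , drop = FALSE]
  vdw <- top$atoms$vdw_radius[atom_idx]
  zs <- seq(z_range[1], z_range[2], by = z_step)
  out <- data.frame(z = zs, radius = NA_real_, x = NA_real_, y = NA_real_,
                    capped = FALSE)
  prev <- axis_point
  for (i in seq_along(zs)) {
    z <- zs[i]
    in_slab <- abs(xyz[, 3] - z) <= slab_halfwidth
    if (!any(in_slab)) {
      out$radius[i] <- max_radius; out$capped[i] <- TRUE
      out$x[i] <- prev[1]; out$y[i] <- prev[2]
      next
    }
    f <- slab_radius_fn(xyz[in_slab, , drop = FALSE], vdw[in_slab], z)
    starts <- rbind(prev, prev + c(3, 0), prev - c(3, 0),
                    prev + c(0, 3), prev - c(0, 3))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      res <- pattern_search(f, starts[s, ])
      if (is.null(best) || res$value > best$value) best <- res
    }
    r <- best$value
    capped <- FALSE
    if (r >= max_radius) { r <- max_radius; capped <- TRUE }
    if (r < 0) r <- 0
    out$radius[i] <- r; out$x[i] <- best$x[1]; out$y[i] <- best$x[2]
    out$capped[i] <- capped
    prev <- best$x
  }
  out
}

#' Bilayer centre from phosphate-marker density
#'
#' Midpoint between the per-leaflet mean z of head-marker atoms (`P` for
#' phospholipids); returns 0 when no markers exist.
#'
#' @param frame N x 3 coordinates.
#' @param top an `abc_topology`.
#' @return z of the bilayer centre, Angstrom.
#' @export
bilayer_center <- function(frame, top) {
  p <- which(top$atoms$name == "P" & top$atoms$role %in% c("lipid", "unassigned"))
  if (!length(p)) return(0)
  z <- frame[p, 3]
  (mean(z[z >= stats::median(z)]) + mean(z[z < stats::median(z)])) / 2
}

#' Time-resolved pore radii at fixed bilayer depths, with bootstrap errors
#'
#' Splits the trajectory into contiguous windows, evaluates the pore
#' radius at each requested depth for every snapshot in the window, and
#' reports the window mean with a bootstrap standard deviation over
#' resampled snapshots.
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param depths depths relative to the bilayer centre, Angstrom.
#' @param window frames per window (a window longer than the trajectory
#'   collapses to a single window with a warning).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap RNG seed.
#' @param center bilayer centre z (default: phosphate-density midpoint of
#'   the first frame).
#' @param ... passed to [pore_profile()].
#' @return data.frame with `window`, `depth`, `mean`, `boot_sd`, `n`.
#' @export
radius_at_depths <- function(traj, top, depths = c(18, 5, -15, -22),
                             window = 10, n_boot = 200, seed = 1,
                             center = NULL, ...) {
  if (window > traj$n_frames) {
    warning("window longer than trajectory; using a single window")
    window <- traj$n_frames
  }
  if (is.null(center)) center <- bilayer_center(get_frame(traj, 1), top)
  n_win <- traj$n_frames %/% window
  set.seed(seed)
  out <- list()
  for (w in seq_len(n_win)) {
    frames <- ((w - 1) * window + 1):(w * window)
    r <- matrix(NA_real_, length(frames), length(depths))
    for (k in seq_along(frames)) {
      fr <- get_frame(traj, frames[k])
      for (d in seq_along(depths)) {
        prof <- pore_profile(fr, top, z_range = rep(center + depths[d], 2),
                             z_step = 1, ...)
        r[k, d] <- prof$radius[1]
      }
    }
    for (d in seq_along(depths)) {
      bm <- vapply(seq_len(n_boot), function(b)
        mean(r[sample.int(nrow(r), replace = TRUE), d]), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        window = w, depth = depths[d], mean = mean(r[, d]),
        boot_sd = stats::sd(bm), n = nrow(r))
    }
  }
  do.call(rbind, out)
}
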