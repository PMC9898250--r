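test_that("centre of mass matches hand arithmetic", {
  fr <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(center_of_mass(fr, 1:2, masses = c(1, 1)), c(1, 0, 0))
  expect_equal(center_of_mass(fr, 1:2, masses = c(1, 3)), c(1.5, 0, 0))
  expect_equal(center_of_mass(fr, 2, masses = c(1, 3)), c(2, 0, 0))
  expect_equal(center_of_mass(fr, 1:2, masses = c(1, 3),
                              mass_weighted = FALSE), c(1, 0, 0))
  expect_error(center_of_mass(fr, integer(0)), "empty atom set")
})

# three-point construction with COMs at hand-picked positions
com_fixture <- function(ic_a, ic_b, ec, nbd1 = NULL, nbd2 = NULL) {
  pts <- rbind(ic_a, ic_b, ec)
  top <- small_protein_topology(nrow(pts))
  scheme <- structure(list(ic_half_a = 1L, ic_half_b = 2L, ec_whole = 3L),
                      class = "abc_scheme")
  list(frame = pts, top = top, scheme = scheme)
}

test_that("IC and EC angles match closed-form constructions", {
  fx <- com_fixture(c(-10, 0, -20), c(10, 0, -20), c(0, 0, 20))
  expect_equal(ic_angle(fx$frame, fx$top, fx$scheme),
               2 * atan(10 / 40) * 180 / pi, tolerance = 1e-9)
  expect_equal(2 * atan(10 / 40) * 180 / pi, 28.0724869, tolerance = 1e-6)
  # coincident IC halves -> 0 degrees
  fx0 <- com_fixture(c(3, 1, -20), c(3, 1, -20), c(0, 0, 20))
  expect_equal(ic_angle(fx0$frame, fx0$top, fx0$scheme), 0)
  # EC side: halves at (+-5, 0, 20), NBDs at origin-side
  pts <- rbind(c(-5, 0, 20), c(5, 0, 20), c(0, 0, -20))
  top <- small_protein_topology(3)
  sch <- structure(list(ec_half_a = 1L, ec_half_b = 2L, nbd_both = 3L),
                   class = "abc_scheme")
  ec <- ec_angle_and_distance(pts, top, sch)
  expect_equal(ec$angle, 2 * atan(5 / 40) * 180 / pi, tolerance = 1e-9)
  expect_equal(ec$distance, 10)
  # translation invariance
  ec2 <- ec_angle_and_distance(sweep(pts, 2, c(7, -3, 11), `+`), top, sch)
  expect_equal(ec2$angle, ec$angle, tolerance = 1e-9)
  expect_equal(ec2$distance, ec$distance, tolerance = 1e-9)
})

test_that("NBD twist follows the signed dihedral convention", {
  top <- small_protein_topology(4)
  sch <- structure(list(nbd1_lobe = 1L, nbd1 = 2L, nbd2 = 3L,
                        nbd2_lobe = 4L), class = "abc_scheme")
  base <- rbind(c(0, 1, 0), c(0, 0, 0), c(5, 0, 0), c(5, 1, 0))
  r <- nbd_distance_and_twist(base, top, sch)
  expect_equal(r$distance, 5)
  expect_equal(r$twist, 0)
  base[4, ] <- c(5, -1, 0)
  expect_equal(nbd_distance_and_twist(base, top, sch)$twist, 180)
  base[4, ] <- c(5, 0, 1)
  expect_equal(nbd_distance_and_twist(base, top, sch)$twist, 90)
  base[4, ] <- c(5, 0, 0)  # collinear
  expect_error(nbd_distance_and_twist(base, top, sch), "degenerate")
})

test_that("anchor distances respect the minimal-image convention", {
  top <- small_protein_topology(4)
  sch <- structure(list(nbs1_gs = c(1L, 2L), nbs2_gs = c(3L, 4L)),
                   class = "abc_scheme")
  fr <- rbind(c(0, 0, 0), c(12, 0, 0), c(1, 0, 0), c(93, 0, 0))
  d <- nbs_gs_distances(fr, top, sch, box = c(100, 100, 100))
  expect_equal(unname(d[1]), 12)
  expect_equal(unname(d[2]), 8)  # 92 apart -> 8 across the boundary
  same <- structure(list(nbs1_gs = c(1L, 1L), nbs2_gs = c(3L, 4L)),
                    class = "abc_scheme")
  expect_equal(unname(nbs_gs_distances(fr, top, same)[1]), 0)
})

test_that("helix tilt folds into [0, 90] against the normal", {
  top <- small_protein_topology(20, atoms_per_res = 3)
  # straight rods: the principal axis is exact
  rz <- make_helix(20, axis = c(0, 0, 1), radius = 0)
  expect_lt(helix_tilt(rz$coords, top, 1:20), 1e-9)
  rx <- make_helix(20, axis = c(1, 0, 0), radius = 0)
  expect_equal(helix_tilt(rx$coords, top, 1:20), 90, tolerance = 1e-9)
  r45 <- make_helix(20, axis = c(1, 0, 1), radius = 0)
  expect_equal(helix_tilt(r45$coords, top, 1:20), 45, tolerance = 1e-9)
  # full helices: the CA-cloud principal axis wobbles sub-degree around
  # the geometric axis because the turn count is non-integer
  hz <- make_helix(20, axis = c(0, 0, 1))
  expect_lt(helix_tilt(hz$coords, top, 1:20), 0.5)
  hx <- make_helix(20, axis = c(1, 0, 0))
  expect_equal(helix_tilt(hx$coords, top, 1:20), 90, tolerance = 0.5)
  flat <- hz$coords; flat[] <- 1
  expect_error(helix_tilt(flat, top, 1:20), "degenerate")
})

test_that("Kabsch superposition gives exact and counted RMSDs", {
  set.seed(5)
  ref <- matrix(rnorm(300), 100, 3)
  rot <- random_rigid_motion(ref)
  fit <- superpose_and_rmsd(rot, ref)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  moved <- ref; moved[1, ] <- moved[1, ] + c(1, 0, 0)
  # without refitting, a 1 A shift of 1 atom in 100 gives 0.1 A
  expect_equal(sqrt(mean(rowSums((moved - ref)^2))), 0.1)
  expect_equal(superpose_and_rmsd(moved, ref)$rmsd,
               superpose_and_rmsd(ref, moved)$rmsd, tolerance = 1e-9)
  # cross-check against bio3d's superposition
  xyz_m <- as.vector(t(rot)); xyz_r <- as.vector(t(ref))
  fitted <- bio3d::fit.xyz(fixed = xyz_r, mobile = xyz_m,
                           fixed.inds = 1:300, mobile.inds = 1:300)
  expect_lt(sqrt(mean((fitted - xyz_r)^2)), 1e-6)
})

test_that("RMSF recovers isotropic jitter and ignores rigid tumbling", {
  sys <- make_transporter(transporter_spec(helix_len = 8))
  static <- make_trajectory(list(sys$coords), 5, noise_sigma = 0, seed = 1)
  expect_equal(max(rmsf(static)), 0)
  n <- 6000
  tr <- make_trajectory(list(sys$coords), n, noise_sigma = 0.5, seed = 2)
  r <- rmsf(tr)
  expect_equal(mean(r), 0.5 * sqrt(3), tolerance = 0.02)
  # add a rigid-body tumble: alignment must remove it
  tumbled <- tr
  set.seed(3)
  for (f in seq_len(n)) {
    q <- rotation_axis_angle_test(runif(3), runif(1, 0, 0.2))
    tumbled$coords[, , f] <- tr$coords[, , f] %*% q
  }
  r2 <- rmsf(tumbled)
  expect_lt(abs(mean(r2) - mean(r)) / mean(r), 0.01)
  expect_error(rmsf(make_trajectory(list(sys$coords), 1, seed = 1)),
               ">= 2 frames")
})

test_that("core PCA isolates a planted one-domain mode", {
  sys <- make_transporter(transporter_spec(helix_len = 8))
  nbd2_atoms <- atom_indices(sys$topology, sys$scheme$nbd2)
  nf <- 200
  coords <- array(rep(sys$coords, nf), c(nrow(sys$coords), 3, nf))
  amp <- rnorm(nf)
  for (f in seq_len(nf))
    coords[nbd2_atoms, 1, f] <- coords[nbd2_atoms, 1, f] + amp[f]
  traj <- new_trajectory(coords)
  pc <- pca_abc_core(traj, sys$topology, sys$scheme, n_components = 1,
                     atoms = "all", align = FALSE)
  expect_gt(pc$explained[1], 0.99)
  expect_gt(pc$domain_contrib["PC1", "NBD2"], 0.99)
  expect_true(all(abs(rowSums(pc$domain_contrib) - 1) < 1e-9))
  expect_true(all(diff(pc$explained_all) < 1e-12))
})

test_that("reference-space projection returns generator coordinates", {
  a <- make_transporter(transporter_spec(ic_angle = 30, nbd_distance = 40))
  b <- make_transporter(transporter_spec(ic_angle = 50, nbd_distance = 60))
  sp <- project_reference_space(list(
    list(label = "A", class = "IF open", frame = a$coords,
         topology = a$topology, scheme = a$scheme),
    list(label = "B", class = "IF open", frame = b$coords,
         topology = b$topology, scheme = b$scheme)))
  expect_equal(sp$ic_angle, c(30, 50), tolerance = 1e-6)
  expect_equal(sp$nbd_distance, c(40, 60), tolerance = 1e-6)
  expect_warning(
    sp2 <- project_reference_space(list(list(label = "C", frame = a$coords,
                                             topology = a$topology))),
    "skipped")
  expect_equal(nrow(sp2), 0)
  expect_equal(nrow(project_reference_space(list())), 0)
})

test_that("descriptors agree with brute-force oracles on random frames", {
  sys <- make_transporter(transporter_spec(helix_len = 8))
  top <- sys$topology; sch <- sys$scheme
  set.seed(42)
  for (i in 1:25) {
    fr <- sys$coords + matrix(rnorm(length(sys$coords), sd = 2),
                              nrow(sys$coords), 3)
    expect_lt(abs(ic_angle(fr, top, sch) - naive_ic_angle(fr, top, sch)),
              1e-9)
    ec <- ec_angle_and_distance(fr, top, sch); eco <- naive_ec(fr, top, sch)
    expect_lt(abs(ec$angle - eco$angle), 1e-9)
    expect_lt(abs(ec$distance - eco$distance), 1e-9)
    nb <- nbd_distance_and_twist(fr, top, sch); nbo <- naive_nbd(fr, top, sch)
    expect_lt(abs(nb$distance - nbo$distance), 1e-9)
    expect_lt(abs(nb$twist - nbo$twist), 1e-9)
    gs <- nbs_gs_distances(fr, top, sch); gso <- naive_gs(fr, top, sch)
    expect_lt(max(abs(unname(gs) - gso)), 1e-9)
  }
})

test_that("descriptors are invariant to rigid motions", {
  sys <- make_transporter(transporter_spec())
  set.seed(7)
  base <- list(ic = ic_angle(sys$coords, sys$topology, sys$scheme),
               nb = nbd_distance_and_twist(sys$coords, sys$topology,
                                           sys$scheme))
  for (i in 1:20) {
    fr <- random_rigid_motion(sys$coords)
    expect_lt(abs(ic_angle(fr, sys$topology, sys$scheme) - base$ic), 1e-9)
    nb <- nbd_distance_and_twist(fr, sys$topology, sys$scheme)
    expect_lt(abs(nb$distance - base$nb$distance), 1e-9)
    expect_lt(abs(nb$twist - base$nb$twist), 1e-9)
  }
})
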