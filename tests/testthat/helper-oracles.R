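# Independent brute-force oracles, deliberately written with naive loops
# and kept separate from the package's implementation paths.

naive_com <- function(frame, idx, masses) {
  tot <- c(0, 0, 0); msum <- 0
  for (i in idx) {
    tot <- tot + masses[i] * frame[i, ]
    msum <- msum + masses[i]
  }
  tot / msum
}

naive_angle <- function(v1, v2) {
  d <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(max(-1, min(1, d))) * 180 / pi
}

naive_ic_angle <- function(frame, top, scheme) {
  m <- top$atoms$mass
  gidx <- function(g) which(top$atoms$res_id %in% scheme[[g]])
  e <- naive_com(frame, gidx("ec_whole"), m)
  a <- naive_com(frame, gidx("ic_half_a"), m)
  b <- naive_com(frame, gidx("ic_half_b"), m)
  naive_angle(a - e, b - e)
}

naive_ec <- function(frame, top, scheme) {
  m <- top$atoms$mass
  gidx <- function(g) which(top$atoms$res_id %in% scheme[[g]])
  n <- naive_com(frame, gidx("nbd_both"), m)
  a <- naive_com(frame, gidx("ec_half_a"), m)
  b <- naive_com(frame, gidx("ec_half_b"), m)
  list(angle = naive_angle(a - n, b - n),
       distance = sqrt(sum((a - b)^2)))
}

# right-handed signed angle about the p2->p3 axis between the projections
# of (p1-p2) and (p4-p3) onto the plane perpendicular to that axis
naive_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  ax <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  a <- (p1 - p2) - sum((p1 - p2) * ax) * ax
  b <- (p4 - p3) - sum((p4 - p3) * ax) * ax
  atan2(sum(cr(a, b) * ax), sum(a * b)) * 180 / pi
}

naive_nbd <- function(frame, top, scheme) {
  m <- top$atoms$mass
  gidx <- function(g) which(top$atoms$res_id %in% scheme[[g]])
  c1 <- naive_com(frame, gidx("nbd1"), m)
  c2 <- naive_com(frame, gidx("nbd2"), m)
  l1 <- naive_com(frame, gidx("nbd1_lobe"), m)
  l2 <- naive_com(frame, gidx("nbd2_lobe"), m)
  list(distance = sqrt(sum((c2 - c1)^2)),
       twist = naive_dihedral(l1, c1, c2, l2))
}

naive_gs <- function(frame, top, scheme) {
  one <- function(g) {
    res <- scheme[[g]]
    ca <- sapply(res, function(r)
      which(top$atoms$res_id == r & top$atoms$name == "CA")[1])
    sqrt(sum((frame[ca[1], ] - frame[ca[2], ])^2))
  }
  c(one("nbs1_gs"), one("nbs2_gs"))
}

# Kron (star-mesh) elimination: exact resistor reduction of a conductance
# matrix down to the two terminals; independent of any Laplacian solve.
kron_effective_conductance <- function(g, s, t) {
  n <- nrow(g)
  others <- setdiff(seq_len(n), c(s, t))
  # drop nodes disconnected from everything to avoid dividing by zero
  for (v in others) {
    tot <- sum(g[v, ])
    if (tot == 0) next
    idx <- setdiff(seq_len(nrow(g)), v)
    for (i in idx) for (j in idx) {
      if (i == j) next
      g[i, j] <- g[i, j] + g[i, v] * g[v, j] / tot
    }
    g[v, ] <- 0; g[, v] <- 0
  }
  g[s, t]
}

# exhaustive best-modularity bipartition of a small unweighted graph
brute_best_bipartition_modularity <- function(adj) {
  n <- nrow(adj)
  m2 <- sum(adj)  # 2m
  deg <- rowSums(adj)
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    memb <- as.integer(intToBits(mask))[1:n]
    q <- 0
    for (i in 1:n) for (j in 1:n)
      if (memb[i] == memb[j]) q <- q + adj[i, j] - deg[i] * deg[j] / m2
    best <- max(best, q / m2)
  }
  best
}

# donor D at origin, H on the x axis, acceptor placed so that the
# D-H...A angle at H equals angle_deg and |D-A| = d_a
hb_fixture <- function(d_a, angle_deg) {
  h <- c(1, 0, 0)
  th <- angle_deg * pi / 180
  dir <- c(cos(pi - th), sin(pi - th), 0)
  f <- function(l) sqrt(sum((h + l * dir)^2)) - d_a
  l <- stats::uniroot(f, c(1e-6, d_a + 2))$root
  rbind(c(0, 0, 0), h, h + l * dir)
}

rotation_axis_angle_test <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ax <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * ax + (1 - ct) * (a %o% a)
}

random_rigid_motion <- function(frame) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(frame %*% q, 2, rnorm(3, sd = 20), `+`)
}

small_protein_topology <- function(n_res, atoms_per_res = 1) {
  n <- n_res * atoms_per_res
  new_topology(data.frame(
    atom_id = seq_len(n), name = "CA", element = "C", mass = 12,
    charge = 0, vdw_radius = 1.7,
    res_id = rep(seq_len(n_res), each = atoms_per_res),
    res_name = "ALA", seg_name = "X", role = "protein"))
}
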