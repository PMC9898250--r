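test_that("node set follows the coarse node model", {
  sys <- make_transporter(transporter_spec(helix_len = 8))
  mb <- make_membrane(membrane_spec(composition = c(pc = 0.5, pe = 0.25,
                                                    sterol = 0.25),
                                    n_per_leaflet = 8, seed = 1))
  atp <- make_ligand("atp_like")
  ltx <- make_ligand("ltx_like", pose = c(20, 0, 0))
  merged <- merge_systems(sys, mb, atp, ltx)
  nodes <- make_node_set(merged$topology)
  res <- residues(merged$topology)
  n_lip <- sum(res$res_name %in% c("PCL", "PEL"))
  n_chl <- sum(res$res_name == "CHL")
  expect_equal(sum(nodes$kind %in% c("lipid_head", "lipid_tail")), 3 * n_lip)
  expect_equal(sum(nodes$kind == "sterol"), n_chl)
  expect_equal(sum(nodes$kind == "atp_part"), 3)
  expect_equal(sum(nodes$kind == "ltx_part"), 3)
  # residue nodes anchored on CA
  rn <- nodes[nodes$kind == "residue", ]
  expect_true(all(merged$topology$atoms$name[rn$anchor] == "CA"))
})

test_that("DCCM has unit diagonal, symmetry, bounds, and planted correlations", {
  sys <- make_transporter(transporter_spec(helix_len = 8))
  tr <- make_trajectory(list(sys$coords), 3000, noise_sigma = 0.4, seed = 6,
                        correlated_modes = list(
                          list(i = 1:3, j = 7:9, rho = 0.95),
                          list(i = 13:15, j = 19:21, rho = -0.95)))
  nodes <- make_node_set(sys$topology)
  sel <- nodes[nodes$anchor %in% c(1, 7, 13, 19), ]
  c_ <- dccm(tr, sel)
  expect_equal(diag(c_), rep(1, 4))
  expect_equal(c_, t(c_))
  expect_true(all(abs(c_) <= 1 + 1e-12))
  expect_gt(c_[1, 2], 0.9)   # positively driven pair
  expect_lt(c_[3, 4], -0.9)  # anti-phase pair
  # zero-variance node handling
  static <- make_trajectory(list(sys$coords), 10, noise_sigma = 0, seed = 1)
  static$coords[1:3, , ] <- static$coords[1:3, , ] +
    array(rnorm(3 * 3 * 10, sd = 0.1), c(3, 3, 10))
  expect_message(c0 <- dccm(static, sel), "zero-variance")
  expect_equal(diag(c0), rep(1, 4))
  expect_equal(c0[2, 3], 0)
})

test_that("contact maps honour cutoffs and neighbour restrictions", {
  # three residues on a line: 1-2 adjacent in sequence and space,
  # 1-3 distant in sequence, close in space; 1-4 beyond cutoff
  top <- small_protein_topology(4)
  fr <- rbind(c(0, 0, 0), c(3, 0, 0), c(4, 0, 0), c(20, 0, 0))
  traj <- new_trajectory(array(rep(fr, 5), c(4, 3, 5)))
  nodes <- make_node_set(top)
  cm <- contact_map(traj, top, nodes, cutoff = 4.5)
  expect_equal(cm[1, 2], 0)  # sequence neighbours excluded
  expect_equal(cm[1, 3], 1)  # in contact every frame
  expect_equal(cm[1, 4], 0)  # beyond cutoff
  expect_equal(cm[2, 3], 0)  # neighbours again
  cm_raw <- contact_map(traj, top, nodes, cutoff = 4.5,
                        restrictions = FALSE)
  expect_equal(cm_raw[1, 2], 1)
  # pair sitting at cutoff + 0.1 never counts
  fr2 <- rbind(c(0, 0, 0), c(100, 0, 0), c(4.6, 0, 0), c(50, 0, 0))
  traj2 <- new_trajectory(array(rep(fr2, 3), c(4, 3, 3)))
  expect_equal(contact_map(traj2, top, nodes, cutoff = 4.5)[1, 3], 0)
})

test_that("communities split planted cliques and merge uniform graphs", {
  # two 5-node cliques joined by one edge
  n <- 10
  adj <- matrix(0, n, n)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1; diag(adj) <- 0
  adj[5, 6] <- adj[6, 5] <- 1
  c_ <- ifelse(adj > 0, 0.8, 0)
  diag(c_) <- 1
  com <- communities(c_, adj, threshold = 0.5)
  expect_equal(com$n_communities, 2)
  expect_equal(length(unique(com$membership[1:5])), 1)
  expect_equal(length(unique(com$membership[6:10])), 1)
  # the partition is modularity-optimal over all bipartitions
  expect_equal(com$modularity, brute_best_bipartition_modularity(adj),
               tolerance = 1e-9)
  # fully connected uniform graph -> one community
  full <- matrix(1, 6, 6); diag(full) <- 0
  cf <- ifelse(full > 0, 0.9, 0); diag(cf) <- 1
  com2 <- communities(cf, full, threshold = 0.5)
  expect_equal(com2$n_communities, 1)
  # empty graph
  com3 <- communities(diag(4), matrix(0, 4, 4))
  expect_equal(com3$n_communities, 0)
})

test_that("planted two-block graphs are recovered across seeds", {
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 16
    blocks <- rep(1:2, each = n / 2)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (blocks[i] == blocks[j]) 0.9 else 0.1
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
    }
    c_ <- ifelse(adj > 0, 0.8, 0); diag(c_) <- 1
    com <- communities(c_, adj, threshold = 0.5)
    if (com$n_communities == 2 &&
        length(unique(com$membership[blocks == 1])) == 1 &&
        length(unique(com$membership[blocks == 2])) == 1) ok <- ok + 1
  }
  expect_equal(ok, 20)
})

test_that("Gaussian MI matches the closed form and stays non-negative", {
  sys <- make_transporter(transporter_spec(helix_len = 8))
  tr <- make_trajectory(list(sys$coords), 20000, noise_sigma = 0.5, seed = 7,
                        correlated_modes = list(list(i = 1:3, j = 7:9,
                                                     rho = 0.9),
                                                list(i = 13:15, j = 19:21,
                                                     rho = 0.5)))
  nodes <- make_node_set(sys$topology)
  sel <- nodes[nodes$anchor %in% c(1, 7, 13, 19, 25, 31), ]
  mi <- mutual_information(tr, sel)
  expect_equal(mi, t(mi))
  expect_true(all(mi >= 0))
  expect_equal(diag(mi), rep(0, 6))
  expect_lt(abs(mi[1, 2] - 0.830) / 0.830, 0.05)
  expect_lt(abs(mi[3, 4] + 0.5 * log(1 - 0.25)) / (0.5 * log(4 / 3)), 0.05)
  expect_lt(mi[5, 6], 0.005)  # independent pair
  # histogram estimator broadly agrees on the strong pair
  mih <- mutual_information(tr, sel, method = "histogram")
  expect_gt(mih[1, 2], mih[5, 6])
})

test_that("efficiency matches Kron reduction on exhaustive and random graphs", {
  # exhaustive 4-node topologies with random conductances
  set.seed(11)
  pairs4 <- t(combn(4, 2))
  for (mask in 1:63) {
    on <- as.logical(intToBits(mask))[1:6]
    g <- matrix(0, 4, 4)
    w <- runif(6, 0.2, 3)
    for (e in which(on)) {
      g[pairs4[e, 1], pairs4[e, 2]] <- w[e]
      g[pairs4[e, 2], pairs4[e, 1]] <- w[e]
    }
    eff <- abctraj:::effective_conductance(g, 1, 4)$efficiency
    expect_lt(abs(eff - kron_effective_conductance(g, 1, 4)), 1e-9)
  }
  # random 5/6-node graphs
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:6, 1)
    g <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.6) g[i, j] <- g[j, i] <- runif(1, 0.1, 4)
    eff <- abctraj:::effective_conductance(g, 1, n)$efficiency
    expect_lt(abs(eff - kron_effective_conductance(g, 1, n)), 1e-9)
  }
})

test_that("series/parallel identities and monotonicity hold", {
  # single edge
  g <- matrix(0, 2, 2); g[1, 2] <- g[2, 1] <- 2.5
  expect_equal(abctraj:::effective_conductance(g, 1, 2)$efficiency, 2.5)
  # series
  g <- matrix(0, 3, 3); g[1, 2] <- g[2, 1] <- 2; g[2, 3] <- g[3, 2] <- 3
  expect_equal(abctraj:::effective_conductance(g, 1, 3)$efficiency, 6 / 5)
  # parallel
  g <- matrix(0, 4, 4)
  g[1, 2] <- g[2, 1] <- 2; g[2, 4] <- g[4, 2] <- 2
  g[1, 3] <- g[3, 1] <- 4; g[3, 4] <- g[4, 3] <- 4
  expect_equal(abctraj:::effective_conductance(g, 1, 4)$efficiency, 3)
  # monotone in any single conductance
  set.seed(12)
  for (t in 1:10) {
    n <- 6
    g <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.7) g[i, j] <- g[j, i] <- runif(1, 0.5, 2)
    base <- abctraj:::effective_conductance(g, 1, n)$efficiency
    e <- which(upper.tri(g) & g > 0)[1]
    g2 <- g; g2[e] <- g2[e] + 0.5; g2 <- pmax(g2, t(g2))
    expect_gte(abctraj:::effective_conductance(g2, 1, n)$efficiency,
               base - 1e-12)
  }
  # disconnection flags zero efficiency
  g <- matrix(0, 4, 4); g[1, 2] <- g[2, 1] <- 1; g[3, 4] <- g[4, 3] <- 1
  r <- abctraj:::effective_conductance(g, 1, 4)
  expect_equal(r$efficiency, 0)
  expect_true(r$flagged)
  expect_equal(sum(r$betweenness), 0)
})

test_that("lipid bridges carry flow and decomposition conserves totals", {
  # protein source and sink connected only through a tagged sterol node
  top <- merge_systems(
    list(topology = small_protein_topology(2), coords = matrix(0, 2, 3)),
    make_ligand("sterol_like"))
  nodes <- make_node_set(top$topology)
  stopifnot(nrow(nodes) == 3)
  st <- which(nodes$kind == "sterol")
  mi <- matrix(0.5, 3, 3); diag(mi) <- 0
  ct <- matrix(0, 3, 3)
  ct[1, st] <- ct[st, 1] <- 1; ct[2, st] <- ct[st, 2] <- 1
  res <- allosteric_efficiency(mi, ct, nodes, source_res = 1, sink_res = 2)
  expect_equal(res$efficiency, 0.25)  # series of two 0.5 edges
  dec <- flow_decomposition(res, nodes)
  expect_equal(sum(dec$by_class), dec$total)
  expect_equal(sum(dec$by_segment), dec$total)
  expect_equal(unname(dec$by_class["lipid"]),
               unname(res$betweenness[st]))
  expect_gte(res$betweenness[st], max(res$betweenness[-st]))
  # removing the bridge kills the efficiency
  ct0 <- ct; ct0[st, ] <- 0; ct0[, st] <- 0
  res0 <- allosteric_efficiency(mi, ct0, nodes, 1, 2)
  expect_equal(res0$efficiency, 0)
  expect_true(res0$flagged)
  # adding a direct (weaker) protein path: dropping the lipid bridge
  # strictly decreases efficiency
  ct2 <- ct; ct2[1, 2] <- ct2[2, 1] <- 0.4
  direct_only <- matrix(0, 3, 3); direct_only[1, 2] <- direct_only[2, 1] <- 0.4
  e_with <- allosteric_efficiency(mi, ct2, nodes, 1, 2)$efficiency
  e_without <- allosteric_efficiency(mi, direct_only, nodes, 1, 2)$efficiency
  expect_gt(e_with, e_without)
  expect_error(allosteric_efficiency(mi, ct, nodes, 1, 1), "disjoint")
  expect_error(allosteric_efficiency(mi, ct, nodes, integer(0), 2),
               "non-empty")
})
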