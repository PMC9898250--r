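# Correlation, contact and allosteric-network analyses.
#
# Coarse node model: protein residues anchored on C-alpha; each
# phospholipid contributes three nodes (polar head, two tails); ATP-like
# ligands three nodes (purine, ribose, triphosphate); LTX-like three
# (glutathione, tail, acid); sterols and ions one each. Communication
# efficiency between two residue sets is the effective conductance of the
# resistor network with edge conductances MI_ij x contact_ij, and node
# betweenness is the current through each node under unit injected flow.

#' Build the coarse node set of a system
#'
#' @param top an `abc_topology`.
#' @param include roles to include.
#' @return data.frame of class `abc_nodes`: `node_id`, `kind`, `res_id`,
#'   `seg_name`, `anchor` (atom id), and a list-column `members`.
#' @export
make_node_set <- function(top, include = c("protein", "lipid", "ligand",
                                           "sterol", "ion")) {
  a <- top$atoms
  protein_roles <- c("tmh", "nbd", "l0", "ch", "anchor", "protein",
                     "unassigned")
  nodes <- list()
  add <- function(kind, res_id, seg, anchor, members)
    nodes[[length(nodes) + 1]] <<- list(kind = kind, res_id = res_id,
                                        seg_name = seg, anchor = anchor,
                                        members = members)
  for (r in split(seq_len(nrow(a)), a$res_id)) {
    role <- a$role[r[1]]
    seg <- a$seg_name[r[1]]
    rid <- a$res_id[r[1]]
    if (role %in% protein_roles && "protein" %in% include) {
      ca <- r[a$name[r] == "CA"]
      add("residue", rid, seg, if (length(ca)) ca[1] else r[1], r)
    } else if (role == "lipid" && "lipid" %in% include) {
      head <- r[a$body[r] == "head"]
      ta <- r[a$body[r] == "tail_a" & a$element[r] != "H"]
      tb <- r[a$body[r] == "tail_b" & a$element[r] != "H"]
      add("lipid_head", rid, seg, head[1], r[a$body[r] == "head"])
      if (length(ta)) add("lipid_tail", rid, seg, ta[ceiling(length(ta) / 2)],
                          r[a$body[r] == "tail_a"])
      if (length(tb)) add("lipid_tail", rid, seg, tb[ceiling(length(tb) / 2)],
                          r[a$body[r] == "tail_b"])
    } else if (role == "sterol" && "sterol" %in% include) {
      add("sterol", rid, seg, r[1], r)
    } else if (role == "ion" && "ion" %in% include) {
      add("ion", rid, seg, r[1], r)
    } else if (role == "ligand" && "ligand" %in% include) {
      kind <- if (a$res_name[r[1]] == "ATP") "atp_part" else "ltx_part"
      for (b in unique(a$body[r])) {
        rb <- r[a$body[r] == b]
        heavy <- rb[a$element[rb] != "H"]
        add(kind, rid, paste0(seg, ":", b),
            heavy[ceiling(length(heavy) / 2)], rb)
      }
    }
  }
  df <- data.frame(node_id = seq_along(nodes),
                   kind = vapply(nodes, `[[`, "", "kind"),
                   res_id = vapply(nodes, `[[`, 0, "res_id"),
                   seg_name = vapply(nodes, `[[`, "", "seg_name"),
                   anchor = vapply(nodes, function(n) n$anchor[1], 0),
                   stringsAsFactors = FALSE)
  df$members <- lapply(nodes, `[[`, "members")
  class(df) <- c("abc_nodes", class(df))
  df
}

node_anchor_series <- function(traj, nodes, align_idx = NULL) {
  anchors <- nodes$anchor
  arr <- array(0, c(length(anchors), 3, traj$n_frames))
  if (is.null(align_idx)) {
    for (f in seq_len(traj$n_frames))
      arr[, , f] <- get_frame(traj, f)[anchors, , drop = FALSE]
  } else {
    avg <- apply(traj$coords, c(1, 2), mean)
    for (f in seq_len(traj$n_frames)) {
      fit <- superpose_kabsch(get_frame(traj, f), avg, align_idx)
      arr[, , f] <- fit$coords[anchors, , drop = FALSE]
    }
  }
  arr
}

#' Dynamic cross-correlation matrix
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>) over node-anchor
#' displacements from the trajectory mean. Zero-variance nodes get zero
#' rows/columns (diagonal 1).
#'
#' @param traj an `abc_trajectory` (>= 2 frames).
#' @param nodes an `abc_nodes` table.
#' @param align_idx optional atom indices to superpose frames on first.
#' @return symmetric matrix with unit diagonal.
#' @export
dccm <- function(traj, nodes, align_idx = NULL) {
  if (traj$n_frames < 2) stop("dccm needs >= 2 frames")
  arr <- node_anchor_series(traj, nodes, align_idx)
  n <- dim(arr)[1]
  mu <- apply(arr, c(1, 2), mean)
  s <- matrix(0, n, n)
  for (d in 1:3) {
    x <- arr[, d, ] - mu[, d]
    s <- s + tcrossprod(x)
  }
  v <- diag(s)
  zero <- v < 1e-12
  denom <- sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
  c_ <- s / denom
  if (any(zero)) {
    message(sum(zero), " zero-variance node(s); rows zeroed")
    c_[zero, ] <- 0; c_[, zero] <- 0
  }
  diag(c_) <- 1
  c_
}

#' Contact-fraction map between nodes
#'
#' Fraction of frames with any heavy-atom pair within `cutoff`. Standard
#' restrictions zero out same-residue pairs and sequence-neighbour
#' residue pairs (the notSameResidue / notNeighboringCAlpha /
#' notNeighboringResidue exclusions of common network tools).
#'
#' @param traj an `abc_trajectory`.
#' @param top an `abc_topology`.
#' @param nodes an `abc_nodes` table.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @param restrictions apply the exclusion rules.
#' @return symmetric fraction matrix (diagonal 0).
#' @export
contact_map <- function(traj, top, nodes, cutoff = 4.5, restrictions = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- top$atoms
  n <- nrow(nodes)
  heavy <- lapply(nodes$members, function(m) m[a$element[m] != "H"])
  cm <- matrix(0, n, n)
  for (f in seq_len(traj$n_frames)) {
    fr <- get_frame(traj, f)
    bx <- frame_box(traj, f)
    for (i in seq_len(n - 1)) {
      xi <- fr[heavy[[i]], , drop = FALSE]
      for (j in (i + 1):n) {
        d <- proxy_min_dists(xi, fr[heavy[[j]], , drop = FALSE], bx)
        if (min(d) <= cutoff) {
          cm[i, j] <- cm[i, j] + 1
        }
      }
    }
  }
  cm <- (cm + t(cm)) / traj$n_frames
  if (restrictions) {
    res_i <- nodes$res_id
    same_kind <- outer(nodes$kind == "residue", nodes$kind == "residue", `&`)
    excl <- (outer(res_i, res_i, function(x, y) abs(x - y)) <= 1) & same_kind
    excl <- excl | outer(res_i, res_i, `==`)
    cm[excl] <- 0
  }
  diag(cm) <- 0
  cm
}

#' Girvan-Newman community detection on a correlation-weighted graph
#'
#' Edges connect node pairs whose contact fraction reaches `threshold`,
#' weighted w_ij = -log|C_ij|; communities come from edge-betweenness
#' removal with the maximum-modularity cut.
#'
#' @param dccm_mat DCCM matrix.
#' @param contact contact-fraction matrix.
#' @param threshold contact-fraction threshold for an edge.
#' @return list with `membership`, `n_communities`, `modularity`, `graph`.
#' @export
communities <- function(dccm_mat, contact, threshold = 0.75) {
  n <- nrow(dccm_mat)
  adj <- contact >= threshold
  diag(adj) <- FALSE
  if (!any(adj)) {
    return(list(membership = integer(0), n_communities = 0,
                modularity = NA_real_, graph = NULL))
  }
  w <- -log(pmin(pmax(abs(dccm_mat), 1e-12), 1 - 1e-12))
  g <- igraph::graph_from_adjacency_matrix(adj * w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # igraph emits an informational warning that the returned membership is
  # the maximum-modularity cut -- which is exactly the behaviour we want
  cl <- suppressWarnings(
    igraph::cluster_edge_betweenness(g, weights = igraph::E(g)$weight,
                                     modularity = TRUE))
  memb <- igraph::membership(cl)
  list(membership = as.integer(memb),
       n_communities = length(unique(memb)),
       modularity = igraph::modularity(g, memb),
       graph = g)
}

#' Mutual information between node fluctuations
#'
#' Gaussian closed form MI = -1/2 ln(1 - rho^2) (nats) with rho the
#' DCCM correlation of node-anchor displacements; a plug-in histogram
#' estimator on displacement magnitudes is available as an alternative.
#'
#' @param traj an `abc_trajectory` (>= 100 frames recommended).
#' @param nodes an `abc_nodes` table.
#' @param method `"gaussian"` or `"histogram"`.
#' @param align_idx optional superposition atoms.
#' @param bins histogram bins for the alternative estimator.
#' @return symmetric non-negative MI matrix (nats), zero diagonal.
#' @export
mutual_information <- function(traj, nodes, method = c("gaussian", "histogram"),
                               align_idx = NULL, bins = 16) {
  method <- match.arg(method)
  if (method == "gaussian") {
    c_ <- dccm(traj, nodes, align_idx)
    mi <- -0.5 * log(pmax(1 - c_^2, 1e-300))
    diag(mi) <- 0
    return(mi)
  }
  arr <- node_anchor_series(traj, nodes, align_idx)
  n <- dim(arr)[1]
  mu <- apply(arr, c(1, 2), mean)
  mag <- sqrt(apply(sweep(arr, c(1, 2), mu)^2, c(1, 3), sum))
  mi <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- mag[i, ]; xj <- mag[j, ]
    if (stats::sd(xi) < 1e-12 || stats::sd(xj) < 1e-12) next
    bi <- cut(xi, bins, labels = FALSE); bj <- cut(xj, bins, labels = FALSE)
    pxy <- table(bi, bj) / length(xi)
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    mi[i, j] <- mi[j, i] <- sum(pxy[nz] * log(pxy[nz] /
                                               outer(px, py)[nz]))
  }
  mi
}

laplacian_from_conductance <- function(g) {
  diag(rowSums(g)) - g
}

#' Allosteric communication efficiency and current-flow betweenness
#'
#' Builds the conductance graph g_ij = MI_ij x contact_ij, contracts the
#' source and sink residue sets into super-nodes, and solves the resistor
#' network: efficiency is the effective conductance between the two
#' super-nodes, and each node's betweenness is the total current through
#' it under unit injected flow (source/sink super-node currents are split
#' equally over their member nodes). A disconnected source-sink pair
#' returns zero efficiency, flagged.
#'
#' @param mi MI matrix (nats).
#' @param contact contact-fraction matrix.
#' @param nodes an `abc_nodes` table.
#' @param source_res,sink_res residue ids of the source and sink sets
#'   (must be non-empty and disjoint).
#' @return list of class `abc_allostery`: `efficiency`, `betweenness`
#'   (per node), `flagged`, `source_nodes`, `sink_nodes`.
#' @export
allosteric_efficiency <- function(mi, contact, nodes, source_res, sink_res) {
  if (!length(source_res) || !length(sink_res))
    stop("source and sink sets must be non-empty")
  if (length(intersect(source_res, sink_res)))
    stop("source and sink sets must be disjoint")
  g <- mi * contact
  g[g < 0] <- 0
  diag(g) <- 0
  src <- which(nodes$res_id %in% source_res & nodes$kind == "residue")
  snk <- which(nodes$res_id %in% sink_res & nodes$kind == "residue")
  if (!length(src) || !length(snk))
    stop("source/sink residues map to no nodes")
  res <- effective_conductance(g, src, snk)
  res$source_nodes <- src; res$sink_nodes <- snk
  class(res) <- "abc_allostery"
  res
}

# Core resistor-network solve on a conductance matrix with source/sink
# index sets contracted to super-nodes.
effective_conductance <- function(g, src, snk) {
  n <- nrow(g)
  keep <- setdiff(seq_len(n), c(src, snk))
  m <- length(keep) + 2  # [internal..., S, T]
  gg <- matrix(0, m, m)
  gg[seq_along(keep), seq_along(keep)] <- g[keep, keep, drop = FALSE]
  s_row <- if (length(src) > 1) colSums(g[src, , drop = FALSE]) else g[src, ]
  t_row <- if (length(snk) > 1) colSums(g[snk, , drop = FALSE]) else g[snk, ]
  gg[m - 1, seq_along(keep)] <- s_row[keep]
  gg[seq_along(keep), m - 1] <- s_row[keep]
  gg[m, seq_along(keep)] <- t_row[keep]
  gg[seq_along(keep), m] <- t_row[keep]
  st <- sum(g[src, snk])
  gg[m - 1, m] <- st; gg[m, m - 1] <- st
  # connectivity check on the contracted graph
  adj <- gg > 0
  seen <- rep(FALSE, m); queue <- m - 1; seen[m - 1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!seen[m]) {
    return(list(efficiency = 0, betweenness = rep(0, n), flagged = TRUE,
                potentials = rep(NA_real_, n)))
  }
  lap <- laplacian_from_conductance(gg)
  active <- which(seen)
  red <- setdiff(active, m)  # ground T
  b <- rep(0, m); b[m - 1] <- 1
  v_red <- solve(lap[red, red, drop = FALSE], b[red])
  v <- rep(0, m); v[red] <- v_red
  r_eff <- v[m - 1]
  eff <- 1 / r_eff
  # currents and node throughflow
  curr <- gg * (matrix(v, m, m) - matrix(v, m, m, byrow = TRUE))
  flow <- rowSums(abs(curr)) / 2
  btw <- rep(0, n)
  btw[keep] <- flow[seq_along(keep)]
  btw[src] <- flow[m - 1] / length(src)
  btw[snk] <- flow[m] / length(snk)
  pot <- rep(NA_real_, n)
  pot[keep] <- v[seq_along(keep)]
  list(efficiency = eff, betweenness = btw, flagged = FALSE,
       potentials = pot)
}

#' Decompose information flow by component class and segment
#'
#' @param result an `abc_allostery` result.
#' @param nodes the matching `abc_nodes` table.
#' @return list with `by_class` (protein / lipid / ligand / ion named
#'   sums), `by_segment` (named sums), `total`.
#' @export
flow_decomposition <- function(result, nodes) {
  cls <- c(residue = "protein", lipid_head = "lipid", lipid_tail = "lipid",
           sterol = "lipid", atp_part = "ligand", ltx_part = "ligand",
           ion = "ion")
  kind_cls <- cls[nodes$kind]
  kind_cls[is.na(kind_cls)] <- "unassigned"
  seg <- nodes$seg_name
  seg[is.na(seg) | seg == ""] <- "unassigned"
  b <- result$betweenness
  list(by_class = tapply(b, kind_cls, sum),
       by_segment = tapply(b, seg, sum),
       total = sum(b))
}
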