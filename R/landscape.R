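# Gaussian-mixture free-energy landscapes over descriptor pairs.
#
# A 2D GMM is fitted by EM for every component count K in a range (the
# default range 2..12 and the 20-iteration EM cap follow common practice
# for landscape estimation on MD descriptor data); K is selected by 3-fold
# cross-validated held-out log-likelihood. The free-energy surface is
# F = -kT ln p on an 80 x 80 grid with the minimum shifted to zero, and
# core states are the gradient-ascent basins of the density grid.

log_dmvnorm2 <- function(x, mu, sigma) {
  # x: n x 2
  ev <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-12)
  ld <- sum(log(vals))
  xi <- sweep(x, 2, mu) %*% ev$vectors
  q <- (xi[, 1]^2) / vals[1] + (xi[, 2]^2) / vals[2]
  -log(2 * pi) - 0.5 * ld - 0.5 * q
}

regularise_cov <- function(sigma, floor = 1e-6) {
  ev <- eigen(sigma, symmetric = TRUE)
  if (any(ev$values < floor)) {
    vals <- pmax(ev$values, floor)
    sigma <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  }
  (sigma + t(sigma)) / 2
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, 2)
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

em_gmm <- function(x, k, max_iter = 20, cov_floor = 1e-6) {
  n <- nrow(x)
  centers <- kmeanspp_centers(x, k)
  w <- rep(1 / k, k)
  v <- stats::var(x)
  covs <- array(rep(regularise_cov(v, cov_floor), k), c(2, 2, k))
  mus <- centers
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j)
      log(w[j]) + log_dmvnorm2(x, mus[j, ], covs[, , j]), numeric(n))
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    r <- exp(logp - lse)
    nk <- colSums(r)
    w <- nk / n
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) next
      mus[j, ] <- colSums(x * r[, j]) / nk[j]
      xc <- sweep(x, 2, mus[j, ])
      s <- crossprod(xc * r[, j], xc) / nk[j]
      covs[, , j] <- regularise_cov(s, cov_floor)
    }
  }
  list(weights = w, means = mus, covs = covs, k = k, loglik = ll)
}

gmm_logdens <- function(gmm, x) {
  n <- nrow(x)
  logp <- vapply(seq_len(gmm$k), function(j)
    log(gmm$weights[j]) + log_dmvnorm2(x, gmm$means[j, ], gmm$covs[, , j]),
    numeric(n))
  if (gmm$k == 1) return(as.vector(logp))
  m <- apply(logp, 1, max)
  m + log(rowSums(exp(logp - m)))
}

#' Mixture density at points
#' @param gmm fitted mixture from [fit_density()].
#' @param x n x 2 points.
#' @return densities.
#' @export
gmm_density <- function(gmm, x) exp(gmm_logdens(gmm, x))

#' Fit a 2D Gaussian mixture to descriptor samples
#'
#' EM is run for every component count in `k_min:k_max` with a
#' deterministic seeded k-means++ initialisation and at most `max_iter`
#' iterations; the component count is chosen by the highest mean held-out
#' log-likelihood under `n_folds`-fold cross-validation, then refitted on
#' the full data. Singular covariances are regularised by an eigenvalue
#' floor.
#'
#' @param samples n x 2 matrix of descriptor pairs (n >= 50).
#' @param k_min,k_max component-count range.
#' @param max_iter EM iteration cap per fit.
#' @param seed RNG seed (initialisation and fold assignment).
#' @param n_folds cross-validation folds.
#' @param cov_floor eigenvalue floor for covariance regularisation.
#' @return list of class `abc_gmm` with `weights`, `means`, `covs`, `k`,
#'   `loglik`, `cv` (per-K held-out log-likelihoods).
#' @export
fit_density <- function(samples, k_min = 2, k_max = 12, max_iter = 20,
                        seed = 1, n_folds = 3, cov_floor = 1e-6) {
  x <- as.matrix(samples)
  if (nrow(x) < 50) stop("need at least 50 samples")
  if (!all(is.finite(x))) stop("samples must be finite")
  if (ncol(x) != 2) stop("samples must be n x 2")
  # canonical sample order makes the fit invariant under permutation of
  # the input rows (fold assignment and initialisation are index-based)
  x <- x[order(x[, 1], x[, 2]), , drop = FALSE]
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = nrow(x)))
  ks <- k_min:k_max
  cv <- numeric(length(ks))
  for (i in seq_along(ks)) {
    held <- 0
    for (f in seq_len(n_folds)) {
      set.seed(seed + 1000 * i + f)
      fit <- em_gmm(x[folds != f, , drop = FALSE], ks[i], max_iter, cov_floor)
      held <- held + sum(gmm_logdens(fit, x[folds == f, , drop = FALSE]))
    }
    cv[i] <- held / nrow(x)
  }
  k_best <- ks[which.max(cv)]
  set.seed(seed)
  fit <- em_gmm(x, k_best, max_iter, cov_floor)
  fit$cv <- stats::setNames(cv, ks)
  class(fit) <- "abc_gmm"
  fit
}

#' Free-energy landscape on a grid
#'
#' F(cell) = -kT ln p(cell centre), shifted so the minimum is 0. Cells
#' with density below `1e-6 * max(p)` are masked.
#'
#' @param gmm an `abc_gmm`.
#' @param ranges list of two length-2 ranges (x then y); default spans the
#'   mixture means +/- 4 sd.
#' @param grid grid size per axis.
#' @param kT thermal energy unit (free energies reported in multiples).
#' @param metrics character length-2 axis names.
#' @return list of class `abc_landscape`: `x`, `y` (cell centres), `F`
#'   (grid x grid matrix, kT), `density`, `mask`, `quadrature` (density
#'   integral over the grid), `mixture`, `kT`.
#' @export
free_energy_grid <- function(gmm, ranges = NULL, grid = 80, kT = 1,
                             metrics = c("x", "y")) {
  if (is.null(ranges)) {
    sds <- sqrt(vapply(seq_len(gmm$k), function(j) diag(gmm$covs[, , j]),
                       numeric(2)))
    lo <- apply(gmm$means - 4 * t(sds), 2, min)
    hi <- apply(gmm$means + 4 * t(sds), 2, max)
    ranges <- list(c(lo[1], hi[1]), c(lo[2], hi[2]))
  }
  gx <- seq(ranges[[1]][1], ranges[[1]][2], length.out = grid + 1)
  gy <- seq(ranges[[2]][1], ranges[[2]][2], length.out = grid + 1)
  cx <- (gx[-1] + gx[-(grid + 1)]) / 2
  cy <- (gy[-1] + gy[-(grid + 1)]) / 2
  pts <- as.matrix(expand.grid(x = cx, y = cy))
  dens <- matrix(gmm_density(gmm, pts), grid, grid)
  cell_area <- diff(gx)[1] * diff(gy)[1]
  quad <- sum(dens) * cell_area
  mask <- dens < 1e-6 * max(dens)
  fe <- -kT * log(dens)
  fe[mask] <- NA
  fe <- fe - min(fe, na.rm = TRUE)
  structure(list(x = cx, y = cy, F = fe, density = dens, mask = mask,
                 quadrature = quad, mixture = gmm, kT = kT,
                 metrics = metrics, states = NULL),
            class = "abc_landscape")
}

#' Core-state detection on a landscape
#'
#' Gradient-ascent (steepest 8-neighbour) basin assignment on the density
#' grid; basins whose peak density is below `merge_frac` of the global
#' peak are merged into the basin of the nearest stronger peak.
#' Populations are the summed density over each basin's unmasked cells,
#' normalised to 1.
#'
#' @param landscape an `abc_landscape`.
#' @param merge_frac weak-peak merge threshold (fraction of global peak).
#' @return the landscape with `states` (grid matrix of labels; 0 =
#'   masked/unassigned) and `populations` filled in.
#' @export
find_core_states <- function(landscape, merge_frac = 0.05) {
  dens <- landscape$density
  mask <- landscape$mask
  g <- nrow(dens)
  if (all(mask)) {
    landscape$states <- matrix(0L, g, g)
    landscape$populations <- numeric(0)
    return(landscape)
  }
  # steepest-ascent pointer for every unmasked cell
  idx <- which(!mask, arr.ind = TRUE)
  ptr <- matrix(0L, g, g)
  lin <- function(i, j) (j - 1L) * g + i
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    # lexicographic (density, -linear index) tie-break so plateau cells
    # of exactly equal density collapse into one basin
    best <- dens[i, j]; bl <- lin(i, j)
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > g || jj < 1 || jj > g) next
      dv <- dens[ii, jj]; lv <- lin(ii, jj)
      if (dv > best || (dv == best && lv < bl)) { best <- dv; bl <- lv }
    }
    ptr[i, j] <- bl
  }
  # follow pointers to peaks
  root <- matrix(0L, g, g)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    cur <- lin(i, j)
    repeat {
      nxt <- ptr[cur]
      if (nxt == cur) break
      cur <- nxt
    }
    root[i, j] <- cur
  }
  peaks <- sort(unique(root[root > 0]))
  peak_dens <- dens[peaks]
  strong <- peaks[peak_dens >= merge_frac * max(peak_dens)]
  if (!length(strong)) strong <- peaks[which.max(peak_dens)]
  # merge weak basins into the nearest strong peak (grid distance)
  pi_ <- ((peaks - 1L) %% g) + 1L; pj_ <- ((peaks - 1L) %/% g) + 1L
  si <- ((strong - 1L) %% g) + 1L; sj <- ((strong - 1L) %/% g) + 1L
  remap <- stats::setNames(peaks, peaks)
  for (t in seq_along(peaks)) {
    if (peaks[t] %in% strong) next
    dd <- (pi_[t] - si)^2 + (pj_[t] - sj)^2
    remap[as.character(peaks[t])] <- strong[which.min(dd)]
  }
  states <- matrix(0L, g, g)
  lab <- stats::setNames(seq_along(strong), strong)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    states[i, j] <- lab[as.character(remap[as.character(root[i, j])])]
  }
  pops <- vapply(seq_along(strong), function(s) sum(dens[states == s]),
                 numeric(1))
  landscape$states <- states
  landscape$populations <- pops / sum(pops)
  landscape
}

#' Block-averaged convergence profile of a descriptor series
#'
#' Splits the series into `n_blocks` equal contiguous blocks, reports
#' per-block mean/sd and the cumulative mean, and flags convergence when
#' the last two block means differ by less than one pooled block sd.
#'
#' @param series numeric vector.
#' @param n_blocks number of blocks (>= 2).
#' @return list with `blocks` (data.frame block, n, mean, sd),
#'   `cumulative_mean` and `converged`.
#' @export
convergence_profile <- function(series, n_blocks = 5) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  n <- length(series)
  if (n < 2 * n_blocks) stop("blocks would hold fewer than 2 samples")
  edges <- floor(seq(0, n, length.out = n_blocks + 1))
  blocks <- data.frame(block = seq_len(n_blocks), n = NA_integer_,
                       mean = NA_real_, sd = NA_real_)
  for (b in seq_len(n_blocks)) {
    seg <- series[(edges[b] + 1):edges[b + 1]]
    blocks$n[b] <- length(seg)
    blocks$mean[b] <- mean(seg)
    blocks$sd[b] <- stats::sd(seg)
  }
  pooled <- sqrt((blocks$sd[n_blocks - 1]^2 + blocks$sd[n_blocks]^2) / 2)
  converged <- abs(blocks$mean[n_blocks] - blocks$mean[n_blocks - 1]) <= pooled
  list(blocks = blocks, cumulative_mean = cumsum(series) / seq_len(n),
       converged = converged)
}
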