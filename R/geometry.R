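# Basic vector geometry used by every descriptor. All coordinates are in
# Angstrom; angles returned in degrees unless noted.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Minimal-image displacement under an orthorhombic box
#'
#' @param d displacement vector (or N x 3 matrix of displacements) in Angstrom.
#' @param box orthorhombic box lengths, length-3 numeric, or `NULL`/`NA` to
#'   skip periodic wrapping.
#' @return displacement with each component folded into `[-box/2, box/2)`.
#' @export
min_image <- function(d, box = NULL) {
  if (is.null(box) || anyNA(box)) return(d)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

#' Angle between two vectors
#'
#' @param v1,v2 numeric length-3 vectors.
#' @return angle in degrees in `[0, 180]`.
#' @export
angle_between <- function(v1, v2) {
  u1 <- unit_vec(v1); u2 <- unit_vec(v2)
  ct <- max(-1, min(1, sum(u1 * u2)))
  acos(ct) * 180 / pi
}

#' Signed dihedral angle of four points
#'
#' Standard torsion convention: the angle between the plane (p1,p2,p3) and
#' the plane (p2,p3,p4), signed right-handed about the p2->p3 axis.
#'
#' @param p1,p2,p3,p4 numeric length-3 points.
#' @return dihedral in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-10 || vec_norm(n2) < 1e-10)
    stop("degenerate dihedral: collinear points")
  b2u <- unit_vec(b2)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation minimising the RMSD between
#' `mobile` and `ref` over the fit atoms. The reflection branch of the SVD
#' solution is corrected to a proper rotation (det R = +1).
#'
#' @param mobile,ref N x 3 coordinate matrices with matching rows.
#' @param fit_idx row indices used for the fit (default: all rows).
#' @return list with `R` (3 x 3), `t` (length 3), `rmsd` (over fit atoms,
#'   Angstrom) and `coords`, the whole mobile frame after superposition.
#' @export
superpose_kabsch <- function(mobile, ref, fit_idx = NULL) {
  if (!is.matrix(mobile) || !is.matrix(ref) || ncol(mobile) != 3 ||
      ncol(ref) != 3 || nrow(mobile) != nrow(ref))
    stop("mobile and ref must be N x 3 matrices with equal atom counts")
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
  if (length(fit_idx) < 3) stop("need at least 3 atoms to superpose")
  pm <- mobile[fit_idx, , drop = FALSE]
  pr <- ref[fit_idx, , drop = FALSE]
  cm <- colMeans(pm); cr <- colMeans(pr)
  a <- crossprod(sweep(pm, 2, cm), sweep(pr, 2, cr))
  sv <- svd(a)
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted_fit <- sweep(pm, 2, cm) %*% rot
  fitted_fit <- sweep(fitted_fit, 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted_fit - pr)^2)))
  coords <- sweep(mobile, 2, cm) %*% rot
  coords <- sweep(coords, 2, cr, `+`)
  list(R = rot, t = cr - as.vector(cm %*% rot), rmsd = rmsd, coords = coords)
}

# Rotation matrix carrying unit vector `from` onto unit vector `to`
# (Rodrigues). Degenerate antiparallel case handled with an arbitrary
# perpendicular axis.
rotation_from_to <- function(from, to) {
  f <- unit_vec(from); t2 <- unit_vec(to)
  v <- cross3(f, t2)
  c_ <- sum(f * t2)
  if (vec_norm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    ax <- if (abs(f[1]) < 0.9) cross3(f, c(1, 0, 0)) else cross3(f, c(0, 1, 0))
    ax <- unit_vec(ax)
    return(rotation_axis_angle(ax, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

rotation_axis_angle <- function(axis, theta) {
  a <- unit_vec(axis)
  ct <- cos(theta); st <- sin(theta)
  ax <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * ax + (1 - ct) * (a %o% a)
}

# Uniform random proper rotation (used by invariance tests and generators).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
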