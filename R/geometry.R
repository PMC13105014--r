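## Low-level rigid-body and angular geometry used across modules.
## Coordinates are Angstrom throughout; angles in degrees unless noted.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric length-3 axis (need not be unit length).
#' @param theta_deg rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_about_axis <- function(axis, theta_deg) {
  a <- unit3(axis)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

rot_z <- function(theta_deg) rot_about_axis(c(0, 0, 1), theta_deg)

#' Optimal least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum || R p_i + t - q_i ||^2` over paired coordinate rows.
#'
#' @param P,Q n x 3 matrices of paired coordinates; `P` is moved onto `Q`.
#' @return list with `R` (3x3 proper rotation), `t` (length 3), and `rmsd`
#'   over the fitted atoms.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3) stop("need at least 3 paired atoms for superposition", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- unname(cq - as.vector(R %*% cp))
  Pf <- sweep(Pc %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((Pf - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Decompose a rigid transform into screw components
#'
#' Extracts the rotation axis, signed rotation angle and the axial
#' translation of a rigid motion `x -> R x + t`. The axis sign is chosen so
#' that the axial translation is non-negative when it is appreciable;
#' otherwise the axis is oriented toward positive z (then x, then y) for
#' determinism.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return list with `axis` (unit vector), `angle_deg` in (-180, 180],
#'   `translation` (signed axial component along `axis`), and `point`, a
#'   point on the screw axis (least-squares; the origin projection for
#'   near-pure translations).
#' @export
screw_decompose <- function(R, t) {
  tr <- (sum(diag(R)) - 1) / 2
  tr <- min(1, max(-1, tr))
  ang <- acos(tr) * 180 / pi   # unsigned, [0, 180]
  if (ang < 1e-7) {
    # pure translation: axis along t (or z if t ~ 0)
    axis <- if (sqrt(sum(t^2)) > 1e-9) unit3(t) else c(0, 0, 1)
    return(list(axis = axis, angle_deg = 0,
                translation = sum(t * axis), point = c(0, 0, 0)))
  }
  if (ang > 175) {
    # near-180 rotations: the antisymmetric part of R vanishes, so take
    # the +1 eigenvector of R instead
    ev <- eigen(R)
    i <- which.min(abs(Re(ev$values) - 1))
    axis <- unit3(Re(ev$vectors[, i]))
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    axis <- unit3(axis)  # sin-weighted; sign encodes rotation sense
  }
  # signed angle about this axis
  sang <- signed_angle_about(R, axis)
  tz <- sum(t * axis)
  # orient axis so translation is positive when meaningful
  if (tz < -1e-6) {
    axis <- -axis; sang <- -sang; tz <- -tz
  } else if (abs(tz) <= 1e-6) {
    ref <- if (abs(axis[3]) > 1e-6) axis[3] else if (abs(axis[1]) > 1e-6) axis[1] else axis[2]
    if (ref < 0) { axis <- -axis; sang <- -sang }
  }
  # point on axis: solve (I - R) p = t_perp in the plane normal to axis
  tp <- t - tz * axis
  A <- diag(3) - R
  p <- tryCatch(qr.solve(rbind(A, matrix(axis, 1, 3)), c(tp, 0)),
                error = function(e) c(0, 0, 0))
  list(axis = axis, angle_deg = sang, translation = tz, point = as.numeric(p))
}

## Signed rotation angle of R about a given unit axis, degrees in (-180, 180].
signed_angle_about <- function(R, axis) {
  a <- unit3(axis)
  # pick a reference vector perpendicular to the axis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(ref - sum(ref * a) * a)
  v <- as.vector(R %*% u)
  v <- v - sum(v * a) * a
  ang <- atan2(sum(cross3(u, v) * a), sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral angle of four points
#'
#' Standard signed torsion about the p2-p3 bond, degrees in (-180, 180].
#' Returns `NA` when any three consecutive points are (near-)collinear, in
#' which case the torsion is undefined.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in degrees, or `NA_real_` if degenerate.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) return(NA_real_)
  m1 <- cross3(unit3(b2), n1)
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Circular mean and standard deviation of angles
#'
#' Mean direction via the resultant vector; dispersion as the circular
#' standard deviation `sqrt(-2 log Rbar)` converted to degrees. `NA` values
#' are dropped.
#'
#' @param x angles in degrees.
#' @return for [circular_mean()] the mean angle in (-180, 180]; for
#'   [circular_sd()] the circular SD in degrees (0 for a single value).
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  ang <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' @rdname circular_mean
#' @export
circular_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  R <- min(1, R)
  sqrt(-2 * log(max(R, 1e-12))) * 180 / pi
}

#' Circular difference of two angles
#'
#' `a - b` wrapped into (-180, 180], so 179 vs -179 gives 2 degrees
#' short-way, not 358.
#'
#' @param a,b angles in degrees (vectorized).
#' @export
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
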