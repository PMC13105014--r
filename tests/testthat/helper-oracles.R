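## Independent oracles and fixture builders used across the test files.

## Horn's closed-form quaternion solution for the optimal superposition:
## an implementation independent of the SVD-based Kabsch path it checks.
horn_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- crossprod(Pc, Qc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  fit <- sweep(Pc %*% t(R), 2, cq, "+")
  sqrt(mean(rowSums((fit - Q)^2)))
}

## Four-point torsion oracle: same geometry, algebraically distinct path
## (explicit plane normals; the torsion sign from the normal triple product
## against the central bond).
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

rand_rotation <- function() {
  ax <- stats::rnorm(3)
  crossbeta:::rot_about_axis(ax, stats::runif(1, -180, 180))
}

## residues covered by a strand-segment table, one subunit
segment_residues <- function(segs, subunit = "A") {
  s <- segs[segs$subunit == subunit, , drop = FALSE]
  if (!nrow(s)) return(integer(0))
  sort(unlist(mapply(seq, s$start, s$end, SIMPLIFY = FALSE)))
}

## precision/recall of detected strand residues against a designed plan
strand_pr <- function(segs, plan, subunit = "A") {
  truth <- sort(unlist(lapply(plan, function(iv) iv[1]:iv[2])))
  det <- segment_residues(segs, subunit)
  c(precision = if (length(det)) length(intersect(det, truth)) / length(det) else 1,
    recall = length(intersect(det, truth)) / length(truth))
}

## apply a random rigid motion to every atom of a fibril model
transform_model <- function(m, R = rand_rotation(), t = stats::rnorm(3, 0, 20)) {
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m$atoms$x <- xyz[, 1] + t[1]
  m$atoms$y <- xyz[, 2] + t[2]
  m$atoms$z <- xyz[, 3] + t[3]
  m$subunit <- NULL; m$layer <- NULL; m$axis <- NULL
  m
}
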