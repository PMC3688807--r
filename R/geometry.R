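#' Internal-coordinate geometry
#'
#' Vector utilities shared by the coarse-grained and backbone potentials:
#' bond angles, torsions (IUPAC right-handed sign convention), their
#' analytic coordinate gradients, axis-angle rotations and circular means.
#' All angles are in radians unless a function name says degrees.
#'
#' @name geometry
#' @keywords internal
NULL

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## row-wise cross product for n x 3 matrices
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(a) sqrt(rowSums(a * a))

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the principal interval `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # map -pi to +pi so the interval is half-open
  y
}

#' Circular mean of angles
#'
#' @param x numeric vector of angles in radians.
#' @param w optional non-negative weights.
#' @return mean direction in `(-pi, pi]`.
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  atan2(sum(w * sin(x)), sum(w * cos(x)))
}

## angle at p2 subtended by p1, p3; vectorised over rows
angle_points <- function(p1, p2, p3) {
  if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3) }
  u <- p1 - p2
  v <- p3 - p2
  cu <- rownorm(u); cv <- rownorm(v)
  ct <- rowSums(u * v) / (cu * cv)
  ct <- pmin(1, pmax(-1, ct))
  acos(ct)
}

## signed torsion p1-p2-p3-p4, IUPAC right-handed; vectorised over rows
dihedral_points <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4) }
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  m1 <- rowcross(n1, b2 / rownorm(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x)
}

## gradient of the angle at p2 w.r.t. the three points (lists of n x 3)
angle_gradient <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cu <- rownorm(u); cv <- rownorm(v)
  uh <- u / cu; vh <- v / cv
  ct <- pmin(1, pmax(-1, rowSums(uh * vh)))
  st <- sqrt(pmax(1 - ct^2, 1e-14))
  g1 <- (ct * uh - vh) / (cu * st)
  g3 <- (ct * vh - uh) / (cv * st)
  list(g1 = g1, g2 = -(g1 + g3), g3 = g3)
}

## gradient of the torsion w.r.t. the four points (standard analytic form)
dihedral_gradient <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  nb2 <- rownorm(b2)
  n1sq <- pmax(rowSums(n1 * n1), 1e-14)
  n2sq <- pmax(rowSums(n2 * n2), 1e-14)
  g1 <- (nb2 / n1sq) * n1
  g4 <- -(nb2 / n2sq) * n2
  f12 <- rowSums(b1 * b2) / nb2^2
  f32 <- rowSums(b3 * b2) / nb2^2
  g2 <- -(1 + f12) * g1 + f32 * g4
  g3 <- f12 * g1 - (1 + f32) * g4
  list(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

#' Rotation matrix from axis and angle
#'
#' @param axis 3-vector (need not be unit length).
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  a <- vunit(axis)
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) * ca + sa * t(K) + (1 - ca) * outer(a, a)
}

## rotate rows of x about the line through `origin` with direction `axis`
rotate_about_axis <- function(x, origin, axis, angle) {
  R <- rotation_matrix(axis, angle)
  sweep((sweep(x, 2, origin) %*% t(R)), 2, origin, `+`)
}
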