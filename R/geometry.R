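#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

# wrap degrees into (-180, 180]
#' @keywords internal
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation about a (not necessarily unit) axis through the origin.
#'
#' @param axis numeric(3), rotation axis.
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing
#' \code{sum || R x_i + t - y_i ||^2} over paired points, i.e. the optimal
#' rigid motion carrying \code{mobile} onto \code{target}. Correspondence is
#' by row order.
#'
#' @param mobile n x 3 matrix of mobile coordinates (Angstrom).
#' @param target n x 3 matrix of target coordinates, same row order.
#' @return A \code{RigidTransform}: list with \code{rotation} (3x3, det +1),
#'   \code{translation} (length 3) and \code{rmsd} (post-fit, Angstrom).
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' tf <- superpose(pts, pts)
#' tf$rmsd  # 0
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) {
    stop("superpose(): point sets differ in cardinality (",
         nrow(mobile), " vs ", nrow(target), ")")
  }
  if (nrow(mobile) < 3L) stop("superpose(): need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)                       # 3x3 covariance
  sv <- svd(H)
  # degenerate (collinear / coincident) point sets have rank < 2
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-30)) {
    stop("superpose(): degenerate (collinear or coincident) point set")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(ct - R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param tf a \code{RigidTransform} from [superpose()].
#' @param xyz n x 3 coordinate matrix (or length-3 vector).
#' @return transformed coordinates, same shape.
#' @export
apply_transform <- function(tf, xyz) {
  v <- is.null(dim(xyz))
  m <- if (v) matrix(xyz, 1, 3) else as.matrix(xyz)
  out <- sweep(m %*% t(tf$rotation), 2, tf$translation, "+")
  if (v) as.numeric(out) else out
}

#' Rotation axis and angle of a rigid transform
#'
#' Extracts the unit eigenvector of the rotation matrix with eigenvalue 1
#' (the rotation axis) and the rotation magnitude. Near-identity rotations
#' have no defined axis and raise an error. The returned axis sign is fixed
#' so its z component (falling back to y, then x, when earlier components
#' vanish) is non-negative; domain-specific orientation rules are applied by
#' callers.
#'
#' @param transform a \code{RigidTransform} or a bare 3x3 rotation matrix.
#' @param min_angle smallest admissible rotation angle in degrees
#'   (default 0.5); below it the axis is considered undefined.
#' @return An \code{AxisAngle}: list with unit \code{axis} (length 3) and
#'   \code{angle} in degrees within \code{[0, 180]}.
#' @export
rotation_axis <- function(transform, min_angle = 0.5) {
  R <- if (is.matrix(transform)) transform else transform$rotation
  tr <- sum(diag(R))
  ang <- rad2deg(acos(max(-1, min(1, (tr - 1) / 2))))
  if (ang < min_angle) {
    stop("rotation_axis(): rotation angle ", format(ang),
         " deg below ", min_angle, " deg; axis undefined")
  }
  e <- eigen(R)
  i <- which.min(Mod(e$values - 1))
  ax <- Re(e$vectors[, i])
  ax <- ax / sqrt(sum(ax^2))
  # deterministic sign: first of (z, y, x) exceeding tolerance made positive
  for (j in c(3L, 2L, 1L)) {
    if (abs(ax[j]) > 1e-8) { if (ax[j] < 0) ax <- -ax; break }
  }
  if (max(abs(R %*% ax - ax)) > 1e-8) {
    stop("rotation_axis(): eigenvector extraction failed (R axis != axis)")
  }
  structure(list(axis = as.numeric(ax), angle = ang), class = "AxisAngle")
}

#' Signed torsion angle of four points
#'
#' IUPAC-signed dihedral of the points \code{p1-p2-p3-p4} about the central
#' \code{p2->p3} axis; cis = 0, trans = 180.
#'
#' @param p1,p2,p3,p4 numeric(3) positions.
#' @return angle in degrees in \code{(-180, 180]}.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-9 || sum(b1^2) < 1e-18 || sum(b3^2) < 1e-18) {
    stop("dihedral(): degenerate geometry (coincident points)")
  }
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18) {
    stop("dihedral(): degenerate geometry (collinear points)")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / nb2
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang == -180) ang <- 180
  ang
}

#' Angle between two vectors
#'
#' @param v1,v2 numeric(3) nonzero vectors.
#' @return angle in degrees in \code{[0, 180]}.
#' @export
angle_between <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("angle_between(): zero vector")
  rad2deg(acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))))
}

#' Center of mass of a point set
#'
#' @param points n x 3 matrix.
#' @param weights optional positive per-point weights; default uniform.
#' @return numeric(3) weighted mean position.
#' @export
center_of_mass <- function(points, weights = NULL) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("center_of_mass(): empty point set")
  if (is.null(weights)) return(colMeans(points))
  if (length(weights) != nrow(points) || any(weights <= 0)) {
    stop("center_of_mass(): weights must be positive, one per point")
  }
  as.numeric(crossprod(points, weights) / sum(weights))
}

#' Spherical coordinates of a direction
#'
#' Projects a vector onto the unit sphere: azimuth
#' \code{theta = atan2(y, x)} in \code{[-180, 180)} and polar angle
#' \code{phi = acos(z/||v||)} in \code{[0, 180]} from +z. The norm is
#' discarded. At the poles (phi = 0 or 180) theta is undefined and reported
#' as 0.
#'
#' @param v numeric(3), nonzero.
#' @return list with \code{theta} and \code{phi}, degrees.
#' @export
to_spherical <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("to_spherical(): zero vector")
  phi <- rad2deg(acos(max(-1, min(1, v[3] / n))))
  theta <- if (phi < 1e-9 || phi > 180 - 1e-9) 0 else rad2deg(atan2(v[2], v[1]))
  if (theta >= 180) theta <- theta - 360
  list(theta = theta, phi = phi)
}

#' Inverse of [to_spherical()]: unit vector from angles
#' @param theta azimuth, degrees.
#' @param phi polar angle from +z, degrees.
#' @return unit numeric(3).
#' @export
from_spherical <- function(theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
}
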