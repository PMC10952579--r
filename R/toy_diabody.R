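# Toy diabody generator. Site A is a canonical toy Fv (dyad axis +z); site B
# is a rigid copy placed so that the measured four-Trp dihedral and diabody
# angle equal requested values exactly:
#   * the copy's dyad axis is tilted to a = (sin(angle), 0, cos(angle)), so
#     the angle between oriented axes is the requested one by construction;
#   * the residual spin about a itself (which cannot change the angle) is the
#     closed-form root of a linear-in-(cos, sin) equation that sets the
#     four-anchor dihedral; infeasible pairs are rejected.

# cross product
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dihedral components (x = cos-part, y = sin-part before atan2) of the
# quadruple (w, h, h + d*xhat, h + d*xhat + u), as linear forms in u
#' @keywords internal
dihedral_xy_of_u <- function(v, d, u) {
  # v = w - h points from the VH anchor to the VL anchor of site A
  b1 <- -v                      # p2 - p1
  b2 <- c(d, 0, 0)              # p3 - p2
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, u)
  m1 <- cross3(n1, b2 / d)
  c(x = sum(n1 * n2), y = sum(m1 * n2))
}

# solve the spin rho (degrees) such that the dihedral of the four anchors
# equals target_deg; returns NULL when infeasible
#' @keywords internal
solve_spin <- function(v, a, w0, d, target_deg) {
  # u(rho) = cos(rho) P + sin(rho) Q + S  (Rodrigues about unit axis a)
  S <- a * sum(a * w0)
  P <- w0 - S
  Q <- cross3(a, w0)
  xyP <- dihedral_xy_of_u(v, d, P)
  xyQ <- dihedral_xy_of_u(v, d, Q)
  xyS <- dihedral_xy_of_u(v, d, S)
  dt <- deg2rad(target_deg)
  G <- xyP["y"] * cos(dt) - xyP["x"] * sin(dt)
  H <- xyQ["y"] * cos(dt) - xyQ["x"] * sin(dt)
  K <- xyS["y"] * cos(dt) - xyS["x"] * sin(dt)
  Rm <- sqrt(G^2 + H^2)
  cand <- if (Rm < 1e-12) {
    if (abs(K) > 1e-9) return(NULL)
    c(0, 180)                      # degenerate family: try the two poles
  } else {
    if (abs(K) > Rm * (1 + 1e-12)) return(NULL)
    ph0 <- atan2(H, G)
    dd <- acos(max(-1, min(1, -K / Rm)))
    rad2deg(c(ph0 + dd, ph0 - dd))
  }
  for (rho in cand) {
    u <- cos(deg2rad(rho)) * P + sin(deg2rad(rho)) * Q + S
    xy <- dihedral_xy_of_u(v, d, u)
    meas <- rad2deg(atan2(xy["y"], xy["x"]))
    if (abs(wrap180(meas - target_deg)) < 1e-6) return(wrap180(rho))
  }
  NULL
}

# rigid placement of site B for requested (dihedral, angle); returns
# list(R, t, axis_b) or NULL if infeasible
#' @keywords internal
place_site_b <- function(truth_a, dihedral, angle, separation) {
  h <- truth_a$anchor_vh
  w <- truth_a$anchor_vl
  v <- w - h
  a <- c(sin(deg2rad(angle)), 0, cos(deg2rad(angle)))
  Ry <- rotation_about_axis(c(0, 1, 0), angle)
  w0 <- as.numeric(Ry %*% v)
  rho <- solve_spin(v, a, w0, separation, dihedral)
  if (is.null(rho)) return(NULL)
  R <- rotation_about_axis(a, rho) %*% Ry
  t <- h + c(separation, 0, 0) - as.numeric(R %*% h)
  list(R = R, t = t, axis_b = a, rho = rho)
}

#' Build a toy diabody with requested dihedral and diabody angle
#'
#' Assembles two C2-exact toy Fvs: site A in the canonical pose (dyad axis
#' +z) and site B a rigid copy solved analytically so that the measured
#' four-anchor dihedral and the angle between the two oriented pseudo-dyad
#' axes equal the requested values (to numerical precision). Infeasible
#' combinations — notably any nonzero dihedral at angle 0 or 180, where the
#' construction degenerates — are rejected with an error.
#'
#' @param spec a [toy_fv_spec()].
#' @param dihedral requested four-Trp dihedral, degrees in \code{(-180, 180]}.
#' @param angle requested diabody angle, degrees in \code{[0, 180]}.
#' @param separation V_H-anchor to V_H-anchor distance, Angstrom (default 30).
#' @return list with \code{model}, \code{defn} (two-site definition; site B
#'   on chains I/M), and \code{truth}: requested \code{dihedral} and
#'   \code{angle}, oriented axes \code{axis_a}, \code{axis_b}, the site-B
#'   placement (\code{R}, \code{t}), anchors, domain CA centroids, and the
#'   site-A construction record.
#' @export
build_toy_diabody <- function(spec = toy_fv_spec(), dihedral, angle,
                              separation = 30) {
  if (angle < 0 || angle > 180) {
    stop("build_toy_diabody(): angle must lie in [0, 180]")
  }
  fv <- build_toy_fv(spec, chains = c("H", "L"))
  pl <- place_site_b(fv$truth, dihedral, angle, separation)
  if (is.null(pl)) {
    stop("build_toy_diabody(): infeasible (dihedral, angle) pair (",
         dihedral, ", ", angle, ")")
  }
  a_atoms <- fv$model$atoms
  b_atoms <- a_atoms
  b_atoms$chain <- c(H = "I", L = "M")[b_atoms$chain]
  # x_B = R (x - h) + h + separation * xhat
  xyz_b <- sweep(sweep(coords(fv$model), 2, fv$truth$anchor_vh) %*% t(pl$R),
                 2, fv$truth$anchor_vh + c(separation, 0, 0), "+")
  b_atoms$x <- xyz_b[, 1]; b_atoms$y <- xyz_b[, 2]; b_atoms$z <- xyz_b[, 3]
  model <- structure_model(rbind(a_atoms, b_atoms))
  defn <- domain_definition(list(A = toy_site_def(spec, "H", "L"),
                                 B = toy_site_def(spec, "I", "M")))
  gB <- function(x) as.numeric(pl$R %*% (x - fv$truth$anchor_vh)) +
    fv$truth$anchor_vh + c(separation, 0, 0)
  truth <- list(
    dihedral = wrap180(dihedral), angle = angle,
    axis_a = c(0, 0, 1), axis_b = pl$axis_b,
    R = pl$R, t = pl$t, separation = separation, spin = pl$rho,
    anchor_vh_a = fv$truth$anchor_vh, anchor_vl_a = fv$truth$anchor_vl,
    anchor_vh_b = gB(fv$truth$anchor_vh), anchor_vl_b = gB(fv$truth$anchor_vl),
    centroid_vh_a = fv$truth$centroid_vh, centroid_vl_a = fv$truth$centroid_vl,
    centroid_vh_b = gB(fv$truth$centroid_vh),
    centroid_vl_b = gB(fv$truth$centroid_vl),
    hinge_centroid = fv$truth$hinge_centroid,
    fv = fv$truth
  )
  list(model = model, defn = defn, truth = truth)
}

#' Build a toy diabody with exact two-fold exchange symmetry
#'
#' Site B is the image of site A under a 180-degree rotation about an axis
#' parallel to x, displaced along y. The whole construct therefore has an
#' exact C2 that swaps the two Fvs, so the two sphere projections of
#' [dual_projection()] coincide exactly.
#'
#' @param spec a [toy_fv_spec()].
#' @param y_offset displacement of the exchange axis along y, Angstrom
#'   (default 18; site B sits at about twice this from site A).
#' @return list with \code{model}, \code{defn}, \code{truth} (includes the
#'   exchange \code{R}, \code{t} and the resulting dihedral/angle).
#' @export
build_toy_diabody_c2 <- function(spec = toy_fv_spec(), y_offset = 18) {
  fv <- build_toy_fv(spec, chains = c("H", "L"))
  R <- rotation_about_axis(c(1, 0, 0), 180)
  p0 <- c(0, y_offset, 0)
  gB <- function(x) as.numeric(R %*% (x - p0)) + p0
  a_atoms <- fv$model$atoms
  b_atoms <- a_atoms
  b_atoms$chain <- c(H = "I", L = "M")[b_atoms$chain]
  xyz_b <- sweep(sweep(coords(fv$model), 2, p0) %*% t(R), 2, p0, "+")
  b_atoms$x <- xyz_b[, 1]; b_atoms$y <- xyz_b[, 2]; b_atoms$z <- xyz_b[, 3]
  model <- structure_model(rbind(a_atoms, b_atoms))
  defn <- domain_definition(list(A = toy_site_def(spec, "H", "L"),
                                 B = toy_site_def(spec, "I", "M")))
  # dihedral_order default is vl_A, vh_A, vh_B, vl_B
  di <- dihedral(fv$truth$anchor_vl, fv$truth$anchor_vh,
                 gB(fv$truth$anchor_vh), gB(fv$truth$anchor_vl))
  truth <- list(
    dihedral = di,
    angle = angle_between(c(0, 0, 1), as.numeric(R %*% c(0, 0, 1))),
    axis_a = c(0, 0, 1), axis_b = as.numeric(R %*% c(0, 0, 1)),
    R = R, t = as.numeric(p0 - R %*% p0),
    fv = fv$truth
  )
  list(model = model, defn = defn, truth = truth)
}

#' Generator-side ground truth for the dual sphere projections
#'
#' Predicts, from a solved toy diabody's construction record alone (no call
#' into the measurement pipeline), the spherical coordinates the sphere
#' projection must report: the canonical-frame map of site A is written down
#' directly from the stored hinge centroid and V_H sheet centroid, the
#' site-B placement is the stored rigid motion, and the align-B projection
#' uses its exact inverse.
#'
#' @param truth the \code{truth} element of [build_toy_diabody()].
#' @return data frame with two rows (aligned_site A, B) and columns
#'   theta_vh, phi_vh, theta_vl, phi_vl (degrees).
#' @export
toy_projection_truth <- function(truth) {
  spec <- truth$fv$spec
  s <- 2:(spec$n_res - 1)                       # sheet residues
  g <- truth$hinge_centroid
  ch <- colMeans(truth$fv$ca_vh[s, , drop = FALSE]) - g
  Rz <- rotation_about_axis(c(0, 0, 1), -rad2deg(atan2(ch[2], ch[1])))
  t_ref <- function(x) as.numeric(Rz %*% (x - g))
  h <- truth$anchor_vh_a
  d <- truth$separation
  g_b <- function(x) as.numeric(truth$R %*% (x - h)) + h + c(d, 0, 0)
  g_b_inv <- function(x) as.numeric(t(truth$R) %*% (x - h - c(d, 0, 0))) + h
  com_vh <- truth$centroid_vh_a
  com_vl <- truth$centroid_vl_a
  row <- function(site, pvh, pvl) {
    svh <- to_spherical(pvh); svl <- to_spherical(pvl)
    data.frame(aligned_site = site,
               theta_vh = svh$theta, phi_vh = svh$phi,
               theta_vl = svl$theta, phi_vl = svl$phi)
  }
  rbind(row("A", t_ref(g_b(com_vh)), t_ref(g_b(com_vl))),
        row("B", t_ref(g_b_inv(com_vh)), t_ref(g_b_inv(com_vl))))
}
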