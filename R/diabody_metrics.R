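# Inter-Fv descriptors: the four-tryptophan dihedral, the pseudo-dyad
# diabody angle, and unit-sphere projections of domain centers of mass.

#' Minimal rotation carrying one direction onto another
#' @keywords internal
rotation_from_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # antiparallel: rotate 180 deg about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * p[3] - a[3] * p[2],
            a[3] * p[1] - a[1] * p[3],
            a[1] * p[2] - a[2] * p[1])
    return(rotation_about_axis(ax, 180))
  }
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  rotation_about_axis(ax, rad2deg(acos(max(-1, min(1, d)))))
}

# CA position of a single-residue selection
#' @keywords internal
anchor_ca <- function(model, defn, name) {
  idx <- resolve_selection(model, defn, name, "CA-only")
  if (length(idx) != 1L) stop("anchor '", name, "' is not a single residue")
  as.numeric(coords(model)[idx, ])
}

#' Inter-Fv diabody dihedral over the four anchor tryptophan CA atoms
#'
#' The signed torsion spanned by the CA atoms of the four conserved anchor
#' tryptophans (one per variable domain), taken in the order declared by
#' \code{defn$dihedral_order}. The default order \code{vl_A, vh_A, vh_B,
#' vl_B} places the central virtual bond across the V_H-V_H interface.
#'
#' @param model a \code{StructureModel} of a two-Fv construct.
#' @param defn a \code{DomainDefinition} with sites A and B.
#' @return dihedral in degrees in \code{(-180, 180]}.
#' @export
diabody_dihedral <- function(model, defn) {
  ord <- defn$dihedral_order
  stopifnot(length(ord) == 4L)
  p <- lapply(ord, function(tok) {
    m <- regmatches(tok, regexec("^(vh|vl)_([AB])$", tok))[[1]]
    if (length(m) != 3L) stop("diabody_dihedral(): bad anchor token '", tok, "'")
    anchor_ca(model, defn, paste0("anchor_trp_", m[2], "_", m[3]))
  })
  dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Oriented pseudo-dyad axis of one Fv
#'
#' The approximate two-fold axis relating V_H and V_L: the rotation axis
#' (unit eigenvector with eigenvalue 1) of the least-squares superposition of
#' the V_H CA atoms onto their V_L equivalents, using the site's declared
#' residue-equivalence table. The sign is fixed by the C-to-N rule: the axis
#' is directed so its dot product with (N-terminal anchor CA minus C-terminal
#' anchor CA) is positive.
#'
#' @param model a \code{StructureModel}.
#' @param defn a \code{DomainDefinition}.
#' @param site \code{"A"} or \code{"B"}.
#' @return oriented unit numeric(3).
#' @export
pseudo_dyad_axis <- function(model, defn, site) {
  st <- defn$sites[[site]]
  if (is.null(st)) stop("pseudo_dyad_axis(): no site '", site, "'")
  eq <- st$equivalence
  if (is.null(eq)) {
    stop("pseudo_dyad_axis(): site ", site, " has no V_H-V_L equivalence table")
  }
  sel_h <- resref(eq$chain_vh, eq$resno_vh, eq$insert_vh)
  sel_l <- resref(eq$chain_vl, eq$resno_vl, eq$insert_vl)
  ih <- resolve_residues(model, sel_h, "CA-only", "equivalence/vh")
  il <- resolve_residues(model, sel_l, "CA-only", "equivalence/vl")
  tf <- superpose(coords(model)[ih, , drop = FALSE],
                  coords(model)[il, , drop = FALSE])
  ax <- rotation_axis(tf)$axis
  nt <- anchor_ca(model, defn, paste0("nterm_", site))
  ct <- anchor_ca(model, defn, paste0("cterm_", site))
  if (sum(ax * (nt - ct)) < 0) ax <- -ax
  ax
}

#' Diabody angle between the two oriented pseudo-dyad axes
#'
#' @inheritParams diabody_dihedral
#' @return angle in degrees in \code{[0, 180]}; symmetric in site order.
#' @export
diabody_angle <- function(model, defn) {
  a <- pseudo_dyad_axis(model, defn, "A")
  b <- pseudo_dyad_axis(model, defn, "B")
  angle_between(a, b)
}

#' Sphere projection of the non-aligned Fv's domain centers of mass
#'
#' Superposes the aligned site's beta-sheet CA atoms onto the canonical
#' reference frame, applies the fitted transform to the other site's V_H and
#' V_L centers of mass, and projects them onto the unit sphere around the
#' reference origin (the hinge centroid).
#'
#' @param model a \code{StructureModel}.
#' @param defn a \code{DomainDefinition} with sites A and B.
#' @param reference a \code{ReferenceFrame} from [build_reference_frame()].
#' @param aligned_site site superposed onto the reference (\code{"A"}/\code{"B"}).
#' @param com one of \code{"CA"} (default: unweighted CA atoms of the
#'   domain's residues) or \code{"heavy"} (all atoms, mass-weighted).
#' @return list with elements \code{vh} and \code{vl}, each a
#'   \code{list(theta, phi)} in degrees.
#' @export
sphere_projection <- function(model, defn, reference, aligned_site,
                              com = c("CA", "heavy")) {
  com <- match.arg(com)
  other <- setdiff(c("A", "B"), aligned_site)
  if (length(other) != 1L || is.null(defn$sites[[other]])) {
    stop("sphere_projection(): need two declared sites")
  }
  ia <- c(resolve_selection(model, defn, paste0("sheet_vh_", aligned_site), "CA-only"),
          resolve_selection(model, defn, paste0("sheet_vl_", aligned_site), "CA-only"))
  if (length(ia) != nrow(reference$coords)) {
    stop("sphere_projection(): beta-sheet correspondence mismatch (",
         length(ia), " model CA vs ", nrow(reference$coords), " reference)")
  }
  tf <- superpose(coords(model)[ia, , drop = FALSE], reference$coords)
  out <- list()
  for (dm in c("vh", "vl")) {
    cm <- domain_com(model, defn, paste0(dm, "_", other), com)
    out[[dm]] <- to_spherical(apply_transform(tf, cm))
  }
  out
}

# center of mass of a domain selection
#' @keywords internal
domain_com <- function(model, defn, name, com = "CA") {
  if (com == "CA") {
    idx <- resolve_selection(model, defn, name, "CA-only")
    return(center_of_mass(coords(model)[idx, , drop = FALSE]))
  }
  idx <- resolve_selection(model, defn, name, "all")
  el <- substr(model$atoms$elety[idx], 1, 1)
  mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)[el]
  mass[is.na(mass)] <- 12.011
  center_of_mass(coords(model)[idx, , drop = FALSE], weights = as.numeric(mass))
}

#' Per-frame diabody geometry with dual sphere projections
#'
#' For every trajectory frame computes the diabody dihedral, the diabody
#' angle, and both sphere projections (site A aligned, then site B aligned;
#' the dual alignment doubles the projection statistics).
#'
#' @param traj a \code{Trajectory}.
#' @param defn a \code{DomainDefinition} with sites A and B.
#' @param reference a \code{ReferenceFrame}.
#' @param on_error \code{"fail"} (default) stops at the first bad frame,
#'   reporting its index; \code{"skip"} drops bad frames with a warning.
#' @param com passed to [sphere_projection()].
#' @return list with data frames \code{angles} (frame, dihedral,
#'   diabody_angle; one row per frame) and \code{projections} (frame,
#'   aligned_site, theta_vh, phi_vh, theta_vl, phi_vl; two rows per frame).
#' @export
dual_projection <- function(traj, defn, reference,
                            on_error = c("fail", "skip"), com = "CA") {
  on_error <- match.arg(on_error)
  n <- nframes(traj)
  ang <- vector("list", n); prj <- vector("list", n)
  for (f in seq_len(n)) {
    res <- tryCatch({
      m <- frame(traj, f)
      di <- diabody_dihedral(m, defn)
      da <- diabody_angle(m, defn)
      rows <- lapply(c("A", "B"), function(s) {
        p <- sphere_projection(m, defn, reference, s, com = com)
        data.frame(frame = f, aligned_site = s,
                   theta_vh = p$vh$theta, phi_vh = p$vh$phi,
                   theta_vl = p$vl$theta, phi_vl = p$vl$phi)
      })
      list(ang = data.frame(frame = f, dihedral = di, diabody_angle = da),
           prj = do.call(rbind, rows))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("frame ", f, ": ", conditionMessage(res))
      if (on_error == "fail") stop("dual_projection(): ", msg)
      warning("dual_projection(): skipping ", msg)
      next
    }
    ang[[f]] <- res$ang; prj[[f]] <- res$prj
  }
  list(angles = do.call(rbind, ang), projections = do.call(rbind, prj))
}
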