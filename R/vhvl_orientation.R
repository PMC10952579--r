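#' Six-measure V_H-V_L packing descriptor
#'
#' Describes the relative orientation of the two variable domains of one Fv,
#' in the style of cylindrical-domain orientation analyses, with four bend
#' angles, one inter-domain distance and one torsion. The construction is
#' deterministic and fixed by this package (values are comparable across runs
#' sharing a reference, not bit-compatible with external tools):
#'
#' 1. Each domain's beta-sheet CA set in the reference frame defines two
#'    canonical unit vectors, the long axis \code{L} and in-plane
#'    perpendicular \code{P} (first and second principal axes, sign-fixed
#'    toward the N-terminal sheet residue).
#' 2. The reference domain is superposed onto the model domain's sheet CA,
#'    transferring \code{L} and \code{P} into the frame's pose.
#' 3. With \code{C} the segment from the V_H to the V_L sheet centroid:
#'    \code{dc = |C|}; \code{a1, a2} are the angles of \code{L_H, P_H} to
#'    \code{C}; \code{a3, a4} those of \code{L_L, P_L} to \code{-C}; and
#'    \code{tor} is the IUPAC torsion \code{L_H - centroid_H - centroid_L -
#'    L_L}.
#'
#' @param model a \code{StructureModel}.
#' @param defn a \code{DomainDefinition}.
#' @param site which Fv to measure (\code{"A"} or \code{"B"}).
#' @param reference a \code{ReferenceFrame} providing the canonical vectors.
#' @return an \code{OrientationMeasures} list: \code{dc} (Angstrom),
#'   \code{tor} (degrees, \code{(-180, 180]}), \code{a1..a4} (degrees,
#'   \code{[0, 180]}).
#' @export
vhvl_orientation_measures <- function(model, defn, site, reference) {
  ih <- resolve_selection(model, defn, paste0("sheet_vh_", site), "CA-only")
  il <- resolve_selection(model, defn, paste0("sheet_vl_", site), "CA-only")
  if (length(ih) != reference$n_vh ||
      length(il) != nrow(reference$coords) - reference$n_vh) {
    stop("vhvl_orientation_measures(): sheet mask does not match reference")
  }
  xyz <- coords(model)
  vh_rows <- seq_len(reference$n_vh)
  vl_rows <- setdiff(seq_len(nrow(reference$coords)), vh_rows)
  tf_h <- superpose(reference$coords[vh_rows, , drop = FALSE],
                    xyz[ih, , drop = FALSE])
  tf_l <- superpose(reference$coords[vl_rows, , drop = FALSE],
                    xyz[il, , drop = FALSE])
  LH <- as.numeric(tf_h$rotation %*% reference$axes$vh$L)
  PH <- as.numeric(tf_h$rotation %*% reference$axes$vh$P)
  LL <- as.numeric(tf_l$rotation %*% reference$axes$vl$L)
  PL <- as.numeric(tf_l$rotation %*% reference$axes$vl$P)
  cen_h <- colMeans(xyz[ih, , drop = FALSE])
  cen_l <- colMeans(xyz[il, , drop = FALSE])
  C <- cen_l - cen_h
  dc <- sqrt(sum(C^2))
  if (dc < 1e-9) stop("vhvl_orientation_measures(): coincident domain centroids")
  structure(list(
    dc = dc,
    tor = dihedral(cen_h + LH, cen_h, cen_l, cen_l + LL),
    a1 = angle_between(LH, C),
    a2 = angle_between(PH, C),
    a3 = angle_between(LL, -C),
    a4 = angle_between(PL, -C)
  ), class = "OrientationMeasures")
}

#' @export
print.OrientationMeasures <- function(x, ...) {
  cat(sprintf("VH-VL orientation: dc=%.2f A tor=%.1f a1=%.1f a2=%.1f a3=%.1f a4=%.1f\n",
              x$dc, x$tor, x$a1, x$a2, x$a3, x$a4))
  invisible(x)
}

#' V_H-V_L orientation measures over a trajectory
#'
#' @param traj a \code{Trajectory}.
#' @param defn a \code{DomainDefinition}.
#' @param site site to measure.
#' @param reference a \code{ReferenceFrame}.
#' @return data frame with one row per frame: frame, dc, tor, a1..a4.
#' @export
vhvl_orientation_trajectory <- function(traj, defn, site, reference) {
  rows <- lapply(seq_len(nframes(traj)), function(f) {
    m <- vhvl_orientation_measures(frame(traj, f), defn, site, reference)
    data.frame(frame = f, dc = m$dc, tor = m$tor,
               a1 = m$a1, a2 = m$a2, a3 = m$a3, a4 = m$a4)
  })
  do.call(rbind, rows)
}
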