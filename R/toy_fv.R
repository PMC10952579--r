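# Synthetic Fv constructs with analytic ground truth. The scaffolds are
# ideal-geometry helices placed so that V_L is the exact image of V_H under a
# 180-degree rotation about the dyad axis (C2-exact), which makes every
# downstream descriptor exactly computable from the construction parameters.

#' Specification of a toy Fv
#'
#' @param n_res residues per pseudo-domain (>= 8; >= 12 when CDR loops are
#'   generated).
#' @param offset radial distance of the V_H helix centroid from the dyad
#'   axis, Angstrom.
#' @param anchor_res index of the tryptophan-equivalent anchor residue.
#' @param hinge_res index of the hinge residue (default: last residue).
#' @param phi,psi scaffold backbone torsions (degrees), recycled over
#'   residues; the default is helix-like.
#' @param cdr logical: declare default CDR loop ranges (needs n_res >= 12).
#' @return a \code{ToyFvSpec} list.
#' @export
toy_fv_spec <- function(n_res = 12L, offset = 12, anchor_res = NULL,
                        hinge_res = NULL, phi = -57, psi = -47, cdr = TRUE) {
  if (n_res < 8L) stop("toy_fv_spec(): need at least 8 residues per domain")
  if (cdr && n_res < 12L) stop("toy_fv_spec(): CDR loops need n_res >= 12")
  list(n_res = as.integer(n_res), offset = offset,
       anchor_res = if (is.null(anchor_res)) ceiling(n_res / 2) else anchor_res,
       hinge_res = if (is.null(hinge_res)) n_res else hinge_res,
       phi = rep_len(phi, n_res), psi = rep_len(psi, n_res), cdr = cdr)
}

# build one domain scaffold in canonical placement:
# helix rotated so (CA_1 - CA_n) lies exactly along +z, centroid at
# (offset, 0, 0)
#' @keywords internal
build_domain <- function(spec, chain) {
  resid <- rep("ALA", spec$n_res)
  resid[spec$anchor_res] <- "TRP"
  pep <- build_peptide(spec$phi, spec$psi, chain = chain, resid = resid)
  xyz <- coords(pep)
  ca <- xyz[pep$atoms$elety == "CA", , drop = FALSE]
  v <- ca[1, ] - ca[spec$n_res, ]
  R <- rotation_from_to(v, c(0, 0, 1))
  xyz <- xyz %*% t(R)
  cen <- colMeans(xyz[pep$atoms$elety == "CA", , drop = FALSE])
  xyz <- sweep(xyz, 2, cen - c(spec$offset, 0, 0))
  set_coords(pep, xyz)
}

# site definition tables for chains (ch_vh, ch_vl)
#' @keywords internal
toy_site_def <- function(spec, ch_vh, ch_vl) {
  n <- spec$n_res
  sheet <- 2:(n - 1)
  st <- list(
    vh = resref(ch_vh, 1:n), vl = resref(ch_vl, 1:n),
    sheet_vh = resref(ch_vh, sheet), sheet_vl = resref(ch_vl, sheet),
    anchor_trp_vh = resref(ch_vh, spec$anchor_res),
    anchor_trp_vl = resref(ch_vl, spec$anchor_res),
    hinge = rbind(resref(ch_vh, spec$hinge_res), resref(ch_vl, spec$hinge_res)),
    nterm = resref(ch_vh, 1), cterm = resref(ch_vh, n),
    equivalence = data.frame(chain_vh = ch_vh, resno_vh = 1:n, insert_vh = "",
                             chain_vl = ch_vl, resno_vl = 1:n, insert_vl = "",
                             stringsAsFactors = FALSE)
  )
  if (spec$cdr) {
    st$cdr <- list(H1 = resref(ch_vh, 3:5), H2 = resref(ch_vh, 6:8),
                   H3 = resref(ch_vh, 9:11), L1 = resref(ch_vl, 3:5),
                   L2 = resref(ch_vl, 6:8), L3 = resref(ch_vl, 9:11))
  }
  st
}

#' Build a toy Fv with exact C2 symmetry
#'
#' Constructs a two-domain Fv analog: an ideal-geometry V_H scaffold placed
#' off the z axis, and a V_L that is its exact image under a 180-degree
#' rotation about the dyad axis. By construction the V_H to V_L superposition
#' rotation axis is exactly the dyad axis, and the C-to-N orientation rule
#' resolves its sign to the stored ground-truth direction.
#'
#' @param spec a [toy_fv_spec()].
#' @param dyad_axis desired dyad axis direction (default +z); the canonical
#'   construct is rigidly rotated so its +z axis maps onto this direction.
#' @param pose optional extra rigid motion, \code{list(R, t)}, applied last.
#' @param chains chain ids for (V_H, V_L), default \code{c("H", "L")}.
#' @return list with \code{model} (\code{StructureModel}), \code{defn}
#'   (single-site \code{DomainDefinition}), and \code{truth}: the exact
#'   oriented dyad axis, anchor CA positions, domain CA centroids, hinge
#'   centroid, and sheet residue indices.
#' @export
build_toy_fv <- function(spec = toy_fv_spec(), dyad_axis = c(0, 0, 1),
                         pose = NULL, chains = c("H", "L")) {
  vh <- build_domain(spec, chains[1])
  Rz <- rotation_about_axis(c(0, 0, 1), 180)
  vl <- set_coords(vh, coords(vh) %*% t(Rz))
  vl$atoms$chain <- chains[2]
  atoms <- rbind(vh$atoms, vl$atoms)
  model <- structure_model(atoms)
  defn <- domain_definition(list(A = toy_site_def(spec, chains[1], chains[2])))
  # ground truth in the canonical pose
  ca_h <- coords(vh)[vh$atoms$elety == "CA", , drop = FALSE]
  truth <- list(
    dyad_axis = c(0, 0, 1),
    anchor_vh = as.numeric(ca_h[spec$anchor_res, ]),
    anchor_vl = as.numeric(Rz %*% ca_h[spec$anchor_res, ]),
    centroid_vh = colMeans(ca_h),
    centroid_vl = as.numeric(Rz %*% colMeans(ca_h)),
    hinge_centroid = c(0, 0, ca_h[spec$hinge_res, 3]),
    ca_vh = ca_h,
    ca_vl = ca_h %*% t(Rz),
    spec = spec
  )
  # optional re-orientation of the whole construct
  R <- rotation_from_to(c(0, 0, 1), dyad_axis)
  t <- c(0, 0, 0)
  if (!is.null(pose)) { t <- pose$t + c(0, 0, 0); R <- pose$R %*% R }
  if (max(abs(R - diag(3))) > 0 || any(t != 0)) {
    model <- set_coords(model, sweep(coords(model) %*% t(R), 2, t, "+"))
    for (nm in c("anchor_vh", "anchor_vl", "centroid_vh", "centroid_vl",
                 "hinge_centroid")) {
      truth[[nm]] <- as.numeric(R %*% truth[[nm]] + t)
    }
    truth$dyad_axis <- as.numeric(R %*% truth$dyad_axis)
    truth$ca_vh <- sweep(truth$ca_vh %*% t(R), 2, t, "+")
    truth$ca_vl <- sweep(truth$ca_vl %*% t(R), 2, t, "+")
  }
  list(model = model, defn = defn, truth = truth)
}
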