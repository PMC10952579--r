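#' Build the canonical Fv reference frame
#'
#' Extracts the beta-sheet CA atoms of one Fv and expresses them in the
#' canonical frame used by the sphere projection and the VH-VL orientation
#' measures: the hinge-residue CA centroid is translated to the origin, the
#' oriented pseudo-dyad axis is rotated onto +z, and the structure is spun
#' about z so the V_H beta-sheet centroid sits at azimuth theta = 0. The
#' azimuth gauge is this package's own convention: absolute theta values are
#' only comparable between runs that share a reference.
#'
#' Canonical unit vectors for the cylindrical-domain orientation measures are
#' derived per domain from the sheet CA coordinates: the long axis \code{L}
#' (first principal axis) and in-plane perpendicular \code{P} (second
#' principal axis), each sign-fixed toward the domain's first (N-terminal)
#' sheet residue.
#'
#' @param model a \code{StructureModel}.
#' @param defn a \code{DomainDefinition}.
#' @param site which Fv to canonicalize (\code{"A"} or \code{"B"}).
#' @return a \code{ReferenceFrame}: list with \code{coords} (sheet CA in the
#'   canonical frame, V_H rows first), \code{residues}, \code{n_vh},
#'   \code{site}, \code{centroid_vh}, \code{centroid_vl}, \code{axes}
#'   (canonical L/P vectors per domain) and \code{transform} (the
#'   \code{RigidTransform} that carried the model into the canonical frame).
#' @export
build_reference_frame <- function(model, defn, site) {
  st <- defn$sites[[site]]
  if (is.null(st)) stop("build_reference_frame(): no site '", site, "'")
  if (nrow(st$sheet_vh) == 0L || nrow(st$sheet_vl) == 0L) {
    stop("build_reference_frame(): empty beta-sheet mask")
  }
  ih <- resolve_selection(model, defn, paste0("sheet_vh_", site), "CA-only")
  il <- resolve_selection(model, defn, paste0("sheet_vl_", site), "CA-only")
  hinge <- resolve_selection(model, defn, paste0("hinge_", site), "CA-only")
  xyz <- coords(model)
  g <- colMeans(xyz[hinge, , drop = FALSE])
  axis <- pseudo_dyad_axis(model, defn, site)
  R1 <- rotation_from_to(axis, c(0, 0, 1))
  sheet <- sweep(xyz[c(ih, il), , drop = FALSE], 2, g) %*% t(R1)
  nvh <- length(ih)
  ch <- colMeans(sheet[seq_len(nvh), , drop = FALSE])
  theta_h <- atan2(ch[2], ch[1])
  R2 <- rotation_about_axis(c(0, 0, 1), -rad2deg(theta_h))
  sheet <- sheet %*% t(R2)
  R <- R2 %*% R1
  tf <- structure(list(rotation = R, translation = as.numeric(-R %*% g),
                       rmsd = 0), class = "RigidTransform")
  if (max(abs(as.numeric(R %*% axis) - c(0, 0, 1))) > 1e-6) {
    stop("build_reference_frame(): dyad axis failed to canonicalize")
  }
  vh_rows <- seq_len(nvh)
  vl_rows <- setdiff(seq_len(nrow(sheet)), vh_rows)
  res <- rbind(cbind(st$sheet_vh, domain = "vh"),
               cbind(st$sheet_vl, domain = "vl"))
  structure(list(
    coords = sheet,
    residues = res,
    n_vh = nvh,
    site = site,
    centroid_vh = colMeans(sheet[vh_rows, , drop = FALSE]),
    centroid_vl = colMeans(sheet[vl_rows, , drop = FALSE]),
    axes = list(vh = canonical_axes(sheet[vh_rows, , drop = FALSE]),
                vl = canonical_axes(sheet[vl_rows, , drop = FALSE])),
    transform = tf
  ), class = "ReferenceFrame")
}

# first two principal axes of a point set, sign-fixed toward the first point
#' @keywords internal
canonical_axes <- function(pts) {
  cen <- colMeans(pts)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  L <- pc$rotation[, 1]; P <- pc$rotation[, 2]
  ref <- pts[1, ] - cen
  if (sum(L * ref) < 0) L <- -L
  if (abs(sum(P * ref)) > 1e-9) {
    if (sum(P * ref) < 0) P <- -P
  } else if (nrow(pts) > 1L) {
    ref2 <- pts[2, ] - cen
    if (sum(P * ref2) < 0) P <- -P
  }
  list(L = as.numeric(L), P = as.numeric(P))
}

#' @export
print.ReferenceFrame <- function(x, ...) {
  cat("ReferenceFrame (site", x$site, "):", nrow(x$coords),
      "sheet CA atoms (", x$n_vh, "V_H )\n")
  invisible(x)
}

#' Write a ReferenceFrame to a PDB file
#'
#' CA-only PDB in the canonical orientation (hinge centroid at the origin,
#' dyad axis along +z, V_H sheet centroid at theta = 0); the V_H row count is
#' recorded on a REMARK line so the file round-trips.
#'
#' @param ref a \code{ReferenceFrame}.
#' @param path output path.
#' @export
write_reference_frame <- function(ref, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("REMARK 300 DBGEOM REFERENCE SITE %s NVH %d",
                       ref$site, ref$n_vh),
               "REMARK 300 CANONICAL FRAME: HINGE CENTROID AT ORIGIN,",
               "REMARK 300 DYAD AXIS +Z, VH SHEET CENTROID AT THETA=0"), con)
  r <- ref$residues
  for (i in seq_len(nrow(ref$coords))) {
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, substr(r$chain[i], 1, 1), r$resno[i],
      ifelse(r$insert[i] == "", " ", r$insert[i]),
      ref$coords[i, 1], ref$coords[i, 2], ref$coords[i, 3], 1, 0), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a ReferenceFrame written by [write_reference_frame()]
#'
#' @param path PDB path with the dbgeom REMARK metadata.
#' @return a \code{ReferenceFrame} (centroids and canonical axes recomputed
#'   from the stored coordinates).
#' @export
read_reference_frame <- function(path) {
  lines <- readLines(path)
  meta <- grep("^REMARK 300 DBGEOM REFERENCE", lines, value = TRUE)
  if (!length(meta)) stop("read_reference_frame(): missing dbgeom REMARK metadata")
  m <- regmatches(meta[1], regexec("SITE (\\S+) NVH (\\d+)", meta[1]))[[1]]
  site <- m[2]; nvh <- as.integer(m[3])
  mod <- read_structure(path)
  sheet <- coords(mod)
  nr <- nrow(sheet)
  vh_rows <- seq_len(nvh); vl_rows <- setdiff(seq_len(nr), vh_rows)
  res <- cbind(mod$atoms[, c("chain", "resno", "insert")],
               domain = c(rep("vh", nvh), rep("vl", nr - nvh)))
  structure(list(
    coords = sheet, residues = res, n_vh = nvh, site = site,
    centroid_vh = colMeans(sheet[vh_rows, , drop = FALSE]),
    centroid_vl = colMeans(sheet[vl_rows, , drop = FALSE]),
    axes = list(vh = canonical_axes(sheet[vh_rows, , drop = FALSE]),
                vl = canonical_axes(sheet[vl_rows, , drop = FALSE])),
    transform = NULL
  ), class = "ReferenceFrame")
}
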