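#' Principal component analysis of loop backbone torsions
#'
#' Circular-safe torsion PCA: each phi/psi angle contributes its cosine and
#' sine as two features, the components are fitted on the pooled frames of
#' all supplied ensembles (so that landscapes of different systems share one
#' basis and are directly comparable), and per-ensemble scores are returned.
#' Per-system fitting is available by passing a single ensemble.
#'
#' @param ensembles named list of \code{TorsionEnsemble}s or angle matrices
#'   (degrees) with identical column layout (same loop definition).
#' @param k number of components to retain (default 2; capped at the feature
#'   count and pooled frame count).
#' @return a \code{TorsionPca}: list with \code{scores} (named list of
#'   frames x k matrices), \code{evr} (explained-variance fractions, all
#'   components), \code{rotation}, \code{center}, \code{sdev}, \code{k}.
#' @export
torsion_pca <- function(ensembles, k = 2L) {
  if (inherits(ensembles, "TorsionEnsemble") || is.matrix(ensembles)) {
    ensembles <- list(ensemble = ensembles)
  }
  mats <- lapply(ensembles, function(e) {
    if (inherits(e, "TorsionEnsemble")) e$angles else as.matrix(e)
  })
  K <- ncol(mats[[1]])
  if (!all(vapply(mats, ncol, 0L) == K)) {
    stop("torsion_pca(): ensembles differ in torsion layout")
  }
  feats <- lapply(mats, function(a) {
    r <- deg2rad(a); cbind(cos(r), sin(r))
  })
  pooled <- do.call(rbind, feats)
  if (nrow(pooled) < 2L) stop("torsion_pca(): fewer than 2 frames")
  k <- min(k, ncol(pooled), nrow(pooled) - 1L)
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  totvar <- sum(pc$sdev^2)
  evr <- if (totvar > 0) pc$sdev^2 / totvar else rep(0, length(pc$sdev))
  scores <- lapply(feats, function(f) {
    s <- sweep(f, 2, pc$center) %*% pc$rotation[, seq_len(k), drop = FALSE]
    colnames(s) <- paste0("PC", seq_len(k))
    s
  })
  structure(list(scores = scores, evr = evr, rotation = pc$rotation,
                 center = pc$center, sdev = pc$sdev, k = k),
            class = "TorsionPca")
}

#' Project additional torsion vectors into a fitted PCA basis
#'
#' Used to locate crystal-structure reference conformations on a simulated
#' landscape.
#'
#' @param pca a \code{TorsionPca}.
#' @param angles matrix (or vector) of torsions in degrees with the fitted
#'   column layout.
#' @return matrix of scores on the retained components.
#' @export
project_torsions <- function(pca, angles) {
  a <- if (is.null(dim(angles))) matrix(angles, 1) else as.matrix(angles)
  r <- deg2rad(a)
  f <- cbind(cos(r), sin(r))
  s <- sweep(f, 2, pca$center) %*% pca$rotation[, seq_len(pca$k), drop = FALSE]
  colnames(s) <- paste0("PC", seq_len(pca$k))
  s
}

#' Free-energy-style landscape on components 1-2
#'
#' Bins the scores of one ensemble on a shared 2D grid and returns
#' \code{-ln(p / p_max)} of the normalized bin counts, so the global minimum
#' of the surface is 0 and empty bins are \code{NA} (missing, not infinite).
#'
#' @param pca a \code{TorsionPca} (needs k >= 2).
#' @param name which ensemble's scores to bin (default the first).
#' @param bins grid resolution per axis (default 60).
#' @param limits optional list(x, y) of axis ranges; default the pooled score
#'   range over all ensembles, so panels of different systems share axes.
#' @return a \code{PcaLandscape}: list with \code{x}, \code{y} (bin centers)
#'   and \code{surface} (bins x bins matrix).
#' @export
pca_landscape <- function(pca, name = NULL, bins = 60L, limits = NULL) {
  if (pca$k < 2L) stop("pca_landscape(): needs at least 2 components")
  if (is.null(name)) name <- names(pca$scores)[1]
  s <- pca$scores[[name]]
  if (is.null(s)) stop("pca_landscape(): no ensemble '", name, "'")
  if (is.null(limits)) {
    all_s <- do.call(rbind, pca$scores)
    limits <- list(x = range(all_s[, 1]), y = range(all_s[, 2]))
  }
  bx <- seq(limits$x[1], limits$x[2], length.out = bins + 1L)
  by <- seq(limits$y[1], limits$y[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(s[, 1], bx, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(s[, 2], by, all.inside = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  p <- counts / sum(counts)
  surf <- -log(p / max(p))
  surf[counts == 0] <- NA_real_
  structure(list(x = (bx[-1] + bx[-length(bx)]) / 2,
                 y = (by[-1] + by[-length(by)]) / 2,
                 surface = surf, name = name),
            class = "PcaLandscape")
}
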