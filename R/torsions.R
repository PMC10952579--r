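# CDR-loop backbone torsions and the circular dihedral distance.

#' Backbone phi/psi torsions of declared loops over a trajectory
#'
#' Computes IUPAC phi (C[i-1]-N-CA-C) and psi (N-CA-C-N[i+1]) for every
#' residue of the named CDR loops. A residue whose flanking residue (and so
#' one of its torsions) is absent from the topology has that torsion excluded
#' identically in every frame, so all frames share one feature layout.
#'
#' @param traj a \code{Trajectory} (a single \code{StructureModel} is
#'   accepted and treated as one frame).
#' @param defn a \code{DomainDefinition}.
#' @param loops character vector of loop names declared under the site's
#'   \code{cdr} element (e.g. \code{c("H1","H2","H3")}).
#' @param site \code{"A"} or \code{"B"}.
#' @return a \code{TorsionEnsemble}: list with \code{angles} (frames x K
#'   matrix, degrees), \code{labels} (K strings \code{"loop:chain:resno:phi|psi"}),
#'   \code{loops}, \code{site}.
#' @export
backbone_torsions <- function(traj, defn, loops, site) {
  if (inherits(traj, "StructureModel")) {
    traj <- trajectory(traj, xyz = matrix(as.numeric(t(coords(traj))), 1))
  }
  top <- frame(traj, 1L)
  at <- top$atoms
  akey <- paste(at$chain, at$resno, at$insert, at$elety)
  find_atom <- function(chain, resno, insert, elety) {
    i <- which(akey == paste(chain, resno, insert, elety))
    if (length(i) != 1L) NA_integer_ else i
  }
  quads <- list(); labels <- character(0)
  for (lp in loops) {
    sel <- get_selection(defn, paste0("cdr_", lp, "_", site))
    for (r in seq_len(nrow(sel))) {
      ch <- sel$chain[r]; rn <- sel$resno[r]; ins <- sel$insert[r]
      N  <- find_atom(ch, rn, ins, "N")
      CA <- find_atom(ch, rn, ins, "CA")
      C  <- find_atom(ch, rn, ins, "C")
      if (any(is.na(c(N, CA, C)))) {
        stop("backbone_torsions(): residue (", ch, " ", rn,
             ") is missing a backbone atom")
      }
      Cprev <- find_atom(ch, rn - 1L, "", "C")
      Nnext <- find_atom(ch, rn + 1L, "", "N")
      if (!is.na(Cprev)) {
        quads[[length(quads) + 1L]] <- c(Cprev, N, CA, C)
        labels <- c(labels, paste(lp, ch, rn, "phi", sep = ":"))
      }
      if (!is.na(Nnext)) {
        quads[[length(quads) + 1L]] <- c(N, CA, C, Nnext)
        labels <- c(labels, paste(lp, ch, rn, "psi", sep = ":"))
      }
    }
  }
  if (!length(quads)) stop("backbone_torsions(): no computable torsions")
  nf <- nframes(traj)
  angles <- matrix(NA_real_, nf, length(quads), dimnames = list(NULL, labels))
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    for (q in seq_along(quads)) {
      i <- quads[[q]]
      angles[f, q] <- dihedral(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ], xyz[i[4], ])
    }
  }
  structure(list(angles = angles, labels = labels, loops = loops, site = site),
            class = "TorsionEnsemble")
}

#' @export
print.TorsionEnsemble <- function(x, ...) {
  cat("TorsionEnsemble:", nrow(x$angles), "frames x", ncol(x$angles),
      "torsions (", paste(x$loops, collapse = ","), "site", x$site, ")\n")
  invisible(x)
}

#' Circular dihedral distance between two torsion vectors
#'
#' The per-angle distance is \code{d(a, b) = 2 (1 - cos(a - b))}, bounded in
#' \code{[0, 4]}; the vector distance is the sum over all phi and psi angles.
#' Inherently periodic: adding 360 degrees to any angle leaves it unchanged.
#'
#' @param a,b torsion vectors in degrees, equal length and residue order.
#' @return non-negative dimensionless distance.
#' @export
torsion_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("torsion_distance(): vectors differ in length (",
         length(a), " vs ", length(b), ")")
  }
  sum(2 * (1 - cos(deg2rad(a - b))))
}

#' Pairwise circular dihedral distance matrix of an ensemble
#'
#' @param ensemble a \code{TorsionEnsemble} or an n x K angle matrix
#'   (degrees), rows = frames.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
distance_matrix <- function(ensemble) {
  A <- if (inherits(ensemble, "TorsionEnsemble")) ensemble$angles else as.matrix(ensemble)
  if (anyNA(A)) stop("distance_matrix(): missing angles")
  R <- deg2rad(A)
  Cm <- cos(R); Sm <- sin(R)
  D <- 2 * (ncol(A) - (Cm %*% t(Cm) + Sm %*% t(Sm)))
  D[D < 0] <- 0            # numerical guard; true distances are >= 0
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}
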