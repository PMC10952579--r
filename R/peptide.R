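# Ideal-geometry backbone builder (natural extension reference frame).
# Toy scaffolds are geometric constructs with valid N/CA/C/O backbones so
# that torsion extraction is exact; they are not physical proteins.

# standard backbone internal coordinates (Angstrom, degrees)
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

# place atom d given a-b-c with bond |cd|, angle b-c-d, torsion a-b-c-d
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle); ph <- -deg2rad(torsion)   # IUPAC sign
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal-geometry peptide backbone from torsion angles
#'
#' Constructs N, CA, C, O coordinates for a chain of residues with standard
#' bond lengths and angles, omega fixed at 180, and the supplied phi/psi
#' torsions. \code{phi[1]} and \code{psi[n]} do not affect atom placement
#' apart from the final carbonyl oxygen (psi of each residue places its O
#' anti to the next amide nitrogen).
#'
#' @param phi,psi per-residue backbone torsions, degrees (equal length).
#' @param chain chain id (default "A").
#' @param resid residue names, recycled (default "ALA").
#' @return a \code{StructureModel} with 4 atoms per residue.
#' @export
build_peptide <- function(phi, psi, chain = "A", resid = "ALA") {
  n <- length(phi)
  stopifnot(n >= 2L, length(psi) == n)
  resid <- rep_len(resid, n)
  P <- .BB
  pos <- vector("list", n)
  # residue 1 seeded in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(P$b_n_ca, 0, 0)
  th <- deg2rad(P$a_n_ca_c)
  C1 <- CA1 + P$b_ca_c * c(-cos(th), sin(th), 0)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    pr <- pos[[i - 1L]]
    Ni <- nerf_place(pr$N, pr$CA, pr$C, P$b_c_n, P$a_ca_c_n, psi[i - 1L])
    CAi <- nerf_place(pr$CA, pr$C, Ni, P$b_n_ca, P$a_c_n_ca, P$omega)
    Ci <- nerf_place(pr$C, Ni, CAi, P$b_ca_c, P$a_n_ca_c, phi[i])
    pos[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  # carbonyl O: torsion N-CA-C-O = psi - 180 (anti to the next N)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pos[[i]]
    O <- nerf_place(p$N, p$CA, p$C, P$b_c_o, P$a_ca_c_o, psi[i] - 180)
    xyz <- rbind(p$N, p$CA, p$C, O)
    rows[[i]] <- data.frame(chain = chain, resno = i, insert = "",
                            resid = resid[i],
                            elety = c("N", "CA", "C", "O"),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows))
}
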