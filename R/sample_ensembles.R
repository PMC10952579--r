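# Synthetic conformational ensembles with machine-readable ground truth.

#' Specification of a synthetic diabody trajectory
#'
#' The inter-Fv dihedral is drawn from a von Mises mixture on the circle;
#' the diabody angle from a von Mises mixture folded into \code{[0, 180]}
#' (the angle between axes is a polar, not a circular, quantity). Optional
#' wrapped-normal noise on the scaffold backbone torsions rebuilds the Fv
#' per frame.
#'
#' @param n number of frames.
#' @param seed RNG seed (R's default Mersenne-Twister stream; generators are
#'   deterministic under a fixed seed across platforms).
#' @param dihedral list(means, kappas, weights) of the von Mises mixture on
#'   the four-Trp dihedral, degrees.
#' @param angle list(means, kappas, weights) for the diabody angle, degrees;
#'   draws are folded into \code{[0, 180]}.
#' @param torsion_sigma wrapped-normal sd (degrees) added to the scaffold
#'   phi/psi per frame; 0 (default) keeps the scaffold rigid, which is what
#'   makes the generator's sphere-projection predictions exact.
#' @return an \code{EnsembleSpec} list.
#' @export
ensemble_spec <- function(n, seed,
                          dihedral = list(means = 120, kappas = 20, weights = 1),
                          angle = list(means = 110, kappas = 50, weights = 1),
                          torsion_sigma = 0) {
  for (mx in list(dihedral, angle)) {
    stopifnot(length(mx$means) == length(mx$kappas),
              all(mx$kappas > 0),
              abs(sum(mx$weights) - 1) < 1e-8)
  }
  stopifnot(torsion_sigma >= 0, n >= 1)
  list(n = as.integer(n), seed = as.integer(seed), dihedral = dihedral,
       angle = angle, torsion_sigma = torsion_sigma)
}

#' Sample a synthetic diabody trajectory with known per-frame ground truth
#'
#' Per frame, draws a (dihedral, angle) pair from the spec's mixtures and
#' re-poses site B of the base toy diabody by the analytic placement, so the
#' sampled values are the exact per-frame truth of the measured descriptors.
#' Infeasible sampled pairs (the solver rejects them) are redrawn and
#' counted. With \code{torsion_sigma > 0} the whole construct is rebuilt per
#' frame with noisy backbone torsions before placement; dihedral/angle truth
#' stays exact but the sphere-projection predictions (which assume the rigid
#' site-A scaffold of frame 1) are then omitted.
#'
#' @param spec an [ensemble_spec()].
#' @param base a [build_toy_diabody()] result (defines the scaffold,
#'   separation and domain definition).
#' @return list with \code{traj} (a \code{Trajectory}), \code{defn}, and
#'   \code{truth}: a data frame with one row per frame (frame, dihedral,
#'   angle, dihedral_label, angle_label, and the eight predicted projection
#'   coordinates theta/phi for V_H/V_L under each alignment), plus attribute
#'   \code{"resampled"} counting redraws.
#' @export
sample_trajectory <- function(spec, base) {
  set.seed(spec$seed)
  fvspec <- base$truth$fv$spec
  d <- base$truth$separation
  di_mix <- spec$dihedral; an_mix <- spec$angle
  draw_pair <- function() {
    li <- sample.int(length(di_mix$means), 1, prob = di_mix$weights)
    la <- sample.int(length(an_mix$means), 1, prob = an_mix$weights)
    dv <- rvonmises(1, di_mix$means[li], di_mix$kappas[li])
    av <- abs(wrap180(rvonmises(1, an_mix$means[la], an_mix$kappas[la])))
    list(d = dv, a = av, li = li, la = la)
  }
  n <- spec$n
  frames <- vector("list", n)
  rows <- vector("list", n)
  resampled <- 0L
  for (f in seq_len(n)) {
    ok <- FALSE
    for (try in 1:100) {
      pr <- draw_pair()
      fv <- if (spec$torsion_sigma > 0) {
        sp2 <- fvspec
        sp2$phi <- wrap180(fvspec$phi + stats::rnorm(fvspec$n_res, 0, spec$torsion_sigma))
        sp2$psi <- wrap180(fvspec$psi + stats::rnorm(fvspec$n_res, 0, spec$torsion_sigma))
        sp2
      } else fvspec
      db <- tryCatch(build_toy_diabody(fv, pr$d, pr$a, separation = d),
                     error = function(e) NULL)
      if (!is.null(db)) { ok <- TRUE; break }
      resampled <- resampled + 1L
    }
    if (!ok) stop("sample_trajectory(): frame ", f,
                  ": no feasible (dihedral, angle) pair after 100 draws")
    frames[[f]] <- db$model
    prj <- if (spec$torsion_sigma > 0) {
      data.frame(theta_vh_A = NA_real_, phi_vh_A = NA_real_,
                 theta_vl_A = NA_real_, phi_vl_A = NA_real_,
                 theta_vh_B = NA_real_, phi_vh_B = NA_real_,
                 theta_vl_B = NA_real_, phi_vl_B = NA_real_)
    } else {
      pt <- toy_projection_truth(db$truth)
      data.frame(theta_vh_A = pt$theta_vh[1], phi_vh_A = pt$phi_vh[1],
                 theta_vl_A = pt$theta_vl[1], phi_vl_A = pt$phi_vl[1],
                 theta_vh_B = pt$theta_vh[2], phi_vh_B = pt$phi_vh[2],
                 theta_vl_B = pt$theta_vl[2], phi_vl_B = pt$phi_vl[2])
    }
    rows[[f]] <- cbind(data.frame(frame = f, dihedral = pr$d, angle = pr$a,
                                  dihedral_label = pr$li, angle_label = pr$la),
                       prj)
  }
  truth <- do.call(rbind, rows)
  attr(truth, "resampled") <- resampled
  list(traj = trajectory(frames), defn = base$defn, truth = truth)
}

#' Sample a synthetic loop-torsion ensemble from a wrapped-normal mixture
#'
#' Draws per-frame phi/psi vectors of a pseudo-loop around component mean
#' vectors with wrapped-normal noise, recording the component label of every
#' frame. This is the ground-truth generator for the clustering and torsion
#' PCA stages.
#'
#' @param loop_length residues in the loop (each contributes one phi and one
#'   psi).
#' @param components list of components, each
#'   \code{list(phi, psi, sigma, weight)}: mean vectors in degrees (recycled
#'   to \code{loop_length}), wrapped-normal sd in degrees, mixture weight.
#' @param n number of frames.
#' @param seed RNG seed.
#' @return list with \code{angles} (n x 2*loop_length matrix, columns
#'   res_i:phi, res_i:psi), \code{labels} (integer component per frame), and
#'   \code{ensemble} (a \code{TorsionEnsemble} wrapper around \code{angles}).
#' @export
sample_torsion_ensemble <- function(loop_length, components, n, seed) {
  w <- vapply(components, function(cc) cc$weight, 0)
  if (abs(sum(w) - 1) > 1e-8) stop("sample_torsion_ensemble(): weights must sum to 1")
  if (any(vapply(components, function(cc) cc$sigma < 0, TRUE))) {
    stop("sample_torsion_ensemble(): negative sigma")
  }
  set.seed(seed)
  lab <- sample.int(length(components), n, replace = TRUE, prob = w)
  K <- 2L * loop_length
  cn <- as.character(t(outer(paste0("res", seq_len(loop_length)),
                             c("phi", "psi"), paste, sep = ":")))
  A <- matrix(NA_real_, n, K, dimnames = list(NULL, cn))
  for (f in seq_len(n)) {
    cc <- components[[lab[f]]]
    mu <- as.numeric(rbind(rep_len(cc$phi, loop_length),
                           rep_len(cc$psi, loop_length)))
    A[f, ] <- if (cc$sigma == 0) wrap180(mu) else rwrappednorm(K, mu, cc$sigma)
  }
  ens <- structure(list(angles = A, labels = cn,
                        loops = "synthetic", site = "A"),
                   class = "TorsionEnsemble")
  list(angles = A, labels = lab, ensemble = ens)
}
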