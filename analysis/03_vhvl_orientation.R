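#!/usr/bin/env Rscript
# VH-VL packing analysis: the six-measure descriptor per frame, against the
# shared canonical reference. Two ensembles illustrate the measure's two
# regimes: a rigid-scaffold ensemble (only the inter-Fv pose varies), where
# all six intra-Fv measures must be point masses, and a torsion-noise
# ensemble whose per-frame scaffold deformation produces genuine
# distributions. Tables and smoothed histograms go to results/.

suppressMessages(library(dbgeom))

dir.create("results/vhvl", recursive = TRUE, showWarnings = FALSE)

base <- build_toy_diabody(toy_fv_spec(), dihedral = 120, angle = 110)
ref <- build_reference_frame(base$model, base$defn, "A")

## rigid scaffold: the six measures are invariant under the inter-Fv re-posing
st_rigid <- sample_trajectory(ensemble_spec(100, seed = 201), base)
tabA <- vhvl_orientation_trajectory(st_rigid$traj, st_rigid$defn, "A", ref)
tabB <- vhvl_orientation_trajectory(st_rigid$traj, st_rigid$defn, "B", ref)
stopifnot(max(vapply(tabA[-1], sd, 0)) < 1e-9,
          max(vapply(tabB[-1], sd, 0)) < 1e-9)
cat("rigid-scaffold ensemble: all six measures are point masses on both sites\n")
cat(sprintf("  site A: dc %.3f A, tor %.2f, a1 %.2f, a2 %.2f, a3 %.2f, a4 %.2f\n",
            tabA$dc[1], tabA$tor[1], tabA$a1[1], tabA$a2[1], tabA$a3[1],
            tabA$a4[1]))

## torsion noise deforms the scaffold per frame: distributions appear
st_noisy <- sample_trajectory(
  ensemble_spec(300, seed = 202, torsion_sigma = 4), base)
for (site in c("A", "B")) {
  tab <- vhvl_orientation_trajectory(st_noisy$traj, st_noisy$defn, site, ref)
  write.table(tab, sprintf("results/vhvl/measures_site%s.tsv", site),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("noisy ensemble, site %s: dc %.3f +- %.3f A | tor %.2f +- %.2f deg\n",
              site, mean(tab$dc), sd(tab$dc), mean(tab$tor), sd(tab$tor)))
  if (site == "A") {
    for (m in c("dc", "tor", "a1", "a2", "a3", "a4")) {
      sh <- smoothed_histogram(tab[[m]], bins = 120)
      write.table(data.frame(center = sh$centers, density = sh$density),
                  sprintf("results/vhvl/hist_siteA_%s.tsv", m),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
}
cat("done: six-measure tables and histograms under results/vhvl/\n")
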