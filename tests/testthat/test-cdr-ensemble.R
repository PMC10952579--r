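test_that("backbone torsions recover canonical helix and extended angles", {
  helix <- build_peptide(rep(-57, 8), rep(-47, 8), chain = "H")
  defn <- domain_definition(list(A = list(
    vh = resref("H", 1:8), vl = resref("H", integer(0)),
    sheet_vh = resref("H", 2:7), sheet_vl = resref("H", integer(0)),
    anchor_trp_vh = resref("H", 4), anchor_trp_vl = resref("H", 4),
    hinge = resref("H", 8), nterm = resref("H", 1), cterm = resref("H", 8),
    cdr = list(H1 = resref("H", 2:7)))))
  te <- backbone_torsions(helix, defn, "H1", "A")
  phis <- te$angles[1, grep(":phi$", te$labels)]
  psis <- te$angles[1, grep(":psi$", te$labels)]
  expect_lt(max(abs(phis + 57)), 1)
  expect_lt(max(abs(psis + 47)), 1)

  ext <- build_peptide(rep(-180, 8), rep(180, 8), chain = "H")
  te2 <- backbone_torsions(ext, defn, "H1", "A")
  psis2 <- te2$angles[1, grep(":psi$", te2$labels)]
  expect_lt(max(abs(abs(psis2) - 180)), 1)
})

test_that("loop torsions match atom-by-atom dihedrals on a random conformer", {
  set.seed(61)
  phi <- runif(8, -180, 180); psi <- runif(8, -180, 180)
  pep <- build_peptide(phi, psi, chain = "H")
  defn <- domain_definition(list(A = list(
    vh = resref("H", 1:8), vl = resref("H", integer(0)),
    sheet_vh = resref("H", 2:7), sheet_vl = resref("H", integer(0)),
    anchor_trp_vh = resref("H", 4), anchor_trp_vl = resref("H", 4),
    hinge = resref("H", 8), nterm = resref("H", 1), cterm = resref("H", 8),
    cdr = list(H1 = resref("H", 3:6)))))
  te <- backbone_torsions(pep, defn, "H1", "A")
  at <- pep$atoms; xyz <- coords(pep)
  pick <- function(rn, el) xyz[which(at$resno == rn & at$elety == el), ]
  for (rn in 3:6) {
    expect_lt(abs(te$angles[1, paste("H1", "H", rn, "phi", sep = ":")] -
                  dihedral(pick(rn - 1, "C"), pick(rn, "N"),
                           pick(rn, "CA"), pick(rn, "C"))), 1e-9)
    expect_lt(abs(te$angles[1, paste("H1", "H", rn, "psi", sep = ":")] -
                  dihedral(pick(rn, "N"), pick(rn, "CA"),
                           pick(rn, "C"), pick(rn + 1, "N"))), 1e-9)
    # construction check: the builder placed exactly the requested torsions
    expect_lt(abs(dbgeom:::wrap180(
      te$angles[1, paste("H1", "H", rn, "phi", sep = ":")] - phi[rn])), 1e-6)
  }
})

test_that("terminal residues lacking neighbors are excluded consistently", {
  pep <- build_peptide(rep(-57, 6), rep(-47, 6), chain = "H")
  defn <- domain_definition(list(A = list(
    vh = resref("H", 1:6), vl = resref("H", integer(0)),
    sheet_vh = resref("H", 2:5), sheet_vl = resref("H", integer(0)),
    anchor_trp_vh = resref("H", 3), anchor_trp_vl = resref("H", 3),
    hinge = resref("H", 6), nterm = resref("H", 1), cterm = resref("H", 6),
    cdr = list(ALL = resref("H", 1:6)))))
  te <- backbone_torsions(pep, defn, "ALL", "A")
  # residue 1 has no phi, residue 6 no psi: 2*6 - 2 torsions
  expect_equal(ncol(te$angles), 10L)
  expect_false(paste("ALL", "H", 1, "phi", sep = ":") %in% te$labels)
  expect_false(paste("ALL", "H", 6, "psi", sep = ":") %in% te$labels)
})

test_that("torsion distance evaluates the circular formula exactly", {
  expect_equal(torsion_distance(c(10, 20), c(10, 20)), 0)
  # single residue: phi differs by 180, psi equal -> 2(1 - cos 180) = 4
  expect_equal(torsion_distance(c(0, 50), c(180, 50)), 4)
  set.seed(62)
  for (i in 1:20) {
    a <- runif(16, -180, 180); b <- runif(16, -180, 180)
    manual <- sum(vapply(seq_along(a), function(j) {
      2 * (1 - cos((a[j] - b[j]) * pi / 180))
    }, 0))
    expect_lt(abs(torsion_distance(a, b) - manual), 1e-12)
    # periodicity: adding 360 to any angle changes nothing
    a2 <- a; a2[5] <- a2[5] + 360
    expect_lt(abs(torsion_distance(a2, b) - torsion_distance(a, b)), 1e-9)
    # per-term bound [0, 4] implies D <= 4 * length
    expect_lte(torsion_distance(a, b), 4 * length(a))
    expect_gte(torsion_distance(a, b), 0)
  }
  expect_error(torsion_distance(1:4, 1:5), "length")
})

test_that("distance matrices are symmetric, zero-diagonal, and exact", {
  set.seed(63)
  A <- matrix(runif(5 * 6, -180, 180), 5, 6)
  D <- distance_matrix(A)
  expect_equal(max(abs(D - t(D))), 0)
  expect_equal(diag(D), rep(0, 5))
  for (i in 1:5) for (j in 1:5) {
    expect_lt(abs(D[i, j] - torsion_distance(A[i, ], A[j, ])), 1e-10)
  }
  # identical vectors: all-zero matrix
  expect_true(all(distance_matrix(A[rep(1, 4), ]) == 0))
})

test_that("average-linkage flat clustering matches the brute-force oracle", {
  set.seed(64)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    M <- matrix(runif(n * n, 0, 10), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    cutoff <- runif(1, 1, 9)
    got <- average_linkage_clusters(D, cutoff)
    expect_identical(got$labels, as.integer(naive_upgma(D, cutoff)))
  }
})

test_that("clustering handles cutoff extremes and medoid rules", {
  set.seed(65)
  A <- matrix(runif(6 * 4, -180, 180), 6, 4)
  D <- distance_matrix(A)
  all_one <- average_linkage_clusters(D, max(D) * 1.01 + 1)
  expect_equal(all_one$n_clusters, 1L)
  singles <- average_linkage_clusters(D, min(D[D > 0]) * 0.99)
  expect_equal(singles$n_clusters, 6L)
  expect_identical(singles$medoids, 1:6)
  # medoid membership and minimality
  mid <- average_linkage_clusters(D, stats::median(D[D > 0]))
  for (cl in seq_len(mid$n_clusters)) {
    mem <- which(mid$labels == cl)
    expect_true(mid$medoids[cl] %in% mem)
    sums <- rowSums(D[mem, mem, drop = FALSE])
    expect_equal(sums[match(mid$medoids[cl], mem)], min(sums))
  }
  # cluster count is non-increasing in the cutoff
  cuts <- seq(0.5, max(D) + 1, length.out = 12)
  ks <- vapply(cuts, function(h) average_linkage_clusters(D, h)$n_clusters, 0L)
  expect_true(all(diff(ks) <= 0))
  expect_error(average_linkage_clusters(D, -1), "cutoff")
  expect_error(average_linkage_clusters(D[, -1], 1), "symmetric")
})

test_that("two tight wrapped-normal torsion clusters are recovered exactly", {
  comps <- list(list(phi = c(-60, -60, -60), psi = c(140, 140, 140),
                     sigma = 5, weight = 0.5),
                list(phi = c(60, -60, -60), psi = c(140, 140, 140),
                     sigma = 5, weight = 0.5))
  e <- sample_torsion_ensemble(3, comps, n = 120, seed = 66)
  D <- distance_matrix(e$angles)
  got <- average_linkage_clusters(D, cutoff = 1.5)
  expect_equal(got$n_clusters, 2L)
  expect_identical(canon_labels(got$labels), canon_labels(e$labels))
  # medoid structures belong to their clusters
  expect_true(all(got$labels[got$medoids] == seq_len(got$n_clusters)))
})

test_that("torsion PCA separates mixture components and reconstructs features", {
  comps <- list(list(phi = c(-60, -60), psi = c(140, 140), sigma = 5,
                     weight = 0.5),
                list(phi = c(60, -60), psi = c(140, 140), sigma = 5,
                     weight = 0.5))
  e <- sample_torsion_ensemble(2, comps, n = 200, seed = 67)
  pca <- torsion_pca(list(sys = e$angles), k = 2)
  s1 <- pca$scores$sys[, 1]
  r1 <- range(s1[e$labels == 1]); r2 <- range(s1[e$labels == 2])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])   # no overlap on PC1

  expect_true(all(diff(pca$evr) <= 1e-12))
  expect_lte(sum(pca$evr), 1 + 1e-9)

  # reconstruction from all components reproduces the centered features
  r <- e$angles * pi / 180
  feats <- cbind(cos(r), sin(r))
  pca_full <- torsion_pca(list(sys = e$angles), k = ncol(feats))
  recon <- pca_full$scores$sys %*% t(pca_full$rotation[, seq_len(pca_full$k)])
  centered <- sweep(feats, 2, colMeans(feats))
  expect_lt(max(abs(recon - centered)), 1e-9)
})

test_that("pooled and per-system PCA coincide for a single system", {
  comps <- list(list(phi = -60, psi = 140, sigma = 20, weight = 1))
  e <- sample_torsion_ensemble(4, comps, n = 80, seed = 68)
  p1 <- torsion_pca(list(only = e$angles), k = 2)
  p2 <- torsion_pca(e$angles, k = 2)
  for (j in 1:2) {
    same <- max(abs(p1$scores$only[, j] - p2$scores$ensemble[, j]))
    flip <- max(abs(p1$scores$only[, j] + p2$scores$ensemble[, j]))
    expect_lt(min(same, flip), 1e-9)   # identical up to component sign
  }
})

test_that("identical frames give zero-variance PCA scores at the origin", {
  A <- matrix(rep(c(-60, 140, 60, -40), each = 10), 10, 4)
  pca <- torsion_pca(list(x = A), k = 2)
  expect_lt(max(abs(pca$scores$x)), 1e-9)
  expect_true(all(pca$evr == 0))
})

test_that("crystal-reference projection lands inside the ensemble cloud", {
  comps <- list(list(phi = -60, psi = 140, sigma = 8, weight = 1))
  e <- sample_torsion_ensemble(3, comps, n = 100, seed = 69)
  pca <- torsion_pca(list(sys = e$angles), k = 2)
  s <- project_torsions(pca, c(-60, 140, -60, 140, -60, 140))
  expect_equal(dim(s), c(1L, 2L))
  expect_true(s[1, 1] > min(pca$scores$sys[, 1]) - 1 &&
              s[1, 1] < max(pca$scores$sys[, 1]) + 1)
})

test_that("PCA landscape is zero at its minimum with NA for empty bins", {
  comps <- list(list(phi = c(-60, 60), psi = c(140, -40), sigma = 15,
                     weight = 1))
  e <- sample_torsion_ensemble(2, comps, n = 300, seed = 70)
  pca <- torsion_pca(list(sys = e$angles), k = 2)
  land <- pca_landscape(pca, "sys", bins = 20)
  expect_equal(min(land$surface, na.rm = TRUE), 0)
  expect_true(anyNA(land$surface))
  expect_true(all(land$surface >= 0, na.rm = TRUE))
})

test_that("smoothed histograms integrate to one and find the right peaks", {
  set.seed(71)
  x <- rnorm(1e5)
  sh <- smoothed_histogram(x, range = c(-5, 5), bins = 400)
  step <- diff(sh$centers[1:2])
  expect_equal(sum(sh$density) * step, 1, tolerance = 1e-6)
  expect_lt(abs(max(sh$density) - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.05)
  expect_true(all(sh$density >= 0))

  # all-identical samples: a single peak at the value
  sh2 <- smoothed_histogram(rep(3.5, 10))
  expect_equal(length(find_modes(sh2)), 1L)
  expect_lt(abs(find_modes(sh2) - 3.5), 0.05)

  # uniform samples: flat within a Monte-Carlo band from resampled replicates
  u <- runif(2e4)
  shu <- smoothed_histogram(u, range = c(0.1, 0.9), bins = 100)
  reps <- replicate(200, {
    d <- stats::density(runif(2e4), bw = shu$bw, from = 0.1, to = 0.9, n = 100)
    max(d$y) - min(d$y)
  })
  expect_lt(max(shu$density) - min(shu$density),
            mean(reps) + 4 * sd(reps))

  expect_error(smoothed_histogram(1), "at least 2")
  expect_error(smoothed_histogram(c(1, NA)), "non-finite")
  expect_error(smoothed_histogram(c(1, 2), range = c(3, 3)), "zero-width")
})
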