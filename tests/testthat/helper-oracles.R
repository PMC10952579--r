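# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# textbook projection-based signed torsion (independent of dbgeom::dihedral)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2; bh <- b / sqrt(sum(b^2))
  u <- p1 - p2; u <- u - sum(u * bh) * bh
  w <- p4 - p3; w <- w - sum(w * bh) * bh
  cx <- c(w[2] * u[3] - w[3] * u[2],
          w[3] * u[1] - w[1] * u[3],
          w[1] * u[2] - w[2] * u[1])
  atan2(sum(cx * bh), sum(u * w)) * 180 / pi
}

# rotation matrix from a unit quaternion (w, x, y, z)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_quaternion <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q   # canonical hemisphere: angle in [0, 180]
  q
}

random_rotation <- function() quat_to_matrix(random_quaternion())

# rigidly move a StructureModel by a random rotation + translation
random_rigid_copy <- function(model, tsd = 25) {
  R <- random_rotation()
  t <- rnorm(3, 0, tsd)
  dbgeom:::set_coords(model, sweep(coords(model) %*% t(R), 2, t, "+"))
}

# brute-force agglomerative average-linkage: recompute every pairwise
# average linkage at each step, merge the minimum while it is <= cutoff
naive_upgma <- function(D, cutoff) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL; bestd <- Inf
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        dij <- mean(D[clusters[[i]], clusters[[j]]])
        if (dij < bestd - 1e-12) { bestd <- dij; best <- c(i, j) }
      }
    }
    if (bestd > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (cl in seq_along(clusters)) lab[clusters[[cl]]] <- cl
  match(lab, lab[!duplicated(lab)])   # first-occurrence relabelling
}

# canonical first-occurrence relabelling of any label vector
canon_labels <- function(lab) match(lab, lab[!duplicated(lab)])

# small toy systems shared across tests
toy_diabody_fixture <- function(dihedral = 77, angle = 95) {
  build_toy_diabody(toy_fv_spec(), dihedral = dihedral, angle = angle)
}
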