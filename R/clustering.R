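#' Average-linkage flat clustering with medoid extraction
#'
#' Agglomerative average-linkage (UPGMA) clustering of a precomputed distance
#' matrix, cut at a fixed linkage height: two frames share a cluster when
#' they merge at an average linkage not exceeding \code{cutoff}. Cluster
#' labels are renumbered by first-occurrence frame order. The representative
#' ("cluster center") of each cluster is its medoid: the member minimizing
#' the summed within-cluster distance, ties resolved toward the lowest frame
#' index. Medoids are the natural centers here because torsion-space means
#' are ill-defined for circular data.
#'
#' @param matrix symmetric non-negative distance matrix (zero diagonal).
#' @param cutoff linkage cutoff (> 0), same units as the distances.
#' @return a \code{ClusterAssignment}: list with \code{labels} (integer per
#'   frame, 1-based, first-occurrence order), \code{medoids} (frame index per
#'   cluster), \code{cutoff}, \code{n_clusters}.
#' @export
average_linkage_clusters <- function(matrix, cutoff) {
  D <- as.matrix(matrix)
  if (cutoff <= 0) stop("average_linkage_clusters(): cutoff must be > 0")
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("average_linkage_clusters(): matrix is not symmetric")
  }
  if (any(D < 0)) stop("average_linkage_clusters(): negative distances")
  n <- nrow(D)
  if (n == 1L) {
    return(structure(list(labels = 1L, medoids = 1L, cutoff = cutoff,
                          n_clusters = 1L), class = "ClusterAssignment"))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  raw <- stats::cutree(hc, h = cutoff)
  # relabel by first occurrence
  first <- match(unique(raw), raw)
  labels <- match(raw, raw[sort(first)])
  k <- max(labels)
  medoids <- integer(k)
  for (cl in seq_len(k)) {
    mem <- which(labels == cl)
    if (length(mem) == 1L) { medoids[cl] <- mem; next }
    ssum <- rowSums(D[mem, mem, drop = FALSE])
    medoids[cl] <- mem[which.min(ssum)]   # which.min takes the first tie
  }
  structure(list(labels = as.integer(labels), medoids = medoids,
                 cutoff = cutoff, n_clusters = k),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", length(x$labels), "frames ->", x$n_clusters,
      "clusters at cutoff", x$cutoff, "\n")
  invisible(x)
}

#' Write cluster medoid frames as a multi-model PDB
#'
#' @param traj the clustered \code{Trajectory}.
#' @param assignment a \code{ClusterAssignment}.
#' @param path output PDB path (one MODEL per medoid, cluster order).
#' @export
write_medoids <- function(traj, assignment, path) {
  models <- lapply(assignment$medoids, function(f) frame(traj, f))
  write_structure(trajectory(models), path)
  invisible(path)
}
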