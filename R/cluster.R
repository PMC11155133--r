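#' Leiden segmentation with a target cluster count
#'
#' Builds a kNN graph (k = 20, Euclidean) on the embedding, runs Leiden
#' community detection (modularity objective), and binary-searches the
#' resolution parameter in `[1e-4, 10]` (at most 40 iterations) for exactly
#' `n_target` communities. If the exact count is unattainable within the
#' search budget, the closest count found is returned and flagged; among
#' resolutions achieving the target count the smallest wins.
#'
#' @param H N x D embedding matrix.
#' @param n_target desired number of communities (>= 2).
#' @param seed RNG seed (Leiden refinement is stochastic).
#' @param k kNN size for the graph on the embedding.
#' @return A list of class `partition`: `assignments` (1-based integer
#'   labels), `n_clusters`, `resolution`, and `exact` (TRUE when the target
#'   count was hit).
#' @export
leiden_with_target_k <- function(H, n_target, seed = 1, k = 20) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (n_target < 2) stop("parameter error: n_target must be >= 2")
  if (n_target > n) stop("parameter error: n_target > number of spots")
  k_eff <- min(k, n - 1)
  nb <- knn_graph(H, k = k_eff)
  g <- igraph::graph_from_adjacency_matrix(nb, mode = "max")

  run <- function(res) {
    set.seed(seed)
    memb <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = res, n_iterations = 5)
    igraph::membership(memb)
  }
  lo <- 1e-4; hi <- 10
  best <- NULL; best_gap <- Inf; best_res <- NA_real_
  hit_res <- Inf
  for (it in seq_len(40)) {
    mid <- sqrt(lo * hi)   # geometric bisection over decades
    memb <- run(mid)
    nc <- length(unique(memb))
    gap <- abs(nc - n_target)
    better <- gap < best_gap ||
      (gap == 0 && best_gap == 0 && mid < hit_res)
    if (better) {
      best <- memb; best_gap <- gap; best_res <- mid
      if (gap == 0) hit_res <- mid
    }
    if (nc < n_target) lo <- mid
    else if (nc > n_target) hi <- mid
    else hi <- mid  # target hit: keep searching downward for smallest res
    if (hi / lo < 1 + 1e-9) break
  }
  assignments <- as.integer(factor(best, levels = unique(best)))
  new_partition(assignments, resolution = best_res, exact = best_gap == 0)
}

new_partition <- function(assignments, resolution = NA_real_, exact = TRUE) {
  assignments <- as.integer(factor(assignments))
  structure(list(assignments = assignments,
                 n_clusters = length(unique(assignments)),
                 resolution = resolution, exact = exact),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition: ", x$n_clusters, " clusters over ",
      length(x$assignments), " spots",
      if (!is.na(x$resolution)) paste0(" (leiden resolution ",
                                       signif(x$resolution, 4),
                                       if (!x$exact) ", target not hit" else "",
                                       ")"), "\n", sep = "")
  invisible(x)
}

as_labels <- function(p) {
  if (inherits(p, "partition")) p$assignments else as.vector(p)
}
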