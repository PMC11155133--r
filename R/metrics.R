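#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' `ARI = (sum_ij C(N_ij,2) - E) / (max - E)` with
#' `E = sum_i C(N_i,2) sum_j C(N_j,2) / C(N,2)` and
#' `max = (sum_i C(N_i,2) + sum_j C(N_j,2)) / 2`, from the contingency table
#' of the two labelings. 1 for identical partitions (up to relabeling),
#' ~0 for independent ones; can be negative.
#'
#' @param g,p two partitions ([leiden_with_target_k()] results or plain
#'   label vectors) of equal length.
#' @return Scalar ARI.
#' @export
ari <- function(g, p) {
  g <- as_labels(g); p <- as_labels(p)
  if (length(g) != length(p)) stop("length mismatch between partitions")
  tab <- table(g, p)
  n <- length(g)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  expected <- sum_i * sum_j / choose2(n)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)  # both partitions trivial (all singletons/one cluster)
  (sum_ij - expected) / (maxi - expected)
}

#' Normalized mutual information
#'
#' `NMI(G, P) = MI(G, P) / sqrt(H(G) H(P))` from the joint contingency
#' distribution, with natural logarithms (the ratio is base-invariant).
#' Returns 1 when both partitions consist of a single cluster, and 0 when
#' exactly one of them does (zero entropy).
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(g, p) {
  g <- as_labels(g); p <- as_labels(p)
  if (length(g) != length(p)) stop("length mismatch between partitions")
  n <- length(g)
  joint <- table(g, p) / n
  pg <- rowSums(joint); pp <- colSums(joint)
  hg <- -sum(pg[pg > 0] * log(pg[pg > 0]))
  hp <- -sum(pp[pp > 0] * log(pp[pp > 0]))
  if (hg == 0 && hp == 0) return(1)
  if (hg == 0 || hp == 0) return(0)
  outer_pp <- outer(pg, pp)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer_pp[nz]))
  mi / sqrt(hg * hp)
}

#' Label Moran's index of spatial coherence
#'
#' A label-free measure of how spatially concentrated a clustering is: the
#' fraction of directed spatial kNN edges whose endpoints share a label,
#' `I = sum_ij A_ij B_ij / sum_ij A_ij` with `A` the binary kNN adjacency of
#' the spot coordinates (k = 20) and `B_ij = 1` iff spots i and j carry the
#' same label. Equals 1 when every neighbourhood is label-pure and about
#' `1/c` for c labels assigned at random.
#'
#' @param p a partition or label vector.
#' @param S N x 2 spot coordinates.
#' @param k spatial kNN size (default 20).
#' @return Scalar in `[0, 1]`.
#' @export
moran_label <- function(p, S, k = 20) {
  y <- as_labels(p)
  S <- as.matrix(S)
  if (length(y) != nrow(S)) stop("length mismatch between labels and coords")
  A <- knn_graph(S, k = k)   # errors when N <= k
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  same <- y[idx[, 1]] == y[idx[, 2]]
  sum(same) / nrow(idx)
}

#' Evaluate a segmentation
#'
#' Computes the label Moran's index always, and ARI/NMI when ground-truth
#' labels are available.
#'
#' @param p predicted partition or labels.
#' @param S spot coordinates.
#' @param truth optional ground-truth labels.
#' @param k spatial kNN size for the Moran graph.
#' @return A list of class `metrics_report` with `moran_label`, optionally
#'   `ari` and `nmi`, and `k`.
#' @export
evaluate_partition <- function(p, S, truth = NULL, k = 20) {
  rep <- list(moran_label = moran_label(p, S, k = k), k = k)
  if (!is.null(truth)) {
    rep$ari <- ari(truth, p)
    rep$nmi <- nmi(truth, p)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("segmentation metrics (Moran kNN k = ", x$k, ")\n", sep = "")
  if (!is.null(x$ari)) cat("  ARI:  ", round(x$ari, 4), "\n", sep = "")
  if (!is.null(x$nmi)) cat("  NMI:  ", round(x$nmi, 4), "\n", sep = "")
  cat("  label Moran's I: ", round(x$moran_label, 4), "\n", sep = "")
  invisible(x)
}
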