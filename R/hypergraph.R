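#' k-nearest-neighbour graph from spatial coordinates
#'
#' Binary N x N matrix whose row i marks the k nearest distinct neighbours of
#' spot i under the Euclidean metric (self excluded). Ties in distance are
#' broken deterministically by ascending spot index, so duplicated
#' coordinates are allowed and pick each other first.
#'
#' @param S numeric N x 2 coordinate matrix.
#' @param k number of neighbours (default 20).
#' @return A sparse binary `Matrix` of dimension N x N with row sums k.
#' @export
knn_graph <- function(S, k = 20) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n <= k) stop("too few spots for k: N = ", n, ", k = ", k)
  if (k < 1) stop("parameter error: k must be >= 1")
  d2 <- pairwise_sq_dists(S, S)
  diag(d2) <- Inf
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    # order() is stable: equal distances resolve by ascending index
    idx[i, ] <- order(d2[i, ])[seq_len(k)]
  }
  Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(idx)),
                       x = 1, dims = c(n, n))
}

pairwise_sq_dists <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Hypergraph from a kNN graph
#'
#' One hyperedge per spot j, containing j itself plus its k nearest
#' neighbours (the self-inclusion keeps the incidence diagonal at 1 and the
#' spectrum numerically stable). Returns the incidence matrix P
#' (`P[v, j] = 1` iff spot v belongs to hyperedge j), identity hyperedge
#' weights `W_e`, the vertex degrees `d(v) = sum_e w(e) P[v, e]` and
#' hyperedge degrees `delta(e) = |e| = k + 1`.
#'
#' @param neighbors binary N x N neighbour matrix from [knn_graph()].
#' @param include_self include each spot in its own hyperedge (default TRUE).
#' @param w_e hyperedge weights, length N or scalar (default 1 = identity).
#' @return A list of class `hypergraph` with `P` (sparse), `w_e`, `d_v`,
#'   `d_e`, and `n_vertices`/`n_edges`.
#' @export
incidence_from_knn <- function(neighbors, include_self = TRUE, w_e = 1) {
  nb <- methods::as(neighbors, "CsparseMatrix")
  n <- nrow(nb)
  if (ncol(nb) != n) stop("neighbor matrix must be square")
  P <- Matrix::t(nb)
  if (include_self) P <- P + Matrix::Diagonal(n)
  P <- methods::as(methods::as(P * 1, "generalMatrix"), "CsparseMatrix")
  P@x[] <- 1  # binary membership even if self already a neighbour
  if (any(Matrix::colSums(P) == 0))
    stop("malformed input: empty hyperedge (empty neighbor row)")
  if (any(Matrix::rowSums(P) == 0))
    stop("malformed input: vertex in no hyperedge")
  w_e <- rep_len(w_e, n)
  if (any(w_e < 0)) stop("hyperedge weights must be non-negative")
  d_v <- as.numeric(P %*% w_e)
  d_e <- Matrix::colSums(P)
  structure(list(P = P, w_e = w_e, d_v = d_v, d_e = d_e,
                 n_vertices = n, n_edges = n),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("hypergraph: ", x$n_vertices, " vertices, ", x$n_edges,
      " hyperedges, mean |e| = ", round(mean(x$d_e), 2), "\n", sep = "")
  invisible(x)
}

#' Normalized hypergraph adjacency and Laplacian
#'
#' Computes `A_hp = D_v^{-1/2} P W_e D_e^{-1} P^T D_v^{-1/2}` and
#' `L_hp = I - A_hp`. `A_hp` is symmetric with eigenvalues in `[0, 1]`; it is
#' the propagation operator of the hypergraph convolution.
#'
#' @param hg a [incidence_from_knn()] hypergraph.
#' @return A list with sparse matrices `A_hp` and `L_hp`.
#' @export
normalized_adjacency <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  if (any(hg$d_v <= 0))
    stop("degenerate vertex degree: isolated vertex with d(v) = 0")
  n <- hg$n_vertices
  dv_is <- Matrix::Diagonal(n, 1 / sqrt(hg$d_v))
  we <- Matrix::Diagonal(hg$n_edges, hg$w_e)
  de_i <- Matrix::Diagonal(hg$n_edges, 1 / hg$d_e)
  half <- dv_is %*% hg$P %*% we %*% de_i
  A <- half %*% Matrix::t(hg$P) %*% dv_is
  A <- methods::as((A + Matrix::t(A)) / 2, "CsparseMatrix")  # enforce exact symmetry
  L <- Matrix::Diagonal(n) - A
  list(A_hp = A, L_hp = L)
}

#' Build the spatial hypergraph operator in one call
#'
#' Convenience wrapper: kNN graph on coordinates, star hyperedges with
#' self-inclusion, normalized adjacency.
#'
#' @inheritParams knn_graph
#' @return A list with `hypergraph`, `A_hp`, `L_hp`, and `k`.
#' @export
spatial_hypergraph <- function(S, k = 20) {
  nb <- knn_graph(S, k = k)
  hg <- incidence_from_knn(nb)
  adj <- normalized_adjacency(hg)
  list(hypergraph = hg, A_hp = adj$A_hp, L_hp = adj$L_hp, k = k)
}

#' Export a hypergraph to disk
#'
#' Writes the incidence matrix as MatrixMarket `incidence.mtx` plus a JSON
#' sidecar with k, hyperedge weights, and degree vectors.
#'
#' @param hg a hypergraph.
#' @param dir output directory.
#' @param k the kNN size used, recorded in the sidecar.
#' @export
export_hypergraph <- function(hg, dir, k = NULL) {
  stopifnot(inherits(hg, "hypergraph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(hg$P, file.path(dir, "incidence.mtx"))
  side <- list(k = k, w_e = hg$w_e, d_v = hg$d_v, d_e = as.numeric(hg$d_e))
  jsonlite::write_json(side, file.path(dir, "hypergraph.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
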