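test_that("knn_graph finds exact nearest neighbours with index tie-breaks", {
  # 3 collinear points at x = 0, 1, 3 with k = 1
  S <- cbind(c(0, 1, 3), 0)
  nb <- as.matrix(knn_graph(S, k = 1))
  expect_equal(unname(nb), rbind(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0)))

  # duplicated points pick each other (zero distance is minimal)
  S2 <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(9, 9), c(0.7, 0.5))
  nb2 <- as.matrix(knn_graph(S2, k = 1))
  expect_equal(nb2[1, 2], 1)
  expect_equal(nb2[2, 1], 1)

  expect_error(knn_graph(S2, k = 4), "too few spots")
})

test_that("knn_graph agrees with an exhaustive distance-sort oracle", {
  set.seed(31)
  S <- matrix(runif(200 * 2), 200, 2)
  k <- 20
  nb <- as.matrix(knn_graph(S, k = k))
  expect_true(all(rowSums(nb) == k))
  d <- as.matrix(dist(S))
  diag(d) <- Inf
  for (i in sample(200, 25)) {
    oracle <- order(d[i, ])[1:k]
    expect_setequal(which(nb[i, ] == 1), oracle)
  }
})

test_that("incidence_from_knn builds star hyperedges with self-inclusion", {
  S <- cbind(c(0, 1, 3), 0)
  hg <- incidence_from_knn(knn_graph(S, k = 1))
  P <- as.matrix(hg$P)
  expect_equal(unname(P), rbind(c(1, 1, 0), c(1, 1, 1), c(0, 0, 1)))
  expect_equal(hg$d_v, c(2, 3, 1))
  expect_equal(unname(as.numeric(hg$d_e)), c(2, 2, 2))

  # degenerate k = 0 (empty neighbour matrix) with self-inclusion -> identity
  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), dims = c(4, 4))
  hg0 <- incidence_from_knn(empty, include_self = TRUE)
  expect_equal(as.matrix(hg0$P), diag(4), ignore_attr = TRUE)
  expect_equal(hg0$d_v, rep(1, 4))
  # without self-inclusion an empty hyperedge is malformed
  expect_error(incidence_from_knn(empty, include_self = FALSE), "malformed")
})

test_that("every hyperedge has size k + 1 on random data", {
  set.seed(32)
  S <- matrix(runif(200 * 2), 200, 2)
  hg <- incidence_from_knn(knn_graph(S, k = 20))
  expect_true(all(Matrix::colSums(hg$P) == 21))
  expect_true(all(Matrix::diag(hg$P) == 1))  # self-similarity on the diagonal
})

test_that("normalized adjacency matches closed forms", {
  # two vertices sharing one hyperedge of unit weight
  P <- Matrix::Matrix(matrix(1, 2, 1), sparse = TRUE)
  hg <- structure(list(P = P, w_e = 1, d_v = c(1, 1), d_e = 2,
                       n_vertices = 2, n_edges = 1), class = "hypergraph")
  adj <- normalized_adjacency(hg)
  expect_equal(as.matrix(adj$A_hp), matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(sort(eigen(as.matrix(adj$A_hp))$values), c(0, 1))
  expect_equal(as.matrix(adj$L_hp),
               rbind(c(0.5, -0.5), c(-0.5, 0.5)), ignore_attr = TRUE)

  # single vertex in a single hyperedge
  P1 <- Matrix::Matrix(matrix(1, 1, 1), sparse = TRUE)
  hg1 <- structure(list(P = P1, w_e = 1, d_v = 1, d_e = 1,
                        n_vertices = 1, n_edges = 1), class = "hypergraph")
  adj1 <- normalized_adjacency(hg1)
  expect_equal(as.matrix(adj1$A_hp)[1, 1], 1)
  expect_equal(as.matrix(adj1$L_hp)[1, 1], 0)

  hg_bad <- hg
  hg_bad$d_v <- c(0, 1)
  expect_error(normalized_adjacency(hg_bad), "degenerate vertex degree")
})

test_that("random hypergraph adjacency equals the dense matrix-product oracle", {
  set.seed(33)
  S <- matrix(runif(50 * 2), 50, 2)
  hg <- incidence_from_knn(knn_graph(S, k = 5))
  adj <- normalized_adjacency(hg)
  A <- as.matrix(adj$A_hp)
  P <- as.matrix(hg$P)
  Dv <- diag(1 / sqrt(hg$d_v))
  De <- diag(1 / as.numeric(hg$d_e))
  oracle <- Dv %*% P %*% diag(hg$w_e) %*% De %*% t(P) %*% Dv
  expect_equal(A, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(A - t(A))), 1e-8)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 & ev <= 1 + 1e-8))
  expect_equal(as.matrix(adj$L_hp), diag(50) - A, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("2-uniform hypergraph reduces to the half-normalized graph form", {
  # 4-node path a-b-c-d: one hyperedge per simple edge, no self-inclusion
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4))
  P <- Matrix::sparseMatrix(i = as.vector(t(edges)),
                            j = rep(1:3, each = 2), x = 1, dims = c(4, 3))
  dv <- Matrix::rowSums(P)
  hg <- structure(list(P = P, w_e = rep(1, 3), d_v = as.numeric(dv),
                       d_e = Matrix::colSums(P), n_vertices = 4, n_edges = 3),
                  class = "hypergraph")
  A_hp <- as.matrix(normalized_adjacency(hg)$A_hp)
  A_simple <- matrix(0, 4, 4)
  A_simple[cbind(edges[, 1], edges[, 2])] <- 1
  A_simple <- A_simple + t(A_simple)
  D <- diag(rowSums(A_simple))
  Dm <- diag(1 / sqrt(diag(D)))
  expect_equal(A_hp, 0.5 * Dm %*% (A_simple + D) %*% Dm, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("spectral bound holds over many random instances", {
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    k <- sample(c(3, 5), 1)
    S <- matrix(runif(n * 2), n, 2)
    A <- as.matrix(spatial_hypergraph(S, k = k)$A_hp)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(ev), 1 + 1e-8)
    expect_gte(min(ev), -1e-8)
  }
})

test_that("permuting spots conjugates the adjacency", {
  set.seed(35)
  S <- matrix(runif(40 * 2), 40, 2)
  A <- as.matrix(spatial_hypergraph(S, k = 4)$A_hp)
  perm <- sample(40)
  A_p <- as.matrix(spatial_hypergraph(S[perm, ], k = 4)$A_hp)
  Pi <- diag(40)[perm, ]
  expect_equal(A_p, Pi %*% A %*% t(Pi), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("hypergraph export writes incidence MTX plus JSON sidecar", {
  S <- matrix(runif(30 * 2), 30, 2)
  hgr <- spatial_hypergraph(S, k = 3)
  dir <- withr::local_tempdir()
  export_hypergraph(hgr$hypergraph, dir, k = 3)
  expect_true(file.exists(file.path(dir, "incidence.mtx")))
  side <- jsonlite::read_json(file.path(dir, "hypergraph.json"),
                              simplifyVector = TRUE)
  expect_equal(side$k, 3)
  expect_equal(side$d_e, rep(4, 30))
  # binary incidence round-trips as a MatrixMarket pattern matrix
  P_back <- as.matrix(Matrix::readMM(file.path(dir, "incidence.mtx"))) * 1
  expect_equal(P_back, as.matrix(hgr$hypergraph$P), ignore_attr = TRUE)
})
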