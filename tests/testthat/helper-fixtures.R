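# Shared fixtures and oracles built in code.

# Tiny raw-count dataset with fixed values.
toy_counts <- function(n = 6, m = 4, seed = 99) {
  set.seed(seed)
  X <- matrix(rpois(n * m, lambda = 3) + 1, n, m)  # +1: no all-zero spots
  S <- cbind(runif(n), runif(n))
  spot_dataset(X, S)
}

# Small config so unit tests stay fast.
tiny_config <- function(...) {
  defaults <- list(pretrain_epochs = 5, train_epochs = 5, d_f = 4, d_g = 2,
                   hidden_expr = 8, hidden_hgcn = 6, n_centroids = 3,
                   k = 5, seed = 7)
  do.call(hyperspot_config, utils::modifyList(defaults, list(...)))
}

# Literal double-sum oracle for the spatial regularizer (min-max normalized
# pairwise distances, mean over ordered pairs).
spatial_loss_oracle <- function(S, H) {
  n <- nrow(S)
  ds <- as.matrix(dist(S)); dh <- as.matrix(dist(H))
  norm01 <- function(d) {
    rng <- range(d)
    if (diff(rng) == 0) return(d * 0)
    (d - rng[1]) / diff(rng)
  }
  ds <- norm01(ds); dh <- norm01(dh)
  acc <- 0
  for (i in 1:n) for (j in 1:n) acc <- acc + ds[i, j] * (1 - dh[i, j])
  acc / n^2
}

# Brute-force pair-counting ARI over all C(N,2) spot pairs.
ari_pair_oracle <- function(g, p) {
  n <- length(g)
  a <- b <- c_ <- d_ <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sg <- g[i] == g[j]; sp <- p[i] == p[j]
    if (sg && sp) a <- a + 1
    else if (sg && !sp) b <- b + 1
    else if (!sg && sp) c_ <- c_ + 1
    else d_ <- d_ + 1
  }
  tot <- a + b + c_ + d_
  exp_a <- (a + b) * (a + c_) / tot
  max_a <- ((a + b) + (a + c_)) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}

# NMI from the joint contingency distribution, evaluated longhand.
nmi_contingency_oracle <- function(g, p) {
  n <- length(g)
  gs <- unique(g); ps <- unique(p)
  joint <- outer(gs, ps, Vectorize(function(a, b) sum(g == a & p == b))) / n
  pg <- rowSums(joint); pp <- colSums(joint)
  ent <- function(x) -sum(x[x > 0] * log(x[x > 0]))
  hg <- ent(pg); hp <- ent(pp)
  if (hg == 0 && hp == 0) return(1)
  if (hg == 0 || hp == 0) return(0)
  mi <- 0
  for (i in seq_along(gs)) for (j in seq_along(ps))
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log(joint[i, j] / (pg[i] * pp[j]))
  mi / sqrt(hg * hp)
}

# Literal printed form of the label Moran index:
# (N / sum(A)) * (sum(A * B) / N) with A the directed spatial kNN adjacency.
moran_literal_oracle <- function(labels, S, k = 20) {
  A <- as.matrix(knn_graph(S, k = k))
  B <- outer(labels, labels, "==") * 1
  n <- length(labels)
  (n / sum(A)) * (sum(A * B) / n)
}
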