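test_that("soft assignment follows the Student-t closed form", {
  # one spot at squared distances 0 and 3 from two centroids
  H <- matrix(c(0, 0), 1, 2)
  C <- rbind(c(0, 0), c(sqrt(3), 0))
  expect_equal(unname(soft_assignment(H, C)[1, ]), c(0.8, 0.2))

  # equidistant spot -> uniform row
  C4 <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(unname(soft_assignment(H, C4)[1, ]), rep(0.25, 4))

  # literal formula oracle on random data
  set.seed(41)
  H7 <- matrix(rnorm(21), 7, 3)
  C4b <- matrix(rnorm(12), 4, 3)
  Q <- soft_assignment(H7, C4b)
  oracle <- matrix(0, 7, 4)
  for (i in 1:7) {
    u <- sapply(1:4, function(k) 1 / (1 + sum((H7[i, ] - C4b[k, ])^2)))
    oracle[i, ] <- u / sum(u)
  }
  expect_equal(unname(Q), oracle, tolerance = 1e-8)
  expect_equal(rowSums(Q), rep(1, 7), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("target distribution sharpens and fixes one-hot assignments", {
  Q1 <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(target_distribution(Q1), Q1)

  # single spot: t = q algebraically
  Qs <- matrix(c(0.3, 0.7), 1, 2)
  expect_equal(target_distribution(Qs), Qs)

  # hand-derived case, 4 decimal places
  Q <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  T_ref <- rbind(c(0.9643, 0.0357), c(0.4286, 0.5714))
  expect_equal(target_distribution(Q), T_ref, tolerance = 1e-4)
  expect_equal(rowSums(target_distribution(Q)), c(1, 1))
})

test_that("DEC KL loss is zero at the fixed point and matches the oracle", {
  Q <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  expect_equal(dec_loss(Q, Q), 0)
  T_mat <- target_distribution(Q)
  oracle <- sum(T_mat * log(T_mat / Q))
  expect_equal(dec_loss(T_mat, Q), oracle, tolerance = 1e-10)
  expect_equal(dec_loss(T_mat, Q), 0.089, tolerance = 1e-2)

  # Gibbs inequality: KL >= 0 for random valid pairs
  set.seed(42)
  for (i in 1:200) {
    q <- matrix(rexp(12), 4, 3); q <- q / rowSums(q)
    t_ <- matrix(rexp(12), 4, 3); t_ <- t_ / rowSums(t_)
    expect_gte(dec_loss(t_, q), 0)
  }
})

test_that("spatial regularization has the stated degenerate values", {
  # two spots: both off-diagonal embedding distances normalize to 1 -> loss 0
  S <- rbind(c(0, 0), c(3, 4))
  H <- rbind(c(0, 0), c(1, 0))
  expect_equal(spatial_regularization(S, H), 0)

  # constant embedding: loss = mean of normalized spatial distances
  set.seed(43)
  S6 <- matrix(runif(12), 6, 2)
  Hc <- matrix(1, 6, 3)
  ds <- as.matrix(dist(S6)); ds <- ds / max(ds)
  expect_equal(spatial_regularization(S6, Hc), mean(ds))
})

test_that("spatial regularization equals the literal double-sum oracle", {
  set.seed(44)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    S <- matrix(runif(n * 2), n, 2)
    H <- matrix(rnorm(n * 3), n, 3)
    expect_equal(spatial_regularization(S, H), spatial_loss_oracle(S, H),
                 tolerance = 1e-8)
  }
  # chunked evaluation is identical to one-shot
  S <- matrix(runif(80), 40, 2)
  H <- matrix(rnorm(120), 40, 3)
  expect_equal(spatial_regularization(S, H, chunk_size = 7),
               spatial_regularization(S, H, chunk_size = 4000),
               tolerance = 1e-12)
})

test_that("total loss is the stated weighted sum", {
  cfg <- hyperspot_config(lambda = 0.1, gamma = 1)
  expect_equal(total_loss(1, 2, 3, cfg), 4.2)
  set.seed(45)
  for (i in 1:20) {
    l <- runif(3); lam <- runif(1); gam <- runif(1)
    cfg2 <- hyperspot_config(lambda = lam, gamma = gam)
    expect_equal(total_loss(l[1], l[2], l[3], cfg2),
                 l[1] + lam * l[2] + gam * l[3])
  }
})

test_that("pretraining reduces reconstruction loss and is deterministic", {
  ds <- simulate_spatial(n_spots = 80, n_genes = 30, n_domains = 2, seed = 46)
  pp <- preprocess(ds, min_spots = 2, n_components = 20)
  cfg <- tiny_config(pretrain_epochs = 30)
  A <- spatial_hypergraph(ds$coords, k = cfg$k)$A_hp
  out <- pretrain(pp$features$values, A, ds$coords, cfg)
  expect_lt(out$trace$rec[30], out$trace$rec[1])
  out2 <- pretrain(pp$features$values, A, ds$coords, cfg)
  expect_equal(out$trace$rec[30], out2$trace$rec[30], tolerance = 1e-6)

  # lr -> 0 freezes the parameters (the loss trace still fluctuates with the
  # per-epoch reparameterization draw)
  cfg0 <- tiny_config(pretrain_epochs = 5, lr = 1e-300)
  p_init <- init_params(ncol(pp$features$values), cfg0)
  out0 <- pretrain(pp$features$values, A, ds$coords, cfg0, params = p_init)
  expect_equal(out0$params, p_init, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fit recovers planted domains on a scaled-down fixture", {
  ds <- simulate_spatial(n_spots = 300, n_genes = 80, n_domains = 4,
                         seed = 47)
  cfg <- hyperspot_config(pretrain_epochs = 60, train_epochs = 60,
                          n_components = 50, seed = 47)
  fit <- hyperspot(ds, config = cfg)
  p <- predict(fit, n_domains = 4)
  expect_gte(ari(ds$labels, p), 0.8)

  # DEC state well formed
  expect_equal(rowSums(fit$cluster$Q), rep(1, 300), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rowSums(fit$cluster$T), rep(1, 300), tolerance = 1e-6,
               ignore_attr = TRUE)
  # optimization progress on the combined objective
  tr <- fit$losses[fit$losses$stage == "train", ]
  expect_lte(tr$total[nrow(tr)], tr$total[1])
})

test_that("degenerate weights reduce fit to autoencoder refinement", {
  ds <- simulate_spatial(n_spots = 100, n_genes = 30, n_domains = 2, seed = 48)
  cfg <- tiny_config(lambda = 0, gamma = 0, pretrain_epochs = 10,
                     train_epochs = 10)
  fit <- hyperspot(ds, config = cfg)
  tr <- fit$losses[fit$losses$stage == "train", ]
  # DEC state still returned, but the clustering loss takes no Adam credit:
  # centroids stay at their k-means initialization
  expect_equal(nrow(fit$cluster$centroids), cfg$n_centroids)
  expect_lte(tr$rec[nrow(tr)], tr$rec[1])
})

test_that("stronger spatial weight does not decouple embedding from space", {
  ds <- simulate_spatial(n_spots = 150, n_genes = 40, n_domains = 3, seed = 49)
  spearman <- function(fit) {
    dh <- as.vector(dist(fit$embedding))
    dsd <- as.vector(dist(fit$coords))
    cor(dh, dsd, method = "spearman")
  }
  cfg1 <- hyperspot_config(gamma = 1, pretrain_epochs = 30, train_epochs = 30,
                           n_components = 30, seed = 49)
  cfg0 <- hyperspot_config(gamma = 0, pretrain_epochs = 30, train_epochs = 30,
                           n_components = 30, seed = 49)
  r1 <- spearman(hyperspot(ds, config = cfg1))
  r0 <- spearman(hyperspot(ds, config = cfg0))
  expect_gte(r1, r0)
})
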