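test_that("leiden recovers well-separated blobs at the target count", {
  set.seed(51)
  n_per <- 40
  H <- rbind(matrix(rnorm(n_per * 2, 0), n_per, 2),
             matrix(rnorm(n_per * 2, 12), n_per, 2))
  truth <- rep(1:2, each = n_per)
  part <- leiden_with_target_k(H, 2, seed = 3)
  expect_equal(part$n_clusters, 2)
  expect_true(part$exact)
  expect_equal(ari(truth, part), 1)

  # determinism
  part2 <- leiden_with_target_k(H, 2, seed = 3)
  expect_identical(part$assignments, part2$assignments)

  # unattainable counts are flagged rather than fabricated
  set.seed(52)
  Hs <- matrix(rnorm(24), 12, 2)
  ps <- leiden_with_target_k(Hs, 12, seed = 1, k = 5)
  expect_s3_class(ps, "partition")
  if (ps$n_clusters != 12) expect_false(ps$exact)

  expect_error(leiden_with_target_k(Hs, 13, seed = 1), "parameter error")
  expect_error(leiden_with_target_k(Hs, 1, seed = 1), "parameter error")
})

test_that("ARI matches the hand-worked case and brute-force pair counting", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  set.seed(53)
  for (rep in 1:50) {
    n <- sample(8:60, 1)
    g <- sample(1:4, n, replace = TRUE)
    p <- sample(1:3, n, replace = TRUE)
    expect_equal(ari(g, p), ari_pair_oracle(g, p), tolerance = 1e-10)
  }
  expect_error(ari(1:4, 1:5), "length mismatch")
})

test_that("NMI matches the contingency oracle and its edge cases", {
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  set.seed(54)
  for (rep in 1:30) {
    n <- sample(8:50, 1)
    g <- sample(1:3, n, replace = TRUE)
    p <- sample(1:4, n, replace = TRUE)
    expect_equal(nmi(g, p), nmi_contingency_oracle(g, p), tolerance = 1e-10)
  }
  # single cluster in both partitions
  expect_equal(nmi(rep(1, 5), rep(2, 5)), 1)
  expect_equal(nmi(rep(1, 5), c(1, 1, 1, 2, 2)), 0)
})

test_that("ARI and NMI are symmetric and invariant to label renaming", {
  set.seed(55)
  g <- sample(1:3, 40, replace = TRUE)
  p <- sample(1:4, 40, replace = TRUE)
  expect_equal(ari(g, p), ari(p, g))
  expect_equal(nmi(g, p), nmi(p, g))
  relab <- c(7, 2, 9)[g]  # injective renaming
  expect_equal(ari(relab, p), ari(g, p))
  expect_equal(nmi(relab, p), nmi(g, p))
})

test_that("label Moran index matches its closed forms", {
  set.seed(56)
  S <- matrix(runif(100), 50, 2)
  expect_equal(moran_label(rep(1, 50), S, k = 5), 1)

  # two distant clumps, uniformly labelled, k too small to cross
  S2 <- rbind(matrix(runif(40, 0, 1), 20, 2),
              matrix(runif(40, 50, 51), 20, 2))
  lab2 <- rep(1:2, each = 20)
  expect_equal(moran_label(lab2, S2, k = 5), 1)
  expect_error(moran_label(lab2, S2, k = 40), "too few spots")

  # label renaming invariance
  lab3 <- sample(1:3, 50, replace = TRUE)
  expect_equal(moran_label(lab3, S, k = 5),
               moran_label(c(9, 4, 7)[lab3], S, k = 5))
})

test_that("the simplified Moran ratio equals the literal printed form", {
  set.seed(57)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    S <- matrix(runif(n * 2), n, 2)
    lab <- sample(1:4, n, replace = TRUE)
    expect_equal(moran_label(lab, S, k = 5),
                 moran_literal_oracle(lab, S, k = 5), tolerance = 1e-12)
  }
})

test_that("random labels give Moran about 1/c", {
  set.seed(58)
  S <- matrix(runif(1000), 500, 2)
  vals <- replicate(20, moran_label(sample(1:4, 500, replace = TRUE), S))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.25), 3 * se + 0.01)
})

test_that("marker ranking recovers planted markers and ignores flat genes", {
  ds <- simulate_spatial(n_spots = 200, n_genes = 50, n_domains = 3,
                         markers_per_domain = 2, marker_effect = 3, seed = 59)
  markers <- attr(ds, "marker_genes")
  dsn <- normalize_log_scale(filter_genes(ds, min_spots = 2))
  res <- rank_marker_genes(dsn, ds$labels, top_n = 10)
  for (d in 1:3) {
    top1 <- res$gene[res$cluster == d & res$rank == 1]
    expect_true(top1 %in% markers[[d]])
  }
  # p-values permutation invariant in the spots
  set.seed(60)
  perm <- sample(200)
  dsp <- dsn
  dsp$lognorm <- dsn$lognorm[perm, ]
  res_p <- rank_marker_genes(dsp, ds$labels[perm], top_n = 10)
  expect_equal(res_p$p_value[order(res_p$cluster, res_p$gene)],
               res$p_value[order(res$cluster, res$gene)], tolerance = 1e-12)

  # a constant gene is never top-1 while planted markers exist
  dsc <- dsn
  dsc$lognorm[, 5] <- 1
  res_c <- rank_marker_genes(dsc, ds$labels, top_n = 10)
  expect_false(any(res_c$gene[res_c$rank == 1] == dsn$gene_names[5]))

  # singleton cluster skipped with a warning
  lab_bad <- ds$labels
  lab_bad[1] <- 99
  expect_warning(rank_marker_genes(dsn, lab_bad, top_n = 5), "skipped")
})

test_that("perfectly separated embeddings round-trip to perfect metrics", {
  set.seed(61)
  H <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
             matrix(rnorm(60, 8, 0.3), 30, 2),
             matrix(rnorm(60, -8, 0.3), 30, 2))
  truth <- rep(1:3, each = 30)
  part <- leiden_with_target_k(H, 3, seed = 2)
  expect_equal(ari(truth, part), 1)
  expect_equal(nmi(truth, part), 1)
})
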