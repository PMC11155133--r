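#' Student-t soft cluster assignment
#'
#' `q_ik = (1 + ||h_i - mu_k||^2)^{-1} / sum_k' (1 + ||h_i - mu_k'||^2)^{-1}`:
#' the similarity of each spot embedding to each centroid under a Student's
#' t kernel (one degree of freedom), normalized so each row sums to 1.
#'
#' @param H N x D embedding matrix.
#' @param centroids K x D centroid matrix.
#' @return N x K soft-assignment matrix Q.
#' @export
soft_assignment <- function(H, centroids) {
  H <- as.matrix(H); centroids <- as.matrix(centroids)
  if (ncol(H) != ncol(centroids))
    stop("dimension error: embedding dim ", ncol(H),
         " vs centroid dim ", ncol(centroids))
  u <- 1 / (1 + pairwise_sq_dists(H, centroids))
  u / rowSums(u)
}

#' DEC target distribution
#'
#' Sharpened auxiliary distribution `t_ik = (q_ik^2 / f_k) / sum_k'
#' (q_ik'^2 / f_k')` with cluster frequencies `f_k = sum_i q_ik`; it
#' up-weights high-confidence assignments while normalizing away cluster
#' size. Clusters with (numerically) zero soft mass are guarded with an
#' epsilon and flagged with a warning.
#'
#' @param Q N x K soft-assignment matrix.
#' @return N x K target matrix T with unit row sums.
#' @export
target_distribution <- function(Q) {
  f <- colSums(Q)
  if (any(f < 1e-12)) {
    warning("cluster(s) with zero total soft mass; epsilon guard applied")
    f <- pmax(f, 1e-12)
  }
  w <- sweep(Q^2, 2, f, "/")
  w / rowSums(w)
}

#' DEC clustering loss
#'
#' `KL(T || Q) = sum_i sum_k t_ik log(t_ik / q_ik)`; non-negative, zero iff
#' `T == Q`. Zero assignment probabilities facing nonzero targets are
#' epsilon-floored with a warning.
#'
#' @param T_mat target distribution.
#' @param Q soft assignment.
#' @return Scalar KL divergence.
#' @export
dec_loss <- function(T_mat, Q) {
  stopifnot(all(dim(T_mat) == dim(Q)))
  if (any(Q <= 0 & T_mat > 0)) {
    warning("zero q with nonzero t; epsilon floor applied")
    Q <- pmax(Q, 1e-12)
  }
  pos <- T_mat > 0
  sum(T_mat[pos] * log(T_mat[pos] / Q[pos]))
}

#' Pairwise spatial regularization
#'
#' `Loss_spa = (1/N^2) sum_ij D_ij^(s) (1 - D_ij^(h))` over all ordered spot
#' pairs, where `D^(s)` and `D^(h)` are the pairwise Euclidean distance
#' matrices of the coordinates and of the embedding, each min-max normalized
#' to `[0, 1]` (a zero-range matrix normalizes to all zeros). Spatially
#' distant pairs are penalized for being close in embedding space.
#'
#' The exact mode evaluates the full double sum in row chunks; the sampled
#' mode is a Monte-Carlo estimate over uniformly drawn ordered pairs, for
#' use when N makes the N^2 sum impractical.
#'
#' @param S N x 2 coordinates.
#' @param H N x D embedding.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_pairs number of sampled ordered pairs in sampled mode.
#' @param seed RNG seed for sampling.
#' @param chunk_size rows per chunk in exact mode.
#' @param return_se in sampled mode, also return the Monte-Carlo standard
#'   error (list with `value`, `se`).
#' @return Scalar loss (or a list in sampled mode with `return_se = TRUE`).
#' @export
spatial_regularization <- function(S, H, mode = c("exact", "sampled"),
                                   n_pairs = 2048, seed = 1,
                                   chunk_size = 2048, return_se = FALSE) {
  mode <- match.arg(mode)
  S <- as.matrix(S); H <- as.matrix(H)
  n <- nrow(S)
  if (n < 2) stop("need at least 2 spots")
  if (nrow(H) != n) stop("dimension error: S and H row mismatch")
  if (any(!is.finite(H))) stop("numerical error: non-finite embedding")
  max_s <- max_pair_dist(S, chunk_size)
  max_h <- max_pair_dist(H, chunk_size)
  if (mode == "exact") {
    total <- 0
    for (rows in chunk_indices(n, chunk_size)) {
      ds <- sqrt(pairwise_sq_dists(S[rows, , drop = FALSE], S))
      dh <- sqrt(pairwise_sq_dists(H[rows, , drop = FALSE], H))
      if (max_s > 0) ds <- ds / max_s else ds[] <- 0
      if (max_h > 0) dh <- dh / max_h else dh[] <- 0
      total <- total + sum(ds * (1 - dh))
    }
    return(total / n^2)
  }
  set.seed(seed)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  ds <- sqrt(rowSums((S[i, , drop = FALSE] - S[j, , drop = FALSE])^2))
  dh <- sqrt(rowSums((H[i, , drop = FALSE] - H[j, , drop = FALSE])^2))
  if (max_s > 0) ds <- ds / max_s else ds[] <- 0
  if (max_h > 0) dh <- dh / max_h else dh[] <- 0
  vals <- ds * (1 - dh)
  if (return_se)
    list(value = mean(vals), se = stats::sd(vals) / sqrt(n_pairs))
  else mean(vals)
}

max_pair_dist <- function(M, chunk_size = 2048) {
  n <- nrow(M)
  mx <- 0
  for (rows in chunk_indices(n, chunk_size))
    mx <- max(mx, pairwise_sq_dists(M[rows, , drop = FALSE], M))
  sqrt(mx)
}

chunk_indices <- function(n, size) {
  starts <- seq(1L, n, by = size)
  lapply(starts, function(s) s:min(s + size - 1L, n))
}

#' Combined training objective
#'
#' `L = Loss_rec + lambda * Loss_clu + gamma * Loss_spa`. Setting
#' `lambda = 0` gives the spatial-only ablation, `gamma = 0` the
#' clustering-only ablation.
#'
#' @param loss_rec,loss_clu,loss_spa component losses.
#' @param cfg a [hyperspot_config()] supplying `lambda` and `gamma`.
#' @return Scalar total loss.
#' @export
total_loss <- function(loss_rec, loss_clu, loss_spa, cfg = hyperspot_config()) {
  stopifnot(is.finite(loss_rec), is.finite(loss_clu), is.finite(loss_spa))
  loss_rec + cfg$lambda * loss_clu + cfg$gamma * loss_spa
}

# ---- analytic gradients -----------------------------------------------------

# Normalized spatial distance matrix (min-max to [0,1]; diagonal zero so the
# minimum is always 0) precomputed once per training run.
normalized_spatial_dists <- function(S) {
  d <- sqrt(pairwise_sq_dists(S, S))
  mx <- max(d)
  if (mx > 0) d / mx else d
}

# Value and gradient wrt H of the exact Eq-style spatial term, including the
# gradient path through the max used for min-max normalization.
spa_value_grad <- function(Dsn, H) {
  n <- nrow(H)
  d2 <- pairwise_sq_dists(H, H)
  dh <- sqrt(d2)
  mx <- max(dh)
  if (mx == 0) {
    # all embeddings identical: loss = mean(Dsn), flat almost everywhere
    return(list(value = mean(Dsn), grad_H = matrix(0, n, ncol(H))))
  }
  value <- sum(Dsn * (1 - dh / mx)) / n^2
  # d L / d dh_ij = -Dsn_ij / (n^2 mx); plus through mx at the argmax pair
  sd_sum <- sum(Dsn * dh)
  W <- Dsn / pmax(dh, 1e-300)
  diag(W) <- 0
  W[dh == 0] <- 0
  # sum over ordered pairs of -Dsn_ij/(n^2 mx) * d dh_ij/dH
  grad <- (-(2 / (n^2 * mx))) * (rowSums(W) * H - W %*% H)
  am <- arrayInd(which.max(dh), dim(dh))
  i <- am[1]; j <- am[2]
  gmax <- (H[i, ] - H[j, ]) / mx
  coef <- sd_sum / (n^2 * mx^2)
  grad[i, ] <- grad[i, ] + coef * gmax
  grad[j, ] <- grad[j, ] - coef * gmax
  list(value = value, grad_H = grad)
}

# DEC loss value and gradients wrt H and centroids, T fixed.
dec_value_grad <- function(H, centroids, T_mat) {
  d2 <- pairwise_sq_dists(H, centroids)
  u <- 1 / (1 + d2)
  Q <- u / rowSums(u)
  value <- dec_loss(T_mat, Q)
  # dL/d d2_ik = u_ik (t_ik - q_ik); dL/dh_i = 2 sum_k u(t-q)(h_i - c_k)
  G <- u * (T_mat - Q)
  grad_H <- 2 * (rowSums(G) * H - G %*% centroids)
  grad_C <- 2 * (colSums(G) * centroids - crossprod(G, H))
  list(value = value, Q = Q, grad_H = grad_H, grad_C = grad_C)
}

# Full loss + analytic gradients for one training step.
# T_mat/centroids NULL -> pretraining (no DEC term).
# eps NULL -> mean-mode spatial embedding.
loss_and_grads <- function(params, X, A_hp, Dsn, lambda, gamma,
                           T_mat = NULL, centroids = NULL, eps = NULL) {
  fw <- forward_model(params, X, A_hp, eps = eps)
  n <- nrow(X); f <- ncol(X)
  df <- ncol(fw$H_f)

  resid <- fw$X_prime - X
  loss_rec <- mean(resid^2)

  dXp <- 2 * resid / (n * f)
  g <- list(W_dec = crossprod(fw$H, dXp), b_dec = colSums(dXp))
  dH <- dXp %*% t(params$W_dec)

  # The DEC KL is a double sum over spots and clusters; inside the training
  # objective it is normalized per spot so that all three loss terms share
  # the per-observation scale and lambda is comparable across dataset sizes.
  loss_clu <- 0
  grad_C <- NULL
  if (!is.null(T_mat) && lambda > 0) {
    dec <- dec_value_grad(fw$H, centroids, T_mat)
    loss_clu <- dec$value / n
    dH <- dH + (lambda / n) * dec$grad_H
    grad_C <- (lambda / n) * dec$grad_C
  } else if (!is.null(T_mat)) {
    loss_clu <- dec_loss(T_mat, soft_assignment(fw$H, centroids)) / n
    grad_C <- matrix(0, nrow(centroids), ncol(centroids))
  }

  loss_spa <- 0
  if (gamma > 0) {
    spa <- spa_value_grad(Dsn, fw$H)
    loss_spa <- spa$value
    dH <- dH + gamma * spa$grad_H
  } else {
    loss_spa <- spa_value_grad(Dsn, fw$H)$value
  }

  dHf <- dH[, seq_len(df), drop = FALSE]
  dHg <- dH[, -seq_len(df), drop = FALSE]

  # spatial head(s)
  dMu <- dHg
  if (!is.null(eps)) {
    dLs <- dHg * fw$eps * fw$sigma
    dLs[fw$ls_raw < -LOGVAR_CLAMP | fw$ls_raw > LOGVAR_CLAMP] <- 0
  }
  bp_head <- function(dOut, r1, m1, W1, W2) {
    AdOut <- as.matrix(A_hp %*% dOut)
    gW2 <- crossprod(r1, AdOut)
    dM1 <- (AdOut %*% t(W2)) * (m1 > 0)
    gW1 <- crossprod(fw$AHf, dM1)
    dHf_part <- as.matrix(A_hp %*% (dM1 %*% t(W1)))
    list(gW1 = gW1, gW2 = gW2, dHf = dHf_part)
  }
  mu_bp <- bp_head(dMu, fw$r_mu, fw$m_mu, params$W1_mu, params$W2_mu)
  g$W1_mu <- mu_bp$gW1; g$W2_mu <- mu_bp$gW2
  dHf_total <- dHf + mu_bp$dHf
  if (!is.null(eps)) {
    sg_bp <- bp_head(dLs, fw$r_sg, fw$m_sg, params$W1_sg, params$W2_sg)
    g$W1_sg <- sg_bp$gW1; g$W2_sg <- sg_bp$gW2
    dHf_total <- dHf_total + sg_bp$dHf
  } else {
    g$W1_sg <- matrix(0, nrow(params$W1_sg), ncol(params$W1_sg))
    g$W2_sg <- matrix(0, nrow(params$W2_sg), ncol(params$W2_sg))
  }

  # expression encoder
  dZ2 <- dHf_total * elu_grad(fw$z2)
  g$W_b <- crossprod(fw$a1, dZ2); g$b_b <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W_b)
  dZ1 <- dA1 * elu_grad(fw$z1)
  g$W_a <- crossprod(X, dZ1); g$b_a <- colSums(dZ1)

  total <- loss_rec + lambda * loss_clu + gamma * loss_spa
  list(losses = c(rec = loss_rec, clu = loss_clu, spa = loss_spa,
                  total = total),
       grads = g[names(params)], grad_centroids = grad_C, forward = fw)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Pretrain the autoencoders
#'
#' Stage one of training: full-batch Adam on the reconstruction loss plus
#' the spatial regularizer (the DEC loss is excluded at this stage), for
#' `cfg$pretrain_epochs` epochs. The variational spatial embedding is
#' sampled (reparameterized) at every step.
#'
#' @param X N x F preprocessed feature matrix.
#' @param A_hp normalized hypergraph adjacency.
#' @param S N x 2 coordinates (for the spatial term).
#' @param cfg a [hyperspot_config()].
#' @param params optional initial parameters (default fresh Glorot init).
#' @return List with trained `params` and a per-epoch `trace` data frame
#'   (`rec`, `clu`, `spa`, `total`).
#' @export
pretrain <- function(X, A_hp, S, cfg = hyperspot_config(), params = NULL) {
  X <- as.matrix(X)
  if (is.null(params)) params <- init_params(ncol(X), cfg)
  Dsn <- normalized_spatial_dists(as.matrix(S))
  st <- adam_init(params)
  set.seed(derive_seed(cfg$seed, "pretrain"))
  n <- nrow(X); dg <- cfg$d_g
  trace <- matrix(NA_real_, cfg$pretrain_epochs, 4,
                  dimnames = list(NULL, c("rec", "clu", "spa", "total")))
  for (ep in seq_len(cfg$pretrain_epochs)) {
    eps <- matrix(stats::rnorm(n * dg), n, dg)
    lg <- loss_and_grads(params, X, A_hp, Dsn, lambda = 0, gamma = cfg$gamma,
                         eps = eps)
    if (!all(is.finite(lg$losses)))
      stop("loss divergence at pretraining epoch ", ep)
    trace[ep, ] <- lg$losses
    upd <- adam_step(params, lg$grads, st, cfg$lr)
    params <- upd$params; st <- upd$state
  }
  list(params = params, trace = as.data.frame(trace))
}
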