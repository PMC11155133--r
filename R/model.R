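#' Model configuration
#'
#' All hyperparameters of the embedding model and its two-stage training
#' schedule, with the defaults used across datasets: kNN size `k = 20`,
#' clustering-loss weight `lambda = 0.1`, spatial-regularization weight
#' `gamma = 1`, Adam learning rate `lr = 0.01`, 200 pretraining and 200
#' clustering-stage epochs, expression-encoder dims 100 -> 20, hypergraph
#' convolution dims 32 -> 8, and 10 k-means centroids.
#'
#' @param k spatial kNN size for the hypergraph.
#' @param lambda weight of the deep-embedded-clustering KL loss.
#' @param gamma weight of the spatial regularizer.
#' @param lr Adam learning rate.
#' @param pretrain_epochs epochs of reconstruction(+spatial) pretraining.
#' @param train_epochs epochs of the clustering stage.
#' @param d_f expression embedding dimension.
#' @param d_g spatial embedding dimension.
#' @param hidden_expr hidden width of the expression encoder.
#' @param hidden_hgcn hidden width of the hypergraph convolution.
#' @param n_centroids number of DEC centroids (k-means initialized).
#' @param n_components PCA dimension target for preprocessing.
#' @param min_spots gene-filter threshold for preprocessing.
#' @param seed master seed; every stochastic stage consumes a sub-seed
#'   derived from it and the stage name.
#' @return A list of class `hyperspot_config`.
#' @export
hyperspot_config <- function(k = 20, lambda = 0.1, gamma = 1, lr = 0.01,
                             pretrain_epochs = 200, train_epochs = 200,
                             d_f = 20, d_g = 8, hidden_expr = 100,
                             hidden_hgcn = 32, n_centroids = 10,
                             n_components = 200, min_spots = 5, seed = 1) {
  cfg <- list(k = k, lambda = lambda, gamma = gamma, lr = lr,
              pretrain_epochs = pretrain_epochs, train_epochs = train_epochs,
              d_f = d_f, d_g = d_g, hidden_expr = hidden_expr,
              hidden_hgcn = hidden_hgcn, n_centroids = n_centroids,
              n_components = n_components, min_spots = min_spots,
              seed = as.integer(seed))
  stopifnot(cfg$lambda >= 0, cfg$gamma >= 0, cfg$lr > 0,
            cfg$pretrain_epochs >= 1, cfg$train_epochs >= 1,
            cfg$d_f >= 1, cfg$d_g >= 1, cfg$n_centroids >= 2, cfg$k >= 1)
  class(cfg) <- "hyperspot_config"
  cfg
}

# Deterministic per-stage sub-seed below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + h * 7919) %% 2147483646 + 1)
}

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))
relu <- function(x) pmax(x, 0)

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' Uniform Glorot (fan-based) initialization under the given seed. The
#' expression encoder uses two affine layers with Elu; the two hypergraph
#' convolution heads (mean and log-std) are bias-free per the convolution
#' definition; the decoder is one affine layer from the joint embedding back
#' to the feature space.
#'
#' @param n_features input feature dimension F.
#' @param cfg a [hyperspot_config()].
#' @param seed RNG seed (defaults to a sub-seed of `cfg$seed`).
#' @return Named list of weight matrices and bias vectors.
#' @export
init_params <- function(n_features, cfg = hyperspot_config(),
                        seed = derive_seed(cfg$seed, "init")) {
  set.seed(seed)
  h1 <- cfg$hidden_expr; df <- cfg$d_f
  h2 <- cfg$hidden_hgcn; dg <- cfg$d_g
  d <- df + dg
  list(
    W_a = glorot(n_features, h1), b_a = numeric(h1),
    W_b = glorot(h1, df), b_b = numeric(df),
    W1_mu = glorot(df, h2), W2_mu = glorot(h2, dg),
    W1_sg = glorot(df, h2), W2_sg = glorot(h2, dg),
    W_dec = glorot(d, n_features), b_dec = numeric(n_features)
  )
}

#' Expression encoder forward pass
#'
#' `H_f = Elu(Elu(X W_a + b_a) W_b + b_b)`: two stacked affine layers with
#' Elu activations mapping features to the low-dimensional expression
#' embedding.
#'
#' @param X N x F feature matrix.
#' @param params parameter list from [init_params()].
#' @return N x D_f embedding matrix.
#' @export
encode_expression <- function(X, params) {
  if (ncol(X) != nrow(params$W_a))
    stop("configuration error: X has ", ncol(X), " features but encoder expects ",
         nrow(params$W_a))
  z1 <- sweep(X %*% params$W_a, 2, params$b_a, "+")
  elu(sweep(elu(z1) %*% params$W_b, 2, params$b_b, "+"))
}

#' Two-layer hypergraph convolution
#'
#' `HGCN(A_hp, H_f) = A_hp ReLU(A_hp H_f W_1) W_2` — message passing driven
#' by the normalized hypergraph adjacency, with no bias terms.
#'
#' @param A_hp N x N normalized hypergraph adjacency.
#' @param H_f N x D_f input embedding.
#' @param W_1,W_2 layer weight matrices.
#' @return N x ncol(W_2) output.
#' @export
hgcn_forward <- function(A_hp, H_f, W_1, W_2) {
  if (nrow(A_hp) != nrow(H_f))
    stop("dimension error: A_hp is ", nrow(A_hp), "x", ncol(A_hp),
         " but H_f has ", nrow(H_f), " rows")
  as.matrix(A_hp %*% relu(as.matrix(A_hp %*% H_f) %*% W_1) %*% W_2)
}

LOGVAR_CLAMP <- 10

#' Variational spatial embedding
#'
#' Two independent hypergraph-convolution heads give the posterior mean
#' `mu = HGCN_mu(A_hp, H_f)` and log standard deviation
#' `log sigma = HGCN_sigma(A_hp, H_f)` (clamped to `[-10, 10]` before
#' exponentiation for numerical stability). With `sample = TRUE` the
#' embedding is the reparameterized draw `H_g = mu + sigma * eps`,
#' `eps ~ N(0, 1)` under `seed`; otherwise (inference mode) `H_g = mu`.
#' No KL prior term is ever added to any loss.
#'
#' @param A_hp normalized hypergraph adjacency.
#' @param H_f expression embedding.
#' @param params parameter list with the two head weights.
#' @param seed RNG seed for the reparameterization noise.
#' @param sample draw from the posterior (TRUE) or return the mean (FALSE).
#' @return N x D_g spatial embedding.
#' @export
vgae_spatial_embedding <- function(A_hp, H_f, params, seed = 1, sample = FALSE) {
  mu <- hgcn_forward(A_hp, H_f, params$W1_mu, params$W2_mu)
  if (!sample) return(mu)
  log_sigma <- hgcn_forward(A_hp, H_f, params$W1_sg, params$W2_sg)
  log_sigma <- pmin(pmax(log_sigma, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  if (any(!is.finite(log_sigma)))
    stop("numerical-stability error: non-finite log-variance head output")
  set.seed(seed)
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(log_sigma) * eps
}

#' Decode the joint embedding and measure reconstruction error
#'
#' One affine layer maps the joint embedding back to feature space;
#' `reconstruction_loss` is the mean squared error over all N x F entries.
#'
#' @param H N x D joint embedding.
#' @param params parameter list (decoder weights).
#' @return `decode_reconstruct`: N x F reconstruction.
#' @export
decode_reconstruct <- function(H, params) {
  if (ncol(H) != nrow(params$W_dec))
    stop("dimension error: joint embedding dim ", ncol(H),
         " does not match decoder input ", nrow(params$W_dec))
  sweep(H %*% params$W_dec, 2, params$b_dec, "+")
}

#' @rdname decode_reconstruct
#' @param X original feature matrix.
#' @param X_prime reconstruction.
#' @return `reconstruction_loss`: scalar mean squared error.
#' @export
reconstruction_loss <- function(X, X_prime) {
  stopifnot(all(dim(X) == dim(X_prime)))
  mean((X - X_prime)^2)
}

# Full forward pass with cached intermediates for backprop.
# eps = NULL -> inference mode (H_g = mu).
forward_model <- function(params, X, A_hp, eps = NULL) {
  z1 <- sweep(X %*% params$W_a, 2, params$b_a, "+")
  a1 <- elu(z1)
  z2 <- sweep(a1 %*% params$W_b, 2, params$b_b, "+")
  hf <- elu(z2)

  ahf <- as.matrix(A_hp %*% hf)
  m_mu <- ahf %*% params$W1_mu
  r_mu <- relu(m_mu)
  mu <- as.matrix(A_hp %*% r_mu) %*% params$W2_mu

  if (is.null(eps)) {
    hg <- mu
    m_sg <- r_sg <- ls_raw <- sigma <- NULL
  } else {
    m_sg <- ahf %*% params$W1_sg
    r_sg <- relu(m_sg)
    ls_raw <- as.matrix(A_hp %*% r_sg) %*% params$W2_sg
    ls <- pmin(pmax(ls_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
    sigma <- exp(ls)
    if (any(!is.finite(sigma)))
      stop("numerical-stability error: non-finite sigma in spatial head")
    hg <- mu + sigma * eps
  }
  h <- cbind(hf, hg)
  xp <- sweep(h %*% params$W_dec, 2, params$b_dec, "+")
  list(z1 = z1, a1 = a1, z2 = z2, H_f = hf, AHf = ahf,
       m_mu = m_mu, r_mu = r_mu, mu = mu,
       m_sg = m_sg, r_sg = r_sg, ls_raw = ls_raw, sigma = sigma,
       H_g = hg, H = h, X_prime = xp, eps = eps)
}
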