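#' Fit the hypergraph spatial-embedding model
#'
#' The main entry point. Takes a spatial transcriptomics dataset (raw counts
#' plus coordinates), preprocesses it (gene filter, per-spot total
#' normalization, log1p, per-gene scaling, optional PCA), builds the spatial
#' kNN hypergraph, and trains the joint embedding in two stages:
#'
#' 1. *Pretraining* — the expression autoencoder and the variational
#'    hypergraph-convolution spatial encoder are optimized with the
#'    reconstruction loss plus the spatial regularizer (no clustering loss).
#' 2. *Clustering stage* — k-means (default 10 centroids) initializes a deep
#'    embedded clustering (DEC) head on the joint embedding; Adam then
#'    minimizes `Loss_rec + lambda * KL(T || Q) + gamma * Loss_spa`, with the
#'    target distribution `T` recomputed from the current soft assignment
#'    once per epoch and the centroids trained as free parameters.
#'
#' The returned object carries the final joint embedding (posterior-mean
#' spatial head), the DEC cluster state, the loss traces, and everything
#' needed by [predict.hyperspot()] to segment domains and by
#' [rank_marker_genes()] to rank markers.
#'
#' @param x a [spot_dataset()] (raw counts, or already normalized), or a
#'   numeric feature matrix (spots x features) if `coords` is given.
#' @param coords N x 2 coordinate matrix; ignored when `x` is a
#'   `spot_dataset`.
#' @param config a [hyperspot_config()].
#' @param ... passed to [hyperspot_config()] when `config` is missing
#'   (e.g. `gamma = 0`, `seed = 7`).
#' @return An object of class `hyperspot`; see Details.
#' @seealso [predict.hyperspot()], [leiden_with_target_k()],
#'   [evaluate_partition()], [rank_marker_genes()]
#' @examples
#' ds <- simulate_spatial(n_spots = 120, n_genes = 40, n_domains = 3,
#'                        seed = 1)
#' cfg <- hyperspot_config(pretrain_epochs = 5, train_epochs = 5, seed = 1)
#' fit <- hyperspot(ds, config = cfg)
#' print(fit)
#' dom <- predict(fit, n_domains = 3)
#' @export
hyperspot <- function(x, coords = NULL, config = NULL, ...) {
  cl <- match.call()
  if (is.null(config)) config <- hyperspot_config(...)
  stopifnot(inherits(config, "hyperspot_config"))

  labels <- NULL
  lognorm <- NULL
  gene_names <- NULL
  if (inherits(x, "spot_dataset")) {
    if (!"normalize_log_scale" %in% x$provenance) {
      pp <- preprocess(x, min_spots = config$min_spots,
                       n_components = config$n_components)
      ds <- pp$dataset
      X <- pp$features$values
    } else {
      ds <- x
      X <- x$X
    }
    S <- ds$coords
    labels <- ds$labels
    lognorm <- ds$lognorm
    gene_names <- ds$gene_names
    spot_ids <- ds$spot_ids
  } else {
    X <- as.matrix(x)
    if (is.null(coords)) stop("no spatial information: coords required")
    S <- as.matrix(coords)
    if (nrow(S) != nrow(X)) stop("alignment error: coords vs matrix rows")
    spot_ids <- rownames(X)
    if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(X)))
  }
  if (config$n_centroids > nrow(X))
    stop("more centroids than spots: K = ", config$n_centroids,
         " > N = ", nrow(X))

  hgr <- spatial_hypergraph(S, k = config$k)
  pre <- pretrain(X, hgr$A_hp, S, config)
  fitted <- fit_dec(pre$params, X, hgr$A_hp, S, config)

  trace <- rbind(cbind(stage = "pretrain", epoch = seq_len(nrow(pre$trace)),
                       pre$trace),
                 cbind(stage = "train", epoch = seq_len(nrow(fitted$trace)),
                       fitted$trace))
  rownames(trace) <- NULL

  obj <- list(embedding = fitted$H, H_f = fitted$H_f, H_g = fitted$H_g,
              reconstruction = fitted$X_prime,
              cluster = fitted$cluster,
              losses = trace, config = config, params = fitted$params,
              coords = S, spot_ids = spot_ids, labels = labels,
              lognorm = lognorm, gene_names = gene_names,
              features = X, A_hp = hgr$A_hp, call = cl)
  class(obj) <- "hyperspot"
  obj
}

# DEC clustering stage: k-means centroid init then joint optimization of
# Eq-style total loss with Adam; T refreshed once per epoch.
fit_dec <- function(params, X, A_hp, S, cfg) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (cfg$n_centroids > n)
    stop("more centroids than spots: K = ", cfg$n_centroids, " > N = ", n)
  Dsn <- normalized_spatial_dists(as.matrix(S))

  fw0 <- forward_model(params, X, A_hp, eps = NULL)
  set.seed(derive_seed(cfg$seed, "kmeans"))
  km <- stats::kmeans(fw0$H, centers = cfg$n_centroids, nstart = 10,
                      iter.max = 100)
  centroids <- unname(km$centers)

  full <- c(params, list(centroids = centroids))
  st <- adam_init(full)
  H_cur <- fw0$H
  trace <- matrix(NA_real_, cfg$train_epochs, 4,
                  dimnames = list(NULL, c("rec", "clu", "spa", "total")))
  set.seed(derive_seed(cfg$seed, "train"))
  for (ep in seq_len(cfg$train_epochs)) {
    Q <- soft_assignment(H_cur, full$centroids)
    if (max(abs(rowSums(Q) - 1)) > 1e-6)
      stop("soft assignment rows do not sum to 1 at epoch ", ep)
    T_mat <- target_distribution(Q)
    eps <- matrix(stats::rnorm(n * cfg$d_g), n, cfg$d_g)
    lg <- loss_and_grads(params, X, A_hp, Dsn,
                         lambda = cfg$lambda, gamma = cfg$gamma,
                         T_mat = T_mat, centroids = full$centroids, eps = eps)
    if (!all(is.finite(lg$losses)))
      stop("loss divergence at clustering-stage epoch ", ep)
    trace[ep, ] <- lg$losses
    grads <- c(lg$grads, list(centroids = lg$grad_centroids))
    upd <- adam_step(full, grads, st, cfg$lr)
    full <- upd$params; st <- upd$state
    params <- full[names(params)]
    H_cur <- lg$forward$H
  }
  fw <- forward_model(params, X, A_hp, eps = NULL)  # mean-mode final embedding
  Q <- soft_assignment(fw$H, full$centroids)
  cluster <- list(centroids = full$centroids, Q = Q,
                  T = target_distribution(Q))
  list(params = params, H = fw$H, H_f = fw$H_f, H_g = fw$H_g,
       X_prime = fw$X_prime, cluster = cluster,
       trace = as.data.frame(trace))
}

#' @export
print.hyperspot <- function(x, ...) {
  cat("hyperspot fit\n")
  cat("  spots: ", nrow(x$embedding), ", features: ", ncol(x$features),
      ", embedding dim: ", ncol(x$embedding),
      " (expression ", ncol(x$H_f), " + spatial ", ncol(x$H_g), ")\n", sep = "")
  last <- x$losses[nrow(x$losses), ]
  cat("  final losses: rec ", signif(last$rec, 4), ", clu ",
      signif(last$clu, 4), ", spa ", signif(last$spa, 4), ", total ",
      signif(last$total, 4), "\n", sep = "")
  cat("  lambda = ", x$config$lambda, ", gamma = ", x$config$gamma,
      ", k = ", x$config$k, ", seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.hyperspot <- function(object, ...) {
  hard <- max.col(object$cluster$Q)
  out <- list(n_spots = nrow(object$embedding),
              dim = ncol(object$embedding),
              config = object$config,
              dec_occupancy = table(factor(hard,
                levels = seq_len(object$config$n_centroids))),
              loss_first = object$losses[1, ],
              loss_last = object$losses[nrow(object$losses), ])
  class(out) <- "summary.hyperspot"
  out
}

#' @export
print.summary.hyperspot <- function(x, ...) {
  cat("hyperspot fit summary\n")
  cat("  N =", x$n_spots, " embedding dim =", x$dim, "\n")
  cat("  DEC centroid occupancy (hard argmax of Q):\n")
  print(x$dec_occupancy)
  cat("  loss first epoch: total", signif(x$loss_first$total, 5), "\n")
  cat("  loss last epoch:  total", signif(x$loss_last$total, 5), "\n")
  invisible(x)
}

#' Cluster centroids of a fitted model
#' @param object a `hyperspot` fit.
#' @param ... ignored.
#' @return K x D matrix of DEC centroids.
#' @export
coef.hyperspot <- function(object, ...) object$cluster$centroids

#' @export
fitted.hyperspot <- function(object, ...) object$reconstruction

#' @export
residuals.hyperspot <- function(object, ...)
  object$features - object$reconstruction

#' Extract embeddings or domain assignments from a fit
#'
#' `type = "embedding"` returns the joint embedding (or its expression /
#' spatial block). `type = "domains"` segments the embedding into
#' `n_domains` clusters: with `assigner = "leiden"` (default) via
#' [leiden_with_target_k()]; with `assigner = "dec"` via the argmax of the
#' DEC soft assignment (ignores `n_domains`; at most the configured number
#' of centroids).
#'
#' @param object a `hyperspot` fit.
#' @param type what to return.
#' @param n_domains target number of domains for the Leiden assigner.
#' @param assigner `"leiden"` or `"dec"`.
#' @param seed RNG seed for Leiden (defaults to the fit's master seed).
#' @param ... ignored.
#' @return A matrix (`embedding`) or an integer label vector (`domains`).
#' @export
predict.hyperspot <- function(object, type = c("domains", "embedding"),
                              n_domains = NULL,
                              assigner = c("leiden", "dec"),
                              seed = NULL, ...) {
  type <- match.arg(type)
  if (type == "embedding") return(object$embedding)
  assigner <- match.arg(assigner)
  if (assigner == "dec") {
    p <- max.col(object$cluster$Q)
    return(as.integer(factor(p)))
  }
  if (is.null(n_domains))
    stop("n_domains is required for the leiden assigner")
  if (is.null(seed)) seed <- derive_seed(object$config$seed, "leiden")
  leiden_with_target_k(object$embedding, n_domains, seed = seed)$assignments
}

#' Plot a fitted spatial segmentation
#'
#' Scatter of the spot coordinates coloured by domain (predicted via
#' [predict.hyperspot()], or ground truth when `use = "truth"`).
#'
#' @param x a `hyperspot` fit.
#' @param n_domains number of domains for the Leiden assigner.
#' @param use `"predicted"` or `"truth"`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.hyperspot <- function(x, n_domains = NULL, use = c("predicted", "truth"),
                           ...) {
  use <- match.arg(use)
  lab <- if (use == "truth") {
    if (is.null(x$labels)) stop("fit has no ground-truth labels")
    x$labels
  } else {
    if (is.null(n_domains))
      n_domains <- max(2L, length(unique(x$labels)))
    predict(x, n_domains = n_domains)
  }
  f <- as.integer(factor(lab))
  graphics::plot(x$coords[, 1], x$coords[, 2],
                 col = grDevices::hcl.colors(max(f), "Dark 3")[f],
                 pch = 16, xlab = "x", ylab = "y",
                 main = paste0("spatial domains (", use, ")"), ...)
  invisible(x)
}

#' Export the joint embedding as CSV
#'
#' @param object a `hyperspot` fit.
#' @param path output CSV path (spot_id + one column per dimension).
#' @export
export_embedding <- function(object, path) {
  stopifnot(inherits(object, "hyperspot"))
  df <- data.frame(spot_id = object$spot_ids, object$embedding)
  names(df)[-1] <- paste0("dim_", seq_len(ncol(object$embedding)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
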