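#' Filter genes by spot support
#'
#' Removes genes detected (nonzero) in fewer than `min_spots` spots. The spot
#' set is unchanged and row alignment with coordinates/labels is preserved.
#'
#' @param ds a raw-count [spot_dataset()].
#' @param min_spots minimum number of spots with nonzero expression a gene
#'   must reach to be kept (default 5).
#' @return The filtered `spot_dataset`.
#' @export
filter_genes <- function(ds, min_spots = 5) {
  stopifnot(inherits(ds, "spot_dataset"))
  check_not_applied(ds, "filter_genes")
  if ("normalize_log_scale" %in% ds$provenance)
    stop("filter_genes expects raw counts; dataset already normalized")
  keep <- colSums(ds$X != 0) >= min_spots
  if (!any(keep)) stop("empty gene set: no gene expressed in >= ",
                       min_spots, " spots")
  ds$X <- ds$X[, keep, drop = FALSE]
  ds$gene_names <- ds$gene_names[keep]
  ds$provenance <- c(ds$provenance, "filter_genes")
  ds
}

#' Normalize, log-transform and scale the expression matrix
#'
#' The three-step chain applied to raw counts before embedding: (1) each
#' spot's counts are divided by its total so every row sums to 1; (2) the
#' matrix is log-transformed with a pseudo-count of 1 (`log1p`); (3) each
#' gene is centred to mean zero and scaled to unit variance across spots.
#' Genes with zero variance after the log step are set to all-zero columns
#' rather than dropped, keeping column indices stable. The log-normalized
#' pre-scaling matrix is retained as `ds$lognorm` for marker-gene testing.
#'
#' @param ds a raw-count [spot_dataset()] with no all-zero spots.
#' @return The transformed `spot_dataset`.
#' @export
normalize_log_scale <- function(ds) {
  stopifnot(inherits(ds, "spot_dataset"))
  check_not_applied(ds, "normalize_log_scale")
  totals <- rowSums(ds$X)
  if (any(totals == 0))
    stop("empty spot: spot(s) with zero total counts: ",
         paste(utils::head(which(totals == 0), 5), collapse = ", "),
         "; drop them before normalizing")
  X <- ds$X / totals
  X <- log1p(X)
  ds$lognorm <- X
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu, "-")
  nz <- sdv > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, sdv[nz], "/")
  Xs[, !nz] <- 0
  ds$X <- Xs
  ds$provenance <- c(ds$provenance, "normalize_log_scale")
  ds
}

#' Reduce the scaled expression matrix with PCA
#'
#' Projects the normalized matrix onto its top principal components. When the
#' gene count is already at or below `n_components` (e.g. targeted panels
#' with a few dozen genes), PCA is skipped and the matrix is returned
#' unchanged, so `F = M` exactly in that case. Components are ordered by
#' decreasing explained variance with the deterministic sign convention that
#' each component's largest-magnitude loading is positive.
#'
#' @param ds a [spot_dataset()] after [normalize_log_scale()].
#' @param n_components number of principal components (default 200).
#' @return A list of class `feature_matrix` with elements `values`
#'   (N x F score matrix), `explained_variance` (per-component variances, or
#'   NULL when skipped) and `provenance`.
#' @export
reduce_pca <- function(ds, n_components = 200) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (n_components < 1) stop("parameter error: n_components must be >= 1")
  if (!"normalize_log_scale" %in% ds$provenance)
    stop("reduce_pca expects a normalized dataset; run normalize_log_scale first")
  M <- ncol(ds$X)
  if (M <= n_components) {
    fm <- list(values = ds$X, explained_variance = NULL,
               provenance = c(ds$provenance, "pca_skipped"))
    class(fm) <- "feature_matrix"
    return(fm)
  }
  Xc <- sweep(ds$X, 2, colMeans(ds$X), "-")
  sv <- svd(Xc, nu = 0, nv = n_components)
  V <- sv$v
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- ds$spot_ids
  ev <- sv$d[seq_len(n_components)]^2 / (nrow(ds$X) - 1)
  fm <- list(values = scores, explained_variance = ev,
             provenance = c(ds$provenance, "pca"))
  class(fm) <- "feature_matrix"
  fm
}

#' Run the full preprocessing chain
#'
#' filter -> normalize -> log -> scale -> (PCA), in the fixed order the
#' embedding model expects.
#'
#' @inheritParams filter_genes
#' @inheritParams reduce_pca
#' @return A list with the processed `dataset` (normalized, carrying
#'   `lognorm`) and the `features` matrix object fed to the model.
#' @export
preprocess <- function(ds, min_spots = 5, n_components = 200) {
  ds <- filter_genes(ds, min_spots = min_spots)
  ds <- normalize_log_scale(ds)
  fm <- reduce_pca(ds, n_components = n_components)
  list(dataset = ds, features = fm)
}

check_not_applied <- function(ds, step) {
  if (step %in% ds$provenance)
    stop("preprocessing step '", step, "' already applied (provenance: ",
         paste(ds$provenance, collapse = " -> "), ")")
  invisible(NULL)
}
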