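#' Rank marker genes per domain
#'
#' For each cluster, a Welch two-sample t-test of every gene, cluster vs all
#' other spots, on the log-normalized pre-scaling matrix (per-gene scaling
#' would destroy effect directionality). Genes are ranked by ascending
#' p-value, ties broken by descending effect size (in-cluster minus
#' out-of-cluster mean). Clusters with fewer than 2 spots are skipped with a
#' warning.
#'
#' @param ds a [spot_dataset()] carrying `lognorm` (i.e. after
#'   [normalize_log_scale()]), or a plain spots x genes matrix of
#'   log-normalized values.
#' @param p a partition or label vector aligned with the spots.
#' @param top_n number of top genes to return per cluster (default 200).
#' @return A data frame with columns `cluster`, `rank`, `gene`, `p_value`,
#'   `effect` (at most `top_n` rows per cluster). The top-1 gene per cluster
#'   is the candidate for spatial expression heatmaps.
#' @export
rank_marker_genes <- function(ds, p, top_n = 200) {
  if (inherits(ds, "spot_dataset")) {
    if (is.null(ds$lognorm))
      stop("dataset has no log-normalized matrix; run normalize_log_scale first")
    X <- ds$lognorm
    genes <- ds$gene_names
  } else {
    X <- as.matrix(ds)
    genes <- colnames(X)
    if (is.null(genes)) genes <- paste0("gene_", seq_len(ncol(X)))
  }
  y <- as_labels(p)
  if (length(y) != nrow(X))
    stop("alignment error: partition length vs spot count")
  out <- list()
  for (cl in sort(unique(y))) {
    inside <- y == cl
    n1 <- sum(inside); n2 <- sum(!inside)
    if (n1 < 2 || n2 < 2) {
      warning("cluster ", cl, " has fewer than 2 spots on one side; skipped")
      next
    }
    tt <- welch_columns(X[inside, , drop = FALSE], X[!inside, , drop = FALSE])
    ord <- order(tt$p, -tt$effect)
    keep <- ord[seq_len(min(top_n, length(ord)))]
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, rank = seq_along(keep), gene = genes[keep],
      p_value = tt$p[keep], effect = tt$effect[keep])
  }
  if (!length(out)) stop("no cluster with at least 2 spots")
  do.call(rbind, out)
}

# Vectorized Welch t-test of every column, group 1 vs group 2.
welch_columns <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2, m1, "-")^2) / (n1 - 1)
  v2 <- colSums(sweep(X2, 2, m2, "-")^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # constant genes: zero variance on both sides -> no evidence
  flat <- se2 == 0
  p[flat] <- 1
  list(p = p, effect = m1 - m2, t = tstat, df = df)
}
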