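#' Simulate spatial transcriptomics data with planted domains
#'
#' Generates a tissue-like fixture: `n_spots` spots placed uniformly in the
#' unit square, partitioned into `n_domains` spatially contiguous domains —
#' horizontal strips of equal height (`layout = "layered_strips"`, emulating
#' layered cortex) or nearest-seed Voronoi cells (`layout = "voronoi"`).
#' Each domain owns `markers_per_domain` dedicated marker genes whose mean is
#' shifted upward by `marker_effect` baseline standard deviations inside that
#' domain, on a noisy background common to all spots.
#'
#' Noise models: `"gaussian"` draws non-negative (truncated at zero)
#' continuous counts around a constant baseline mean; `"negative_binomial"`
#' draws integer counts with the given dispersion, exercising count-data
#' code paths (gene filtering, normalization).
#'
#' The generator is fully deterministic given `seed`.
#'
#' @param n_spots number of spots (default 800).
#' @param n_genes number of genes (default 200).
#' @param n_domains number of planted domains K (default 4).
#' @param layout `"layered_strips"` or `"voronoi"`.
#' @param markers_per_domain marker genes per domain (default 5).
#' @param marker_effect in-domain mean shift of marker genes, in units of
#'   the baseline SD (default 3).
#' @param noise_model `"gaussian"` or `"negative_binomial"`.
#' @param baseline_mean baseline expression mean (default 2).
#' @param baseline_sd baseline SD for the gaussian model (default 1).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param seed RNG seed.
#' @return A [spot_dataset()] with ground-truth domain labels, plus
#'   attributes `marker_genes` (list: domain -> marker gene names) and
#'   `sim_spec` (the generating parameters).
#' @export
simulate_spatial <- function(n_spots = 800, n_genes = 200, n_domains = 4,
                             layout = c("layered_strips", "voronoi"),
                             markers_per_domain = 5, marker_effect = 3,
                             noise_model = c("gaussian", "negative_binomial"),
                             baseline_mean = 2, baseline_sd = 1,
                             dispersion = 2, seed = 1) {
  layout <- match.arg(layout)
  noise_model <- match.arg(noise_model)
  if (n_domains < 2) stop("need at least 2 domains")
  if (markers_per_domain < 1) stop("need at least 1 marker per domain")
  if (n_genes < n_domains * markers_per_domain)
    stop("infeasible spec: markers (", n_domains * markers_per_domain,
         ") exceed genes (", n_genes, ")")
  set.seed(seed)
  S <- cbind(x = stats::runif(n_spots), y = stats::runif(n_spots))
  labels <- switch(layout,
    layered_strips = pmin(floor(S[, "y"] * n_domains) + 1L, n_domains),
    voronoi = {
      seeds <- cbind(stats::runif(n_domains), stats::runif(n_domains))
      max.col(-pairwise_sq_dists(S, seeds))
    })
  labels <- as.integer(labels)

  marker_idx <- split(seq_len(n_domains * markers_per_domain),
                      rep(seq_len(n_domains), each = markers_per_domain))

  if (noise_model == "gaussian") {
    X <- matrix(pmax(stats::rnorm(n_spots * n_genes, baseline_mean,
                                  baseline_sd), 0),
                n_spots, n_genes)
    shift <- marker_effect * baseline_sd
    for (d in seq_len(n_domains)) {
      rows <- labels == d
      for (gi in marker_idx[[d]])
        X[rows, gi] <- pmax(stats::rnorm(sum(rows), baseline_mean + shift,
                                         baseline_sd), 0)
    }
  } else {
    sd_nb <- sqrt(baseline_mean + baseline_mean^2 / dispersion)
    X <- matrix(stats::rnbinom(n_spots * n_genes, size = dispersion,
                               mu = baseline_mean),
                n_spots, n_genes)
    storage.mode(X) <- "double"
    mu_hi <- baseline_mean + marker_effect * sd_nb
    for (d in seq_len(n_domains)) {
      rows <- labels == d
      for (gi in marker_idx[[d]])
        X[rows, gi] <- stats::rnbinom(sum(rows), size = dispersion,
                                      mu = mu_hi)
    }
  }
  gene_names <- paste0("gene_", seq_len(n_genes))
  ds <- spot_dataset(X, S, gene_names = gene_names, labels = labels)
  attr(ds, "marker_genes") <- lapply(marker_idx, function(i) gene_names[i])
  attr(ds, "sim_spec") <- list(n_spots = n_spots, n_genes = n_genes,
                               n_domains = n_domains, layout = layout,
                               markers_per_domain = markers_per_domain,
                               marker_effect = marker_effect,
                               noise_model = noise_model,
                               baseline_mean = baseline_mean,
                               baseline_sd = baseline_sd,
                               dispersion = dispersion, seed = seed)
  ds
}
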