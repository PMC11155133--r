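#' Spatial expression dataset container
#'
#' Bundles a spots-by-genes expression matrix with per-spot 2-D spatial
#' coordinates, optional ground-truth domain labels, and a provenance record
#' of the preprocessing steps applied so far.
#'
#' @param X numeric matrix, N spots x M genes; raw counts on construction.
#' @param coords numeric matrix or data frame, N x 2 spatial coordinates.
#' @param spot_ids character vector of length N; defaults to rownames of `X`
#'   or `spot_1..spot_N`.
#' @param gene_names character vector of length M; defaults to colnames of
#'   `X` or `gene_1..gene_M`. Duplicates are disambiguated by suffixing.
#' @param labels optional length-N vector of ground-truth domain labels.
#' @param provenance character vector of preprocessing steps already applied.
#'
#' @return An object of class `spot_dataset`: a list with elements `X`,
#'   `coords`, `spot_ids`, `gene_names`, `labels`, `provenance`, and (after
#'   [normalize_log_scale()]) `lognorm`, the log-normalized pre-scaling
#'   matrix used for marker-gene testing.
#' @export
spot_dataset <- function(X, coords, spot_ids = NULL, gene_names = NULL,
                         labels = NULL, provenance = character()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 spots")
  if (ncol(X) < 1L) stop("need at least 1 gene")
  if (nrow(coords) != nrow(X))
    stop("alignment error: coordinate table has ", nrow(coords),
         " rows but expression matrix has ", nrow(X))
  if (ncol(coords) != 2L) stop("coordinates must have exactly 2 columns")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("no spatial information: missing or non-finite coordinates")
  if (anyNA(X) || any(!is.finite(X)))
    stop("expression matrix contains missing or non-finite values")
  if (length(provenance) == 0L && any(X < 0))
    stop("raw counts must be non-negative")

  if (is.null(spot_ids)) {
    spot_ids <- rownames(X)
    if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(X)))
  }
  if (is.null(gene_names)) {
    gene_names <- colnames(X)
    if (is.null(gene_names)) gene_names <- paste0("gene_", seq_len(ncol(X)))
  }
  gene_names <- make.unique(as.character(gene_names), sep = "-")
  if (length(spot_ids) != nrow(X)) stop("spot_ids length mismatch")
  if (length(gene_names) != ncol(X)) stop("gene_names length mismatch")
  if (!is.null(labels)) {
    if (length(labels) != nrow(X))
      stop("alignment error: labels length ", length(labels),
           " does not match ", nrow(X), " spots")
    labels <- as.vector(labels)
  }
  dimnames(X) <- list(spot_ids, gene_names)
  colnames(coords) <- c("x", "y")
  rownames(coords) <- spot_ids

  structure(list(X = X, coords = coords, spot_ids = spot_ids,
                 gene_names = gene_names, labels = labels,
                 provenance = provenance),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat("spot_dataset: ", nrow(x$X), " spots x ", ncol(x$X), " genes\n", sep = "")
  cat("  labels: ", if (is.null(x$labels)) "none" else
    paste0(length(unique(x$labels)), " domains"), "\n", sep = "")
  cat("  provenance: ", if (length(x$provenance)) paste(x$provenance, collapse = " -> ")
      else "raw", "\n", sep = "")
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$X)

#' Load a spatial transcriptomics dataset from disk
#'
#' Supported formats:
#' * `"csv"` — `path` is a directory (or a prefix) holding `expression.csv`
#'   (spots x genes, first column = spot id) and `coords.csv` (columns
#'   `barcode,x,y`; an optional `label` column is read as ground truth).
#' * `"mtx_dir"` — a directory with `matrix.mtx` (genes x spots or spots x
#'   genes, auto-oriented via the barcode/gene counts), `genes.tsv`,
#'   `barcodes.tsv` and `coords.csv` (columns `barcode,x,y`).
#' * `"h5ad"` — an annotated expression-matrix container; coordinates are
#'   taken from the standard spatial slot (`obsm["spatial"]`). Requires the
#'   `python` interpreter with the `anndata` package on the PATH (the file is
#'   converted through a bundled helper script).
#'
#' @param path file or directory location.
#' @param format one of `"csv"`, `"mtx_dir"`, `"h5ad"`.
#' @param label_column for h5ad, the `obs` column holding ground-truth
#'   labels, if any.
#' @return A [spot_dataset()].
#' @export
load_dataset <- function(path, format = c("csv", "mtx_dir", "h5ad"),
                         label_column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  switch(format,
         csv = load_csv_bundle(path),
         mtx_dir = load_mtx_dir(path),
         h5ad = load_h5ad(path, label_column))
}

load_csv_bundle <- function(path) {
  if (dir.exists(path)) {
    expr_f <- file.path(path, "expression.csv")
    coord_f <- file.path(path, "coords.csv")
  } else {
    expr_f <- paste0(path, "_expression.csv")
    coord_f <- paste0(path, "_coords.csv")
  }
  if (!file.exists(expr_f)) stop("expression file not found: ", expr_f)
  if (!file.exists(coord_f))
    stop("no spatial information: coordinates file not found: ", coord_f)
  expr <- utils::read.csv(expr_f, row.names = 1, check.names = FALSE)
  co <- utils::read.csv(coord_f, check.names = FALSE)
  read_coord_frame(as.matrix(expr), co)
}

load_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("mtx_dir must be a directory: ", path)
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "coords.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("mtx_dir is missing file(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
  genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.table(file.path(path, "barcodes.tsv"), sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  # 10x convention stores genes x spots; accept either orientation
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- t(m)
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
    stop("alignment error: matrix is ", nrow(m), "x", ncol(m),
         " but there are ", length(barcodes), " barcodes and ",
         length(genes), " genes")
  }
  co <- utils::read.csv(file.path(path, "coords.csv"), check.names = FALSE)
  read_coord_frame(m, co, barcodes = barcodes, genes = genes)
}

read_coord_frame <- function(X, co, barcodes = rownames(X), genes = colnames(X)) {
  if (!all(c("x", "y") %in% names(co)))
    stop("no spatial information: coords file needs columns x,y")
  if (nrow(co) != nrow(X))
    stop("alignment error: coordinates file has ", nrow(co),
         " rows but matrix has ", nrow(X), " spots")
  if ("barcode" %in% names(co) && !is.null(barcodes)) {
    idx <- match(barcodes, co$barcode)
    if (anyNA(idx)) stop("alignment error: barcodes missing from coords file")
    co <- co[idx, , drop = FALSE]
  }
  labels <- if ("label" %in% names(co)) co$label else NULL
  spot_dataset(X, co[, c("x", "y")], spot_ids = barcodes,
               gene_names = genes, labels = labels)
}

load_h5ad <- function(path, label_column = NULL) {
  py <- Sys.which("python")
  if (py == "") stop("h5ad input requires a python interpreter on the PATH")
  helper <- system.file("python", "h5ad_to_csv.py", package = "hyperspot")
  if (helper == "") stop("bundled h5ad converter not found")
  out <- tempfile("h5ad_")
  dir.create(out)
  args <- c(helper, path, out)
  if (!is.null(label_column)) args <- c(args, label_column)
  status <- system2(py, shQuote(args), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("h5ad conversion failed:\n", paste(status, collapse = "\n"))
  load_csv_bundle(out)
}

#' Write a dataset as a CSV bundle
#'
#' Writes `expression.csv` and `coords.csv` (with a `label` column when
#' ground truth is present) into `dir`, the same layout [load_dataset()]
#' reads with `format = "csv"`.
#'
#' @param ds a [spot_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # 17 significant digits so doubles survive the text round trip bitwise
  fmt <- function(m) apply(m, 2, function(col) sprintf("%.17g", col))
  expr <- data.frame(barcode = ds$spot_ids, fmt(ds$X), check.names = FALSE)
  names(expr)[-1] <- ds$gene_names
  utils::write.csv(expr, file.path(dir, "expression.csv"), row.names = FALSE,
                   quote = FALSE)
  co <- data.frame(barcode = ds$spot_ids, fmt(ds$coords))
  names(co)[-1] <- c("x", "y")
  if (!is.null(ds$labels)) co$label <- ds$labels
  utils::write.csv(co, file.path(dir, "coords.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
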