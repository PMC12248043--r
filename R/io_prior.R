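#' Filtering and normalization configuration
#'
#' Thresholds for the standard preprocessing pass: genes must be expressed
#' in at least `min_cells_per_gene` cells, cells must express at least
#' `min_genes_per_cell` genes, every retained gene must have at least one
#' TF in the prior, and TFs regulating fewer than `min_targets_per_tf`
#' surviving genes are dropped. Mitochondrial-fraction and highly-variable
#' gene filters are opt-in.
#'
#' @param min_cells_per_gene integer, default 10.
#' @param min_genes_per_cell integer, default 3.
#' @param min_targets_per_tf integer, default 10.
#' @param mito_fraction_max optional real in (0, 1]; `NULL` disables the
#'   mitochondrial filter.
#' @param mito_prefix regex prefix identifying mitochondrial genes.
#' @param hvg_n optional integer; restrict to the `hvg_n` most variable
#'   genes (log-scale variance). `NULL` (default) keeps all genes.
#' @param target_sum per-cell total after library-size scaling, default 1e4.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_cells_per_gene = 10L,
                          min_genes_per_cell = 3L,
                          min_targets_per_tf = 10L,
                          mito_fraction_max = NULL,
                          mito_prefix = "^(MT-|mt-)",
                          hvg_n = NULL,
                          target_sum = 1e4) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0,
            min_targets_per_tf >= 0, target_sum > 0)
  if (!is.null(mito_fraction_max))
    stopifnot(mito_fraction_max > 0, mito_fraction_max <= 1)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_targets_per_tf = as.integer(min_targets_per_tf),
                 mito_fraction_max = mito_fraction_max,
                 mito_prefix = mito_prefix,
                 hvg_n = if (is.null(hvg_n)) NULL else as.integer(hvg_n),
                 target_sum = target_sum),
            class = "filter_config")
}

#' Load an expression matrix from disk
#'
#' Reads a cells x genes count matrix from one of three dialects:
#' * `mtx` — Matrix Market triplet file with gene/cell identifier sidecars
#'   (`features.tsv`/`genes.tsv` and `barcodes.tsv` next to the `.mtx`, or
#'   explicit paths). Orientation is resolved from the sidecar lengths.
#' * `csv` — dense CSV/TSV, header row = gene ids, first column = cell ids.
#' * `h5ad` — HDF5 single-cell container; converted through a Python
#'   subprocess running `anndata` (must be on `PATH`).
#'
#' @param path file path (for `mtx`, the `.mtx` file or its directory).
#' @param format one of `"auto"`, `"mtx"`, `"csv"`, `"h5ad"`.
#' @param genes_path,cells_path optional explicit sidecar paths (mtx only).
#' @param layer for h5ad: layer name to read, `NULL` = the main matrix.
#' @return An [expression_matrix()] with `layer = "counts"`.
#' @export
load_expression <- function(path, format = c("auto", "mtx", "csv", "h5ad"),
                            genes_path = NULL, cells_path = NULL,
                            layer = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     mtx = "mtx", csv = "csv", tsv = "csv", txt = "csv",
                     h5ad = "h5ad",
                     if (dir.exists(path)) "mtx"
                     else stop("cannot guess format of '", path, "'"))
  }
  switch(format,
         mtx = load_expression_mtx(path, genes_path, cells_path),
         csv = load_expression_csv(path),
         h5ad = load_expression_h5ad(path, layer))
}

load_expression_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cell_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  expression_matrix(m, cell_ids, colnames(df)[-1], layer = "counts")
}

load_expression_mtx <- function(path, genes_path = NULL, cells_path = NULL) {
  if (dir.exists(path)) {
    mtxs <- list.files(path, pattern = "\\.mtx$", full.names = TRUE)
    if (length(mtxs) != 1) stop("expected exactly one .mtx file in ", path)
    path <- mtxs[1]
  }
  if (!file.exists(path)) stop("file not found: ", path)
  dir <- dirname(path)
  find_sidecar <- function(given, candidates) {
    if (!is.null(given)) return(given)
    for (cand in candidates) {
      f <- file.path(dir, cand)
      if (file.exists(f)) return(f)
    }
    stop("no sidecar found among: ", paste(candidates, collapse = ", "))
  }
  genes_path <- find_sidecar(genes_path,
                             c("features.tsv", "genes.tsv", "genes.txt"))
  cells_path <- find_sidecar(cells_path,
                             c("barcodes.tsv", "cells.tsv", "barcodes.txt"))
  gene_ids <- utils::read.table(genes_path, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  cell_ids <- utils::read.table(cells_path, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  m <- Matrix::readMM(path)
  if (nrow(m) == length(gene_ids) && ncol(m) == length(cell_ids)) {
    m <- Matrix::t(m)   # genes x cells on disk (CellRanger convention)
  } else if (!(nrow(m) == length(cell_ids) && ncol(m) == length(gene_ids))) {
    stop("matrix dimensions match neither orientation of the sidecars")
  }
  expression_matrix(m, cell_ids, gene_ids, layer = "counts")
}

load_expression_h5ad <- function(path, layer = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  py <- Sys.which("python")
  if (!nzchar(py)) stop("h5ad input requires a 'python' with anndata on PATH")
  out <- tempfile("h5ad2mtx")
  dir.create(out)
  script <- sprintf('
import sys, anndata, numpy as np, scipy.sparse as sp, scipy.io as sio
ad = anndata.read_h5ad(sys.argv[1])
X = ad.layers[sys.argv[3]] if len(sys.argv) > 3 else ad.X
X = sp.csr_matrix(X)
sio.mmwrite(sys.argv[2] + "/matrix.mtx", X.T)
open(sys.argv[2] + "/barcodes.tsv", "w").write("\\n".join(map(str, ad.obs_names)) + "\\n")
open(sys.argv[2] + "/features.tsv", "w").write("\\n".join(map(str, ad.var_names)) + "\\n")
')
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  args <- c(sf, path, out, layer)
  status <- system2(py, shQuote(args), stdout = TRUE, stderr = TRUE)
  if (!file.exists(file.path(out, "matrix.mtx")))
    stop("h5ad conversion failed:\n", paste(status, collapse = "\n"))
  load_expression_mtx(file.path(out, "matrix.mtx"))
}

#' Load a signed prior regulatory network
#'
#' Reads a TF / target / sign edge table (TSV or CSV; the sign column may
#' be absent, numeric, or the text labels `activation`/`repression`).
#' Duplicate (TF, target) rows are collapsed by summing signs and clamping
#' to \{-1, 0, +1\}; conflicting duplicates therefore cancel to 0 and a
#' message reports how many did.
#'
#' @param path edge-table path.
#' @param strict if `TRUE`, a sign outside \{-1, +1\} is an error rather
#'   than being clamped.
#' @return A [prior_network()].
#' @export
load_prior_network <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("prior network table is empty")
  if (ncol(df) < 2) stop("prior network needs at least TF and target columns")
  tf <- as.character(df[[1]]); target <- as.character(df[[2]])
  sign_raw <- if (ncol(df) >= 3) df[[3]] else rep(1, nrow(df))
  sgn <- parse_sign(sign_raw, strict)
  prior_from_edges(tf, target, sgn)
}

parse_sign <- function(x, strict = FALSE) {
  if (is.character(x) || is.factor(x)) {
    x <- tolower(trimws(as.character(x)))
    map <- c(activation = 1, activator = 1, activate = 1, positive = 1,
             "+" = 1, "+1" = 1, "1" = 1,
             repression = -1, repressor = -1, repress = -1, inhibition = -1,
             negative = -1, "-" = -1, "-1" = -1)
    out <- unname(map[x])
    suppressWarnings(num <- as.numeric(x))
    out[is.na(out)] <- num[is.na(out)]
    if (any(is.na(out)))
      stop("unparseable sign value(s): ",
           paste(unique(x[is.na(out)]), collapse = ", "))
    x <- out
  }
  x <- as.numeric(x)
  if (strict && any(!x %in% c(-1, 1)))
    stop("sign outside {-1, +1} with strict = TRUE")
  x
}

prior_from_edges <- function(tf, target, sgn) {
  tf_ids <- sort(unique(tf)); gene_ids <- sort(unique(target))
  w <- Matrix::sparseMatrix(i = match(tf, tf_ids),
                            j = match(target, gene_ids),
                            x = sgn,
                            dims = c(length(tf_ids), length(gene_ids)))
  # duplicate edges sum; clamp and report sign conflicts that cancelled
  clamped <- w
  clamped@x <- pmax(-1, pmin(1, clamped@x))
  cancelled <- length(unique(paste0(tf, "\r", target))) - Matrix::nnzero(clamped)
  if (cancelled > 0)
    message(cancelled, " edge(s) with conflicting duplicate signs cancelled to 0")
  clamped <- Matrix::drop0(clamped)
  prior_network(clamped, tf_ids, gene_ids)
}

#' Filter an expression matrix and prior network jointly
#'
#' Applies, in order: (1) drop genes expressed in fewer than
#' `min_cells_per_gene` cells; (2) drop cells expressing fewer than
#' `min_genes_per_cell` genes; (3) drop genes with no TF in the prior;
#' (4) drop TFs with fewer than `min_targets_per_tf` targets among
#' surviving genes; then (5) the optional mitochondrial-fraction cell
#' filter and (6) the optional restriction to the most variable genes.
#' Gene names are matched case-insensitively between expression and
#' prior. Steps (1)-(4) are iterated to a fixpoint — removing a TF in (4)
#' orphans its exclusive targets, which (3) then drops, which can expose
#' further TFs — so the operation is idempotent. The loop almost always
#' settles within two passes; the number of passes is reported via
#' `message()` when it exceeds one.
#'
#' @param expr counts-layer [expression_matrix()].
#' @param prior [prior_network()].
#' @param cfg [filter_config()].
#' @return list with elements `expr` and `prior`, gene-aligned (prior
#'   columns in expression gene order).
#' @export
filter_dataset <- function(expr, prior, cfg = filter_config()) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(prior, "prior_network"),
            inherits(cfg, "filter_config"))
  if (expr$layer != "counts")
    stop("filter_dataset expects the counts layer")
  X <- expr$values
  # align the prior to the expression gene namespace once (genes absent
  # from the prior get an all-zero column, removed by step (3))
  pj <- match(tolower(colnames(X)), tolower(prior$gene_ids))
  W <- Matrix::Matrix(0, length(prior$tf_ids), ncol(X), sparse = TRUE)
  rownames(W) <- prior$tf_ids
  W[, !is.na(pj)] <- prior$weights[, pj[!is.na(pj)], drop = FALSE]
  colnames(W) <- colnames(X)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    dim_before <- c(dim(X), nrow(W))
    keep_g <- colSums(X > 0) >= cfg$min_cells_per_gene             # (1)
    X <- X[, keep_g, drop = FALSE]; W <- W[, keep_g, drop = FALSE]
    keep_c <- rowSums(X > 0) >= cfg$min_genes_per_cell             # (2)
    X <- X[keep_c, , drop = FALSE]
    has_tf <- Matrix::colSums(abs(W) > 0) > 0                      # (3)
    X <- X[, has_tf, drop = FALSE]; W <- W[, has_tf, drop = FALSE]
    keep_tf <- Matrix::rowSums(abs(W) > 0) >= cfg$min_targets_per_tf # (4)
    W <- W[keep_tf, , drop = FALSE]
    if (nrow(W) == 0 || ncol(X) == 0)
      stop("filtering removed all TFs or genes; relax filter_config ",
           "thresholds")
    if (identical(c(dim(X), nrow(W)), dim_before) || passes >= 25L) break
  }
  if (passes > 2L)
    message("gene/TF filters needed ", passes, " passes to stabilize")
  if (!is.null(cfg$mito_fraction_max)) {                            # (5)
    mito <- grepl(cfg$mito_prefix, colnames(X))
    frac <- if (any(mito)) rowSums(X[, mito, drop = FALSE]) / pmax(rowSums(X), 1)
            else rep(0, nrow(X))
    X <- X[frac <= cfg$mito_fraction_max, , drop = FALSE]
  }
  if (!is.null(cfg$hvg_n) && cfg$hvg_n < ncol(X)) {                 # (6)
    v <- apply(log1p(X), 2, stats::var)
    keep <- rank(-v, ties.method = "first") <= cfg$hvg_n
    X <- X[, keep, drop = FALSE]
    W <- W[, keep, drop = FALSE]
  }
  list(expr = expression_matrix(X, rownames(X), colnames(X), "counts"),
       prior = prior_network(W, rownames(W), colnames(W)))
}

#' Library-size normalize and log-transform counts
#'
#' Each cell's counts are scaled to sum to `target_sum`, then transformed
#' by `log1p`. All-zero cells pass through as zeros. Refuses to run twice.
#'
#' @param expr counts-layer [expression_matrix()].
#' @param target_sum per-cell total after scaling (default 1e4).
#' @return [expression_matrix()] with `layer = "lognorm"`.
#' @export
lognormalize <- function(expr, target_sum = 1e4) {
  stopifnot(inherits(expr, "expression_matrix"), target_sum > 0)
  if (expr$layer == "lognorm")
    stop("input is already log-normalized (double normalization)")
  X <- expr$values
  totals <- rowSums(X)
  scale <- ifelse(totals > 0, target_sum / totals, 0)
  X <- log1p(X * scale)
  expression_matrix(X, expr$cell_ids, expr$gene_ids, layer = "lognorm")
}
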