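#' @keywords internal
"_PACKAGE"

#' Construct an expression matrix container
#'
#' Thin S3 container for a cells x genes expression matrix with unique cell
#' and gene identifiers and a layer flag distinguishing raw counts from
#' log-normalized values.
#'
#' @param values numeric cells x genes matrix (base or Matrix sparse),
#'   finite and non-negative.
#' @param cell_ids character vector of unique cell identifiers.
#' @param gene_ids character vector of unique gene identifiers.
#' @param layer `"counts"` or `"lognorm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_ids, gene_ids,
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- as_dense(values)
  if (nrow(values) != length(cell_ids))
    stop("nrow(values) != length(cell_ids)")
  if (ncol(values) != length(gene_ids))
    stop("ncol(values) != length(gene_ids)")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at cell '%s', gene '%s'",
                 cell_ids[bad[1]], gene_ids[bad[2]]))
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 gene_ids = gene_ids, layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes [%s]\n",
              length(x$cell_ids), length(x$gene_ids), x$layer))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

as_dense <- function(m) {
  if (methods::is(m, "Matrix")) m <- as.matrix(m)
  if (!is.matrix(m)) m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

#' Construct a prior regulatory network
#'
#' Signed sparse TF x gene matrix holding the prior regulatory topology.
#' Entries are conventionally in {-1, 0, +1} (activation / absent /
#' repression) but real-valued weighted priors are accepted.
#'
#' @param weights TF x gene matrix (dense or sparse).
#' @param tf_ids,gene_ids unique identifier vectors matching `weights`.
#' @return An object of class `prior_network`.
#' @export
prior_network <- function(weights, tf_ids, gene_ids) {
  tf_ids <- as.character(tf_ids); gene_ids <- as.character(gene_ids)
  if (anyDuplicated(tf_ids)) stop("duplicate TF identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  weights <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                                     "generalMatrix"), "CsparseMatrix")
  if (nrow(weights) != length(tf_ids) || ncol(weights) != length(gene_ids))
    stop("weight matrix dimensions do not match identifier lists")
  dimnames(weights) <- list(tf_ids, gene_ids)
  structure(list(tf_ids = tf_ids, gene_ids = gene_ids, weights = weights),
            class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  cat(sprintf("<prior_network> %d TFs x %d genes, %d edges\n",
              length(x$tf_ids), length(x$gene_ids),
              Matrix::nnzero(x$weights)))
  invisible(x)
}

#' Construct a TF activity matrix
#'
#' @param values cells x TFs numeric matrix of activity scores.
#' @param cell_ids,tf_ids identifier vectors.
#' @param source provenance flag: `"ulm"` (prior-driven univariate linear
#'   model), `"model"` (decoder output), or `"blended"`.
#' @return An object of class `tf_activity`.
#' @export
tf_activity <- function(values, cell_ids, tf_ids,
                        source = c("ulm", "model", "blended")) {
  source <- match.arg(source)
  values <- as_dense(values)
  if (any(!is.finite(values))) stop("activity values must be finite")
  if (nrow(values) != length(cell_ids) || ncol(values) != length(tf_ids))
    stop("activity matrix dimensions do not match identifier lists")
  dimnames(values) <- list(cell_ids, tf_ids)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 tf_ids = as.character(tf_ids), source = source),
            class = "tf_activity")
}

#' @export
print.tf_activity <- function(x, ...) {
  cat(sprintf("<tf_activity> %d cells x %d TFs [%s]\n",
              length(x$cell_ids), length(x$tf_ids), x$source))
  invisible(x)
}

#' Construct a weighted GRN
#'
#' Real-valued TF x gene weight matrix, i.e. the decoder's final linear
#' layer. `context` records whether the network is global or specific to a
#' named cell type.
#'
#' @param weights TF x gene numeric matrix.
#' @param tf_ids,gene_ids identifier vectors.
#' @param context `"global"` or a cell-type label.
#' @return An object of class `weighted_grn`.
#' @export
weighted_grn <- function(weights, tf_ids, gene_ids, context = "global") {
  weights <- as_dense(weights)
  if (any(!is.finite(weights))) stop("GRN weights must be finite")
  if (nrow(weights) != length(tf_ids) || ncol(weights) != length(gene_ids))
    stop("GRN dimensions do not match identifier lists")
  dimnames(weights) <- list(tf_ids, gene_ids)
  structure(list(tf_ids = as.character(tf_ids),
                 gene_ids = as.character(gene_ids),
                 weights = weights, context = as.character(context)),
            class = "weighted_grn")
}

#' @export
print.weighted_grn <- function(x, ...) {
  cat(sprintf("<weighted_grn> %d TFs x %d genes [context: %s]\n",
              length(x$tf_ids), length(x$gene_ids), x$context))
  invisible(x)
}
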