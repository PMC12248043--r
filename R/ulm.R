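#' Prior-driven TF activity via a univariate linear model
#'
#' For each cell and each TF, the cell's log-normalized expression vector
#' (over all genes, with non-targets carrying weight 0) is regressed on the
#' TF's signed prior weight vector with an intercept. The activity score is
#' the t-statistic of the slope — the standard ULM regulon-scoring
#' convention. The raw weighted sum of target expression is available as an
#' alternative scorer.
#'
#' A cell whose expression is exactly proportional to the weight vector has
#' zero residual and an unbounded t; such scores are capped at +/- 1e6.
#'
#' @param expr log-normalized [expression_matrix()], gene-aligned with
#'   `prior` (same genes, same order).
#' @param prior [prior_network()].
#' @param method `"tstat"` (default) or `"wsum"` (raw weighted sum).
#' @param t_cap cap for degenerate perfect-fit t-statistics.
#' @return A [tf_activity()] with `source = "ulm"`, cells x TFs.
#' @export
ulm_activities <- function(expr, prior, method = c("tstat", "wsum"),
                           t_cap = 1e6) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(prior, "prior_network"))
  if (!identical(tolower(expr$gene_ids), tolower(prior$gene_ids)))
    stop("expression and prior must be gene-aligned (run filter_dataset)")
  G <- length(expr$gene_ids)
  if (G < 3) stop("need at least 3 genes for a slope t-statistic")
  W <- as.matrix(prior$weights)            # TFs x genes
  wvar <- apply(W, 1, stats::var)
  if (any(wvar == 0))
    stop("zero-variance prior weight vector for TF(s): ",
         paste(prior$tf_ids[wvar == 0], collapse = ", "))
  Y <- t(expr$values)                      # genes x cells
  if (method == "wsum") {
    A <- crossprod(Y, t(W))                # cells x TFs
    return(tf_activity(A, expr$cell_ids, prior$tf_ids, source = "ulm"))
  }
  C <- ncol(Y)
  ybar <- colMeans(Y)
  Syy <- colSums(Y^2) - G * ybar^2
  A <- matrix(0, C, nrow(W))
  for (f in seq_len(nrow(W))) {
    w <- W[f, ]
    wc <- w - mean(w)
    Sxx <- sum(wc^2)
    b <- as.numeric(crossprod(Y, wc)) / Sxx          # slope per cell
    rss <- pmax(Syy - b^2 * Sxx, 0)
    se <- sqrt(rss / ((G - 2) * Sxx))
    t <- ifelse(se > 0, b / se, sign(b) * t_cap)
    t[b == 0] <- 0
    A[, f] <- pmax(pmin(t, t_cap), -t_cap)
  }
  tf_activity(A, expr$cell_ids, prior$tf_ids, source = "ulm")
}
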