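#' Sweep Leiden clustering of TF activities against truth labels
#'
#' Builds a k-nearest-neighbor graph (Euclidean, `k = 15` by default,
#' undirected union) on the activity matrix once, then partitions it with
#' Leiden community detection at each resolution. Clusters are mapped to
#' truth labels by maximum voting (ties broken lexicographically) and
#' scored by ARI, NMI, macro F1 and a macro one-vs-rest AUROC in which a
#' cell's score for class `c` is the fraction of its cluster truly labeled
#' `c` (cluster-composition score — a reconstruction, since no standard
#' "clustering AUC" definition exists).
#'
#' @param acts [tf_activity()] (or plain cells x features matrix).
#' @param truth_labels per-cell ground-truth labels (>= 2 distinct).
#' @param resolutions Leiden resolution grid; default 15 evenly spaced
#'   values in \[0.2, 3\].
#' @param k neighbors for the graph, default 15.
#' @param seed seed for the Leiden refinement RNG.
#' @return data.frame `(resolution, n_clusters, ari, nmi, macro_f1, auc)`.
#' @export
evaluate_clustering <- function(acts, truth_labels,
                                resolutions = seq(0.2, 3, length.out = 15),
                                k = 15L, seed = 0L) {
  A <- if (inherits(acts, "tf_activity")) acts$values else as.matrix(acts)
  truth <- as.character(truth_labels)
  if (nrow(A) < 2) stop("need at least 2 cells")
  if (length(unique(truth)) < 2) stop("need at least 2 truth labels")
  if (!length(resolutions)) stop("resolutions must be nonempty")
  g <- knn_graph(A, k)
  out <- lapply(resolutions, function(res) {
    old <- local_seed(seed); on.exit(restore_seed(old))
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = res,
                                 n_iterations = 5)$membership
    mf <- macro_f1_voting(cl, truth)
    data.frame(resolution = res, n_clusters = length(unique(cl)),
               ari = adjusted_rand_index(cl, truth),
               nmi = normalized_mutual_info(cl, truth),
               macro_f1 = mf$macro_f1,
               auc = composition_auc(cl, truth))
  })
  do.call(rbind, out)
}

knn_graph <- function(A, k) {
  n <- nrow(A)
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(A))
  diag(D) <- Inf
  nb <- apply(D, 1, function(d) order(d)[seq_len(k)])
  edges <- cbind(rep(seq_len(n), each = k), as.vector(nb))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# macro one-vs-rest AUROC from cluster-composition scores
composition_auc <- function(clusters, truth) {
  clusters <- as.character(clusters); truth <- as.character(truth)
  comp <- prop.table(table(clusters, truth), margin = 1)
  classes <- colnames(comp)
  aucs <- vapply(classes, function(cl) {
    score <- comp[clusters, cl]
    y <- truth == cl
    if (all(y) || !any(y)) return(NA_real_)
    auroc(score, y)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Bernoulli dropout masking of an expression matrix
#'
#' Each entry is retained with probability `1 - p` (the `U > p` rule on an
#' independent uniform draw per entry) and set to zero otherwise.
#' Bitwise reproducible given the seed; already-zero entries stay zero.
#'
#' @param expr [expression_matrix()].
#' @param p dropout probability in \[0, 1\].
#' @param seed RNG seed.
#' @return Masked [expression_matrix()] (same layer flag).
#' @export
apply_dropout <- function(expr, p, seed = 0L) {
  stopifnot(inherits(expr, "expression_matrix"), p >= 0, p <= 1)
  old <- local_seed(seed); on.exit(restore_seed(old))
  U <- matrix(stats::runif(length(expr$values)), nrow(expr$values))
  X <- expr$values * (U > p)
  expression_matrix(X, expr$cell_ids, expr$gene_ids, layer = expr$layer)
}

#' Edge-recovery evaluation of an inferred GRN
#'
#' Scores every (TF, gene) pair in the intersection of the prediction's
#' and the gold standard's namespaces by `|weight|`; gold membership is
#' the positive label. AUROC and AUPRC summarize the full binarization
#' threshold sweep (rank-based, ties averaged).
#'
#' @param pred [weighted_grn()].
#' @param gold_edges data.frame with columns `tf`, `gene` (or a 2-column
#'   matrix) of gold-standard edges.
#' @return list: `auroc`, `auprc`, `prevalence`, `n_edges_gold` (gold
#'   edges inside the intersection), `n_pairs_scored`.
#' @export
evaluate_grn <- function(pred, gold_edges) {
  stopifnot(inherits(pred, "weighted_grn"))
  gold_edges <- as.data.frame(gold_edges)
  colnames(gold_edges)[1:2] <- c("tf", "gene")
  tfs <- intersect(pred$tf_ids, unique(gold_edges$tf))
  genes <- pred$gene_ids
  if (!length(tfs)) stop("no TF overlap between prediction and gold")
  W <- abs(pred$weights[tfs, genes, drop = FALSE])
  pos <- matrix(FALSE, length(tfs), length(genes),
                dimnames = list(tfs, genes))
  inside <- gold_edges$tf %in% tfs & gold_edges$gene %in% genes
  pos[cbind(gold_edges$tf[inside], gold_edges$gene[inside])] <- TRUE
  y <- as.vector(pos); s <- as.vector(W)
  if (!any(y) || all(y))
    stop("gold standard has no positives or no negatives in intersection")
  list(auroc = auroc(s, y), auprc = auprc(s, y),
       prevalence = mean(y),
       n_edges_gold = sum(y), n_pairs_scored = length(y))
}

#' Proportional stratified subsets
#'
#' Splits cells into `k` disjoint subsets that each preserve the cluster
#' composition of the whole dataset: within every cluster, cells are
#' shuffled under the seed and dealt round-robin, so per-subset cluster
#' proportions deviate from the global ones by at most one cell. Clusters
#' come from user labels, or from a Leiden partition of log-normalized
#' expression when labels are absent.
#'
#' @param expr [expression_matrix()].
#' @param k number of subsets, default 5.
#' @param seed RNG seed.
#' @param labels optional per-cell cluster/stratum labels.
#' @param resolution Leiden resolution when clustering internally.
#' @return list of `k` integer index vectors (disjoint, covering).
#' @export
stratified_subsets <- function(expr, k = 5L, seed = 0L, labels = NULL,
                               resolution = 1.0) {
  stopifnot(k >= 2)
  n <- nrow(expr$values)
  if (is.null(labels)) {
    X <- if (expr$layer == "counts") lognormalize(expr)$values
         else expr$values
    g <- knn_graph(X, 15L)
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
    labels <- igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 5)$membership
  }
  labels <- as.character(labels)
  old2 <- local_seed(seed + 1L)
  on.exit(restore_seed(old2), add = TRUE)
  subsets <- vector("list", k)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      warning("cluster '", cl, "' has fewer than ", k,
              " cells; spread over ", length(idx), " subset(s)")
    idx <- idx[sample.int(length(idx))]
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (s in seq_len(k))
      subsets[[s]] <- c(subsets[[s]], idx[assign_to == s])
  }
  lapply(subsets, sort)
}

#' Knockdown evaluation of inferred TF activity
#'
#' Compares a TF's activity between perturbed and control cells: the
#' activity column is min-max rescaled, group means are floored at the
#' pseudocount, and `lfc = log2(mean_perturbed / mean_control)`; a
#' two-sided Wilcoxon rank-sum test supplies the p-value. CRISPRi-style
#' knockdowns are expected to give negative LFC.
#'
#' @param acts [tf_activity()].
#' @param groups per-cell labels, `"perturbed"` or `"control"`.
#' @param tf TF identifier.
#' @param pseudocount floor for rescaled group means, default 0.01.
#' @return list: `lfc`, `p`.
#' @export
knockdown_evaluation <- function(acts, groups, tf, pseudocount = 0.01) {
  stopifnot(inherits(acts, "tf_activity"))
  if (!tf %in% acts$tf_ids) stop("unknown TF: ", tf)
  groups <- as.character(groups)
  if (!all(groups %in% c("perturbed", "control")))
    stop("groups must be 'perturbed' or 'control'")
  if (sum(groups == "perturbed") < 3 || sum(groups == "control") < 3)
    stop("both groups need at least 3 cells")
  v <- acts$values[, tf]
  r <- minmax_rescale(v)
  m1 <- max(mean(r[groups == "perturbed"]), pseudocount)
  m0 <- max(mean(r[groups == "control"]), pseudocount)
  p <- suppressWarnings(stats::wilcox.test(v[groups == "perturbed"],
                                           v[groups == "control"])$p.value)
  list(lfc = log2(m1 / m0), p = p)
}
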