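#' Differential TF activity between cell types
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per (TF, cell type), with
#' Benjamini-Hochberg adjustment across TFs within each cell type. The
#' log2 fold change is computed on per-TF min-max rescaled activities
#' (t-statistic activities can be negative, so a positive scale is needed
#' for a meaningful ratio); each group mean is floored at `pseudocount`
#' before the ratio. The raw mean difference is reported alongside.
#'
#' @param acts [tf_activity()].
#' @param labels per-cell cell-type labels (>= 2 distinct).
#' @param p_threshold keep rows with adjusted p below this, default 0.05.
#' @param min_cells groups smaller than this are excluded with a warning.
#' @param pseudocount floor for rescaled group means, default 0.01.
#' @return data.frame `(tf, cell_type, lfc, mean_diff, p, p_adj)` sorted
#'   by decreasing `lfc` within cell type; only rows passing
#'   `p_adj < p_threshold`.
#' @export
differential_tf_activity <- function(acts, labels, p_threshold = 0.05,
                                     min_cells = 3L, pseudocount = 0.01) {
  stopifnot(inherits(acts, "tf_activity"),
            length(labels) == length(acts$cell_ids))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 cell-type labels")
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning("group(s) below ", min_cells, " cells excluded: ",
            paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  A <- acts$values
  R <- apply(A, 2, minmax_rescale)
  rows <- list()
  for (g in groups) {
    ing <- labels == g
    res <- lapply(seq_along(acts$tf_ids), function(j) {
      x <- A[ing, j]; y <- A[!ing, j]
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      m1 <- max(mean(R[ing, j]), pseudocount)
      m0 <- max(mean(R[!ing, j]), pseudocount)
      data.frame(tf = acts$tf_ids[j], cell_type = g,
                 lfc = log2(m1 / m0), mean_diff = mean(x) - mean(y),
                 p = p)
    })
    df <- do.call(rbind, res)
    df$p_adj <- stats::p.adjust(df$p, method = "BH")
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$p_adj) & out$p_adj < p_threshold, , drop = FALSE]
  out <- out[order(out$cell_type, -out$lfc), ]
  rownames(out) <- NULL
  out
}

minmax_rescale <- function(v) {
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
}

#' Cosine similarity between two weight vectors
#'
#' Dot product over the product of Euclidean norms; bounded in \[-1, 1\]
#' and invariant to positive rescaling of either vector.
#'
#' @param w1,w2 equal-length nonzero numeric vectors.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(w1, w2) {
  if (length(w1) != length(w2)) stop("vectors differ in length")
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for zero vector")
  sum(w1 * w2) / (n1 * n2)
}

#' TF-TF co-regulation network across cell types
#'
#' Nodes are (TF, cell type) pairs: the `top_k_per_type` differentially
#' active TFs of each cell type, each carrying its cell-type GRN weight
#' vector. Undirected edges connect node pairs whose regulatory profiles
#' have cosine similarity at or above `sim_threshold`; each unordered pair
#' appears once and self-pairs are excluded.
#'
#' @param grns named list of [weighted_grn()] (one per cell type,
#'   gene-aligned).
#' @param da output of [differential_tf_activity()].
#' @param top_k_per_type DA rows taken per cell type, default 5.
#' @param sim_threshold minimum cosine similarity for an edge.
#' @return data.frame `(tf1, type1, tf2, type2, similarity)`.
#' @export
coregulatory_network <- function(grns, da, top_k_per_type = 5L,
                                 sim_threshold = 0.5) {
  if (nrow(da) == 0) stop("differential activity table is empty")
  nodes <- do.call(rbind, lapply(split(da, da$cell_type), function(d) {
    utils::head(d[order(-d$lfc), c("tf", "cell_type")], top_k_per_type)
  }))
  nodes <- nodes[nodes$cell_type %in% names(grns), , drop = FALSE]
  vecs <- lapply(seq_len(nrow(nodes)), function(i) {
    g <- grns[[nodes$cell_type[i]]]
    g$weights[nodes$tf[i], ]
  })
  edges <- list()
  n <- nrow(nodes)
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n)) {
    s <- cosine_similarity(vecs[[i]], vecs[[j]])
    if (s >= sim_threshold)
      edges[[length(edges) + 1]] <- data.frame(
        tf1 = nodes$tf[i], type1 = nodes$cell_type[i],
        tf2 = nodes$tf[j], type2 = nodes$cell_type[j],
        similarity = s)
  }
  if (!length(edges))
    return(data.frame(tf1 = character(), type1 = character(),
                      tf2 = character(), type2 = character(),
                      similarity = numeric()))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Cross-cell-type GRN correlation with hierarchical clustering
#'
#' Each GRN's absolute weights are min-max normalized to \[0, 1\], then
#' Pearson correlation is computed between flattened matrices for every
#' pair of contexts. Average-linkage (UPGMA) hierarchical clustering on
#' the distance `1 - r` yields a leaf ordering of contexts.
#'
#' @param grns named list of >= 2 [weighted_grn()] with identical TF and
#'   gene index sets.
#' @return list: `correlation` (symmetric matrix, unit diagonal), `order`
#'   (leaf order of context names), `hclust` (the tree).
#' @export
grn_correlation_clustering <- function(grns) {
  if (length(grns) < 2) stop("need at least 2 GRNs")
  ref <- grns[[1]]
  V <- sapply(names(grns), function(nm) {
    g <- grns[[nm]]
    if (!identical(g$tf_ids, ref$tf_ids) ||
        !identical(g$gene_ids, ref$gene_ids))
      stop("GRN '", nm, "' is not index-aligned with the others")
    v <- abs(as.numeric(g$weights))
    rng <- range(v)
    if (rng[2] == rng[1])
      stop("GRN '", nm, "' is constant; correlation undefined")
    (v - rng[1]) / (rng[2] - rng[1])
  })
  R <- stats::cor(V)
  hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
  list(correlation = R, order = colnames(V)[hc$order], hclust = hc)
}

#' Over-representation of gene sets among a TF's top-ranked targets
#'
#' Targets are ranked by descending signed GRN weight (activation-oriented;
#' set `by_abs = TRUE` to rank by magnitude); the top
#' `ceiling(top_fraction * G)` genes are tested against each gene set with
#' a hypergeometric over-representation test over the GRN gene universe,
#' Benjamini-Hochberg adjusted across sets.
#'
#' @param grn [weighted_grn()].
#' @param tf TF identifier present in `grn`.
#' @param gene_sets named list of character gene vectors (e.g. read with
#'   [read_gmt()]).
#' @param top_fraction fraction of the universe taken as top targets,
#'   default 0.01.
#' @param p_threshold significance flag threshold on adjusted p.
#' @param by_abs rank by `|weight|` instead of signed weight.
#' @return data.frame `(set, overlap, set_size, top_size, p, p_adj,
#'   significant)`.
#' @export
top_targets_enrichment <- function(grn, tf, gene_sets,
                                   top_fraction = 0.01,
                                   p_threshold = 0.05, by_abs = FALSE) {
  stopifnot(inherits(grn, "weighted_grn"), length(gene_sets) >= 1)
  if (!tf %in% grn$tf_ids) stop("unknown TF: ", tf)
  w <- grn$weights[tf, ]
  score <- if (by_abs) abs(w) else w
  universe <- grn$gene_ids
  G <- length(universe)
  k_top <- ceiling(top_fraction * G)
  top <- universe[order(-score)][seq_len(k_top)]
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    if (!length(set)) {
      warning("gene set '", nm, "' has no overlap with the GRN universe; ",
              "skipped")
      return(NULL)
    }
    ov <- length(intersect(set, top))
    p <- stats::phyper(ov - 1, length(set), G - length(set), k_top,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set),
               top_size = k_top, p = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene set overlaps the GRN universe")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < p_threshold
  out[order(out$p_adj), ]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  out
}
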