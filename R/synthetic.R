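#' Synthetic dataset configuration
#'
#' States the world the generator emulates: cell-type-structured latent TF
#' activities, a sparse signed ground-truth GRN mapping activities to gene
#' means through a softplus link, Poisson counts with log-normal library
#' sizes, and Bernoulli dropout.
#'
#' @param n_cells,n_genes,n_tfs,n_cell_types dataset dimensions.
#' @param edges_per_tf targets sampled (without replacement) per TF.
#' @param activity_scale up-regulation of a cell type's signature TFs
#'   above the baseline 0, in activity units; default 3 gives clearly
#'   separated but overlapping types (silhouette > 0).
#' @param noise_sd per-cell Gaussian jitter around the type mean,
#'   default 1 (standard normal).
#' @param dropout_p technical dropout probability, default 0.1.
#' @param neg_edge_fraction fraction of repressive (negative) edges,
#'   default 0.25.
#' @param library_mu,library_sd log-normal library-size parameters
#'   (meanlog `log(5000)`, sdlog 0.3 by default).
#' @param seed RNG seed; the dataset is bitwise reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 200L, n_tfs = 20L,
                       n_cell_types = 3L, edges_per_tf = 15L,
                       activity_scale = 3, noise_sd = 1,
                       dropout_p = 0.1, neg_edge_fraction = 0.25,
                       library_mu = log(5000), library_sd = 0.3,
                       seed = 42L) {
  stopifnot(n_genes >= n_tfs, edges_per_tf >= 1,
            edges_per_tf <= n_genes, n_cell_types >= 1,
            dropout_p >= 0, dropout_p < 1,
            neg_edge_fraction >= 0, neg_edge_fraction <= 1)
  if (n_tfs < n_cell_types)
    stop("need at least one signature TF per cell type")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_tfs = as.integer(n_tfs),
                 n_cell_types = as.integer(n_cell_types),
                 edges_per_tf = as.integer(edges_per_tf),
                 activity_scale = activity_scale, noise_sd = noise_sd,
                 dropout_p = dropout_p,
                 neg_edge_fraction = neg_edge_fraction,
                 library_mu = library_mu, library_sd = library_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a single-cell dataset with known regulatory ground truth
#'
#' Generative process (all draws under `cfg$seed`):
#' 1. the TFs are split into disjoint signature blocks, one per cell type;
#'    a type's mean activity vector is `activity_scale` on its block, 0
#'    elsewhere;
#' 2. per-cell activities are the type mean plus `noise_sd`-scaled
#'    standard normal jitter;
#' 3. the true GRN gives each TF `edges_per_tf` targets sampled without
#'    replacement, weights `|N(0, 1)|` with a `neg_edge_fraction` subset
#'    negated;
#' 4. gene means are `softplus(activities \%*\% W_true)`;
#' 5. counts are Poisson with per-cell log-normal library-size scaling;
#' 6. entries are zeroed by Bernoulli dropout (`U > p` rule).
#'
#' An optional knockdown multiplies one TF's true activity by a factor in
#' a random half (or `fraction`) of cells before step 4, recording
#' perturbed/control groups — the in-silico analogue of a CRISPRi
#' experiment.
#'
#' @param cfg [sim_config()].
#' @param knockdown optional list `(tf = index or id, factor = 0.2,
#'   fraction = 0.5)`.
#' @return A `synthetic_dataset`: `expr` (counts [expression_matrix()]),
#'   `true_activities` ([tf_activity()]), `true_grn` ([weighted_grn()]),
#'   `labels`, optional `groups`, and the `config` echo.
#' @export
simulate_dataset <- function(cfg = sim_config(), knockdown = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- local_seed(cfg$seed); on.exit(restore_seed(old))
  n <- cfg$n_cells; G <- cfg$n_genes; Tf <- cfg$n_tfs
  K <- cfg$n_cell_types
  tf_ids <- sprintf("TF%02d", seq_len(Tf))
  gene_ids <- sprintf("G%04d", seq_len(G))
  cell_ids <- sprintf("cell%05d", seq_len(n))
  labels <- sprintf("type%d", rep(seq_len(K), length.out = n))
  block <- rep(seq_len(K), length.out = Tf)      # signature block per TF
  mean_mat <- matrix(0, K, Tf)
  for (k in seq_len(K)) mean_mat[k, block == k] <- cfg$activity_scale
  A <- mean_mat[rep(seq_len(K), length.out = n), , drop = FALSE] +
    matrix(stats::rnorm(n * Tf, sd = cfg$noise_sd), n, Tf)
  W <- matrix(0, Tf, G)
  for (f in seq_len(Tf)) {
    targets <- sample.int(G, cfg$edges_per_tf)
    w <- abs(stats::rnorm(cfg$edges_per_tf))
    n_neg <- round(cfg$neg_edge_fraction * cfg$edges_per_tf)
    if (n_neg > 0) {
      neg <- sample.int(cfg$edges_per_tf, n_neg)
      w[neg] <- -w[neg]
    }
    W[f, targets] <- w
  }
  groups <- NULL
  if (!is.null(knockdown)) {
    tf_idx <- if (is.character(knockdown$tf)) match(knockdown$tf, tf_ids)
              else as.integer(knockdown$tf)
    if (is.na(tf_idx) || tf_idx < 1 || tf_idx > Tf)
      stop("knockdown TF not found")
    frac <- if (is.null(knockdown$fraction)) 0.5 else knockdown$fraction
    fac <- if (is.null(knockdown$factor)) 0.2 else knockdown$factor
    perturbed <- sample.int(n, round(frac * n))
    A[perturbed, tf_idx] <- A[perturbed, tf_idx] * fac
    groups <- rep("control", n)
    groups[perturbed] <- "perturbed"
  }
  M <- softplus(A %*% W)                         # n x G positive means
  lib <- stats::rlnorm(n, cfg$library_mu, cfg$library_sd)
  rate <- M * (lib / rowSums(M))
  counts <- matrix(stats::rpois(n * G, as.vector(rate)), n, G)
  if (cfg$dropout_p > 0) {
    U <- matrix(stats::runif(n * G), n, G)
    counts <- counts * (U > cfg$dropout_p)
  }
  structure(list(
    expr = expression_matrix(counts, cell_ids, gene_ids, "counts"),
    true_activities = tf_activity(A, cell_ids, tf_ids, source = "model"),
    true_grn = weighted_grn(W, tf_ids, gene_ids, context = "truth"),
    labels = labels, groups = groups, config = cfg),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d cells x %d genes, %d TFs, ",
                     "%d cell types (seed %d)\n"),
              x$config$n_cells, x$config$n_genes, x$config$n_tfs,
              x$config$n_cell_types, x$config$seed))
  invisible(x)
}

#' Corrupt a ground-truth GRN into a plausible prior
#'
#' Drops a fraction of the true edges and adds an equal number of random
#' false edges (random signs), yielding the kind of incomplete, partly
#' wrong prior a curated database provides. Used to exercise the model's
#' ability to both exploit and outgrow its prior.
#'
#' @param true_grn [weighted_grn()] (or `synthetic_dataset`).
#' @param drop_frac fraction of true edges removed, default 0.2.
#' @param add_frac false edges added, as a fraction of the original edge
#'   count; default equals `drop_frac`.
#' @param seed RNG seed.
#' @return A signed [prior_network()] (entries in \{-1, +1\}).
#' @export
corrupt_prior <- function(true_grn, drop_frac = 0.2, add_frac = drop_frac,
                          seed = 0L) {
  if (inherits(true_grn, "synthetic_dataset")) true_grn <- true_grn$true_grn
  stopifnot(inherits(true_grn, "weighted_grn"),
            drop_frac >= 0, drop_frac < 1)
  old <- local_seed(seed); on.exit(restore_seed(old))
  S <- sign(true_grn$weights)
  edges <- which(S != 0)
  non_edges <- which(S == 0)
  n_drop <- round(drop_frac * length(edges))
  n_add <- round(add_frac * length(edges))
  if (n_drop > 0) S[sample(edges, n_drop)] <- 0
  if (n_add > 0)
    S[sample(non_edges, n_add)] <- sample(c(-1, 1), n_add, replace = TRUE)
  prior_network(S, true_grn$tf_ids, true_grn$gene_ids)
}

#' True edges of a synthetic dataset as a gold-standard edge list
#'
#' @param ds `synthetic_dataset` (or [weighted_grn()]).
#' @return data.frame `(tf, gene)` of nonzero true edges.
#' @export
gold_edges <- function(ds) {
  g <- if (inherits(ds, "synthetic_dataset")) ds$true_grn else ds
  nz <- which(g$weights != 0, arr.ind = TRUE)
  data.frame(tf = g$tf_ids[nz[, 1]], gene = g$gene_ids[nz[, 2]])
}
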