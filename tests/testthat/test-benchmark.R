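test_that("clustering metrics match the contingency-table oracle", {
  # 3-class toy with one swapped cell
  truth <- rep(c("a", "b", "c"), each = 5)
  cl <- rep(1:3, each = 5); cl[1] <- 2
  o <- contingency_oracle(cl, truth)
  expect_equal(adjusted_rand_index(cl, truth), o$ari, tolerance = 1e-12)
  expect_equal(normalized_mutual_info(cl, truth), o$nmi,
               tolerance = 1e-12)
  # perfect recovery: all metrics 1 (label names may differ)
  expect_equal(adjusted_rand_index(truth, truth), 1)
  expect_equal(normalized_mutual_info(rep(1:3, each = 5), truth), 1)
  expect_equal(macro_f1_voting(rep(1:3, each = 5), truth)$macro_f1, 1)
  # one cluster over two balanced classes: ARI = 0
  expect_equal(adjusted_rand_index(rep(1, 10), rep(c("a", "b"), 5)), 0)
  # majority-vote tie broken lexicographically
  expect_identical(unique(macro_f1_voting(rep(1, 4),
                                          c("b", "b", "a", "a"))$mapped),
                   "a")
})

test_that("auroc/auprc behave at the extremes and under permutation", {
  y <- c(rep(TRUE, 20), rep(FALSE, 180))
  s_perfect <- c(runif(20, 0.8, 1), runif(180, 0, 0.5))
  expect_equal(auroc(s_perfect, y), 1)
  expect_equal(auprc(s_perfect, y), 1)
  expect_equal(auroc(-s_perfect, y), 0)
  # monotone-transform invariance
  expect_equal(auroc(exp(3 * s_perfect), y), 1)
  set.seed(19)
  a_ro <- replicate(40, auroc(runif(200), y))
  a_pr <- replicate(40, auprc(runif(200), y))
  expect_lt(abs(mean(a_ro) - 0.5), 0.05)
  expect_lt(abs(mean(a_pr) - 0.1), 0.05)
  expect_error(auroc(runif(5), rep(TRUE, 5)), "negative")
})

test_that("evaluate_clustering recovers well-separated blobs", {
  set.seed(20)
  n_per <- 40
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0))
  A <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n_per * 3, sd = 0.5), n_per, 3) +
      matrix(centers[k, ], n_per, 3, byrow = TRUE)))
  truth <- rep(c("x", "y", "z"), each = n_per)
  rep_ <- evaluate_clustering(A, truth, resolutions = c(0.5, 1.0))
  expect_true(any(rep_$ari == 1))
  best <- rep_[which.max(rep_$ari), ]
  expect_equal(best$nmi, 1)
  expect_equal(best$macro_f1, 1)
  expect_equal(best$auc, 1)
  expect_error(evaluate_clustering(A, rep("x", nrow(A)), 1), "labels")
})

test_that("apply_dropout endpoints, reproducibility and concentration", {
  sw_e <- toy_expr()
  expect_identical(apply_dropout(sw_e, 0, seed = 1)$values, sw_e$values)
  expect_true(all(apply_dropout(sw_e, 1, seed = 1)$values == 0))
  set.seed(21)
  big <- expression_matrix(matrix(rpois(1e6, 5) + 1, 1000, 1000),
                           paste0("c", 1:1000), paste0("g", 1:1000),
                           "counts")
  d1 <- apply_dropout(big, 0.3, seed = 9)
  d2 <- apply_dropout(big, 0.3, seed = 9)
  expect_identical(d1$values, d2$values)
  frac <- mean(d1$values == 0)
  sd3 <- 3 * sqrt(0.3 * 0.7 / 1e6)
  expect_lt(abs(frac - 0.3), sd3)
  # already-zero entries stay zero
  dz <- apply_dropout(toy_expr(), 0.5, seed = 2)
  expect_true(all(dz$values[toy_expr()$values == 0] == 0))
})

test_that("evaluate_grn ranks gold edges over the pair universe", {
  set.seed(22)
  tfs <- paste0("T", 1:4); genes <- paste0("g", 1:25)
  truthW <- matrix(0, 4, 25, dimnames = list(tfs, genes))
  for (f in 1:4) truthW[f, sample(25, 5)] <- rnorm(5)
  gold <- gold_edges(weighted_grn(truthW, tfs, genes))
  # perfect scores: |truth| itself
  perfect <- weighted_grn(truthW, tfs, genes)
  ev <- evaluate_grn(perfect, gold)
  expect_equal(ev$auroc, 1)
  expect_equal(ev$auprc, 1)
  expect_equal(ev$prevalence, 20 / 100)
  # inverted scores: AUROC 0
  inv <- weighted_grn(max(abs(truthW)) + 1 - abs(truthW), tfs, genes)
  expect_equal(evaluate_grn(inv, gold)$auroc, 0)
  # monotone transform of |weights| leaves AUROC unchanged
  mono <- weighted_grn(sign(truthW) * sqrt(abs(truthW)), tfs, genes)
  expect_equal(evaluate_grn(mono, gold)$auroc, 1)
  # random scores hover at chance level
  set.seed(23)
  r_ro <- replicate(30, {
    rnd <- weighted_grn(matrix(rnorm(100), 4, 25), tfs, genes)
    unlist(evaluate_grn(rnd, gold)[c("auroc", "auprc")])
  })
  expect_lt(abs(mean(r_ro["auroc", ]) - 0.5), 0.05)
  expect_lt(abs(mean(r_ro["auprc", ]) - 0.2), 0.07)
  expect_error(evaluate_grn(perfect, gold[0, ]), "overlap|positives")
})

test_that("stratified subsets preserve cluster proportions", {
  counts <- matrix(rpois(150 * 5, 4), 150, 5)
  expr <- expression_matrix(counts, paste0("c", 1:150), paste0("g", 1:5),
                            "counts")
  labels <- rep(c("big", "small"), c(100, 50))
  ss <- stratified_subsets(expr, k = 5, seed = 1, labels = labels)
  expect_length(ss, 5)
  all_idx <- sort(unlist(ss))
  expect_identical(all_idx, 1:150)
  for (s in ss) {
    expect_equal(sum(labels[s] == "big"), 20)
    expect_equal(sum(labels[s] == "small"), 10)
  }
  # per-subset proportions within one cell of global even when uneven
  labels2 <- rep(c("a", "b"), c(101, 49))
  ss2 <- stratified_subsets(expr, k = 5, seed = 2, labels = labels2)
  for (s in ss2)
    expect_lte(abs(sum(labels2[s] == "a") - 101 / 5), 1)
  # reproducible bitwise
  expect_identical(stratified_subsets(expr, k = 5, seed = 1,
                                      labels = labels), ss)
  # tiny cluster triggers a warning, never an error
  labels3 <- c(rep("big", 147), rep("tiny", 3))
  expect_warning(ss3 <- stratified_subsets(expr, k = 5, seed = 3,
                                           labels = labels3), "tiny")
  expect_identical(sort(unlist(ss3)), 1:150)
})

test_that("knockdown evaluation: null case and exact LFC arithmetic", {
  set.seed(24)
  v <- rnorm(40)
  acts <- tf_activity(cbind(TFa = v), paste0("c", 1:40), "TFa", "model")
  groups <- rep(c("perturbed", "control"), 20)
  # same distribution in both groups: tiny |lfc|, large p
  kd0 <- knockdown_evaluation(acts, sample(groups), "TFa")
  expect_gt(kd0$p, 0.05)
  # rescaled means 0.25 (perturbed) vs 0.5 (control) -> lfc exactly -1
  vv <- c(0, 0.25, 0.25, 0.5, 1, 0.5, 0.25, 0.25)
  g2 <- c("perturbed", "perturbed", "perturbed", "perturbed",
          "control", "control", "control", "control")
  a2 <- tf_activity(cbind(TFb = vv), paste0("c", 1:8), "TFb", "model")
  kd2 <- knockdown_evaluation(a2, g2, "TFb")
  expect_equal(kd2$lfc, -1.0)
  expect_error(knockdown_evaluation(a2, g2, "TFz"), "unknown")
  expect_error(knockdown_evaluation(a2, rep("perturbed", 8), "TFb"),
               "3 cells")
})
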