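test_that("differential activity: null, separated, and LFC arithmetic", {
  set.seed(14)
  n <- 20
  labs <- rep(c("A", "B"), each = 10)
  # TF1: identical distribution in both groups -> excluded at any
  # reasonable threshold; TF2: perfectly separated
  v_null <- rnorm(n)
  v_sep <- c(rnorm(10, 10), rnorm(10, 0))
  acts <- tf_activity(cbind(TF1 = v_null, TF2 = v_sep),
                      paste0("c", 1:n), c("TF1", "TF2"), "model")
  da <- differential_tf_activity(acts, labs, p_threshold = 0.05)
  expect_false("TF1" %in% da$tf)
  expect_true("TF2" %in% da$tf)
  # perfectly separated 10 vs 10 without ties attains the minimal exact
  # two-sided rank-sum p = 2 / choose(20, 10)
  p_obs <- min(da$p[da$tf == "TF2"])
  expect_equal(p_obs, 2 / choose(20, 10), tolerance = 1e-12)
  # and matches the enumeration oracle on a smaller instance
  x <- c(5.2, 6.1, 7.3, 8.5); y <- c(1.1, 2.0, 3.4, 0.2)
  expect_equal(suppressWarnings(stats::wilcox.test(x, y)$p.value),
               exact_wilcox_oracle(x, y), tolerance = 1e-12)

  # rescaled group means 0.5 vs 0.25 give LFC exactly 1
  v <- c(0.4, 0.6, 0, 1, 0, 0)     # already spans [0,1]: rescale is identity
  labs2 <- c("g", "g", "r", "r", "r", "r")
  acts2 <- tf_activity(cbind(TFx = v), paste0("c", 1:6), "TFx", "model")
  da2 <- differential_tf_activity(acts2, labs2, p_threshold = 1.1,
                                  min_cells = 2L)
  expect_equal(da2$lfc[da2$cell_type == "g"], 1.0)
})

test_that("differential activity p-values are uniform under label permutation", {
  set.seed(15)
  acts <- tf_activity(matrix(rnorm(200 * 10), 200, 10),
                      paste0("c", 1:200), paste0("TF", 1:10), "model")
  labs <- sample(rep(c("A", "B"), each = 100))
  da <- differential_tf_activity(acts, labs, p_threshold = 1.1)
  ks <- suppressWarnings(stats::ks.test(unique(da$p), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cosine similarity formula, bounds and errors", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(cosine_similarity(c(1, 2), 5 * c(1, 2)), 1)
  expect_error(cosine_similarity(c(0, 0), c(1, 2)), "zero")
  expect_error(cosine_similarity(1:3, 1:2), "length")
  set.seed(16)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    s <- cosine_similarity(a, b)
    expect_lte(abs(s), 1 + 1e-12)
    expect_equal(s, cosine_similarity(b, a))
    expect_equal(s, cosine_similarity(3.7 * a, b), tolerance = 1e-12)
  }
})

make_da_fixture <- function() {
  data.frame(tf = c("T1", "T2", "T3", "T1"),
             cell_type = c("X", "X", "Y", "Y"),
             lfc = c(2, 1, 1.5, 0.5),
             p = 1e-4, p_adj = 1e-3)
}

test_that("co-regulatory network edges follow the similarity threshold", {
  set.seed(17)
  W <- matrix(rnorm(3 * 8), 3, 8,
              dimnames = list(c("T1", "T2", "T3"), paste0("g", 1:8)))
  gX <- weighted_grn(W, rownames(W), colnames(W), context = "X")
  gY <- weighted_grn(W, rownames(W), colnames(W), context = "Y")  # copy
  grns <- list(X = gX, Y = gY)
  da <- make_da_fixture()
  # unattainable threshold: no edges
  e0 <- coregulatory_network(grns, da, top_k_per_type = 2,
                             sim_threshold = 1 + 1e-9)
  expect_equal(nrow(e0), 0)
  # duplicated GRN: every TF pairs with itself across contexts at sim 1
  e1 <- coregulatory_network(grns, da, top_k_per_type = 2,
                             sim_threshold = 0.999999)
  self <- e1[e1$tf1 == e1$tf2, ]
  expect_true("T1" %in% self$tf1)
  expect_true(all(abs(self$similarity - 1) < 1e-9))
  # each unordered pair appears exactly once
  key <- apply(e1[, 1:4], 1, function(r)
    paste(sort(c(paste(r[1], r[2]), paste(r[3], r[4]))), collapse = "|"))
  expect_false(any(duplicated(key)))
})

test_that("GRN correlation clustering groups shared-support contexts", {
  set.seed(18)
  base <- matrix(0, 4, 30, dimnames = list(paste0("T", 1:4),
                                           paste0("g", 1:30)))
  A <- base; A[, 1:10] <- abs(rnorm(40))
  B <- base; B[, 1:10] <- A[, 1:10] + matrix(rnorm(40, sd = 0.05), 4)
  C <- base; C[, 21:30] <- abs(rnorm(40))
  grns <- list(A = weighted_grn(A, rownames(A), colnames(A), "A"),
               B = weighted_grn(B, rownames(B), colnames(B), "B"),
               C = weighted_grn(C, rownames(C), colnames(C), "C"))
  out <- grn_correlation_clustering(grns)
  expect_equal(diag(out$correlation), c(A = 1, B = 1, C = 1))
  expect_equal(out$correlation, t(out$correlation))
  # scale invariance through |.|-min-max: 2*W correlates at exactly 1
  grns2 <- list(A = grns$A,
                A2 = weighted_grn(2 * A, rownames(A), colnames(A), "A2"))
  expect_equal(grn_correlation_clustering(grns2)$correlation["A", "A2"], 1)
  # A and B are adjacent leaves, C apart
  ord <- out$order
  expect_equal(abs(diff(match(c("A", "B"), ord))), 1)
  # constant GRN is rejected by name
  grns3 <- c(grns[1:2],
             list(K = weighted_grn(base * 0, rownames(base),
                                   colnames(base), "K")))
  expect_error(grn_correlation_clustering(grns3), "K")
})

test_that("top-target enrichment matches the exact hypergeometric tail", {
  W <- matrix(0, 1, 4, dimnames = list("T1", paste0("g", 1:4)))
  W[1, ] <- c(4, 3, 2, 1)
  g <- weighted_grn(W, "T1", colnames(W))
  sets <- list(hit1 = c("g1", "g3"),    # overlaps top-2 {g1,g2} once
               perfect = c("g1", "g2"),
               none = c("g3", "g4"))
  out <- top_targets_enrichment(g, "T1", sets, top_fraction = 0.5,
                                p_threshold = 0.05)
  # exact enumeration: P(overlap >= k) drawing 2 of 4 with 2 marked
  enum_p <- function(k) {
    sum(sapply(k:2, function(i)
      choose(2, i) * choose(2, 2 - i))) / choose(4, 2)
  }
  expect_equal(out$p[out$set == "hit1"], enum_p(1), tolerance = 1e-12)
  expect_equal(out$p[out$set == "perfect"], enum_p(2), tolerance = 1e-12)
  expect_equal(out$p[out$set == "none"], 1, tolerance = 1e-12)
  expect_equal(out$p[out$set == "perfect"], min(out$p))
  expect_error(top_targets_enrichment(g, "T9", sets), "unknown")
  expect_warning(
    top_targets_enrichment(g, "T1", list(x = "g1", off = "zzz"),
                           top_fraction = 0.5),
    "'off'")
})

test_that("GMT reading returns named member lists", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), f)
  gs <- read_gmt(f)
  expect_named(gs, c("setA", "setB"))
  expect_equal(gs$setA, c("g1", "g2", "g3"))
})
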