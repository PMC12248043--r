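test_that("split_train_val produces a deterministic 85/15 partition", {
  sp <- split_train_val(100, 0.15, seed = 9)
  expect_length(sp$val, 15)
  expect_length(sp$train, 85)
  expect_identical(sort(c(sp$train, sp$val)), 1:100)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(split_train_val(100, 0.15, seed = 9), sp)
  expect_false(identical(split_train_val(100, 0.15, seed = 10)$val,
                         sp$val))
  expect_error(split_train_val(1, 0.15, 1))
})

sw <- small_world(seed = 21)
mc_small <- model_config(latent_dim = 8, encoder_widths = 32L,
                         decoder_widths = 16L, epochs = 30, seed = 1)
tc_small <- train_config(max_epochs = 30, seed = 1, batch_size = 64)
tm_small <- fit(sw$lognorm, sw$prior, model_cfg = mc_small,
                train_cfg = tc_small)

test_that("fit improves validation loss and returns the best checkpoint", {
  h <- tm_small$history
  expect_lte(min(h$val_total), h$val_total[1])
  expect_equal(min(h$val_total), h$val_total[tm_small$best_epoch])
  expect_s3_class(tm_small$grn, "weighted_grn")
  expect_equal(dim(tm_small$grn$weights),
               dim(as.matrix(sw$prior$weights)))
  # alpha schedule recorded: non-decreasing, clipped at alpha_max
  expect_true(all(diff(h$alpha) >= 0))
  expect_lte(max(h$alpha), mc_small$alpha_max)
  # mask factor strictly decreasing along the epoch budget
  expect_true(all(diff(h$mask) < 0))
})

test_that("fit is deterministic under a fixed seed", {
  tm2 <- fit(sw$lognorm, sw$prior, model_cfg = mc_small,
             train_cfg = tc_small)
  expect_equal(tm2$history, tm_small$history, tolerance = 1e-12)
  a1 <- infer_activities(tm_small, sw$lognorm)
  a2 <- infer_activities(tm2, sw$lognorm)
  expect_identical(a1$values, a2$values)
})

test_that("a one-step alpha schedule completes and is well formed", {
  mc1 <- model_config(latent_dim = 8, encoder_widths = 32L,
                      decoder_widths = 16L, epochs = 5,
                      delta_alpha = 0.9, alpha_max = 0.9, seed = 1)
  tm1 <- fit(sw$lognorm, sw$prior, model_cfg = mc1,
             train_cfg = train_config(max_epochs = 5, seed = 1,
                                      batch_size = 64))
  expect_equal(tm1$history$alpha, c(0, rep(0.9, 4)))
  expect_equal(nrow(tm1$history), 5)
})

test_that("early in a long budget the GRN stays pinned to the prior", {
  # 3 epochs of a 100-epoch mask horizon: m(t) > 0.99 throughout, so the
  # returned GRN must sit within optimizer-step distance of the prior
  mc <- model_config(latent_dim = 8, encoder_widths = 32L,
                     decoder_widths = 16L, epochs = 100, seed = 1)
  tm <- fit(sw$lognorm, sw$prior, model_cfg = mc,
            train_cfg = train_config(max_epochs = 3, seed = 1,
                                     batch_size = 64))
  expect_gt(min(tm$history$mask), 0.99)
  expect_lt(max(abs(tm$model$params$W_grn -
                      as.matrix(sw$prior$weights))), 0.05)
})

test_that("infer_activities is deterministic, shaped, and data-sensitive", {
  a1 <- infer_activities(tm_small, sw$lognorm)
  expect_identical(dim(a1$values),
                   c(length(sw$lognorm$cell_ids),
                     length(sw$prior$tf_ids)))
  expect_identical(a1$values,
                   infer_activities(tm_small, sw$lognorm)$values)
  expect_identical(a1$source, "blended")
  # raw decoder output is also exposed
  expect_identical(infer_activities(tm_small, sw$lognorm,
                                    blend = FALSE)$source, "model")
  # missing genes are named
  sub <- sw$lognorm
  sub$values <- sub$values[, -1]; sub$gene_ids <- sub$gene_ids[-1]
  expect_error(infer_activities(tm_small, sub), sw$lognorm$gene_ids[1])
  # permuted-gene control: true-activity correlation beats permutation
  tru <- sw$ds$true_activities
  tru_m <- tru$values[match(a1$cell_ids, tru$cell_ids),
                      match(a1$tf_ids, tru$tf_ids)]
  per_tf <- function(av) mean(sapply(seq_len(ncol(av)), function(j)
    stats::cor(av[, j], tru_m[, j])))
  set.seed(33)
  Xp <- sw$lognorm$values[, sample(ncol(sw$lognorm$values))]
  colnames(Xp) <- sw$lognorm$gene_ids
  permuted <- expression_matrix(Xp, sw$lognorm$cell_ids,
                                sw$lognorm$gene_ids, "lognorm")
  ap <- infer_activities(tm_small, permuted)
  expect_gt(per_tf(a1$values), per_tf(ap$values))
})

test_that("fine-tuned GRNs separate cell types beyond rerun noise", {
  labs <- sw$ds$labels[match(sw$lognorm$cell_ids, sw$ds$expr$cell_ids)]
  set.seed(7)
  ft1 <- finetune_celltypes(tm_small, sw$lognorm, labs, epochs = 5)
  set.seed(7)
  ft_rep <- finetune_celltypes(tm_small, sw$lognorm, labs, epochs = 5)
  set.seed(8)
  ft2 <- finetune_celltypes(tm_small, sw$lognorm, labs, epochs = 5)
  expect_setequal(names(ft1$grns), unique(labs))
  # same RNG stream -> identical clone
  expect_identical(ft1$grns[[1]]$weights, ft_rep$grns[[1]]$weights)
  d <- function(a, b) sqrt(mean((a$weights - b$weights)^2))
  between <- d(ft1$grns[[1]], ft1$grns[[2]])
  replicate_dist <- d(ft1$grns[[1]], ft2$grns[[1]])
  expect_gt(between, replicate_dist)
  # context labels carried through
  expect_identical(ft1$grns[["type1"]]$context, "type1")
  # undersized labels are skipped with a warning
  labs_bad <- labs; labs_bad[1:5] <- "rare"
  labs_bad[-(1:5)] <- "common"
  expect_warning(ft3 <- finetune_celltypes(tm_small, sw$lognorm, labs_bad,
                                           epochs = 1),
                 "rare")
  expect_named(ft3$grns, "common")
})

test_that("GRN export/import round-trips and omits zeros", {
  g <- tm_small$grn
  g$weights[1, 1:3] <- 0
  f <- tempfile(fileext = ".tsv")
  export_grn(g, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_false(any(tab$weight == 0))
  g2 <- import_grn(f, tf_ids = g$tf_ids, gene_ids = g$gene_ids)
  expect_equal(g2$weights, g$weights, tolerance = 1e-12)
  expect_identical(unique(tab$context), "global")
  # cell-type context survives the round trip
  gc <- weighted_grn(g$weights, g$tf_ids, g$gene_ids, context = "Bcell")
  export_grn(gc, f)
  expect_identical(import_grn(f, g$tf_ids, g$gene_ids)$context, "Bcell")
})

test_that("model checkpoints save and load losslessly", {
  f <- tempfile(fileext = ".rds")
  save_model(tm_small, f)
  tm2 <- load_model(f)
  expect_identical(tm2$model$params$W_grn, tm_small$model$params$W_grn)
  expect_identical(infer_activities(tm2, sw$lognorm)$values,
                   infer_activities(tm_small, sw$lognorm)$values)
})
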