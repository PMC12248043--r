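#' Training configuration
#'
#' @param val_fraction validation fraction of cells (default 0.15, the
#'   conventional 85/15 split).
#' @param learning_rate Adam learning rate, default 1e-3.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is halved (reduce-on-plateau), default 10.
#' @param lr_factor multiplicative decay on plateau, default 0.5.
#' @param batch_size minibatch size, default 128.
#' @param max_epochs epoch budget (also the mask-schedule horizon unless
#'   the model config says otherwise), default 100.
#' @param early_stop_patience epochs without improvement before stopping;
#'   `Inf` disables early stopping.
#' @param grad_clip global gradient-norm clip, default 5.
#' @param seed RNG seed controlling split, init, batching and sampling.
#' @param verbose print a progress line every `verbose` epochs (0 = quiet).
#' @return A `train_config` list.
#' @export
train_config <- function(val_fraction = 0.15, learning_rate = 1e-3,
                         lr_patience = 10L, lr_factor = 0.5,
                         batch_size = 128L, max_epochs = 100L,
                         early_stop_patience = Inf, grad_clip = 5,
                         seed = 42L, verbose = 0L) {
  stopifnot(val_fraction > 0, val_fraction < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1)
  structure(list(val_fraction = val_fraction,
                 learning_rate = learning_rate,
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 grad_clip = grad_clip, seed = as.integer(seed),
                 verbose = as.integer(verbose)),
            class = "train_config")
}

#' Deterministic train/validation split
#'
#' Validation size is `round(n_cells * val_fraction)` (at least 1), drawn
#' without replacement under the given seed; the remainder trains.
#'
#' @param n_cells number of cells (>= 2).
#' @param val_fraction fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(n_cells, val_fraction, seed) {
  stopifnot(n_cells >= 2, val_fraction > 0, val_fraction < 1)
  n_val <- max(1L, round(n_cells * val_fraction))
  if (n_val >= n_cells) stop("validation split leaves no training cells")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  val <- sort(sample.int(n_cells, n_val))
  list(train = setdiff(seq_len(n_cells), val), val = val)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- Adam optimizer over nested parameter lists -----------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) return(lapply(p, zero_like))
    p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

grad_global_norm <- function(g) {
  sqrt(sum(vapply(
    rapply(drop_nulls(g), function(x) sum(x^2), how = "unlist"),
    identity, numeric(1))))
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gn <- grad_global_norm(grads)
  sc <- if (is.finite(clip) && gn > clip) clip / gn else 1
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  walk <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- g * sc
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, st$m, st$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = st$t))
}

#' Fit the GRN-prior VAE
#'
#' Runs the prior-initialization and dynamic-inference phases: Adam over
#' minibatches, the alpha schedule stepping per epoch, gamma linearly
#' interpolated over epochs, and the prior mask blend
#' `W <- m(t) W_prior + (1 - m(t)) W` applied after each epoch's optimizer
#' steps. The mask and gamma schedules run over the `model_cfg$epochs`
#' horizon; `train_cfg$max_epochs` caps the actual number of epochs
#' (normally the two are equal). Validation loss (deterministic pass, z = mu) drives
#' reduce-on-plateau learning-rate decay, optional early stopping, and
#' selection of the returned best checkpoint.
#'
#' @param expr log-normalized [expression_matrix()], gene-aligned with
#'   `prior`.
#' @param prior filtered [prior_network()].
#' @param e_ulm optional precomputed [ulm_activities()] matrix for all
#'   cells; computed internally when `NULL`.
#' @param model_cfg [model_config()].
#' @param train_cfg [train_config()].
#' @return A `trained_model`: best-validation parameters, the global
#'   [weighted_grn()], per-epoch `history` (train/val loss breakdowns),
#'   the ULM anchor matrix, and schedule state.
#' @export
fit <- function(expr, prior, e_ulm = NULL,
                model_cfg = model_config(), train_cfg = train_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$layer != "lognorm" && model_cfg$recon == "mse")
    stop("fit with the Gaussian head expects log-normalized input")
  if (is.null(e_ulm)) {
    e_src <- if (expr$layer == "lognorm") expr else lognormalize(expr)
    e_ulm <- ulm_activities(e_src, prior)
  }
  E <- e_ulm$values
  # z-score the ULM anchor per TF so anchor and decoder live on one scale
  E <- scale(E)
  E[!is.finite(E)] <- 0
  attr(E, "scaled:center") <- NULL; attr(E, "scaled:scale") <- NULL
  X <- expr$values
  n <- nrow(X)
  old <- local_seed(train_cfg$seed)
  on.exit(restore_seed(old))
  sp <- split_train_val(n, train_cfg$val_fraction, train_cfg$seed)
  model <- init_model(model_cfg, prior)
  opt <- adam_init(model$params)
  lr <- train_cfg$learning_rate
  T_total <- train_cfg$max_epochs
  T_sched <- model_cfg$epochs    # mask/gamma horizon; may exceed the cap
  alpha <- model_cfg$alpha_start
  best <- list(val = Inf, params = model$params, epoch = 0L)
  since_improve <- 0L; since_lr <- 0L
  hist <- vector("list", T_total)
  Xtr <- X[sp$train, , drop = FALSE]; Etr <- E[sp$train, , drop = FALSE]
  Xva <- X[sp$val, , drop = FALSE];  Eva <- E[sp$val, , drop = FALSE]
  d <- model_cfg$latent_dim
  for (t in seq_len(T_total)) {
    gamma_t <- model_cfg$gamma_start +
      (model_cfg$gamma_end - model_cfg$gamma_start) *
      min((t - 1) / max(T_sched - 1, 1), 1)
    ord <- sample.int(nrow(Xtr))
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    tr_tot <- tr_rec <- tr_kl <- 0
    for (b in batches) {
      xb <- Xtr[b, , drop = FALSE]; eb <- Etr[b, , drop = FALSE]
      noise <- matrix(stats::rnorm(length(b) * d), length(b), d)
      st <- vae_forward(model, xb, eb, alpha, noise)
      lb <- total_loss(st, xb, model$params$W_grn, gamma_t,
                       recon = model_cfg$recon,
                       nb_theta = model_cfg$nb_theta)
      if (!is.finite(lb$total)) {
        warning("non-finite loss at epoch ", t, "; aborting with last ",
                "finite state")
        return(finish_fit(model, best, hist[seq_len(t - 1)], prior,
                          model_cfg, train_cfg, E, alpha, diverged = TRUE))
      }
      g <- vae_backward(model, st, gamma_t)
      up <- adam_step(model$params, g, opt, lr, clip = train_cfg$grad_clip)
      model$params <- up$params
      opt <- up$state
      w <- length(b) / nrow(Xtr)
      tr_tot <- tr_tot + lb$total * w
      tr_rec <- tr_rec + lb$recon * w
      tr_kl <- tr_kl + lb$kl * w
    }
    m_t <- mask_factor(min(t, T_sched), T_sched)
    model$params$W_grn <- blend_weights(model$W_prior, model$params$W_grn,
                                        m_t)
    stv <- vae_forward(model, Xva, Eva, alpha, noise = NULL)
    vl <- total_loss(stv, Xva, model$params$W_grn, gamma_t,
                     recon = model_cfg$recon, nb_theta = model_cfg$nb_theta)
    hist[[t]] <- data.frame(epoch = t, alpha = alpha, gamma = gamma_t,
                            mask = m_t, lr = lr,
                            train_total = tr_tot, train_recon = tr_rec,
                            train_kl = tr_kl,
                            val_total = vl$total, val_recon = vl$recon,
                            val_kl = vl$kl, val_grn_l1 = vl$grn_l1)
    if (train_cfg$verbose > 0 && t %% train_cfg$verbose == 0)
      message(sprintf("epoch %3d  alpha %.2f  m %.3f  train %.3f  val %.3f",
                      t, alpha, m_t, tr_tot, vl$total))
    if (vl$total < best$val) {
      best <- list(val = vl$total, params = model$params, epoch = t)
      since_improve <- 0L; since_lr <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_lr <- since_lr + 1L
      if (since_lr >= train_cfg$lr_patience) {
        lr <- lr * train_cfg$lr_factor
        since_lr <- 0L
      }
      if (since_improve >= train_cfg$early_stop_patience) {
        hist <- hist[seq_len(t)]
        break
      }
    }
    alpha <- alpha_step(alpha, model_cfg$delta_alpha, model_cfg$alpha_max)
  }
  finish_fit(model, best, hist, prior, model_cfg, train_cfg, E, alpha)
}

finish_fit <- function(model, best, hist, prior, model_cfg, train_cfg,
                       E, alpha, diverged = FALSE) {
  model$params <- best$params
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  structure(list(model = model,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 grn = weighted_grn(best$params$W_grn, model$tf_ids,
                                    model$gene_ids, context = "global"),
                 history = history,
                 e_ulm = E,
                 best_epoch = best$epoch,
                 alpha_final = alpha,
                 diverged = diverged),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %d epochs run, best epoch %d (val loss %.4f)%s\n",
    nrow(x$history), x$best_epoch,
    min(x$history$val_total), if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Infer per-cell TF activities with a trained model
#'
#' Deterministic noise-free forward pass (z = mu). The reported activity
#' is the blended estimate
#' `e_hat = (1 - alpha) e_ulm + alpha e_dec` evaluated at the alpha of the
#' returned best checkpoint, with the ULM component recomputed on the
#' supplied cells and standardized per TF (as during training). When the
#' anchor was fully released (`alpha = 1`) this reduces to the raw decoder
#' output.
#'
#' @param trained a `trained_model` from [fit()].
#' @param expr log-normalized [expression_matrix()] covering the model's
#'   genes.
#' @param blend return the blended estimate (default); `FALSE` returns
#'   the raw decoder output `e_dec`.
#' @return A [tf_activity()] with `source = "blended"` (or `"model"` when
#'   unblended).
#' @export
infer_activities <- function(trained, expr, blend = TRUE) {
  model <- trained$model
  missing <- setdiff(model$gene_ids, expr$gene_ids)
  if (length(missing))
    stop("expression is missing model genes: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  X <- expr$values[, model$gene_ids, drop = FALSE]
  sub <- expression_matrix(X, expr$cell_ids, model$gene_ids,
                           layer = "lognorm")
  af <- infer_alpha(trained)
  if (blend && af < 1) {
    pr <- prior_network(model$W_prior, model$tf_ids, model$gene_ids)
    E <- scale(ulm_activities(sub, pr)$values)
    E[!is.finite(E)] <- 0
  } else {
    E <- matrix(0, nrow(X), length(model$tf_ids))
    af <- 1
  }
  st <- vae_forward(model, X, E, alpha = af, noise = NULL)
  tf_activity(st$e_hat, expr$cell_ids, model$tf_ids,
              source = if (af < 1) "blended" else "model")
}

# alpha in force at the best checkpoint (falls back to the final alpha)
infer_alpha <- function(trained) {
  if (!is.null(trained$history) && trained$best_epoch >= 1 &&
      trained$best_epoch <= nrow(trained$history))
    trained$history$alpha[trained$best_epoch]
  else trained$alpha_final
}

#' Fine-tune GRNs and activities per cell type
#'
#' Phase three: for each cell-type label with at least `min_cells` cells,
#' the global model is cloned and training continues on that subset only,
#' at a reduced learning rate, with the anchor fixed at `alpha_max` and no
#' prior re-blending (the mask schedule has run its course). Each clone
#' contributes a cell-type-specific GRN and activity matrix.
#'
#' @param trained global `trained_model`.
#' @param expr log-normalized [expression_matrix()] (all cells).
#' @param labels per-cell character vector of cell-type labels.
#' @param epochs fine-tuning epoch cap per cell type, default 20.
#' @param lr_mult learning-rate reduction factor, default 0.1.
#' @param min_cells labels with fewer cells are skipped with a warning.
#' @param freeze_encoder if `TRUE`, only decoder/GRN parameters update.
#' @return list with named lists `grns` ([weighted_grn()] per label,
#'   `context` set) and `activities` ([tf_activity()] per label).
#' @export
finetune_celltypes <- function(trained, expr, labels, epochs = 20L,
                               lr_mult = 0.1, min_cells = 20L,
                               freeze_encoder = FALSE) {
  stopifnot(length(labels) == nrow(expr$values))
  labels <- as.character(labels)
  out_grn <- list(); out_act <- list()
  lr <- trained$train_cfg$learning_rate * lr_mult
  d <- trained$model_cfg$latent_dim
  gamma <- trained$model_cfg$gamma_end
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    if (length(idx) < min_cells) {
      warning("cell type '", lab, "' has ", length(idx),
              " cells (< ", min_cells, "); skipped")
      next
    }
    model <- trained$model
    opt <- adam_init(model$params)
    X <- expr$values[idx, model$gene_ids, drop = FALSE]
    E <- trained$e_ulm[idx, , drop = FALSE]
    alpha <- trained$model_cfg$alpha_max
    bs <- trained$train_cfg$batch_size
    for (t in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      for (b in split(ord, ceiling(seq_along(ord) / bs))) {
        xb <- X[b, , drop = FALSE]; eb <- E[b, , drop = FALSE]
        noise <- matrix(stats::rnorm(length(b) * d), length(b), d)
        st <- vae_forward(model, xb, eb, alpha, noise)
        g <- vae_backward(model, st, gamma)
        if (freeze_encoder) {
          g$enc <- lapply(g$enc, function(l) lapply(l, function(x) x * 0))
          g$head_mu <- lapply(g$head_mu, function(x) x * 0)
          g$head_lv <- lapply(g$head_lv, function(x) x * 0)
        }
        up <- adam_step(model$params, g, opt, lr,
                        clip = trained$train_cfg$grad_clip)
        model$params <- up$params
        opt <- up$state
      }
    }
    sub_expr <- expression_matrix(X, expr$cell_ids[idx], model$gene_ids,
                                  layer = "lognorm")
    clone <- trained; clone$model <- model
    out_grn[[lab]] <- weighted_grn(model$params$W_grn, model$tf_ids,
                                   model$gene_ids, context = lab)
    out_act[[lab]] <- infer_activities(clone, sub_expr)
  }
  list(grns = out_grn, activities = out_act)
}

#' Export a weighted GRN to a long-format TSV
#'
#' Columns `tf`, `gene`, `weight`, `context`; zero-weight pairs are
#' omitted. Round-trips through [import_grn()] losslessly.
#'
#' @param grn [weighted_grn()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_grn <- function(grn, path) {
  stopifnot(inherits(grn, "weighted_grn"))
  nz <- which(grn$weights != 0, arr.ind = TRUE)
  df <- data.frame(tf = grn$tf_ids[nz[, 1]],
                   gene = grn$gene_ids[nz[, 2]],
                   weight = grn$weights[nz],
                   context = grn$context)
  df <- df[order(df$tf, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import a long-format GRN TSV
#'
#' @param path TSV written by [export_grn()].
#' @param tf_ids,gene_ids optional full identifier sets (restores rows or
#'   columns that were all-zero on export).
#' @return A [weighted_grn()].
#' @export
import_grn <- function(path, tf_ids = NULL, gene_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(tf_ids)) tf_ids <- sort(unique(df$tf))
  if (is.null(gene_ids)) gene_ids <- sort(unique(df$gene))
  W <- matrix(0, length(tf_ids), length(gene_ids),
              dimnames = list(tf_ids, gene_ids))
  W[cbind(match(df$tf, tf_ids), match(df$gene, gene_ids))] <- df$weight
  ctx <- if (nrow(df)) df$context[1] else "global"
  weighted_grn(W, tf_ids, gene_ids, context = ctx)
}

#' Save / load a trained model checkpoint
#'
#' Single-file RDS archive containing configs, parameter tensors,
#' identifier lists and schedule state, tagged with a schema version.
#'
#' @param trained a `trained_model`.
#' @param path checkpoint path.
#' @return `path` invisibly; `load_model` returns the `trained_model`.
#' @export
save_model <- function(trained, path) {
  stopifnot(inherits(trained, "trained_model"))
  saveRDS(list(schema = 1L, object = trained), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, 1L)) stop("unknown checkpoint schema")
  x$object
}
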