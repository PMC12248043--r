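#' Model architecture configuration
#'
#' The encoder (1-3 fully connected ReLU layers) maps log-normalized
#' expression to a Gaussian latent posterior; the decoder (1-2 ReLU layers
#' plus a linear TF head) maps latent samples to TF activities; the final
#' linear layer is the trainable TF x gene GRN weight matrix, initialized
#' from the signed prior.
#'
#' Schedules: the ULM anchor weight `alpha` steps by `delta_alpha` per
#' epoch from `alpha_start` up to `alpha_max` (activities move from
#' prior-driven to data-driven); the L1 sparsity coefficient `gamma` is
#' linearly interpolated from `gamma_start` to `gamma_end` over epochs; the
#' prior mask factor m(t) decays logistically from ~1 to ~0 with midpoint
#' at half the epoch budget.
#'
#' @param latent_dim latent dimension, default 64.
#' @param encoder_widths 1-3 hidden widths, default `c(512, 256)`.
#' @param decoder_widths 1-2 hidden widths, default `256`.
#' @param alpha_start,alpha_max anchor schedule endpoints in \[0, 1\].
#'   The default `alpha_max = 0.9` keeps a residual ULM anchor in the
#'   blended activity: with a fully released anchor (`alpha_max = 1`) a
#'   TF's decoder activity and its GRN row can jointly flip sign without
#'   any reconstruction cost, destroying the interpretability of activity
#'   directions.
#' @param delta_alpha per-epoch alpha increment (> 0), default 0.02.
#' @param gamma_start,gamma_end L1 schedule endpoints (>= 0).
#' @param epochs total epoch budget T (also the mask-schedule horizon).
#' @param seed integer seed for weight initialization noise.
#' @param gene_bias add a per-gene intercept to the reconstruction
#'   (default `FALSE`: pure `W_GRN . e_TF` readout).
#' @param recon reconstruction likelihood: `"mse"` (Gaussian, on lognorm
#'   input; default) or `"nb"` (negative binomial on counts via a softplus
#'   mean link).
#' @param nb_theta fixed NB dispersion when `recon = "nb"`.
#' @param grn_jitter_sd std. dev. of optional init jitter on `W_GRN`
#'   (0 = off, the default).
#' @return A `model_config` list.
#' @export
model_config <- function(latent_dim = 64L,
                         encoder_widths = c(512L, 256L),
                         decoder_widths = 256L,
                         alpha_start = 0, alpha_max = 0.9,
                         delta_alpha = 0.02,
                         gamma_start = 0, gamma_end = 1e-4,
                         epochs = 100L,
                         seed = 42L,
                         gene_bias = FALSE,
                         recon = c("mse", "nb"),
                         nb_theta = 10,
                         grn_jitter_sd = 0) {
  recon <- match.arg(recon)
  stopifnot(length(encoder_widths) >= 1, length(encoder_widths) <= 3,
            length(decoder_widths) >= 1, length(decoder_widths) <= 2,
            alpha_start >= 0, alpha_start <= alpha_max, alpha_max <= 1,
            delta_alpha > 0, gamma_start >= 0, gamma_end >= 0,
            epochs >= 1, latent_dim >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 alpha_start = alpha_start, alpha_max = alpha_max,
                 delta_alpha = delta_alpha,
                 gamma_start = gamma_start, gamma_end = gamma_end,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 gene_bias = isTRUE(gene_bias), recon = recon,
                 nb_theta = nb_theta, grn_jitter_sd = grn_jitter_sd),
            class = "model_config")
}

# He-initialized dense layer
init_layer <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = rep(0, n_out))
}

#' Initialize model parameters from a prior network
#'
#' `W_GRN` starts as the dense signed prior matrix (entries in
#' \{-1, 0, +1\}); encoder/decoder weights use He initialization. The
#' log-variance head starts at zero so the posterior opens at sigma = 1.
#'
#' @param cfg [model_config()].
#' @param prior [prior_network()] (fixes TF and gene dimensions).
#' @return A `grnvae_model` (untrained).
#' @export
init_model <- function(cfg, prior) {
  stopifnot(inherits(cfg, "model_config"), inherits(prior, "prior_network"))
  G <- length(prior$gene_ids); n_tf <- length(prior$tf_ids)
  d <- cfg$latent_dim
  enc <- list(); n_in <- G
  for (w in cfg$encoder_widths) {
    enc[[length(enc) + 1]] <- init_layer(n_in, w); n_in <- w
  }
  head_mu <- init_layer(n_in, d, scale = 0.01)
  head_lv <- list(W = matrix(0, n_in, d), b = rep(0, d))
  dec <- list(); n_in <- d
  for (w in cfg$decoder_widths) {
    dec[[length(dec) + 1]] <- init_layer(n_in, w); n_in <- w
  }
  head_tf <- init_layer(n_in, n_tf, scale = 0.01)
  W_grn <- as.matrix(prior$weights)
  if (cfg$grn_jitter_sd > 0)
    W_grn <- W_grn + matrix(stats::rnorm(length(W_grn),
                                         sd = cfg$grn_jitter_sd),
                            nrow(W_grn))
  params <- list(enc = enc, head_mu = head_mu, head_lv = head_lv,
                 dec = dec, head_tf = head_tf, W_grn = W_grn,
                 b_gene = if (cfg$gene_bias) rep(0, G) else NULL)
  structure(list(cfg = cfg, params = params,
                 tf_ids = prior$tf_ids, gene_ids = prior$gene_ids,
                 W_prior = as.matrix(prior$weights),
                 schema = 1L),
            class = "grnvae_model")
}

#' @export
print.grnvae_model <- function(x, ...) {
  cat(sprintf("<grnvae_model> %d genes -> [%s] -> z(%d) -> [%s] -> %d TFs\n",
              length(x$gene_ids),
              paste(x$cfg$encoder_widths, collapse = ","),
              x$cfg$latent_dim,
              paste(x$cfg$decoder_widths, collapse = ","),
              length(x$tf_ids)))
  invisible(x)
}

relu <- function(x) (x > 0) * x

#' Deterministic or sampled forward pass
#'
#' Runs a batch (or a single cell) through encoder, reparameterization,
#' decoder, ULM blending and the GRN readout:
#' `z = mu + sigma * eps`, `e_hat = (1 - alpha) e_ulm + alpha e_dec`,
#' `x_hat = e_hat \%*\% W_GRN`.
#'
#' @param model `grnvae_model`.
#' @param x expression vector (length G) or n x G matrix, log-normalized.
#' @param e_ulm matching ULM activity vector / matrix (n x TFs).
#' @param alpha blend weight in \[0, 1\].
#' @param noise `NULL` for a deterministic pass (z = mu), or a standard
#'   normal vector / n x latent_dim matrix.
#' @return A `forward_state` list with fields `mu`, `sigma`, `z`, `e_dec`,
#'   `e_hat`, `x_hat` (matrices, one row per cell) plus an internal cache.
#' @export
vae_forward <- function(model, x, e_ulm, alpha, noise = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  p <- model$params
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  E <- if (is.matrix(e_ulm)) e_ulm else matrix(e_ulm, nrow = 1)
  if (ncol(X) != length(model$gene_ids))
    stop("x has ", ncol(X), " genes; model expects ",
         length(model$gene_ids))
  if (ncol(E) != length(model$tf_ids))
    stop("e_ulm has ", ncol(E), " TFs; model expects ",
         length(model$tf_ids))
  if (nrow(E) != nrow(X)) stop("x and e_ulm row counts differ")
  n <- nrow(X)
  enc_pre <- list(); enc_act <- list(); h <- X
  for (i in seq_along(p$enc)) {
    pre <- sweep(h %*% p$enc[[i]]$W, 2, p$enc[[i]]$b, "+")
    enc_pre[[i]] <- pre
    h <- relu(pre)
    enc_act[[i]] <- h
  }
  mu <- sweep(h %*% p$head_mu$W, 2, p$head_mu$b, "+")
  lv <- sweep(h %*% p$head_lv$W, 2, p$head_lv$b, "+")
  lv <- pmax(pmin(lv, 15), -15)
  sigma <- exp(0.5 * lv)
  eps <- if (is.null(noise)) matrix(0, n, ncol(mu))
         else if (is.matrix(noise)) noise else matrix(noise, nrow = 1)
  z <- mu + sigma * eps
  dec_pre <- list(); dec_act <- list(); dh <- z
  for (i in seq_along(p$dec)) {
    pre <- sweep(dh %*% p$dec[[i]]$W, 2, p$dec[[i]]$b, "+")
    dec_pre[[i]] <- pre
    dh <- relu(pre)
    dec_act[[i]] <- dh
  }
  e_dec <- sweep(dh %*% p$head_tf$W, 2, p$head_tf$b, "+")
  e_hat <- (1 - alpha) * E + alpha * e_dec
  x_hat <- e_hat %*% p$W_grn
  if (!is.null(p$b_gene)) x_hat <- sweep(x_hat, 2, p$b_gene, "+")
  structure(list(mu = mu, sigma = sigma, z = z, e_dec = e_dec,
                 e_hat = e_hat, x_hat = x_hat,
                 cache = list(X = X, E = E, eps = eps, lv = lv,
                              enc_pre = enc_pre, enc_act = enc_act,
                              dec_pre = dec_pre, dec_act = dec_act,
                              alpha = alpha)),
            class = "forward_state")
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `-0.5 * sum(1 + log sigma^2 - mu^2 - sigma^2)`. For matrix
#' input (one distribution per row) the per-row KLs are averaged, matching
#' the per-cell mean used in the training loss.
#'
#' @param mu mean vector or matrix (rows = cells).
#' @param sigma standard deviation, same shape, strictly positive.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  kl_el <- -0.5 * (1 + 2 * log(sigma) - mu^2 - sigma^2)
  if (is.matrix(mu)) mean(rowSums(kl_el)) else sum(kl_el)
}

#' L1 sparsity penalty on GRN weights
#'
#' @param W [weighted_grn()] or numeric matrix.
#' @param gamma non-negative coefficient.
#' @return `gamma * sum(abs(W))`.
#' @export
grn_sparsity_loss <- function(W, gamma) {
  stopifnot(gamma >= 0)
  if (inherits(W, "weighted_grn")) W <- W$weights
  gamma * sum(abs(W))
}

#' Assemble the total training loss
#'
#' `recon` is the Gaussian reconstruction term (mean over cells of the
#' summed squared error; for the NB head, the mean per-cell NB negative
#' log-likelihood), `kl` the mean per-cell KL divergence, `grn_l1` the
#' sparsity penalty. Bookkeeping: `elbo = recon + kl`,
#' `total = elbo + grn_l1` (all terms are minimized penalties).
#'
#' @param state a `forward_state` from [vae_forward()].
#' @param x the input expression (vector or matrix matching the state).
#' @param W [weighted_grn()] or matrix used for the sparsity term.
#' @param gamma L1 coefficient.
#' @param recon `"mse"` or `"nb"`; `nb_theta` the NB dispersion.
#' @param nb_theta NB dispersion (ignored for `"mse"`).
#' @return A `loss_breakdown` list: `recon`, `kl`, `elbo`, `grn_l1`,
#'   `total`.
#' @export
total_loss <- function(state, x, W, gamma, recon = "mse", nb_theta = 10) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- nrow(X)
  if (recon == "mse") {
    rec <- sum((X - state$x_hat)^2) / n
  } else {
    mu <- softplus(state$x_hat)
    rec <- sum(nb_nll(X, mu, nb_theta)) / n
  }
  kl <- kl_divergence(state$mu, state$sigma)
  l1 <- grn_sparsity_loss(W, gamma)
  loss_breakdown(rec, kl, l1)
}

loss_breakdown <- function(recon, kl, grn_l1) {
  structure(list(recon = recon, kl = kl, elbo = recon + kl,
                 grn_l1 = grn_l1, total = recon + kl + grn_l1),
            class = "loss_breakdown")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

nb_nll <- function(x, mu, theta) {
  mu <- pmax(mu, 1e-8)
  -(lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
      theta * log(theta / (theta + mu)) + x * log(mu / (theta + mu)))
}

#' Step the ULM-anchor blend weight
#'
#' `alpha(t+1) = min(alpha_max, alpha(t) + delta_alpha)` — a non-decreasing
#' schedule saturating at `alpha_max`.
#'
#' @param alpha current value.
#' @param delta_alpha increment.
#' @param alpha_max ceiling.
#' @return Updated alpha.
#' @export
alpha_step <- function(alpha, delta_alpha, alpha_max) {
  min(alpha_max, alpha + delta_alpha)
}

#' Prior mask factor schedule
#'
#' Decreasing logistic `m(t) = 1 / (1 + exp((t - T/2) / (T/20)))`:
#' approximately 1 at the start of training (prior constraints enforced),
#' 0.5 at the midpoint, approximately 0 at the end (weights free to move).
#'
#' @param t epoch index in \[0, T\].
#' @param T total epoch budget (> 0).
#' @return m(t) in (0, 1).
#' @export
mask_factor <- function(t, T) {
  if (T <= 0) stop("T must be positive")
  1 / (1 + exp((t - T / 2) / (T / 20)))
}

#' Blend learned GRN weights with the prior
#'
#' `W <- m * W_prior + (1 - m) * W_t`, applied once per epoch after the
#' optimizer step; early in training (m ~ 1) this pins the GRN to the
#' prior, late (m ~ 0) it leaves learned weights untouched.
#'
#' @param W_prior prior weight matrix (or [prior_network()]).
#' @param W_t current weights (matrix or [weighted_grn()]).
#' @param m mask factor in \[0, 1\].
#' @return Blended weights, same type as `W_t`.
#' @export
blend_weights <- function(W_prior, W_t, m) {
  stopifnot(m >= 0, m <= 1)
  Wp <- if (inherits(W_prior, "prior_network")) as.matrix(W_prior$weights)
        else as.matrix(W_prior)
  if (inherits(W_t, "weighted_grn")) {
    if (!all(dim(Wp) == dim(W_t$weights))) stop("shape mismatch")
    out <- W_t
    out$weights <- m * Wp + (1 - m) * W_t$weights
    return(out)
  }
  if (!all(dim(Wp) == dim(W_t))) stop("shape mismatch")
  m * Wp + (1 - m) * W_t
}

# ---- backward pass (training internals) -------------------------------

# Analytic gradients of total_loss wrt every parameter, for one batch.
# Returns a list mirroring model$params.
vae_backward <- function(model, state, gamma) {
  p <- model$params; ca <- state$cache
  X <- ca$X; E <- ca$E; n <- nrow(X); alpha <- ca$alpha
  if (model$cfg$recon == "mse") {
    dxhat <- 2 * (state$x_hat - X) / n
  } else {
    mu <- pmax(softplus(state$x_hat), 1e-8)
    dmu <- ((model$cfg$nb_theta + X) / (model$cfg$nb_theta + mu) - X / mu) / n
    dxhat <- dmu * stats::plogis(state$x_hat)
  }
  g <- list()
  gW_grn <- crossprod(state$e_hat, dxhat) + gamma * sign(p$W_grn)
  gb_gene <- if (!is.null(p$b_gene)) colSums(dxhat) else NULL
  dehat <- dxhat %*% t(p$W_grn)
  dedec <- alpha * dehat
  dec_in <- if (length(p$dec)) ca$dec_act[[length(p$dec)]] else state$z
  g$head_tf <- list(W = crossprod(dec_in, dedec), b = colSums(dedec))
  dd <- dedec %*% t(p$head_tf$W)
  g$dec <- vector("list", length(p$dec))
  for (i in rev(seq_along(p$dec))) {
    dd <- dd * (ca$dec_pre[[i]] > 0)
    inp <- if (i == 1) state$z else ca$dec_act[[i - 1]]
    g$dec[[i]] <- list(W = crossprod(inp, dd), b = colSums(dd))
    dd <- dd %*% t(p$dec[[i]]$W)
  }
  dz <- dd
  dmu_ <- dz + state$mu / n
  dlv <- dz * ca$eps * 0.5 * state$sigma + 0.5 * (exp(ca$lv) - 1) / n
  enc_out <- if (length(p$enc)) ca$enc_act[[length(p$enc)]] else X
  g$head_mu <- list(W = crossprod(enc_out, dmu_), b = colSums(dmu_))
  g$head_lv <- list(W = crossprod(enc_out, dlv), b = colSums(dlv))
  dh <- dmu_ %*% t(p$head_mu$W) + dlv %*% t(p$head_lv$W)
  g$enc <- vector("list", length(p$enc))
  for (i in rev(seq_along(p$enc))) {
    dh <- dh * (ca$enc_pre[[i]] > 0)
    inp <- if (i == 1) X else ca$enc_act[[i - 1]]
    g$enc[[i]] <- list(W = crossprod(inp, dh), b = colSums(dh))
    dh <- dh %*% t(p$enc[[i]]$W)
  }
  # return in the exact field order of model$params
  list(enc = g$enc, head_mu = g$head_mu, head_lv = g$head_lv,
       dec = g$dec, head_tf = g$head_tf, W_grn = gW_grn,
       b_gene = gb_gene)
}

# flatten/unflatten parameter trees (used by the finite-difference check);
# NULL leaves (e.g. a disabled gene bias) are dropped on both sides
drop_nulls <- function(p) {
  if (!is.list(p)) return(p)
  p <- p[!vapply(p, is.null, logical(1))]
  lapply(p, drop_nulls)
}

flatten_params <- function(p) {
  unlist(drop_nulls(p), use.names = FALSE)
}

unflatten_params <- function(template, v) {
  template <- drop_nulls(template)
  rel <- utils::relist(v, skeleton = template)
  restore <- function(t, r) {
    if (is.matrix(t)) return(matrix(unlist(r, use.names = FALSE),
                                    nrow(t), ncol(t)))
    if (is.list(t)) return(mapply(restore, t, r, SIMPLIFY = FALSE))
    as.numeric(unlist(r, use.names = FALSE))
  }
  restore(template, rel)
}
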