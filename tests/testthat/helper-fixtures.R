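# Shared fixtures and independent oracles. Everything is generated in code
# at test time; nothing is read from disk except files the tests write.

# small two/three-type synthetic world for module-level tests
small_world <- function(seed = 1, n_cells = 300, n_types = 3) {
  ds <- simulate_dataset(sim_config(n_cells = n_cells, n_genes = 60,
                                    n_tfs = 6, n_cell_types = n_types,
                                    edges_per_tf = 12, seed = seed))
  prior <- corrupt_prior(ds, seed = seed + 1)
  fl <- filter_dataset(ds$expr, prior, filter_config(min_targets_per_tf = 5))
  list(ds = ds, prior = fl$prior, expr = fl$expr,
       lognorm = lognormalize(fl$expr))
}

# tiny fully-specified expression/prior pair for exact-value tests
toy_expr <- function() {
  m <- matrix(c(1, 0, 2,
                0, 3, 1,
                4, 1, 0,
                2, 2, 2), nrow = 4, byrow = TRUE)
  expression_matrix(m, paste0("c", 1:4), paste0("g", 1:3), "counts")
}

# independent OLS slope t-statistic via explicit normal equations
ols_t_oracle <- function(y, w, cap = 1e6) {
  X <- cbind(1, w)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  if (se == 0) return(sign(beta[2]) * cap)
  max(min(beta[2] / se, cap), -cap)
}

# exact two-sided rank-sum p-value by full enumeration of assignments
exact_wilcox_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(i) sum(r[i]))
  mu <- mean(ws)
  p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  p
}

# contingency-table clustering metrics computed from first principles
contingency_oracle <- function(cl, truth) {
  ct <- table(cl, truth)
  n <- sum(ct)
  # Rand-index path, independently of the package's choose()-based route
  same_cl <- outer(cl, cl, "==")
  same_tr <- outer(truth, truth, "==")
  up <- upper.tri(same_cl)
  a <- sum(same_cl[up] & same_tr[up])
  b <- sum(!same_cl[up] & !same_tr[up])
  exp_idx <- sum(choose(rowSums(ct), 2)) * sum(choose(colSums(ct), 2)) /
    choose(n, 2)
  max_idx <- (sum(choose(rowSums(ct), 2)) + sum(choose(colSums(ct), 2))) / 2
  ari <- (a - exp_idx) / (max_idx - exp_idx)
  # mutual information from joint frequencies
  p <- ct / n
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  nmi <- mi / ((h(rowSums(p)) + h(colSums(p))) / 2)
  list(ari = ari, nmi = nmi)
}

write_prior_table <- function(df, ext = "tsv") {
  f <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, f, sep = if (ext == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  f
}
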