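# independent oracles, deliberately coded differently from the package

# brute-force mixed-ANOVA: explicit cell-mean arithmetic, SPSS Type III
# conventions (unweighted marginal means for within effects)
oracle_mixed_anova <- function(wide, g) {
  g <- as.character(g)
  groups <- sort(unique(g))
  k <- ncol(wide); N <- nrow(wide)
  ng <- sapply(groups, function(gg) sum(g == gg))
  G <- length(groups)

  subj_mean <- apply(wide, 1, mean)
  gm <- sapply(groups, function(gg) mean(subj_mean[g == gg]))
  grand_w <- mean(subj_mean)
  ss_group <- 0
  for (j in seq_len(G)) ss_group <- ss_group + k * ng[j] * (gm[j] - grand_w)^2
  ss_subj <- 0
  for (i in seq_len(N)) ss_subj <- ss_subj + k * (subj_mean[i] - gm[match(g[i], groups)])^2
  F_group <- (ss_group / (G - 1)) / (ss_subj / (N - G))

  # within part: subtract subject means, then work with group x condition cells
  W <- wide - subj_mean %o% rep(1, k)
  cell <- matrix(0, G, k)
  for (j in seq_len(G)) for (c in seq_len(k)) cell[j, c] <- mean(W[g == groups[j], c])
  # condition effect from UNWEIGHTED mean of group cell means
  cond_u <- apply(cell, 2, mean)
  n_eff <- G^2 / sum(1 / ng)
  ss_cond <- n_eff * sum(cond_u^2)
  # interaction: weighted deviation of cells from (weighted) condition means
  cond_w <- rep(0, k)
  for (c in seq_len(k)) cond_w[c] <- sum(ng * cell[, c]) / N
  ss_int <- 0
  for (j in seq_len(G)) for (c in seq_len(k))
    ss_int <- ss_int + ng[j] * (cell[j, c] - cond_w[c])^2
  # error: residual within-subject variation around group cells
  ss_err <- 0
  for (i in seq_len(N)) for (c in seq_len(k))
    ss_err <- ss_err + (W[i, c] - cell[match(g[i], groups), c])^2
  df_c <- k - 1; df_i <- (G - 1) * (k - 1); df_e <- (N - G) * (k - 1)
  F_cond <- (ss_cond / df_c) / (ss_err / df_e)
  F_int <- (ss_int / df_i) / (ss_err / df_e)

  # epsilon from pooled within-group covariance, eigenvalue form
  Sp <- matrix(0, k, k)
  for (j in seq_len(G)) {
    Wg <- wide[g == groups[j], , drop = FALSE]
    Sp <- Sp + cov(Wg) * (nrow(Wg) - 1)
  }
  Sp <- Sp / (N - G)
  ctr <- diag(k) - matrix(1 / k, k, k)
  lam <- eigen(ctr %*% Sp %*% ctr, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-12]
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))

  list(F_group = unname(F_group), F_cond = unname(F_cond),
       F_int = unname(F_int), eps = unname(eps),
       df_group = c(G - 1, N - G), df_cond = c(df_c, df_e))
}

# dense-grid cross-correlation lag of a TR-sampled series vs a reference
oracle_xcorr_lag <- function(y, ref, tr, lag_range = c(-2, 2), dt = 0.01) {
  n <- length(y)
  t_coarse <- (seq_len(n) - 1) * tr
  lags <- seq(lag_range[1], lag_range[2], by = dt)
  score <- sapply(lags, function(L) {
    shifted <- approx(t_coarse + L, ref, xout = t_coarse, rule = 1)$y
    ok <- !is.na(shifted)
    sum(y[ok] * shifted[ok]) / sqrt(sum(y[ok]^2) * sum(shifted[ok]^2))
  })
  lags[which.max(score)]
}
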