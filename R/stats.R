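#' Greenhouse-Geisser epsilon from a within-subject covariance
#'
#' Sphericity-correction factor for k repeated measures:
#' `epsilon = tr(A)^2 / ((k - 1) * tr(A^2))` where A is the
#' double-centred covariance matrix of the condition scores (equivalently
#' the covariance projected onto any orthonormal contrast set).  Bounded
#' in [1/(k-1), 1]; equals 1 exactly under compound symmetry.
#'
#' @param within_cov k x k covariance matrix of the condition scores
#'   (pooled within groups for a mixed design).
#' @return Epsilon, a scalar.
#' @export
greenhouse_geisser_epsilon <- function(within_cov) {
  S <- as.matrix(within_cov)
  k <- nrow(S)
  stopifnot(k >= 2, ncol(S) == k)
  if (all(S == 0)) stop("zero covariance: epsilon undefined")
  J <- matrix(1 / k, k, k)
  P <- diag(k) - J
  A <- P %*% S %*% P
  lam <- sum(diag(A))
  lam2 <- sum(A * A)            # tr(A %*% A) for symmetric A
  if (lam2 == 0) stop("degenerate covariance: epsilon undefined")
  eps <- lam^2 / ((k - 1) * lam2)
  max(min(eps, 1), 1 / (k - 1))
}

# orthonormal polynomial-free contrast set (k x (k-1)), C'C = I, C'1 = 0
.orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Mixed two-group repeated-measures ANOVA
#'
#' Between-within ANOVA by direct sums-of-squares decomposition, SPSS
#' conventions: the between-subject (group) effect is tested against the
#' subjects-within-groups error; the within-subject effects (condition
#' and the group x condition interaction) against the
#' condition-by-subject-within-group error, with Type III (unweighted
#' marginal means) sums of squares so unequal group sizes are handled as
#' SPSS GLM does.  The Greenhouse-Geisser epsilon is computed from the
#' pooled within-group covariance of the condition scores and applied to
#' the within-subject tests only (the group effect has a 1-df numerator).
#'
#' Subjects with any missing cell are removed listwise (a message reports
#' the count).
#'
#' @param data Long data.frame.
#' @param value,subject,group,condition Column names in `data`.
#' @param m_bonferroni Number of test families for the Bonferroni flag
#'   (default 9, one per ROI).
#' @param alpha Family-wise alpha (default 0.05).
#' @return Object of class `rm_anova`: data.frame with one row per
#'   effect (`group`, `condition`, `group:condition`): `F`, `df1`, `df2`
#'   (uncorrected), `epsilon`, `p_uncorrected`, `p_gg` (GG-corrected for
#'   within effects, equal to `p_uncorrected` for the group effect), and
#'   `significant_bonferroni` at `alpha / m_bonferroni`.
#' @export
rm_anova <- function(data, value = "value", subject = "subject",
                     group = "group", condition = "condition",
                     m_bonferroni = 9, alpha = 0.05) {
  d <- data.frame(subject = as.character(data[[subject]]),
                  group = as.character(data[[group]]),
                  condition = as.character(data[[condition]]),
                  value = as.numeric(data[[value]]),
                  stringsAsFactors = FALSE)
  conds <- sort(unique(d$condition))
  k <- length(conds)
  stopifnot(k >= 2)
  # one group per subject
  gmap <- tapply(d$group, d$subject, function(g) unique(g))
  if (any(lengths(gmap) != 1)) stop("a subject appears in more than one group")

  wide <- tapply(d$value, list(d$subject, d$condition), mean)
  wide <- wide[, conds, drop = FALSE]
  complete <- stats::complete.cases(wide)
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped listwise (missing cells)")
  wide <- wide[complete, , drop = FALSE]
  g <- factor(unlist(gmap[rownames(wide)]))
  G <- nlevels(g); N <- nrow(wide)
  ng <- as.numeric(table(g))
  if (G < 2 || any(ng < 2)) stop("need >= 2 subjects in each of >= 2 groups")

  ## between-subject part: one-way ANOVA of the subject means, scaled by k
  s <- rowMeans(wide)
  mg <- tapply(s, g, mean)
  grand <- mean(s)                       # weighted grand mean of subjects
  ss_group <- k * sum(ng * (mg - grand)^2)
  ss_subj <- k * sum((s - mg[g])^2)
  df_g <- G - 1; df_s <- N - G
  F_group <- (ss_group / df_g) / (ss_subj / df_s)
  p_group <- stats::pf(F_group, df_g, df_s, lower.tail = FALSE)

  ## within-subject part on orthonormal contrast scores
  C <- .orth_contrasts(k)
  Z <- wide %*% C                        # N x (k-1)
  zg <- apply(Z, 2, function(z) tapply(z, g, mean))  # G x (k-1)
  zg <- matrix(zg, nrow = G)
  # Type III condition effect: unweighted mean of group means
  zu <- colMeans(zg)
  n_eff <- G^2 / sum(1 / ng)
  ss_cond <- n_eff * sum(zu^2)
  # interaction: group effect within each contrast column
  zw <- colSums(zg * ng) / N             # weighted grand mean per column
  ss_int <- sum(t(ng * sweep(zg, 2, zw)^2))
  ss_err <- sum((Z - zg[g, , drop = FALSE])^2)
  df_c <- k - 1; df_i <- (G - 1) * (k - 1); df_e <- (N - G) * (k - 1)
  ms_e <- ss_err / df_e
  F_cond <- (ss_cond / df_c) / ms_e
  F_int <- (ss_int / df_i) / ms_e

  ## pooled within-group covariance -> epsilon
  Sp <- matrix(0, k, k)
  for (lev in levels(g)) {
    W <- wide[g == lev, , drop = FALSE]
    Sp <- Sp + stats::cov(W) * (nrow(W) - 1)
  }
  Sp <- Sp / (N - G)
  eps <- greenhouse_geisser_epsilon(Sp)

  p_cond <- stats::pf(F_cond, df_c, df_e, lower.tail = FALSE)
  p_int <- stats::pf(F_int, df_i, df_e, lower.tail = FALSE)
  p_cond_gg <- stats::pf(F_cond, df_c * eps, df_e * eps, lower.tail = FALSE)
  p_int_gg <- stats::pf(F_int, df_i * eps, df_e * eps, lower.tail = FALSE)

  thr <- alpha / m_bonferroni
  out <- data.frame(
    effect = c("group", "condition", "group:condition"),
    F = c(F_group, F_cond, F_int),
    df1 = c(df_g, df_c, df_i),
    df2 = c(df_s, df_e, df_e),
    epsilon = c(NA_real_, eps, eps),
    p_uncorrected = c(p_group, p_cond, p_int),
    p_gg = c(p_group, p_cond_gg, p_int_gg),
    significant_bonferroni = c(p_group, p_cond_gg, p_int_gg) < thr,
    stringsAsFactors = FALSE)
  structure(list(table = out, n_subjects = N, n_per_group = ng,
                 k = k, epsilon = eps, alpha = alpha,
                 m_bonferroni = m_bonferroni),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA: %d subjects (%s), %d conditions\n",
              x$n_subjects, paste(x$n_per_group, collapse = " + "), x$k))
  cat(sprintf("Greenhouse-Geisser epsilon = %.4f; Bonferroni alpha = %.4f\n",
              x$epsilon, x$alpha / x$m_bonferroni))
  tb <- x$table
  tb$F <- round(tb$F, digits)
  tb$p_uncorrected <- signif(tb$p_uncorrected, digits)
  tb$p_gg <- signif(tb$p_gg, digits)
  tb$epsilon <- round(tb$epsilon, 4)
  print.data.frame(tb, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rm_anova <- function(object, ...) object$table

#' Pooled-variance two-sample t from summary statistics
#'
#' @param mean_a,sd_a,n_a Summary statistics of group a.
#' @param mean_b,sd_b,n_b Summary statistics of group b.
#' @return List: `t`, `df` (= n_a + n_b - 2), `p` (two-sided).
#' @examples
#' pooled_two_sample_t(1125, 262, 32, 714, 121, 23)  # t ~= 7.0, df 53
#' @export
pooled_two_sample_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a > 0, sd_b > 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level (0 < alpha < 1).
#' @param m Number of families (>= 1).
#' @return `alpha / m`, reported at 4 decimals.
#' @examples
#' bonferroni_threshold(0.05, 9)  # 0.0056
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  round(alpha / m, 4)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks handle ties; missing pairs are dropped pairwise.  The p
#' value uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on n - 2 degrees of freedom (p = 0 at |rho| = 1).
#'
#' @param x,y Paired numeric vectors (>= 4 complete pairs required).
#' @return List: `rho`, `p`, `n`.  `rho` is `NA` when either rank vector
#'   has zero variance.
#' @export
spearman_assoc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Run the per-ROI mixed ANOVA over a summary table
#'
#' Applies [rm_anova()] separately to every ROI for one measure and
#' binds the results, the analysis the long-format summary TSV feeds.
#'
#' @param summary_table A [roi_summary_table()]-format data.frame.
#' @param measure `"bold_magnitude"` or `"bold_latency"` (or any measure
#'   label present in the table).
#' @param ... Passed to [rm_anova()].
#' @return data.frame with columns roi, effect, F, df1, df2, epsilon,
#'   p_gg, bonferroni_significant.
#' @export
anova_by_roi <- function(summary_table, measure, ...) {
  st <- summary_table[summary_table$measure == measure, ]
  if (!nrow(st)) stop("measure '", measure, "' not present")
  out <- lapply(split(st, st$roi), function(droi) {
    a <- rm_anova(droi, ...)
    cbind(roi = droi$roi[1], a$table[, c("effect", "F", "df1", "df2",
                                         "epsilon", "p_gg")],
          bonferroni_significant = a$table$significant_bonferroni)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
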