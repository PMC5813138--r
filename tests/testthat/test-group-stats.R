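test_that("Greenhouse-Geisser epsilon obeys its closed form and bounds", {
  # compound symmetry -> exactly 1
  cs <- matrix(0.4, 3, 3); diag(cs) <- 1
  expect_equal(greenhouse_geisser_epsilon(cs), 1)
  # k = 2: sphericity is vacuous
  expect_equal(greenhouse_geisser_epsilon(matrix(c(2, 0.3, 0.3, 1), 2)), 1)
  # one dominant eigenvalue -> lower bound 1/(k-1)
  v <- c(1, 0, -1)
  expect_equal(greenhouse_geisser_epsilon(v %o% v), 0.5)
  # centred eigenvalues (2, 1) -> 9/10
  C <- contr.helmert(3)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  S <- C %*% diag(c(2, 1)) %*% t(C)
  expect_equal(greenhouse_geisser_epsilon(S), 9 / 10)
  expect_error(greenhouse_geisser_epsilon(matrix(0, 3, 3)), "zero covariance")
})

test_that("the 6-subject worked example matches the frozen brute-force values", {
  Y <- rbind(c(1, 2, 3), c(2, 3, 5), c(0, 1, 2),
             c(3, 5, 7), c(4, 4, 6), c(2, 6, 7))
  d <- data.frame(subject = rep(sprintf("s%d", 1:6), 3),
                  group = rep(rep(c("a", "b"), each = 3), 3),
                  condition = rep(c("c1", "c2", "c3"), each = 6),
                  value = as.numeric(Y))
  a <- rm_anova(d)
  tb <- a$table
  # frozen from explicit spreadsheet-style sums of squares
  expect_equal(tb$F[tb$effect == "group"], 16.4473684211, tolerance = 1e-9)
  expect_equal(tb$F[tb$effect == "condition"], 22.0909090909, tolerance = 1e-9)
  expect_equal(tb$F[tb$effect == "group:condition"], 1.1818181818,
               tolerance = 1e-9)
  expect_equal(a$epsilon, 0.6142131980, tolerance = 1e-9)
  expect_equal(tb$df1, c(1, 2, 2))
  expect_equal(tb$df2, c(4, 8, 8))
})

test_that("rm_anova equals the brute-force oracle on random small designs", {
  for (seed in 1:100) {
    set.seed(seed)
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1); N <- n1 + n2
    wide <- matrix(rnorm(N * 3), N, 3) + rnorm(N)   # subject heterogeneity
    g <- rep(c("a", "b"), c(n1, n2))
    d <- data.frame(subject = rep(sprintf("s%02d", 1:N), 3),
                    group = rep(g, 3),
                    condition = rep(c("c1", "c2", "c3"), each = N),
                    value = as.numeric(wide))
    a <- rm_anova(d)$table
    o <- oracle_mixed_anova(wide, g)
    expect_equal(a$F[1], o$F_group, tolerance = 1e-10)
    expect_equal(a$F[2], o$F_cond, tolerance = 1e-10)
    expect_equal(a$F[3], o$F_int, tolerance = 1e-10)
    expect_equal(a$epsilon[2], o$eps, tolerance = 1e-10)
  }
})

test_that("rm_anova agrees with car's SPSS-convention repeated-measures ANOVA", {
  skip_if_not_installed("car")
  set.seed(77)
  n1 <- 5; n2 <- 8; N <- n1 + n2
  wide <- matrix(rnorm(N * 3), N, 3) + rnorm(N) * 1.2 +
    outer(rep(1, N), c(0, 0.5, 1))
  g <- factor(rep(c("a", "b"), c(n1, n2)))
  d <- data.frame(subject = rep(sprintf("s%02d", 1:N), 3), group = rep(g, 3),
                  condition = rep(c("c1", "c2", "c3"), each = N),
                  value = as.numeric(wide))
  a <- rm_anova(d)$table
  df <- data.frame(g = g, wide)
  mod <- lm(cbind(X1, X2, X3) ~ g, data = df,
            contrasts = list(g = contr.sum))
  # suppressed warning: car also reports Huynh-Feldt, whose epsilon can
  # exceed 1; only the Greenhouse-Geisser part is compared here
  s <- suppressWarnings(
    summary(car::Anova(mod, idata = data.frame(condition = factor(1:3)),
                       idesign = ~condition, type = 3),
            multivariate = FALSE))
  u <- s$univariate.tests
  expect_equal(a$F[1], unname(u["g", "F value"]), tolerance = 1e-10)
  expect_equal(a$F[2], unname(u["condition", "F value"]), tolerance = 1e-10)
  expect_equal(a$F[3], unname(u["g:condition", "F value"]), tolerance = 1e-10)
  expect_equal(a$epsilon[2], unname(s$pval.adjustments["condition", "GG eps"]),
               tolerance = 1e-10)
})

test_that("group-effect degrees of freedom follow the group sizes", {
  set.seed(10)
  N <- 55
  d <- data.frame(subject = rep(sprintf("s%02d", 1:N), 3),
                  group = rep(rep(c("control", "patient"), c(23, 32)), 3),
                  condition = rep(event_conditions(), each = N),
                  value = rnorm(N * 3))
  a <- rm_anova(d)$table
  expect_equal(a$df1[a$effect == "group"], 1)
  expect_equal(a$df2[a$effect == "group"], 53)
  expect_equal(a$df2[a$effect == "condition"], 106)
})

test_that("subjects with missing cells are dropped listwise", {
  set.seed(2)
  N <- 8
  d <- data.frame(subject = rep(sprintf("s%d", 1:N), 3),
                  group = rep(rep(c("a", "b"), each = 4), 3),
                  condition = rep(c("c1", "c2", "c3"), each = N),
                  value = rnorm(N * 3))
  d <- d[!(d$subject == "s3" & d$condition == "c2"), ]
  expect_message(a <- rm_anova(d), "1 subject")
  expect_equal(a$n_subjects, 7)
  expect_equal(a$table$df2[1], 5)
})

test_that("pooled t, Bonferroni threshold and Spearman match their oracles", {
  # printed congruent RT summaries: slower patients vs controls
  r <- pooled_two_sample_t(1125, 262, 32, 714, 121, 23)
  expect_equal(round(r$t, 1), 7.0)
  expect_identical(r$df, 53)
  expect_lt(r$p, 0.001)
  expect_equal(pooled_two_sample_t(5, 1, 10, 5, 1, 10)$t, 0)
  t1 <- pooled_two_sample_t(6, 1, 12, 5, 1, 10)$t
  t2 <- pooled_two_sample_t(6, 2, 12, 5, 2, 10)$t
  expect_equal(t2, t1 / 2)

  expect_equal(bonferroni_threshold(0.05, 9), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)

  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_assoc(x, x)$rho, 1)
  expect_equal(spearman_assoc(x, -x)$rho, -1)
  expect_equal(spearman_assoc(x, x)$p, 0)
  # 5-point fixture with one tie: ranks of y are (1, 2.5, 2.5, 4, 5)
  y <- c(10, 20, 20, 30, 40)
  rho_hand <- cor(c(1, 2, 3, 4, 5), c(1, 2.5, 2.5, 4, 5))
  out <- spearman_assoc(x, y)
  expect_equal(out$rho, rho_hand)
  expect_equal(out$rho,
               unname(cor.test(x, y, method = "spearman", exact = FALSE)$estimate))
  expect_true(is.na(spearman_assoc(x, rep(1, 5))$rho))
  expect_error(spearman_assoc(1:3, 1:3), "4 complete pairs")
})

test_that("injected latency slowing is detected in task ROIs but not DMN", {
  # summary-level cohorts at the study's group sizes: patients 0.3 s later
  # in the seven task-positive regions, no group difference in the DMN
  task <- setdiff(roi_names(), c("pDMN", "fDMN"))
  n_cohorts <- 150
  thr <- bonferroni_threshold(0.05, 9)
  set.seed(314)
  hits <- matrix(FALSE, n_cohorts, 9, dimnames = list(NULL, roi_names()))
  for (b in seq_len(n_cohorts)) {
    N <- 55
    g <- rep(c("control", "patient"), c(23, 32))
    for (roi in roi_names()) {
      subj_eff <- rnorm(N, 0, 0.2)
      delta <- if (roi %in% task) 0.3 else 0
      val <- as.numeric(sapply(1:3, function(cc)
        subj_eff + (g == "patient") * delta + rnorm(N, 0, 0.15)))
      d <- data.frame(subject = rep(sprintf("s%02d", 1:N), 3),
                      group = rep(g, 3),
                      condition = rep(event_conditions(), each = N),
                      value = val)
      a <- rm_anova(d)$table
      hits[b, roi] <- a$p_gg[a$effect == "group"] < thr
    }
  }
  expect_true(all(colMeans(hits[, task]) >= 0.9))
  expect_true(all(colMeans(hits[, c("pDMN", "fDMN")]) <= 0.1))
})

test_that("anova_by_roi returns one labelled block of results per region", {
  set.seed(6)
  N <- 12
  g <- rep(c("control", "patient"), each = 6)
  tbl <- do.call(rbind, lapply(c("motor", "pDMN"), function(roi) {
    data.frame(subject = rep(sprintf("s%d", 1:N), 3), group = rep(g, 3),
               roi = roi, condition = rep(event_conditions(), each = N),
               measure = "bold_latency", value = rnorm(N * 3))
  }))
  out <- anova_by_roi(tbl, "bold_latency", m_bonferroni = 9)
  expect_identical(nrow(out), 6L)
  expect_setequal(unique(out$roi), c("motor", "pDMN"))
  expect_true(all(c("F", "epsilon", "p_gg", "bonferroni_significant")
                  %in% names(out)))
  expect_error(anova_by_roi(tbl, "nope"), "not present")
})
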