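test_that("Spearman rho matches monotone expectations and a mid-rank brute force", {
  r1 <- spearman_cor(1:4, c(10, 20, 30, 40))
  expect_equal(unname(r1$statistic), 1)
  r2 <- spearman_cor(1:4, c(40, 30, 20, 10))
  expect_equal(unname(r2$statistic), -1)
  expect_equal(r2$df, 2)

  set.seed(10)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- x + sample(0:3, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_cor(x, y)
    expect_equal(unname(got$statistic), brute_spearman(x, y),
                 tolerance = 1e-12)
    # t-approximation p on n - 2 df
    rho <- brute_spearman(x, y)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-9)
  }
  # invariance under strictly monotone transforms
  x <- rnorm(20); y <- x + rnorm(20)
  expect_equal(spearman_cor(exp(x), y^3 + 5 * y)$statistic,
               spearman_cor(x, y)$statistic)
  flagged <- spearman_cor(rep(1, 10), rnorm(10))
  expect_true(is.na(flagged$statistic))
  expect_match(flagged$options$note, "constant")
})

test_that("Mann-Whitney U counts pairs and partitions between the samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 4)          # all a < b pairs
  expect_equal(r$options$u_min, 0)
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r2$statistic), 4.5)       # = n1*n2/2 under ties
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  # U_a + U_b = n1*n2 with or without ties
  set.seed(20)
  for (i in 1:10) {
    a <- sample(1:8, 6, replace = TRUE); b <- sample(1:8, 5, replace = TRUE)
    ua <- unname(mann_whitney_u(a, b)$statistic)
    ub <- unname(mann_whitney_u(b, a)$statistic)
    expect_equal(ua + ub, length(a) * length(b))
  }
  # p invariant under strictly monotone transforms of the pooled data
  a <- rnorm(8); b <- rnorm(9) + 0.5
  expect_equal(mann_whitney_u(a, b)$p,
               mann_whitney_u(exp(a), exp(b))$p)
})

test_that("exact Mann-Whitney p equals full labeling enumeration", {
  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- rnorm(n1); b <- rnorm(n2) + runif(1, -1, 1)
    got <- mann_whitney_u(a, b)
    oracle <- enum_mwu(a, b)
    expect_equal(unname(got$statistic), oracle$u)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
    expect_equal(got$options$p_method, "exact")
    expect_gt(got$p, 0); expect_lte(got$p, 1)
  }
})

test_that("t tests match the textbook formula and flag degenerate input", {
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), 0.3)
    got <- t_test_one(x, bf = FALSE)
    tv <- mean(x) / (sd(x) / sqrt(length(x)))
    expect_equal(unname(got$statistic), tv, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(tv), length(x) - 1), tolerance = 1e-12)
  }
  z <- t_test_one(c(1, 1, 1), mu0 = 1)
  expect_equal(unname(z$statistic), 0)
  expect_equal(z$options$note, "zero variance")
  pz <- t_test_paired(c(2, 3, 4), c(1, 2, 3))
  expect_equal(pz$options$note, "zero variance")
  # paired test is the one-sample test on differences
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(t_test_paired(x, y, bf = FALSE)$statistic,
               t_test_one(x - y, bf = FALSE)$statistic)
})

test_that("the JZS Bayes factor matches an independent quadrature and known anchors", {
  # published anchor: a near-zero t in 15 controls gives BF10 of 0.263
  expect_equal(round(jzs_bayes_factor(0.088, 15), 3), 0.263)
  expect_lt(jzs_bayes_factor(0, 15), 1)
  for (t in c(-3, 0, 0.5, 2, 4)) {
    for (n in c(5, 15, 25, 60)) {
      expect_equal(jzs_bayes_factor(t, n), trapezoid_bf10(t, n),
                   tolerance = 1e-4)
    }
  }
  # monotone in |t|, symmetric in sign
  bf <- vapply(c(0, 1, 2, 3), jzs_bayes_factor, numeric(1), n = 20)
  expect_true(all(diff(bf) > 0))
  expect_equal(jzs_bayes_factor(-2.2, 18), jzs_bayes_factor(2.2, 18))
})

test_that("the 2x2 mixed ANOVA matches the sum/difference-score decomposition", {
  set.seed(23)
  for (i in 1:10) {
    m <- sample(5:12, 1)                     # balanced groups
    df <- data.frame(id = rep(sprintf("s%02d", 1:(2 * m)), 2),
                     group = rep(rep(c("g1", "g2"), each = m), 2),
                     arm = rep(c("a1", "a2"), each = 2 * m),
                     value = rnorm(4 * m, 10, 3) +
                       rep(rnorm(2 * m), 2))    # subject random effect
    got <- mixed_anova_2x2(df)
    wide <- reshape(df, idvar = c("id", "group"), timevar = "arm",
                    direction = "wide")
    d <- wide$value.a1 - wide$value.a2
    s <- wide$value.a1 + wide$value.a2
    grp <- wide$group
    t_g <- t.test(s ~ grp, var.equal = TRUE)$statistic
    t_i <- t.test(d ~ grp, var.equal = TRUE)$statistic
    N <- nrow(wide)
    sp2 <- sum(tapply(d, grp, function(v) sum((v - mean(v))^2))) / (N - 2)
    f_arm <- N * mean(d)^2 / sp2
    expect_equal(unname(got$group$statistic), unname(t_g^2),
                 tolerance = 1e-9)
    expect_equal(unname(got$interaction$statistic), unname(t_i^2),
                 tolerance = 1e-9)
    expect_equal(unname(got$arm$statistic), f_arm, tolerance = 1e-9)
    expect_equal(got$interaction$df, c(1, N - 2))
  }
})

test_that("the mixed ANOVA handles degenerate and constructed patterns", {
  df0 <- data.frame(id = rep(sprintf("s%d", 1:8), 2),
                    group = rep(rep(c("g1", "g2"), each = 4), 2),
                    arm = rep(c("a1", "a2"), each = 8),
                    value = 5)
  got <- mixed_anova_2x2(df0)
  expect_equal(unname(got$group$statistic), 0)
  expect_equal(unname(got$interaction$statistic), 0)

  # crossed arm effects with equal group means: pure interaction
  d <- 2
  base <- rnorm(8, 10, 0.1)
  dfx <- data.frame(id = rep(sprintf("s%d", 1:8), 2),
                    group = rep(rep(c("g1", "g2"), each = 4), 2),
                    arm = rep(c("a1", "a2"), each = 8),
                    value = c(base + rep(c(d, -d), each = 4) / 2,
                              base - rep(c(d, -d), each = 4) / 2))
  gx <- mixed_anova_2x2(dfx)
  expect_gt(unname(gx$interaction$statistic), 10)
  expect_lt(gx$group$p, 1.01)
  expect_lt(unname(gx$group$statistic), 1)

  expect_error(mixed_anova_2x2(df0[-1, ]), "exactly one value per arm")
})

test_that("Type III ANCOVA terms match nested-model residual comparisons", {
  set.seed(24)
  n <- 24
  df <- data.frame(cause = sample(c("congenital", "acquired"), n, TRUE),
                   ptype = sample(c("passive", "active"), n, TRUE),
                   use = rnorm(n))
  df$y <- 0.8 * df$use + 0.3 * (df$cause == "congenital") + rnorm(n, 0, 0.6)
  got <- ancova_terms(df, "y", fixed = c("cause", "ptype"),
                      covariate = "use")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  d2 <- df; d2$cause <- factor(d2$cause); d2$ptype <- factor(d2$ptype)
  full <- lm(y ~ cause + ptype + use, data = d2)
  rss <- function(m) sum(resid(m)^2)
  f_for <- function(reduced, df_term = 1) {
    ((rss(reduced) - rss(full)) / df_term) / (rss(full) / full$df.residual)
  }
  expect_equal(unname(got$cause$statistic),
               f_for(lm(y ~ ptype + use, data = d2)), tolerance = 1e-9)
  expect_equal(unname(got$ptype$statistic),
               f_for(lm(y ~ cause + use, data = d2)), tolerance = 1e-9)
  expect_equal(unname(got$use$statistic),
               f_for(lm(y ~ cause + ptype, data = d2)), tolerance = 1e-9)
  expect_equal(got$use$df, c(1, n - 4))

  # a response exactly linear in the covariate with pure-noise factors
  df$y2 <- 2 * df$use + rnorm(n, 0, 0.4)
  got2 <- ancova_terms(df, "y2", fixed = c("cause", "ptype"),
                       covariate = "use")
  expect_lt(got2$use$p, 0.01)
  expect_error(ancova_terms(data.frame(a = c("x", "x", "x"), y = 1:3),
                            "y", fixed = "a"), "empty cell")
})

test_that("the ANCOVA covariate term has power at a 40%-variance slope", {
  set.seed(25)
  hits <- 0
  for (i in 1:200) {
    n <- 24
    use <- rnorm(n)
    y <- use + rnorm(n, 0, sqrt(1.5))   # slope explains ~40% of variance
    d <- data.frame(use = use, y = y,
                    cause = sample(c("c", "a"), n, TRUE),
                    ptype = sample(c("p", "m"), n, TRUE))
    r <- ancova_terms(d, "y", fixed = c("cause", "ptype"),
                      covariate = "use")
    hits <- hits + (r$use$p < 0.05)
  }
  expect_gt(hits / 200, 0.9)
})

test_that("the MAD outlier rule flags gross outliers and little else", {
  expect_identical(outlier_flags(c(0, 0, 0, 0, 10)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(outlier_flags(rep(3.2, 6)), rep(FALSE, 6))
  expect_error(outlier_flags(1:3), ">= 5")
  set.seed(26)
  flags <- replicate(400, mean(outlier_flags(rnorm(100))))
  expect_lt(mean(flags), 0.01)
})
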