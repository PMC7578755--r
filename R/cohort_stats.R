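#' Construct a statistical test result
#'
#' Light container used by every test in the battery: the statistic, its
#' degrees of freedom, the p value, the effect direction, an optional JZS
#' Bayes factor, sample sizes and the options that produced it.
#'
#' @param test Test name.
#' @param statistic Named scalar (e.g. `c(U = 47)`).
#' @param df Degrees of freedom (scalar or pair), or `NULL`.
#' @param p Two-sided p value.
#' @param direction Signed effect direction or estimate, or `NA`.
#' @param bf10 JZS Bayes factor in favour of the alternative, or `NA`.
#' @param n Sample size(s).
#' @param options Named list of options used (exact vs approximate, tie
#'   handling, prior scale, exclusions).
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, df = NULL, p = NA_real_,
                        direction = NA_real_, bf10 = NA_real_, n = NULL,
                        options = list()) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p value outside [0, 1]")
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 direction = direction, bf10 = bf10, n = n,
                 options = options),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, digits = 4, ...) {
  dfs <- if (is.null(x$df)) "" else
    paste0("(", paste(format(x$df, digits = digits), collapse = ","), ")")
  cat(sprintf("%s: %s%s = %s, p = %s", x$test, names(x$statistic)[1], dfs,
              format(x$statistic[[1]], digits = digits),
              format.pval(x$p, digits = digits)))
  if (!is.na(x$bf10)) cat(sprintf(", BF10 = %s", format(x$bf10, digits = digits)))
  cat("\n")
  opts <- x$options[!vapply(x$options, is.null, logical(1))]
  if (length(opts))
    cat("  options:", paste(names(opts), vapply(opts, function(v)
      paste(format(v), collapse = ","), character(1)), sep = "=",
      collapse = "; "), "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks; the two-sided p value comes
#' from the t approximation on n - 2 degrees of freedom, or (optionally, no
#' ties, n <= 10) from the exact permutation distribution.
#'
#' @param x,y Paired numeric vectors, n >= 4; ties allowed.
#' @param exact Use the exact permutation null (only without ties and
#'   n <= 10).
#' @return A [stat_result()] with statistic `rho` and df `n - 2`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("Spearman correlation needs n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(stat_result("spearman", c(rho = NA_real_), df = n - 2, p = NA_real_,
                       n = n, options = list(note = "constant input")))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  use_exact <- exact && !ties && n <= 10
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = use_exact))
  stat_result("spearman", c(rho = unname(ct$estimate)), df = n - 2,
              p = ct$p.value, direction = sign(unname(ct$estimate)), n = n,
              options = list(p_method = if (use_exact) "exact permutation"
                             else "t approximation", ties = ties))
}

#' Mann-Whitney U test
#'
#' `U` is the number of pairs with `a_i < b_j`, plus half the tied pairs,
#' reported for the first sample (`u_min`, the min-U convention, is included
#' in the options). The p value is exact (from the null Wilcoxon
#' distribution) whenever there are no ties and `n1 * n2 <= exact_limit`;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Numeric samples, each non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact p; default
#'   `NULL` decides by feasibility.
#' @param exact_limit Largest `n1 * n2` for which the exact null is used
#'   (default 400).
#' @return A [stat_result()] with statistic `U`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL, exact_limit = 400) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  cmp <- outer(a, b, "<")
  eq <- outer(a, b, "==")
  u <- sum(cmp) + 0.5 * sum(eq)
  ties <- any(duplicated(c(a, b)))
  use_exact <- if (is.null(exact)) !ties && n1 * n2 <= exact_limit else exact
  if (use_exact && ties)
    stop("exact Mann-Whitney p unavailable with ties")
  if (use_exact) {
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        1 - stats::pwilcox(u - 1, n1, n2)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(a, b))
    N <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie and continuity corrected"
  }
  stat_result("mann_whitney", c(U = u), p = p,
              direction = sign(u - n1 * n2 / 2), n = c(n1 = n1, n2 = n2),
              options = list(p_method = method, ties = ties,
                             u_min = min(u, n1 * n2 - u)))
}

#' One-sample and paired t tests
#'
#' Two-sided Student t tests against `mu0`, with an optional default JZS
#' Bayes factor. `t_test_paired(x, y)` is the one-sample test on `x - y`.
#'
#' @param x Numeric sample (or first member of each pair).
#' @param mu0 Null value (default 0).
#' @param bf Attach the JZS Bayes factor (default `TRUE`).
#' @param r_scale Cauchy prior scale for the Bayes factor (default 0.707).
#' @return A [stat_result()] with statistic `t`, df `n - 1`, and the sample
#'   mean (minus `mu0`) as `direction`.
#' @export
t_test_one <- function(x, mu0 = 0, bf = TRUE, r_scale = sqrt(2) / 2) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("t test needs n >= 2")
  if (stats::sd(x) == 0) {
    tv <- if (mean(x) == mu0) 0 else NA_real_
    return(stat_result("t_one_sample", c(t = tv), df = n - 1, p = NA_real_,
                       direction = mean(x) - mu0, n = n,
                       options = list(note = "zero variance")))
  }
  tt <- stats::t.test(x, mu = mu0)
  tv <- unname(tt$statistic)
  stat_result("t_one_sample", c(t = tv), df = n - 1, p = tt$p.value,
              direction = mean(x) - mu0,
              bf10 = if (bf) jzs_bayes_factor(tv, n, r_scale) else NA_real_,
              n = n, options = list(r_scale = if (bf) r_scale else NULL))
}

#' @rdname t_test_one
#' @param y Second member of each pair.
#' @export
t_test_paired <- function(x, y, mu0 = 0, bf = TRUE, r_scale = sqrt(2) / 2) {
  ok <- stats::complete.cases(x, y)
  res <- t_test_one(x[ok] - y[ok], mu0 = mu0, bf = bf, r_scale = r_scale)
  res$test <- "t_paired"
  res
}

#' Default JZS Bayes factor for a one-sample or paired t test
#'
#' Evidence in favour of a nonzero standardized effect under a Cauchy prior
#' of scale `r_scale` (Zellner-Siow / unit-information family), computed by
#' numerical integration over the prior's mixing parameter:
#' \deqn{BF_{10} = \frac{\int_0^\infty (1 + N g r^2)^{-1/2}
#'   \left(1 + \frac{t^2}{(1 + N g r^2)\,\nu}\right)^{-(\nu+1)/2}
#'   (2\pi)^{-1/2} g^{-3/2} e^{-1/(2g)}\, dg}
#'   {\left(1 + t^2/\nu\right)^{-(\nu+1)/2}}}
#' with \eqn{\nu = N - 1}. Values below 1 favour the null.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs for a paired design).
#' @param r_scale Cauchy prior scale (default `sqrt(2)/2`, about 0.707).
#' @param rel_tol Relative integration tolerance (default 1e-6).
#' @return `BF10 > 0`.
#' @export
jzs_bayes_factor <- function(t, n, r_scale = sqrt(2) / 2, rel_tol = 1e-6) {
  stopifnot(is.finite(t), n >= 2, r_scale > 0)
  nu <- n - 1
  integrand <- function(g)
    (1 + n * g * r_scale^2)^(-0.5) *
    (1 + t^2 / ((1 + n * g * r_scale^2) * nu))^(-(nu + 1) / 2) *
    (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  num <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                     subdivisions = 500L),
    error = function(e) stop("JZS quadrature failed to converge: ",
                             conditionMessage(e)))
  num$value / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

#' 2x2 mixed (repeated-measures) ANOVA
#'
#' One between-subjects factor (group, 2 levels) and one within-subjects
#' factor (arm, 2 levels), every participant contributing both within
#' levels. F statistics carry (1, N - 2) degrees of freedom.
#'
#' @param df Long data.frame with columns `id`, `group`, `arm`, `value`.
#' @return Named list of [stat_result()]s: `group`, `arm`, `interaction`.
#' @export
mixed_anova_2x2 <- function(df) {
  need <- c("id", "group", "arm", "value")
  stopifnot(all(need %in% names(df)))
  df$id <- factor(df$id); df$group <- factor(df$group)
  df$arm <- factor(df$arm)
  if (nlevels(df$group) != 2 || nlevels(df$arm) != 2)
    stop("both factors must have exactly 2 levels")
  counts <- table(df$id, df$arm)
  if (any(counts != 1))
    stop("every participant needs exactly one value per arm level")
  if (any(table(unique(df[c("id", "group")])$group) < 2))
    stop("need >= 2 participants per group")
  fit <- stats::aov(value ~ group * arm + Error(id), data = df)
  sm <- summary(fit)
  btab <- sm[["Error: id"]][[1]]
  wtab <- sm[["Error: Within"]][[1]]
  grab <- function(tab, term, name) {
    i <- trimws(rownames(tab)) == term
    f <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
    if (is.nan(f)) { f <- 0; p <- 1 }   # constant data: no variance anywhere
    stat_result(paste0("rm_anova_", name), c(F = f),
                df = c(tab[i, "Df"], tab[nrow(tab), "Df"]), p = p,
                n = nlevels(df$id))
  }
  list(group = grab(btab, "group", "group"),
       arm = grab(wtab, "arm", "arm"),
       interaction = grab(wtab, "group:arm", "interaction"))
}

#' ANCOVA with fixed factors and a covariate (Type III)
#'
#' Additive linear model of the response on the fixed factors and covariate,
#' with sum-to-zero contrasts and Type III sums of squares, as used to test
#' whether the laterality-use relationship survives adjustment for cause of
#' limb loss and prosthesis type.
#'
#' @param df Data.frame containing the model variables.
#' @param response Response column name.
#' @param fixed Character vector of factor column names.
#' @param covariate Covariate column name (or `NULL`).
#' @return Named list of [stat_result()]s, one per model term, each with
#'   `(term df, residual df)`.
#' @export
ancova_terms <- function(df, response, fixed, covariate = NULL) {
  vars <- c(fixed, covariate)
  df <- df[stats::complete.cases(df[, c(response, vars)]), , drop = FALSE]
  for (f in fixed) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2)
      stop("factor '", f, "' has an empty cell after exclusions")
  }
  form <- stats::reformulate(vars, response = response)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient ANCOVA design")
  tab <- car::Anova(fit, type = 3)
  res_df <- tab["Residuals", "Df"]
  terms <- setdiff(rownames(tab), c("(Intercept)", "Residuals"))
  out <- lapply(terms, function(tm)
    stat_result(paste0("ancova_", tm), c(F = tab[tm, "F value"]),
                df = c(tab[tm, "Df"], res_df), p = tab[tm, "Pr(>F)"],
                n = nrow(df), options = list(ss_type = "III")))
  stats::setNames(out, terms)
}

#' Outlier flags for parametric analyses
#'
#' Default rule: flag values more than `k` scaled median absolute deviations
#' from the median. Flags are advisory: parametric analyses exclude flagged
#' rows, nonparametric analyses keep everything, and every exclusion is
#' reported with its rule and value rather than silently dropped.
#'
#' @param values Numeric vector, length >= 5.
#' @param k MAD multiplier (default 3).
#' @return Logical vector of flags.
#' @export
outlier_flags <- function(values, k = 3) {
  stopifnot(length(values) >= 5)
  med <- stats::median(values, na.rm = TRUE)
  s <- stats::mad(values, na.rm = TRUE)
  flag <- abs(values - med) > k * s
  flag & !is.na(flag)
}
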