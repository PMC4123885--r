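#' Log-transform count data
#'
#' Natural-log transform applied to microwear counts before parametric
#' analysis, to stabilise variances.  Counts of zero occur (e.g. no large
#' pits in a field), so an offset is added before taking logs; the offset
#' defaults to 1 and is configurable so strictly positive data can be
#' analysed with offset 0.
#'
#' @param x non-negative numeric vector.
#' @param offset non-negative constant added before the log (default 1).
#' @return `log(x + offset)`.
#' @export
log_transform <- function(x, offset = 1) {
  stopifnot(length(offset) == 1, offset >= 0)
  if (any(!is.na(x) & x < 0)) stop("log_transform expects non-negative values")
  if (offset == 0 && any(!is.na(x) & x == 0)) {
    stop("offset 0 requires strictly positive values")
  }
  log(x + offset)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within decomposition,
#' `F = MSB/MSW`, upper-tail p from the F distribution), computed through
#' [stats::aov()].  Returns the pieces downstream procedures need: group
#' means, the pooled within-group mean square, and residuals for
#' homoscedasticity plots.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`; at least two
#'   groups, and at least one group with two or more values so the
#'   within-group degrees of freedom are positive.
#' @return an object of class `anova_fit`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `group_n`, `mse_within`, `ss_between`,
#'   `ss_within`, `residuals`.
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) stop("one_way_anova needs at least two groups")
  if (length(values) - nlevels(groups) < 1) {
    stop("no within-group degrees of freedom: every group has a single value")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ssb <- tab[["Sum Sq"]][1]
  ssw <- tab[["Sum Sq"]][2]
  if (ssw == 0 && ssb == 0) {
    stop("F undefined: zero variance both between and within groups")
  }
  msw <- tab[["Mean Sq"]][2]
  f <- if (ssw == 0) Inf else tab[["F value"]][1]
  p <- if (ssw == 0) 0 else tab[["Pr(>F)"]][1]
  structure(list(
    F = f,
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p = p,
    group_means = stats::setNames(as.numeric(tapply(values, groups, mean)),
                                  levels(groups)),
    group_n = as.integer(table(groups)),
    mse_within = msw,
    ss_between = ssb,
    ss_within = ssw,
    residuals = stats::residuals(fit)
  ), class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Fisher LSD post-hoc comparisons
#'
#' Least-significant-difference pairwise tests following a one-way ANOVA:
#' for each group pair, `t = (mean_a - mean_b) / sqrt(MSW (1/n_a + 1/n_b))`
#' with the ANOVA's pooled within-group mean square and degrees of freedom,
#' two-sided p.  By definition LSD applies no multiple-testing correction;
#' interpret the grid accordingly.
#'
#' @inheritParams one_way_anova
#' @return an object of class `lsd_table`: list with symmetric matrices `p`
#'   and `t` (rows/columns are groups, diagonal `NA`), plus `mse_within` and
#'   `df_within` used for all pairs.
#' @export
lsd_posthoc <- function(values, groups) {
  fit <- one_way_anova(values, groups)
  m <- fit$group_means
  n <- fit$group_n
  g <- length(m)
  tmat <- pmat <- matrix(NA_real_, g, g, dimnames = list(names(m), names(m)))
  for (a in seq_len(g - 1)) {
    for (b in (a + 1):g) {
      se <- sqrt(fit$mse_within * (1 / n[a] + 1 / n[b]))
      t_ab <- (m[a] - m[b]) / se
      p_ab <- 2 * stats::pt(-abs(t_ab), df = fit$df_within)
      tmat[a, b] <- t_ab
      tmat[b, a] <- -t_ab
      pmat[a, b] <- pmat[b, a] <- p_ab
    }
  }
  structure(list(p = pmat, t = tmat, mse_within = fit$mse_within,
                 df_within = fit$df_within, group_means = m),
            class = "lsd_table")
}

#' @export
print.lsd_table <- function(x, ...) {
  cat("Fisher LSD pairwise p-values (uncorrected), within df =",
      x$df_within, "\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Independent-samples t-test with pooled variance for exactly two groups
#' (via [stats::t.test()] with `var.equal = TRUE`).  The statistic is
#' computed as first group minus second, groups ordered by sorted label;
#' its square equals the two-group one-way ANOVA F on the same data.
#'
#' @inheritParams one_way_anova
#' @return list with `t`, `df`, `p`, `group_means`.
#' @export
two_sample_t <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) != 2) stop("two_sample_t needs exactly two groups")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       group_means = stats::setNames(c(mean(a), mean(b)), levels(groups)))
}

#' Shapiro-Wilk normality diagnostic
#'
#' Thin wrapper around [stats::shapiro.test()], reported as a diagnostic
#' alongside residual plots; it is never used as an automated gate on the
#' downstream parametric analyses.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("normality_check needs at least 3 values")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}
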