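#' Nested (hierarchical) analysis of variance
#'
#' Two-factor nested ANOVA with hierarchical sums of squares: the nested
#' factor is re-coded as `outer:nested` so every nested level sits inside
#' exactly one outer level, the decomposition is taken from
#' [stats::aov()]`(y ~ outer / nested)`, the outer factor is tested over
#' the nested-within-outer mean square and the nested factor over the
#' residual.  Used here with total pit and scratch counts as the response
#' and feature class nested within diet (or within lineage).
#'
#' @param values numeric response.
#' @param outer outer-factor labels (e.g. diet guild or lineage).
#' @param nested nested-factor labels (e.g. feature class counted).
#' @return an object of class `nested_anova_fit`: list with per-stratum
#'   `ss`, `df`, `ms`, `F` and `p` for `outer` and `nested`, plus
#'   `residual` df/ss and `ss_total`.
#' @export
nested_anova <- function(values, outer, nested) {
  keep <- !is.na(values) & !is.na(outer) & !is.na(nested)
  values <- values[keep]
  outer <- factor(as.character(outer[keep]))
  nested <- factor(paste(as.character(outer), as.character(nested[keep]),
                         sep = ":"))
  if (nlevels(outer) < 2) stop("nested_anova needs >= 2 outer levels")
  df_res <- length(values) - nlevels(nested)
  if (df_res < 1) {
    stop("insufficient replication: no residual degrees of freedom")
  }
  df_nested <- nlevels(nested) - nlevels(outer)
  if (df_nested < 1) {
    stop("nested factor adds no levels within the outer factor")
  }
  fit <- stats::aov(values ~ outer + nested)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  df <- tab[["Df"]]
  # strata: outer, nested-within-outer, residual
  ms_outer <- ss[1] / df[1]
  ms_nested <- ss[2] / df[2]
  ms_res <- ss[3] / df[3]
  f_outer <- ms_outer / ms_nested
  f_nested <- ms_nested / ms_res
  structure(list(
    outer = list(ss = ss[1], df = df[1], ms = ms_outer, F = f_outer,
                 p = stats::pf(f_outer, df[1], df[2], lower.tail = FALSE)),
    nested = list(ss = ss[2], df = df[2], ms = ms_nested, F = f_nested,
                  p = stats::pf(f_nested, df[2], df[3], lower.tail = FALSE)),
    residual = list(ss = ss[3], df = df[3], ms = ms_res),
    ss_total = sum(ss)
  ), class = "nested_anova_fit")
}

#' @export
print.nested_anova_fit <- function(x, ...) {
  cat(sprintf("nested ANOVA\n  outer:  F(%d, %d) = %.4g, p = %.4g\n",
              x$outer$df, x$nested$df, x$outer$F, x$outer$p))
  cat(sprintf("  nested: F(%d, %d) = %.4g, p = %.4g\n",
              x$nested$df, x$residual$df, x$nested$F, x$nested$p))
  invisible(x)
}
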