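#' Canonical linear discriminant analysis
#'
#' Fits canonical LDA from scratch: solves the generalized eigenproblem of
#' the between-group scatter against the pooled within-group scatter via a
#' Cholesky whitening of the within matrix, yielding `min(p, g - 1)`
#' canonical functions whose scores have unit pooled within-group variance.
#' Reports eigenvalues, percent variance, the structure matrix (pooled
#' within-group correlations of features with canonical scores), Wilks'
#' Lambda with Bartlett's chi-square approximation, and the classification
#' machinery used for post-hoc and leave-one-out evaluation.
#'
#' Sign convention: each function is oriented so its largest-magnitude
#' structure coefficient is positive (signs are otherwise arbitrary).
#'
#' @param x numeric matrix or data frame, rows are items, columns features
#'   (here typically the log-transformed per-specimen mean counts of fine
#'   scratches, coarse scratches, small pits and large pits).
#' @param groups group labels, one per row of `x`; every group needs at
#'   least two items.
#' @param priors `"equal"` (default, the convention assumed throughout the
#'   diet analyses), `"proportional"` to group sizes, or a named numeric
#'   vector summing to 1.
#' @return an object of class `canonical_lda` with elements
#'   `group_labels`, `feature_names`, `group_means`, `grand_mean`,
#'   `pooled_within_cov`, `coefficients` (features x functions, applied to
#'   grand-mean-centred data), `eigenvalues`, `percent_variance`,
#'   `structure_matrix`, `wilks_lambda`, `chi_square`, `df`, `p`, `priors`,
#'   `n`.
#' @seealso [classify_lda()], [loo_classification()], [wilks_test()]
#' @export
fit_canonical_lda <- function(x, groups, priors = "equal") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  groups <- factor(as.character(groups))
  if (nrow(x) != length(groups)) stop("x and groups lengths differ")
  if (anyNA(x)) stop("x must not contain missing values")
  g <- nlevels(groups)
  p <- ncol(x)
  n <- nrow(x)
  if (g < 2) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) of size 1 cannot contribute within-group scatter: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (n <= p + g) {
    stop("too few items (n = ", n, ") for ", p, " features and ", g,
         " groups")
  }

  means <- rowsum(x, groups) / as.vector(sizes)
  grand <- colMeans(x)
  centred <- x - means[as.integer(groups), , drop = FALSE]
  sw <- crossprod(centred)                       # within-group SS matrix
  md <- sweep(means, 2, grand)
  sb <- crossprod(md * sqrt(as.vector(sizes)))   # between-group SS matrix

  ch <- tryCatch(chol(sw), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) *
                         max(diag(ch)))) {
    qr_sw <- qr(sw)
    dep <- colnames(x)[qr_sw$pivot[-seq_len(qr_sw$rank)]]
    stop("pooled within-group scatter is singular; collinear or constant ",
         "feature(s): ",
         paste(if (length(dep)) dep else colnames(x), collapse = ", "))
  }
  ri <- backsolve(ch, diag(p))                   # R^{-1}, sw = R'R
  eg <- eigen(crossprod(ri, sb %*% ri), symmetric = TRUE)
  m <- min(p, g - 1)
  lambda <- pmax(eg$values[seq_len(m)], 0)
  v <- ri %*% eg$vectors[, seq_len(m), drop = FALSE]
  # unit pooled within-group variance of scores: v' (sw/(n-g)) v = I
  v <- v * sqrt(n - g)
  dimnames(v) <- list(colnames(x), paste0("LD", seq_len(m)))

  pooled_cov <- sw / (n - g)
  # structure matrix: pooled within-group feature/score correlations
  struct <- (sw %*% v) / (n - g) / sqrt(diag(pooled_cov))
  flip <- apply(struct, 2, function(s) sign(s[which.max(abs(s))]))
  flip[flip == 0] <- 1
  v <- sweep(v, 2, flip, "*")
  struct <- sweep(struct, 2, flip, "*")

  priors <- .resolve_priors(priors, sizes)
  wilks <- prod(1 / (1 + lambda))
  chi_sq <- -(n - 1 - (p + g) / 2) * log(wilks)
  df <- p * (g - 1)

  structure(list(
    group_labels = levels(groups),
    feature_names = colnames(x),
    group_means = means,
    grand_mean = grand,
    pooled_within_cov = pooled_cov,
    coefficients = v,
    eigenvalues = lambda,
    percent_variance = if (sum(lambda) > 0) 100 * lambda / sum(lambda)
                       else rep(0, m),
    structure_matrix = struct,
    wilks_lambda = wilks,
    chi_square = chi_sq,
    df = df,
    p = stats::pchisq(chi_sq, df, lower.tail = FALSE),
    priors = priors,
    n = n,
    group_n = as.vector(sizes)
  ), class = "canonical_lda")
}

.resolve_priors <- function(priors, sizes) {
  g <- length(sizes)
  if (is.character(priors)) {
    priors <- match.arg(priors, c("equal", "proportional"))
    pr <- if (priors == "equal") rep(1 / g, g) else as.vector(sizes) / sum(sizes)
  } else {
    pr <- as.numeric(priors[names(sizes)])
    if (anyNA(pr) || abs(sum(pr) - 1) > 1e-8) {
      stop("numeric priors must be named by group and sum to 1")
    }
  }
  stats::setNames(pr, names(sizes))
}

#' @export
print.canonical_lda <- function(x, ...) {
  cat(sprintf(
    "canonical LDA: %d groups, %d features, n = %d\n",
    length(x$group_labels), length(x$feature_names), x$n))
  cat(sprintf("  Wilks' Lambda = %.4g, chi-square = %.4g, df = %d, p = %.4g\n",
              x$wilks_lambda, x$chi_square, x$df, x$p))
  pv <- paste(sprintf("%.1f%%", x$percent_variance), collapse = ", ")
  cat("  percent variance by function: ", pv, "\n", sep = "")
  invisible(x)
}

#' Canonical scores
#'
#' Projects items onto the canonical functions (grand-mean-centred linear
#' combinations), e.g. for ordination plots of the dietary space.
#'
#' @param model a fitted `canonical_lda`.
#' @param x items to project; defaults would be the training data, which
#'   the model does not retain, so `x` is required.
#' @return matrix of scores, one column per canonical function.
#' @export
canonical_scores <- function(model, x) {
  x <- .check_feature_matrix(model, x)
  sweep(x, 2, model$grand_mean) %*% model$coefficients
}

.check_feature_matrix <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names)) {
    stop("expected ", length(model$feature_names), " features (",
         paste(model$feature_names, collapse = ", "), "), got ", ncol(x))
  }
  if (!is.null(colnames(x)) &&
      all(model$feature_names %in% colnames(x))) {
    x <- x[, model$feature_names, drop = FALSE]
  }
  storage.mode(x) <- "double"
  x
}

#' Classify items with a fitted canonical LDA
#'
#' Linear (Fisher) classification: per-group scores from the group means and
#' pooled within-group covariance plus the log prior; the predicted label is
#' the argmax, with exact ties broken deterministically in favour of the
#' first group label in the model's ordering.  Posteriors are the softmax of
#' the scores.
#'
#' @param model a fitted `canonical_lda`.
#' @param x a feature vector or matrix of items.
#' @return list with `label` (character vector) and `posterior` (items x
#'   groups matrix, rows summing to 1).
#' @export
classify_lda <- function(model, x) {
  x <- .check_feature_matrix(model, x)
  si <- chol2inv(chol(model$pooled_within_cov))
  mu <- model$group_means
  const <- -0.5 * rowSums((mu %*% si) * mu) + log(model$priors)
  scores <- x %*% si %*% t(mu) + rep(const, each = nrow(x))
  colnames(scores) <- model$group_labels
  shifted <- scores - apply(scores, 1, max)
  post <- exp(shifted) / rowSums(exp(shifted))
  label <- model$group_labels[apply(scores, 1, which.max)]
  list(label = label, posterior = post)
}

#' Wilks' Lambda significance test
#'
#' Recomputes Wilks' Lambda from the model's eigenvalues (`prod 1/(1 +
#' lambda_i)` over all retained functions) and Bartlett's chi-square
#' approximation `-(n - 1 - (p + g)/2) log(Lambda)` on `p (g - 1)` degrees
#' of freedom.
#'
#' @param model a fitted `canonical_lda`.
#' @param n the total number of items used in the fit; must match.
#' @return list with `lambda`, `chi_square`, `df`, `p`.
#' @export
wilks_test <- function(model, n = model$n) {
  if (n != model$n) {
    stop("n = ", n, " does not match the fitted model (n = ", model$n, ")")
  }
  p <- length(model$feature_names)
  g <- length(model$group_labels)
  lambda <- prod(1 / (1 + model$eigenvalues))
  chi_sq <- -(n - 1 - (p + g) / 2) * log(lambda)
  df <- p * (g - 1)
  list(lambda = lambda, chi_square = chi_sq, df = df,
       p = stats::pchisq(chi_sq, df, lower.tail = FALSE))
}

#' Leave-one-out classification
#'
#' Post-hoc leave-one-out evaluation: each item is classified by a model
#' refitted on the remaining `n - 1` items (naive full refits, no
#' shortcut), summarised as percent correct and a true-by-predicted
#' confusion matrix.
#'
#' @inheritParams fit_canonical_lda
#' @return an object of class `classification_report`: list with
#'   `predicted`, `confusion_matrix`, `percent_correct`, `per_group_recall`.
#' @export
loo_classification <- function(x, groups, priors = "equal") {
  x <- as.matrix(x)
  groups <- factor(as.character(groups))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("leave-one-out needs every group size >= 2; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  n <- nrow(x)
  predicted <- character(n)
  for (i in seq_len(n)) {
    fold <- tryCatch(
      fit_canonical_lda(x[-i, , drop = FALSE], groups[-i], priors = priors),
      error = function(e) {
        stop("leave-one-out refit failed at held-out item ", i, ": ",
             conditionMessage(e))
      })
    predicted[i] <- classify_lda(fold, x[i, , drop = FALSE])$label
  }
  classification_report(as.character(groups), predicted,
                        labels = levels(groups))
}

#' Build a classification report
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param labels label universe for the confusion matrix axes.
#' @return list with `predicted`, `confusion_matrix` (true rows, predicted
#'   columns), `percent_correct` (0-100) and `per_group_recall`.
#' @export
classification_report <- function(truth, predicted,
                                  labels = sort(unique(c(truth, predicted)))) {
  truth <- factor(truth, levels = labels)
  predicted <- factor(predicted, levels = labels)
  cm <- table(true = truth, predicted = predicted)
  structure(list(
    predicted = as.character(predicted),
    confusion_matrix = cm,
    percent_correct = 100 * sum(diag(cm)) / sum(cm),
    per_group_recall = diag(cm) / rowSums(cm)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification: %.1f%% correct\n", x$percent_correct))
  print(x$confusion_matrix)
  invisible(x)
}

#' Serialize a canonical LDA model to JSON
#'
#' Writes the full model (matrices row-major with named axes) so fitted
#' models can be archived or consumed outside R.
#'
#' @param model a fitted `canonical_lda`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lda_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
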