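random_problem <- function(seed, n_per = 8, p = 3, g = 3, sep = 2) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(g), function(k) {
    matrix(rnorm(n_per * p, mean = k * sep), n_per, p)
  }))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, groups = rep(letters[seq_len(g)], each = n_per))
}

test_that("Wilks' Lambda agrees with the determinant-ratio oracle", {
  for (seed in 1:8) {
    d <- random_problem(seed)
    m <- fit_canonical_lda(d$x, d$groups)
    # oracle: det(W)/det(T) from raw scatter matrices
    gm <- rowsum(d$x, d$groups) / as.vector(table(d$groups))
    sw <- crossprod(d$x - gm[d$groups, , drop = FALSE])
    st <- crossprod(sweep(d$x, 2, colMeans(d$x)))
    expect_equal(m$wilks_lambda, det(sw) / det(st), tolerance = 1e-9)
    expect_true(m$wilks_lambda > 0 && m$wilks_lambda <= 1)
  }
})

test_that("eigenstructure invariants hold", {
  d <- random_problem(4, p = 4, g = 3)
  m <- fit_canonical_lda(d$x, d$groups)
  expect_equal(length(m$eigenvalues), min(4, 3 - 1))
  expect_true(all(diff(m$eigenvalues) <= 1e-9))       # non-increasing
  expect_equal(sum(m$percent_variance), 100, tolerance = 1e-9)
  expect_equal(m$wilks_lambda, prod(1 / (1 + m$eigenvalues)),
               tolerance = 1e-12)
  # canonical scores have unit pooled within-group variance
  sc <- canonical_scores(m, d$x)
  pooled <- Reduce(`+`, lapply(split(as.data.frame(sc), d$groups),
                               function(s) crossprod(scale(s, scale = FALSE))))
  expect_equal(diag(pooled / (nrow(d$x) - 3)), c(LD1 = 1, LD2 = 1),
               tolerance = 1e-9)
  # two well-separated univariate groups: a single function carries all
  d2 <- list(x = cbind(f1 = c(rnorm(10), rnorm(10, 20))),
             groups = rep(c("a", "b"), each = 10))
  m2 <- fit_canonical_lda(d2$x, d2$groups)
  expect_equal(length(m2$eigenvalues), 1)
  expect_equal(m2$percent_variance, 100)
})

test_that("fit agrees with MASS::lda on predictions and variance split", {
  d <- random_problem(7, n_per = 12, p = 4, g = 3, sep = 1.5)
  m <- fit_canonical_lda(d$x, d$groups, priors = "equal")
  ref <- MASS::lda(d$x, grouping = d$groups, prior = rep(1 / 3, 3))
  pred <- classify_lda(m, d$x)
  ref_pred <- predict(ref, d$x)
  expect_equal(pred$label, as.character(ref_pred$class))
  expect_equal(unname(pred$posterior), unname(ref_pred$posterior),
               tolerance = 1e-6)
  expect_equal(m$percent_variance / 100, ref$svd^2 / sum(ref$svd^2),
               tolerance = 1e-6)
})

test_that("degenerate and invalid inputs are handled", {
  # identical group means: all eigenvalues ~0, Lambda ~1, chi-square ~0
  set.seed(12)
  base <- matrix(rnorm(20 * 2), 20, 2)
  x <- rbind(base, base)
  colnames(x) <- c("f1", "f2")
  g <- rep(c("a", "b"), each = 20)
  m <- fit_canonical_lda(x, g)
  expect_lt(max(m$eigenvalues), 1e-9)
  expect_equal(m$wilks_lambda, 1, tolerance = 1e-9)
  expect_equal(m$chi_square, 0, tolerance = 1e-6)
  expect_gt(m$p, 0.999)

  d <- random_problem(2)
  expect_error(fit_canonical_lda(d$x, c("a", rep("b", nrow(d$x) - 1))),
               "size 1")
  collinear <- cbind(d$x, dup = d$x[, 1] * 2)
  expect_error(fit_canonical_lda(collinear, d$groups), "singular")
  expect_error(fit_canonical_lda(d$x[1:10, ], d$groups[1:10] ,
                                 priors = c(a = 0.5, b = 0.6)), "sum to 1")
})

test_that("classification is a nearest-mean rule with documented ties", {
  d <- random_problem(3)
  m <- fit_canonical_lda(d$x, d$groups)
  for (k in seq_along(m$group_labels)) {
    expect_equal(classify_lda(m, m$group_means[k, ])$label,
                 m$group_labels[k])
  }
  post <- classify_lda(m, d$x)$posterior
  expect_equal(unname(rowSums(post)), rep(1, nrow(d$x)), tolerance = 1e-12)
  # symmetric two-group problem: the exact midpoint ties to the first label
  x <- rbind(matrix(c(-1, -1, -1, 1, -3, 0), 3, 2, byrow = TRUE),
             matrix(c(1, 1, 1, -1, 3, 0), 3, 2, byrow = TRUE))
  colnames(x) <- c("f1", "f2")
  m2 <- fit_canonical_lda(x, rep(c("a", "b"), each = 3))
  expect_equal(classify_lda(m2, c(f1 = 0, f2 = 0))$label, "a")
  expect_error(classify_lda(m, c(1, 2)), "expected 3 features")
})

test_that("canonical structure is invariant under affine feature maps", {
  d <- random_problem(9, n_per = 10, p = 3)
  m0 <- fit_canonical_lda(d$x, d$groups)
  set.seed(31)
  a <- matrix(rnorm(9), 3, 3) + diag(3) * 2
  b <- rnorm(3)
  xt <- sweep(d$x %*% a, 2, b, "+")
  colnames(xt) <- colnames(d$x)
  m1 <- fit_canonical_lda(xt, d$groups)
  s0 <- canonical_scores(m0, d$x)
  s1 <- canonical_scores(m1, xt)
  for (j in seq_len(ncol(s0))) {
    expect_equal(abs(cor(s0[, j], s1[, j])), 1, tolerance = 1e-6)
  }
  expect_equal(m1$eigenvalues, m0$eigenvalues, tolerance = 1e-6)
  expect_equal(classify_lda(m1, xt)$label, classify_lda(m0, d$x)$label)
})

test_that("Bartlett's test follows the formula and checks n", {
  d <- random_problem(6)
  m <- fit_canonical_lda(d$x, d$groups)
  w <- wilks_test(m)
  p <- ncol(d$x); g <- 3; n <- nrow(d$x)
  expect_equal(w$chi_square, -(n - 1 - (p + g) / 2) * log(w$lambda),
               tolerance = 1e-12)
  expect_equal(w$df, p * (g - 1))
  expect_equal(w$p, pchisq(w$chi_square, w$df, lower.tail = FALSE))
  # chi-square is monotone in n at fixed Lambda
  bart <- function(n) -(n - 1 - (p + g) / 2) * log(m$wilks_lambda)
  expect_gt(bart(2 * n), bart(n))
  expect_error(wilks_test(m, n = n + 1), "does not match")
})

test_that("leave-one-out matches per-fold refits with MASS as oracle", {
  d <- random_problem(10, n_per = 10, p = 3, g = 3, sep = 1)  # 30 items
  rep_loo <- loo_classification(d$x, d$groups)
  oracle <- vapply(seq_len(nrow(d$x)), function(i) {
    fold <- MASS::lda(d$x[-i, ], grouping = d$groups[-i],
                      prior = rep(1 / 3, 3))
    as.character(predict(fold, d$x[i, , drop = FALSE])$class)
  }, character(1))
  expect_equal(rep_loo$predicted, oracle)
  expect_true(rep_loo$percent_correct >= 0 && rep_loo$percent_correct <= 100)
  expect_equal(unname(rowSums(rep_loo$confusion_matrix)),
               unname(as.vector(table(d$groups))))
})

test_that("separable clusters classify perfectly, permuted labels at chance", {
  d <- separated_clusters(n_per = 10, gap = 10)
  rep_loo <- loo_classification(d$x, d$groups)
  expect_equal(rep_loo$percent_correct, 100)
  # random labels on the same data: chance level ~ 100/3 on average
  set.seed(77)
  rates <- vapply(1:15, function(i) {
    loo_classification(d$x, sample(d$groups))$percent_correct
  }, numeric(1))
  expect_lt(abs(mean(rates) - 100 / 3), 12)
  expect_error(loo_classification(d$x, c("z", d$groups[-1])), "size")
})

test_that("models serialize to JSON and back-read intact", {
  d <- random_problem(13)
  m <- fit_canonical_lda(d$x, d$groups)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$wilks_lambda, m$wilks_lambda, tolerance = 1e-12)
  expect_equal(unlist(back$eigenvalues), unname(m$eigenvalues),
               tolerance = 1e-12)
  expect_equal(back$group_labels, m$group_labels)
})
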