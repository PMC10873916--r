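test_that("unpenalized fit inverts the correlation matrix", {
  set.seed(21)
  S <- random_correlation(6)
  K <- glasso_fit(S, 0)
  expect_lt(max(abs(K - solve(S))), 1e-8)
})

test_that("penalty at or above max |S_ij| yields the empty network exactly", {
  set.seed(22)
  S <- random_correlation(5)
  lam_max <- max(abs(S[upper.tri(S)]))
  K <- glasso_fit(S, lam_max)
  expect_true(all(K[upper.tri(K)] == 0))
  expect_equal(diag(K), 1 / diag(S), tolerance = 1e-12)
})

test_that("lambda grid is log-spaced with closed-form endpoints", {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.5
  expect_equal(lambda_grid(S, n_lambda = 3, min_ratio = 0.01),
               c(0.5, 0.05, 0.005), tolerance = 1e-12)
  expect_equal(lambda_grid(S, n_lambda = 1), 0.5)
  g <- lambda_grid(S, n_lambda = 50, min_ratio = 0.1)
  expect_equal(g[1], 0.5)
  expect_equal(g[50], 0.05, tolerance = 1e-12)
  expect_true(all(diff(g) < 0))
  expect_warning(lambda_grid(diag(3)), "all off-diagonal")
})

test_that("Gaussian log-likelihood and EBIC follow their formulas", {
  set.seed(23)
  S <- random_correlation(4)
  K <- solve(S)
  n <- 150
  expect_equal(gaussian_loglik(S, K, n),
               (n / 2) * (-determinant(S)$modulus[1] - 4), tolerance = 1e-10)
  expect_equal(gaussian_loglik(diag(3), diag(3), 100), -150)
  # EBIC arithmetic
  Kd <- diag(3)
  expect_equal(ebic(-7, Kd, 100), 14)                    # E = 0 -> -2L
  K2 <- diag(3)
  K2[1, 2] <- K2[2, 1] <- 0.1
  K2[1, 3] <- K2[3, 1] <- 0.2
  expect_equal(ebic(0, K2, 100, gamma = 0.5),
               2 * log(100) + 4 * log(3), tolerance = 1e-12)
  expect_equal(ebic(0, K2, 100, gamma = 0), 2 * log(100), tolerance = 1e-12)
})

test_that("precision-to-partial conversion matches the conditioning oracle", {
  expect_true(all(precision_to_partial(diag(c(2, 3, 4))) == 0))
  K <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial(K)[1, 2], 0.5, tolerance = 1e-12)
  set.seed(24)
  for (rep in 1:5) {
    S <- random_correlation(4)
    K <- solve(S)
    P <- precision_to_partial(K)
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(P[i, j], partial_cor_conditioning(S, i, j),
                   tolerance = 1e-10)
  }
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)),
               "non-positive diagonal")
})

test_that("coordinate-descent solution matches the proximal-gradient oracle", {
  set.seed(25)
  for (rep in 1:10) {
    S <- random_correlation(4)
    for (lam in c(0.05, 0.2)) {
      K <- glasso_fit(S, lam, tol = 1e-12, maxit = 2000)
      K_o <- fista_glasso(S, lam)
      expect_lt(abs(glasso_objective(K, S, lam) -
                    glasso_objective(K_o, S, lam)), 1e-6)
      expect_identical(abs(K[upper.tri(K)]) > 1e-6,
                       abs(K_o[upper.tri(K_o)]) > 1e-6)
    }
  }
})

test_that("EBIC selection minimizes the criterion and shrinks monotonically", {
  spec <- random_sparse_ggm(p = 10, edge_density = 0.25, seed = 31,
                            n_respondents = 1200)
  tab <- sample_ordinal_responses(spec)
  fit <- ebic_glasso(tab$values)
  expect_equal(fit$path$selected, which.min(fit$path$ebics))
  expect_true(all(fit$path$ebics >= fit$path$ebics[fit$path$selected]))
  # total absolute partial correlation non-increasing in lambda
  S <- fit$correlation
  lams <- fit$path$lambdas[seq(1, 100, by = 7)]
  totals <- vapply(lams, function(l) {
    K <- glasso_fit(S, l, tol = 1e-9)
    sum(abs(precision_to_partial(K)))
  }, 1)
  expect_true(all(diff(totals) >= -1e-6))  # lams decrease along the path
  # weight invariants
  W <- fit$weights
  expect_true(all(abs(W) < 1))
  expect_true(all(diag(W) == 0))
  expect_identical(W == 0, t(W) == 0)
  expect_identical(unname(W == 0)[upper.tri(W)],
                   unname(fit$precision == 0)[upper.tri(W)])
})

test_that("estimation recovers a sparse truth at large n", {
  spec <- random_sparse_ggm(p = 10, edge_density = 0.2, seed = 32,
                            n_respondents = 3000)
  tab <- sample_ordinal_responses(spec)
  fit <- ebic_glasso(tab$values)
  rec <- recovery_scores(fit, spec)
  expect_gte(rec$sensitivity, 0.7)
  expect_gte(rec$specificity, 0.8)
})

test_that("correlation-matrix input requires n and duplicate data fail upstream", {
  S <- random_correlation(4)
  expect_error(ebic_glasso(S), "sample size")
  x <- matrix(rnorm(60), 20, 3)
  expect_error(ebic_glasso(cbind(x, dup = x[, 1])), "perfectly correlated")
})
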