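boot_fixture_data <- function(n = 400, seed = 51) {
  spec <- random_sparse_ggm(p = 6, edge_density = 0.4, seed = seed,
                            weight_range = c(0.25, 0.4), n_respondents = n)
  sample_ordinal_responses(spec)$values
}

test_that("identity resample reproduces the full-sample network", {
  X <- boot_fixture_data()
  ens <- bootstrap_networks(X, B = 1, seed = 1,
                            indices = list(seq_len(nrow(X))))
  expect_equal(ens$weights[, , 1], ens$fit$weights, tolerance = 1e-12)
  expect_equal(ens$ei[, 1], expected_influence(ens$fit), tolerance = 1e-12)
})

test_that("bootstrap ensembles are reproducible under a fixed seed", {
  X <- boot_fixture_data()
  e1 <- bootstrap_networks(X, B = 5, seed = 7)
  e2 <- bootstrap_networks(X, B = 5, seed = 7)
  expect_identical(e1$weights, e2$weights)
  expect_equal(e1$n_failed, 0)
})

test_that("edge CIs follow the percentile rule", {
  X <- boot_fixture_data()
  # constant replicates: zero-width interval
  ens <- bootstrap_networks(X, B = 3, seed = 1,
                            indices = rep(list(seq_len(nrow(X))), 3))
  ci <- edge_ci(ens)
  expect_true(all(ci$upper - ci$lower == 0))
  expect_equal(ci$lower, ci$estimate)
  # two distinct replicates: endpoints from the quantile interpolation rule
  ens2 <- bootstrap_networks(X, B = 2, seed = 1,
                             indices = list(1:200, 201:400))
  ci2 <- edge_ci(ens2, level = 0.95)
  v <- sort(ens2$weights[1, 2, ])
  # type-7 interpolation at probabilities 0.025 / 0.975 on two points
  expect_equal(ci2$lower[1], v[1] + 0.025 * (v[2] - v[1]), tolerance = 1e-12)
  expect_equal(ci2$upper[1], v[1] + 0.975 * (v[2] - v[1]), tolerance = 1e-12)
})

test_that("difference tests use the bootstrap CI of the difference", {
  X <- boot_fixture_data()
  ens <- bootstrap_networks(X, B = 20, seed = 3)
  lab <- ens$fit$labels
  same <- difference_test(ens, c(lab[1], lab[2]), c(lab[1], lab[2]))
  expect_false(same$significant)
  expect_equal(same$observed_difference, 0)
  # constructed straddling-zero case
  ens$weights[1, 2, ] <- seq(-0.1, 0.1, length.out = 20)
  ens$weights[1, 3, ] <- 0
  strad <- difference_test(ens, c(lab[1], lab[2]), c(lab[1], lab[3]))
  expect_false(strad$significant)
})

test_that("case-dropping profile is reproducible and correlations valid", {
  X <- boot_fixture_data(n = 500)
  pr1 <- case_dropping_bootstrap(X, proportions = c(0.1, 0.3, 0.5),
                                 B = 8, seed = 5)
  pr2 <- case_dropping_bootstrap(X, proportions = c(0.1, 0.3, 0.5),
                                 B = 8, seed = 5)
  expect_identical(pr1$correlations, pr2$correlations)
  expect_true(all(pr1$correlations >= -1 & pr1$correlations <= 1,
                  na.rm = TRUE))
  med <- apply(pr1$correlations, 1, median, na.rm = TRUE)
  expect_gte(med[1], med[3])  # stability degrades as more cases are dropped
})

test_that("CS coefficient follows its definition and monotonicities", {
  props <- seq(0.05, 0.75, by = 0.1)
  perfect <- structure(list(
    correlations = matrix(1, length(props), 50), proportions = props,
    B = 50), class = "case_drop_profile")
  expect_equal(cs_coefficient(perfect), max(props))
  # constructed profile that fails beyond 0.25
  props2 <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  cors <- matrix(1, 5, 40)
  cors[4:5, ] <- 0.3
  prof <- structure(list(correlations = cors, proportions = props2, B = 40),
                    class = "case_drop_profile")
  expect_equal(cs_coefficient(prof), 0.25)
  expect_equal(cs_coefficient(prof, cor_threshold = 0.2), 0.45)
  # non-increasing in threshold and certainty
  set.seed(52)
  rand <- structure(list(
    correlations = matrix(runif(5 * 40, 0.2, 1), 5, 40),
    proportions = props2, B = 40), class = "case_drop_profile")
  for (th in c(0.3, 0.5, 0.7, 0.9)[-4])
    expect_gte(cs_coefficient(rand, cor_threshold = th),
               cs_coefficient(rand, cor_threshold = th + 0.2))
  for (ce in c(0.5, 0.7, 0.9))
    expect_gte(cs_coefficient(rand, certainty = ce),
               cs_coefficient(rand, certainty = ce + 0.05))
})
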