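test_that("partial / precision / covariance round trip is exact", {
  set.seed(101)
  for (rep in 1:8) {
    spec <- random_sparse_ggm(p = sample(3:8, 1), edge_density = runif(1, 0.1, 0.5),
                              seed = rep)
    Sigma <- ggm_covariance(spec)
    P_back <- precision_to_partial(solve(Sigma))
    expect_lt(max(abs(P_back - spec$true_partial)), 1e-10)
  }
})

test_that("degenerate generator cases match closed forms", {
  # empty graph: zero partials, identity covariance
  spec0 <- random_sparse_ggm(p = 5, edge_density = 0, seed = 1)
  expect_true(all(spec0$true_partial == 0))
  expect_equal(unname(ggm_covariance(spec0)), diag(5))
  # 2-node model: covariance off-diagonal equals the partial correlation
  P <- matrix(c(0, 0.5, 0.5, 0), 2)
  spec2 <- symptomnet:::new_ggm_spec(P, c("a", "b"), c(1, 1),
                                     list(0, 0), c(0L, 0L), 100, 1)
  expect_equal(ggm_covariance(spec2)["a", "b"], 0.5, tolerance = 1e-12)
})

test_that("spec generation and sampling are deterministic under a fixed seed", {
  s1 <- random_sparse_ggm(p = 10, edge_density = 0.2, seed = 42)
  s2 <- random_sparse_ggm(p = 10, edge_density = 0.2, seed = 42)
  expect_identical(s1$true_partial, s2$true_partial)
  t1 <- sample_ordinal_responses(s1, n = 200)
  t2 <- sample_ordinal_responses(s2, n = 200)
  expect_identical(t1$values, t2$values)
})

test_that("sampled responses respect declared ranges and thresholds", {
  spec <- random_sparse_ggm(p = 6, edge_density = 0.3, n_categories = 4, seed = 5)
  tab <- sample_ordinal_responses(spec, n = 400)
  expect_true(all(tab$values >= 0 & tab$values <= 3))
  # a single cut point produces a binary column
  spec$thresholds[[1]] <- 0
  tab2 <- sample_ordinal_responses(spec, n = 400)
  expect_setequal(unique(tab2$values[, 1]), c(0L, 1L))
})

test_that("independent nodes sample to near-zero Spearman correlations", {
  spec <- random_sparse_ggm(p = 5, edge_density = 0, seed = 9)
  tab <- sample_ordinal_responses(spec, n = 5000)
  C <- cor(tab$values, method = "spearman")
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("ordinal marginals converge to the Gaussian orthant probabilities", {
  spec <- random_sparse_ggm(p = 4, edge_density = 0.3, n_categories = 4, seed = 3)
  tab <- sample_ordinal_responses(spec, n = 50000)
  for (j in 1:4) {
    freq <- tabulate(tab$values[, j] + 1L, nbins = 4) / nrow(tab$values)
    expected <- diff(c(0, pnorm(spec$thresholds[[j]]), 1))
    expect_lt(max(abs(freq - expected)), 0.01)
  }
})

test_that("positive-definiteness repair preserves the sparsity pattern", {
  set.seed(7)
  spec <- random_sparse_ggm(p = 12, edge_density = 0.4,
                            weight_range = c(0.3, 0.5), seed = 77)
  K <- symptomnet:::partial_to_precision(spec$true_partial)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("study fixture mirrors the 28-node design with a stronger group", {
  fx <- study_fixture(seed = 4, n_per_group = c(150, 150))
  expect_identical(colnames(fx$table$values),
                   c(paste0("PHQ", 1:9), paste0("GAD", 1:7), paste0("IES", 1:6),
                     "FW", "PHY", "MF", "FFC", "SSFm", "SSFr"))
  expect_identical(as.integer(table(fx$table$group)), c(150L, 150L))
  # group 1's true network is globally stronger by construction
  expect_gt(global_strength(fx$spec$group1$true_partial),
            global_strength(fx$spec$base$true_partial))
  # protective support edge is negative in the truth
  expect_lt(fx$spec$base$true_partial["SSFm", "PHQ9"], 0)
  # support items live on the 1..7 scale, stressors collapsed to 0..2
  expect_true(all(fx$table$values[, "SSFm"] >= 1 & fx$table$values[, "SSFm"] <= 7))
  expect_true(all(fx$table$values[, "FW"] %in% 0:2))
})

test_that("two-group modification keeps a valid model and planted edges", {
  base <- random_sparse_ggm(p = 8, edge_density = 0.3, min_eig = 0.3, seed = 2)
  tg <- two_group_ggm(base, strength_multiplier = 1.3,
                      planted_edge_diffs = data.frame(
                        node_i = "V1", node_j = "V2", delta = 0.2),
                      group_sizes = c(50, 60))
  K1 <- symptomnet:::partial_to_precision(tg$group1$true_partial)
  expect_gt(min(eigen(K1, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(tg$group1$true_partial["V1", "V2"], base$true_partial["V1", "V2"])
  expect_error(two_group_ggm(base, planted_edge_diffs = data.frame(
    node_i = "V1", node_j = "nope", delta = 0.1)), "unknown node")
  tab <- sample_two_group_responses(tg, seed = 1)
  expect_identical(as.integer(table(tab$group)), c(50L, 60L))
})

test_that("spec JSON and response CSV round-trip losslessly", {
  spec <- random_sparse_ggm(p = 5, edge_density = 0.4, seed = 13)
  f <- tempfile(fileext = ".json")
  write_ggm_spec(spec, f)
  spec2 <- read_ggm_spec(f)
  expect_equal(spec2$true_partial, spec$true_partial, ignore_attr = TRUE)
  expect_identical(spec2$seed, spec$seed)

  tab <- sample_ordinal_responses(spec, n = 30)
  g <- tempfile(fileext = ".csv")
  write_response_csv(tab, g)
  tab2 <- read_response_csv(g)
  expect_identical(unname(tab2$values), unname(tab$values))
})
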