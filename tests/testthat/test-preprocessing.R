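make_toy_table <- function() {
  set.seed(1)
  vals <- cbind(
    matrix(sample(0:3, 9 * 20, TRUE), 20, 9,
           dimnames = list(NULL, paste0("PHQ", 1:9))),
    matrix(sample(0:4, 2 * 20, TRUE), 20, 2,
           dimnames = list(NULL, c("STR_finance", "STR_work")))
  )
  meta <- data.frame(item = colnames(vals),
                     scale = c(rep("PHQ", 9), rep("STRESSOR", 2)),
                     min = 0, max = c(rep(3, 9), 4, 4))
  item_response_table(vals, meta)
}

test_that("complete-case filtering drops exactly the incomplete respondents", {
  tab <- make_toy_table()
  expect_identical(filter_complete_cases(tab)$values, tab$values)
  vals <- tab$values
  vals[3, "PHQ2"] <- NA
  tab2 <- item_response_table(vals, tab$item_meta)
  out <- filter_complete_cases(tab2, core_items = paste0("PHQ", 1:9))
  expect_equal(nrow(out$values), 19)
  expect_equal(attr(out, "n_removed"), 1)
  vals[] <- NA
  expect_error(filter_complete_cases(item_response_table(vals, tab$item_meta)),
               "no complete cases")
  expect_error(filter_complete_cases(tab, core_items = "nope"), "unknown core")
})

test_that("scale scoring sums items and caseness uses the >= 10 rule", {
  tab <- make_toy_table()
  tot <- score_scale(tab, "PHQ")
  expect_equal(tot, rowSums(tab$values[, paste0("PHQ", 1:9)]))
  all3 <- tab
  all3$values[, paste0("PHQ", 1:9)] <- 3L
  expect_true(all(score_scale(all3, "PHQ") == 27))
  expect_true(classify_probable_case(10))
  expect_false(classify_probable_case(9))
  expect_true(classify_probable_case(27))
  # monotone in the total
  tots <- 0:27
  expect_true(all(diff(classify_probable_case(tots)) >= 0))
})

test_that("stressor merging averages and collapsing uses the three anchors", {
  expect_equal(merge_stressor_domains(2, 4), 3)
  expect_equal(merge_stressor_domains(0, 0), 0)
  expect_equal(merge_stressor_domains(1, 2), 1.5)
  expect_error(merge_stressor_domains(5, 0), "\\[0, 4\\]")
  expect_identical(collapse_stressor_levels(c(0, 1, 3.5, 0.5, 2, 4)),
                   c(0L, 1L, 2L, 1L, 2L, 2L))
  expect_error(collapse_stressor_levels(-1), "negative")
  # idempotent on already-collapsed values: merging equal levels returns them
  for (v in 0:2)
    expect_identical(collapse_stressor_levels(merge_stressor_domains(v, v)),
                     as.integer(v))
})

test_that("Cronbach's alpha matches its defining variance decomposition", {
  set.seed(2)
  x <- matrix(rnorm(300), 100, 3)
  items <- x + rnorm(100)          # shared factor induces consistency
  # direct arithmetic oracle
  k <- 3
  alpha_hand <- k / (k - 1) *
    (1 - (var(items[, 1]) + var(items[, 2]) + var(items[, 3])) /
       var(items[, 1] + items[, 2] + items[, 3]))
  expect_equal(cronbach_alpha(items), alpha_hand, tolerance = 1e-12)
  # parallel items: alpha = 1; shifted items: unchanged
  same <- cbind(x[, 1], x[, 1], x[, 1])
  expect_equal(cronbach_alpha(same), 1, tolerance = 1e-12)
  shifted <- items
  shifted[, 2] <- shifted[, 2] + 5
  expect_equal(cronbach_alpha(shifted), cronbach_alpha(items), tolerance = 1e-12)
  # independent items at large n: near zero
  set.seed(3)
  indep <- matrix(rnorm(3 * 5000), ncol = 3)
  expect_lt(abs(cronbach_alpha(indep)), 0.1)
  expect_error(cronbach_alpha(matrix(1, 10, 2)), "zero variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), 10, 1)), "at least 2")
})

test_that("odds ratios match the textbook formula with Wald intervals", {
  sym <- odds_ratio(matrix(c(10, 10, 10, 10), 2))
  expect_equal(sym$or, 1)
  expect_equal(odds_ratio(matrix(c(20, 10, 10, 20), 2))$or, 4)
  set.seed(4)
  tab <- matrix(rpois(4, 30) + 1, 2)
  res <- odds_ratio(tab)
  or_hand <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  se_hand <- sqrt(sum(1 / tab))
  expect_equal(res$or, or_hand, tolerance = 1e-12)
  expect_equal(res$ci,
               exp(log(or_hand) + c(-1, 1) * qnorm(0.975) * se_hand),
               tolerance = 1e-12)
  expect_equal(res$p, chisq.test(tab, correct = TRUE)$p.value, tolerance = 1e-12)
  expect_false(res$corrected)
  zero <- odds_ratio(matrix(c(5, 0, 3, 7), 2))
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or))
})

test_that("node matrix construction merges, collapses, orders canonically", {
  fx <- study_fixture(seed = 3, n_per_group = c(60, 60))
  nodes <- build_node_matrix(fx$table)
  expect_equal(ncol(nodes), 28)
  expect_identical(colnames(nodes), symptomnet:::study_node_labels())
  expect_true(all(unclass(nodes)[, "MF"] %in% 0:2))
  # raw 7-domain layout: merge then collapse
  set.seed(5)
  vals <- cbind(
    matrix(sample(0:3, 22 * 10, TRUE), 10, 22,
           dimnames = list(NULL, c(paste0("PHQ", 1:9), paste0("GAD", 1:7),
                                   paste0("IES", 1:6)))),
    STR_finance = rep(4L, 10), STR_work = rep(0L, 10),
    STR_physical = sample(0:4, 10, TRUE),
    STR_medical = sample(0:4, 10, TRUE), STR_food = sample(0:4, 10, TRUE),
    STR_family = sample(0:4, 10, TRUE), STR_friends = sample(0:4, 10, TRUE),
    SSFm = sample(1:7, 10, TRUE), SSFr = sample(1:7, 10, TRUE)
  )
  meta <- data.frame(
    item = colnames(vals),
    scale = c(rep("PHQ", 9), rep("GAD", 7), rep("IES", 6),
              rep("STRESSOR", 7), rep("SUPPORT", 2)),
    min = c(rep(0, 22), rep(0, 7), 1, 1),
    max = c(rep(3, 22), rep(4, 7), 7, 7)
  )
  raw <- item_response_table(vals, meta)
  nodes2 <- build_node_matrix(raw, merge_plan = symptomnet:::default_merge_plan())
  expect_identical(colnames(nodes2), symptomnet:::study_node_labels())
  # finance 4 + work 0 -> mean 2 -> collapsed level 2
  expect_true(all(unclass(nodes2)[, "FW"] == 2))
  # without a plan, the 7 stressors are collapsed individually
  nodes3 <- build_node_matrix(raw, merge_plan = NULL)
  expect_equal(ncol(nodes3), 31)
  expect_true(all(unclass(nodes3)[, "STR_physical"] %in% 0:2))
  expect_error(build_node_matrix(raw, merge_plan = list(X = c("PHQ1", "PHQ2"))),
               "non-stressor")
  expect_error(build_node_matrix(raw, merge_plan = list(X = "STR_nope")),
               "unknown items")
})

test_that("sample description reports caseness and group odds ratios", {
  fx <- study_fixture(seed = 6, n_per_group = c(200, 200))
  d <- describe_sample(fx$table)
  expect_identical(d$scale, c("PHQ", "GAD", "IES"))
  expect_true(all(d$pct_cases >= 0 & d$pct_cases <= 100))
  expect_true(all(is.finite(d$or_group)))
})
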