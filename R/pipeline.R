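#' Configuration for a full network analysis run
#'
#' Collects every tunable of the end-to-end pipeline with the conventional
#' defaults. One global seed spawns independent per-stage streams (bootstrap,
#' case-dropping, permutation test), so disabling one stage never perturbs
#' another stage's draws.
#'
#' @param out_dir output directory for the report bundle.
#' @param merge_plan stressor merge plan for [build_node_matrix()] (`NULL`
#'   collapses stressors individually).
#' @param gamma EBIC hyperparameter.
#' @param bootstrap_B nonparametric bootstrap replicates (0 skips the stage).
#' @param case_drop_B subsamples per drop proportion (0 skips the stage).
#' @param case_drop_proportions drop-proportion grid.
#' @param nct_n_perm permutations for the group comparison.
#' @param nct_seed permutation seed (123 by convention).
#' @param use_group run the two-group comparison when a group label exists.
#' @param seed global RNG seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(out_dir = tempfile("symptomnet_run"),
                            merge_plan = NULL, gamma = 0.5,
                            bootstrap_B = 200, case_drop_B = 50,
                            case_drop_proportions = seq(0.05, 0.75, by = 0.05),
                            nct_n_perm = 1000, nct_seed = 123,
                            use_group = TRUE, seed = 1) {
  stopifnot(gamma >= 0, bootstrap_B >= 0, case_drop_B >= 0, nct_n_perm >= 1)
  structure(list(out_dir = out_dir, merge_plan = merge_plan, gamma = gamma,
                 bootstrap_B = as.integer(bootstrap_B),
                 case_drop_B = as.integer(case_drop_B),
                 case_drop_proportions = case_drop_proportions,
                 nct_n_perm = as.integer(nct_n_perm),
                 nct_seed = as.integer(nct_seed),
                 use_group = use_group, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys match the [analysis_config()] arguments.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' Run the full network analysis pipeline
#'
#' Executes preprocessing, Spearman association, EBIC graphical lasso
#' estimation, centrality and predictability, bootstrap accuracy and
#' case-dropping stability, walktrap communities and — when a group label is
#' present — the permutation network comparison test. All artifacts are
#' written under `config$out_dir` and listed in a manifest that records every
#' setting and seed needed to reproduce the run bit-for-bit.
#'
#' @param table an [item_response_table()] (or CSV path readable by
#'   [read_response_csv()]).
#' @param config an [analysis_config()].
#' @return object of class `report_bundle` with the fitted objects and the
#'   manifest.
#' @export
run_full_analysis <- function(table, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(table)) table <- read_response_csv(table)
  stopifnot(inherits(table, "item_response_table"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  # --- preprocessing -------------------------------------------------------
  table <- filter_complete_cases(table)
  say("preprocessing: %d incomplete respondents removed, %d retained",
      attr(table, "n_removed"), nrow(table$values))
  nodes <- build_node_matrix(table, merge_plan = config$merge_plan)
  write.csv(as.data.frame(unclass(nodes)), out("node_matrix.csv"),
            row.names = FALSE)
  files <- c(files, "node_matrix.csv")

  # --- estimation ----------------------------------------------------------
  fit <- ebic_glasso(nodes, gamma = config$gamma)
  write_network(fit, out("network_overall_edges.csv"), "edgelist")
  write_network(fit, out("network_overall.graphml"), "graphml")
  files <- c(files, "network_overall_edges.csv", "network_overall.graphml")
  say("estimation: %d edges, lambda = %.5g", count_edges(fit$weights),
      fit$path$lambda)

  # --- communities ---------------------------------------------------------
  eg <- ega(nodes, gamma = config$gamma)
  partition <- eg$partition
  write_partition_csv(partition, out("communities_overall.csv"))
  files <- c(files, "communities_overall.csv")

  # --- metrics -------------------------------------------------------------
  centrality <- centrality_table(fit, data = nodes, partition = partition,
                                 z_scores = TRUE)
  write.csv(centrality, out("centrality_overall.csv"), row.names = FALSE)
  files <- c(files, "centrality_overall.csv")

  # --- stability -----------------------------------------------------------
  boot <- NULL
  profile <- NULL
  cs <- NA_real_
  if (config$bootstrap_B > 0) {
    boot <- bootstrap_networks(nodes, B = config$bootstrap_B,
                               seed = derive_seed(config$seed, 101L),
                               gamma = config$gamma)
    write_stability_csv(boot, out("bootstrap_edges.csv"))
    files <- c(files, "bootstrap_edges.csv")
    say("bootstrap: %d replicates, %d failed", boot$B, boot$n_failed)
  }
  if (config$case_drop_B > 0) {
    profile <- case_dropping_bootstrap(
      nodes, proportions = config$case_drop_proportions,
      B = config$case_drop_B, seed = derive_seed(config$seed, 211L),
      gamma = config$gamma)
    cs <- cs_coefficient(profile)
    write_stability_csv(profile, out("case_dropping.csv"))
    files <- c(files, "case_dropping.csv")
    say("case-dropping: CS coefficient = %.2f", cs)
  }

  # --- per-group networks and comparison -----------------------------------
  group_fits <- NULL
  group_partitions <- NULL
  comparison <- NULL
  if (config$use_group && !is.null(table$group)) {
    grp <- attr(nodes, "group")
    g0 <- unclass(nodes)[grp == 0, , drop = FALSE]
    g1 <- unclass(nodes)[grp == 1, , drop = FALSE]
    eg0 <- ega(g0, gamma = config$gamma)
    eg1 <- ega(g1, gamma = config$gamma)
    group_fits <- list(group0 = eg0$fit, group1 = eg1$fit)
    group_partitions <- list(group0 = eg0$partition, group1 = eg1$partition)
    for (g in c("group0", "group1")) {
      write_network(group_fits[[g]], out(paste0("network_", g, "_edges.csv")),
                    "edgelist")
      write_partition_csv(group_partitions[[g]],
                          out(paste0("communities_", g, ".csv")))
      files <- c(files, paste0("network_", g, "_edges.csv"),
                 paste0("communities_", g, ".csv"))
    }
    comparison <- nct(g1, g0, n_perm = config$nct_n_perm,
                      seed = config$nct_seed, gamma = config$gamma)
    write_nct(comparison, out("nct.json"), edge_csv = out("nct_edges.csv"))
    files <- c(files, "nct.json", "nct_edges.csv")
    say("comparison: S = %.3f (p = %.3g), M = %.3f (p = %.3g)",
        comparison$observed_S, comparison$p_S,
        comparison$observed_M, comparison$p_M)
  }

  manifest <- list(
    package = "symptomnet",
    version = as.character(utils::packageVersion("symptomnet")),
    settings = unclass(config)[setdiff(names(config), "out_dir")],
    files = files,
    log = log
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(fit = fit, partition = partition, centrality = centrality,
                 bootstrap = boot, case_drop = profile, cs = cs,
                 group_fits = group_fits, group_partitions = group_partitions,
                 comparison = comparison, manifest = manifest,
                 out_dir = config$out_dir),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report bundle in", x$out_dir, "\n")
  for (l in x$manifest$log) cat(" -", l, "\n")
  invisible(x)
}

#' Score an estimated network against the generating truth
#'
#' @param fit a `ggm_fit`.
#' @param spec the generating `ggm_spec`.
#' @param partition optional `community_partition` to score against the
#'   planted communities (adjusted Rand index).
#' @return list with edge-recovery `sensitivity`, `specificity`,
#'   `n_true_edges`, `n_estimated_edges`, and `ari` when a partition is
#'   given.
#' @export
recovery_scores <- function(fit, spec, partition = NULL) {
  stopifnot(inherits(fit, "ggm_fit"), inherits(spec, "ggm_spec"))
  ut <- upper.tri(spec$true_partial)
  truth <- spec$true_partial[ut] != 0
  est <- fit$weights[spec$node_labels, spec$node_labels][ut] != 0
  out <- list(
    sensitivity = if (any(truth)) mean(est[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!est[!truth]) else NA_real_,
    n_true_edges = sum(truth),
    n_estimated_edges = sum(est)
  )
  if (!is.null(partition)) {
    memb <- partition$membership[spec$node_labels]
    out$ari <- mclust::adjustedRandIndex(memb, spec$community_assignment)
  }
  out
}

#' Simulate a study-shaped dataset and run the full pipeline on it
#'
#' Generates the two-group synthetic fixture, runs [run_full_analysis()] and
#' scores the estimates against the generating truth (edge
#' sensitivity/specificity per group, community recovery, global-strength
#' ordering).
#'
#' @param seed simulation seed.
#' @param n_per_group respondents per group.
#' @param strength_multiplier group-1 connectivity multiplier.
#' @param config an [analysis_config()].
#' @return list with the `bundle` (a `report_bundle`), the generating
#'   `spec`, and `recovery` (per-group recovery scores plus
#'   `strength_order_correct`).
#' @export
simulate_and_run <- function(seed = 1, n_per_group = c(1000, 1000),
                             strength_multiplier = 1.3,
                             config = analysis_config(seed = seed)) {
  fx <- study_fixture(seed = seed, n_per_group = n_per_group,
                      strength_multiplier = strength_multiplier)
  bundle <- run_full_analysis(fx$table, config)
  rec <- list(
    group0 = recovery_scores(bundle$group_fits$group0, fx$spec$base,
                             bundle$group_partitions$group0),
    group1 = recovery_scores(bundle$group_fits$group1, fx$spec$group1,
                             bundle$group_partitions$group1)
  )
  true_order <- global_strength(fx$spec$group1$true_partial) >
    global_strength(fx$spec$base$true_partial)
  est_order <- global_strength(bundle$group_fits$group1) >
    global_strength(bundle$group_fits$group0)
  rec$strength_order_correct <- identical(true_order, est_order)
  list(bundle = bundle, spec = fx$spec, recovery = rec)
}
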