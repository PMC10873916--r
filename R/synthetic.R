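#' Synthetic ordinal survey data from known sparse Gaussian graphical models
#'
#' These generators produce respondent-by-item ordinal tables whose latent
#' structure is a known sparse partial-correlation network, so that network
#' estimation, community detection and group comparison can be benchmarked
#' against ground truth. The latent model is multivariate Gaussian; each item
#' is discretized by per-node thresholds into Likert-type categories.
#'
#' @name synthetic
NULL

# Precision matrix implied by a partial-correlation matrix under the
# unit-diagonal convention kappa_ii = 1, kappa_ij = -rho_ij.
partial_to_precision <- function(P) {
  K <- -P
  diag(K) <- 1
  K
}

#' Convert a precision matrix to partial correlations
#'
#' Computes `rho_ij = -kappa_ij / sqrt(kappa_ii * kappa_jj)` with a zero
#' diagonal. Exact zeros in the precision stay exact zeros.
#'
#' @param K symmetric positive-definite precision matrix.
#' @return symmetric matrix of partial correlations with zero diagonal.
#' @export
precision_to_partial <- function(K) {
  if (!is_symmetric_num(K)) stop("precision matrix must be symmetric")
  d <- diag(K)
  if (any(d <= 0)) stop("precision matrix has non-positive diagonal entries")
  P <- -K / sqrt(outer(d, d))
  diag(P) <- 0
  P[K == 0] <- 0
  diag(P) <- 0
  P
}

# Deterministic positive-definiteness repair: scale all partials by the single
# factor that lifts the smallest eigenvalue of K = I - P to `min_eig`.
# Because eig(K) = 1 + eig(-P), scaling P by c maps eigenvalue 1 + e to
# 1 + c*e, so c = (1 - min_eig) / (1 - lambda_min) works in one shot and
# preserves the sparsity pattern exactly.
pd_rescale_partial <- function(P, min_eig = 0.05) {
  lmin <- min_eigenvalue(partial_to_precision(P))
  if (lmin >= min_eig) return(list(partial = P, scaled = FALSE, factor = 1))
  c_fac <- (1 - min_eig) / (1 - lmin)
  if (!is.finite(c_fac) || c_fac <= 0)
    stop("positive-definiteness repair failed (lambda_min = ", signif(lmin, 4), ")")
  list(partial = P * c_fac, scaled = TRUE, factor = c_fac)
}

# Equal-probability standard-normal cut points for `k` ordinal categories.
equal_prob_thresholds <- function(k) {
  if (k < 2) stop("need at least 2 categories")
  qnorm(seq_len(k - 1) / k)
}

new_ggm_spec <- function(partial, labels, communities, thresholds, level_min,
                         n_respondents, seed) {
  K <- partial_to_precision(partial)
  lmin <- min_eigenvalue(K)
  if (lmin <= 0)
    stop("implied precision matrix is not positive definite (lambda_min = ",
         signif(lmin, 4), ")")
  stopifnot(all(vapply(thresholds, function(t) all(diff(t) > 0), TRUE)))
  dimnames(partial) <- list(labels, labels)
  structure(list(
    n_respondents = as.integer(n_respondents),
    true_partial = partial,
    node_labels = labels,
    community_assignment = setNames(as.integer(communities), labels),
    thresholds = setNames(thresholds, labels),
    level_min = setNames(as.integer(level_min), labels),
    seed = as.integer(seed)
  ), class = "ggm_spec")
}

#' Random sparse Gaussian graphical model specification
#'
#' Draws a sparse symmetric partial-correlation matrix with a requested edge
#' density and edge-weight range, optionally organized into communities
#' (within-community pairs receive a higher edge probability than
#' between-community pairs). Positive definiteness of the implied precision
#' matrix is enforced by a deterministic symmetric rescaling of the
#' off-diagonals, which preserves the sparsity pattern.
#'
#' @param p number of nodes (>= 2).
#' @param edge_density expected proportion of present edges, in `[0, 1)`.
#' @param weight_range magnitude range for nonzero partial correlations.
#' @param community_sizes optional integer vector of community sizes summing
#'   to `p`; when given, within-community edges are favoured.
#' @param n_respondents default sample size carried by the spec.
#' @param n_categories ordinal categories per item (equal-probability
#'   thresholds).
#' @param prob_positive probability that a nonzero weight is positive;
#'   symptom networks are predominantly positive.
#' @param min_eig smallest eigenvalue enforced for the implied precision.
#' @param seed RNG seed; identical seeds give identical specs.
#' @return a `ggm_spec` with fields `true_partial`, `node_labels`,
#'   `community_assignment`, `thresholds`, `n_respondents`, `seed`.
#' @export
random_sparse_ggm <- function(p, edge_density, weight_range = c(0.15, 0.35),
                              community_sizes = NULL, n_respondents = 1000,
                              n_categories = 4, prob_positive = 0.85,
                              min_eig = 0.05, seed = 1) {
  stopifnot(p >= 2, edge_density >= 0, edge_density < 1,
            length(weight_range) == 2, all(weight_range >= 0))
  if (!is.null(community_sizes)) {
    stopifnot(sum(community_sizes) == p)
    comm <- rep(seq_along(community_sizes), community_sizes)
  } else {
    comm <- rep(1L, p)
  }
  set.seed(as.integer(seed))
  P <- matrix(0, p, p)
  pairs <- edge_pairs(p)
  within <- comm[pairs[, 1]] == comm[pairs[, 2]]
  if (!is.null(community_sizes) && any(within) && any(!within)) {
    # favour within-community edges while keeping the overall density
    p_within <- min(0.95, 3 * edge_density)
    n_w <- sum(within); n_b <- sum(!within)
    p_between <- max(0, (edge_density * (n_w + n_b) - p_within * n_w) / n_b)
    prob <- ifelse(within, p_within, p_between)
  } else {
    prob <- rep(edge_density, nrow(pairs))
  }
  present <- runif(nrow(pairs)) < prob
  mag <- runif(nrow(pairs), weight_range[1], weight_range[2])
  sgn <- ifelse(runif(nrow(pairs)) < prob_positive, 1, -1)
  w <- ifelse(present, mag * sgn, 0)
  P[pairs] <- w
  P[pairs[, c(2, 1), drop = FALSE]] <- w
  P <- pd_rescale_partial(P, min_eig)$partial
  labels <- paste0("V", seq_len(p))
  thresholds <- replicate(p, equal_prob_thresholds(n_categories), simplify = FALSE)
  new_ggm_spec(P, labels, comm, thresholds, rep(0L, p), n_respondents, seed)
}

#' Deterministic planted-block Gaussian graphical model
#'
#' All within-block pairs receive partial correlation `within`, all
#' between-block pairs `between` (before positive-definiteness rescaling,
#' which shrinks every weight by one common factor). Used for community
#' recovery benchmarks.
#'
#' @inheritParams random_sparse_ggm
#' @param block_sizes integer vector of block sizes.
#' @param within,between partial correlation assigned to within- and
#'   between-block pairs.
#' @export
planted_block_ggm <- function(block_sizes, within = 0.35, between = 0.03,
                              n_respondents = 3000, n_categories = 4,
                              min_eig = 0.05, seed = 1) {
  p <- sum(block_sizes)
  comm <- rep(seq_along(block_sizes), block_sizes)
  P <- outer(comm, comm, function(a, b) ifelse(a == b, within, between))
  diag(P) <- 0
  P <- pd_rescale_partial(P, min_eig)$partial
  labels <- paste0("V", seq_len(p))
  thresholds <- replicate(p, equal_prob_thresholds(n_categories), simplify = FALSE)
  new_ggm_spec(P, labels, comm, thresholds, rep(0L, p), n_respondents, seed)
}

#' Covariance matrix implied by a graphical-model spec
#'
#' Reconstructs the precision matrix from the spec's partial correlations
#' (unit-diagonal convention), inverts it, and standardizes to a correlation
#' scale. Partial correlations are invariant to that diagonal
#' standardization, so the round trip
#' `precision_to_partial(solve(ggm_covariance(spec)))` returns
#' `spec$true_partial`.
#'
#' @param spec a `ggm_spec`.
#' @return the implied latent correlation (covariance) matrix.
#' @export
ggm_covariance <- function(spec) {
  stopifnot(inherits(spec, "ggm_spec"))
  K <- partial_to_precision(spec$true_partial)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied precision not positive definite; eigenvalues: ",
         paste(signif(ev, 4), collapse = ", "))
  Sigma <- chol2inv(chol(K))
  Sigma <- stats::cov2cor(Sigma)
  dimnames(Sigma) <- dimnames(spec$true_partial)
  Sigma
}

#' Sample ordinal item responses from a graphical-model spec
#'
#' Draws latent multivariate-Gaussian scores from the spec's implied
#' correlation matrix and discretizes each node by its thresholds into
#' ordinal categories (`level_min .. level_min + K`).
#'
#' @param spec a `ggm_spec`.
#' @param n number of respondents; defaults to `spec$n_respondents`.
#' @param seed RNG seed; defaults to `spec$seed`. Identical seeds give
#'   identical tables.
#' @param latent if `TRUE`, return the continuous latent draws instead of the
#'   discretized responses (useful for closed-form checks).
#' @return an [item_response_table()].
#' @export
sample_ordinal_responses <- function(spec, n = spec$n_respondents,
                                     seed = spec$seed, latent = FALSE) {
  stopifnot(inherits(spec, "ggm_spec"), n >= 1)
  Sigma <- ggm_covariance(spec)
  set.seed(as.integer(seed))
  Z <- MASS::mvrnorm(n, mu = rep(0, ncol(Sigma)), Sigma = Sigma)
  colnames(Z) <- spec$node_labels
  p <- length(spec$node_labels)
  scales <- attr(spec, "scales")
  if (is.null(scales)) scales <- rep("OTHER", p)
  if (latent) {
    meta <- data.frame(item = spec$node_labels, scale = scales,
                       min = -Inf, max = Inf, stringsAsFactors = FALSE)
    return(item_response_table(Z, item_meta = meta))
  }
  X <- matrix(0L, nrow = n, ncol = p, dimnames = list(NULL, spec$node_labels))
  warn <- character(0)
  for (j in seq_len(p)) {
    X[, j] <- spec$level_min[j] + findInterval(Z[, j], spec$thresholds[[j]])
    if (length(unique(X[, j])) == 1L)
      warn <- c(warn, paste0("node ", spec$node_labels[j],
                             " is constant after discretization"))
  }
  n_cat <- vapply(spec$thresholds, length, 1L) + 1L
  meta <- data.frame(item = spec$node_labels, scale = scales,
                     min = spec$level_min, max = spec$level_min + n_cat - 1L,
                     stringsAsFactors = FALSE)
  tab <- item_response_table(X, item_meta = meta)
  if (length(warn)) {
    attr(tab, "warnings") <- warn
    warning(paste(warn, collapse = "; "))
  }
  tab
}

#' Two-group graphical-model specification
#'
#' Derives a second network from a base spec by multiplying every nonzero
#' partial correlation by `strength_multiplier` (applied on the
#' partial-correlation scale, before positive-definiteness repair) and adding
#' planted per-edge differences. Group 1 carries the modified (stronger)
#' network, group 0 the base network — emulating a case/control contrast in
#' which one group's network is globally stronger.
#'
#' @param base a `ggm_spec`.
#' @param strength_multiplier positive factor applied to group 1's nonzero
#'   partials.
#' @param planted_edge_diffs optional data.frame with columns `node_i`,
#'   `node_j`, `delta` added to group 1's partials.
#' @param group_sizes respondents per group `c(n0, n1)`.
#' @param min_eig smallest precision eigenvalue enforced after modification.
#' @return a `two_group_ggm_spec` with elements `base`, `group1`, the
#'   multiplier, the planted differences and `group_sizes`.
#' @export
two_group_ggm <- function(base, strength_multiplier = 1.3,
                          planted_edge_diffs = NULL,
                          group_sizes = c(1000, 1000), min_eig = 0.05) {
  stopifnot(inherits(base, "ggm_spec"), strength_multiplier > 0,
            length(group_sizes) == 2, all(group_sizes >= 1))
  P1 <- base$true_partial * strength_multiplier
  if (!is.null(planted_edge_diffs)) {
    stopifnot(all(c("node_i", "node_j", "delta") %in% names(planted_edge_diffs)))
    for (r in seq_len(nrow(planted_edge_diffs))) {
      i <- match(planted_edge_diffs$node_i[r], base$node_labels)
      j <- match(planted_edge_diffs$node_j[r], base$node_labels)
      if (is.na(i) || is.na(j))
        stop("planted edge refers to unknown node: ",
             planted_edge_diffs$node_i[r], "-", planted_edge_diffs$node_j[r])
      P1[i, j] <- P1[i, j] + planted_edge_diffs$delta[r]
      P1[j, i] <- P1[i, j]
    }
  }
  P1 <- pd_rescale_partial(P1, min_eig)$partial
  g1 <- new_ggm_spec(P1, base$node_labels, base$community_assignment,
                     base$thresholds, base$level_min,
                     group_sizes[2], base$seed + 1L)
  attr(g1, "scales") <- attr(base, "scales")
  structure(list(base = base, group1 = g1,
                 strength_multiplier = strength_multiplier,
                 planted_edge_diffs = planted_edge_diffs,
                 group_sizes = as.integer(group_sizes)),
            class = "two_group_ggm_spec")
}

#' Sample a labelled two-group ordinal dataset
#'
#' @param spec a `two_group_ggm_spec`.
#' @param seed RNG seed.
#' @return an [item_response_table()] with a binary `group` label
#'   (0 = base network, 1 = modified network).
#' @export
sample_two_group_responses <- function(spec, seed = spec$base$seed) {
  stopifnot(inherits(spec, "two_group_ggm_spec"))
  t0 <- sample_ordinal_responses(spec$base, n = spec$group_sizes[1],
                                 seed = derive_seed(seed, 11L))
  t1 <- sample_ordinal_responses(spec$group1, n = spec$group_sizes[2],
                                 seed = derive_seed(seed, 23L))
  values <- rbind(t0$values, t1$values)
  tab <- item_response_table(values, item_meta = t0$item_meta,
                             group = rep(c(0L, 1L), spec$group_sizes))
  tab
}

# canonical 28 analysis nodes of the study design
study_node_labels <- function() {
  c(paste0("PHQ", 1:9), paste0("GAD", 1:7), paste0("IES", 1:6),
    "FW", "PHY", "MF", "FFC", "SSFm", "SSFr")
}

study_node_scales <- function() {
  c(rep("PHQ", 9), rep("GAD", 7), rep("IES", 6),
    rep("STRESSOR", 4), rep("SUPPORT", 2))
}

#' Study-shaped synthetic two-group fixture
#'
#' Builds a 28-node network emulating the analysis layout of a pandemic-era
#' student mental-health survey: 9 depression items (PHQ), 7 anxiety items
#' (GAD), 6 acute-stress items (IES), 4 recoded stressor nodes (finance/work,
#' physical condition, medical care/food, family-or-friend conflicts) and two
#' social-support nodes (family, friends). The three symptom scales form
#' planted communities; stressor and support nodes are weakly connected to
#' symptoms, with negative support-to-suicidality edges. Group 1's network is
#' uniformly stronger (`strength_multiplier`) and carries planted per-edge
#' differences, so the two-group comparison has a known answer.
#'
#' @param seed RNG seed driving both network construction and sampling.
#' @param n_per_group respondents per group (length 1 or 2).
#' @param strength_multiplier group-1 connectivity multiplier.
#' @param n_categories ordinal categories for the symptom items.
#' @return a list with `table` (an [item_response_table()] with `group`) and
#'   `spec` (the generating `two_group_ggm_spec`).
#' @export
study_fixture <- function(seed = 1, n_per_group = c(1000, 1000),
                          strength_multiplier = 1.3, n_categories = 4) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  labels <- study_node_labels()
  scales <- study_node_scales()
  p <- length(labels)
  comm <- c(rep(1L, 9), rep(2L, 7), rep(3L, 6), rep(4L, 6))
  set.seed(derive_seed(seed, 5L))
  P <- matrix(0, p, p, dimnames = list(labels, labels))
  set_edge <- function(a, b, w) {
    P[a, b] <<- w
    P[b, a] <<- w
  }
  scale_block <- function(idx, chain_w = c(0.15, 0.3), extra_prob = 0.35,
                          extra_w = c(0.08, 0.2)) {
    for (k in seq_len(length(idx) - 1))
      set_edge(idx[k], idx[k + 1], runif(1, chain_w[1], chain_w[2]))
    prs <- utils::combn(idx, 2)
    for (c_i in seq_len(ncol(prs))) {
      a <- prs[1, c_i]; b <- prs[2, c_i]
      if (P[a, b] == 0 && runif(1) < extra_prob)
        set_edge(a, b, runif(1, extra_w[1], extra_w[2]))
    }
  }
  scale_block(1:9)       # PHQ
  scale_block(10:16)     # GAD
  scale_block(17:22)     # IES
  # sparse weak cross-scale bridges (comorbidity links)
  cross <- rbind(expand.grid(1:9, 10:16), expand.grid(1:9, 17:22),
                 expand.grid(10:16, 17:22))
  for (r in seq_len(nrow(cross))) {
    a <- cross[r, 1]; b <- cross[r, 2]
    if (runif(1) < 0.08) set_edge(a, b, runif(1, 0.04, 0.1))
  }
  set_edge("PHQ7", "GAD2", 0.12)   # concentration - worry bridge
  set_edge("PHQ8", "GAD6", 0.10)   # psychomotor - irritability bridge
  # stressor block: inter-stressor links, weak links into symptoms
  stressors <- c("FW", "PHY", "MF", "FFC")
  prs <- utils::combn(stressors, 2)
  for (c_i in seq_len(ncol(prs)))
    set_edge(prs[1, c_i], prs[2, c_i], runif(1, 0.1, 0.2))
  for (s in stressors)
    for (sym in labels[1:22])
      if (runif(1) < 0.12) set_edge(s, sym, runif(1, 0.03, 0.08))
  set_edge("FFC", "GAD6", 0.10)    # conflicts - irritability
  set_edge("PHY", "IES1", 0.06)
  # support: mutually positive, protective (negative) edges into symptoms
  set_edge("SSFm", "SSFr", 0.30)
  set_edge("SSFm", "PHQ9", -0.09)
  set_edge("SSFm", "PHQ3", -0.05)
  set_edge("SSFm", "GAD6", -0.05)
  set_edge("SSFr", "PHQ9", -0.05)
  P <- pd_rescale_partial(P, 0.05)$partial
  thresholds <- c(
    replicate(22, equal_prob_thresholds(n_categories), simplify = FALSE),
    replicate(4, equal_prob_thresholds(3), simplify = FALSE),
    replicate(2, equal_prob_thresholds(7), simplify = FALSE)
  )
  level_min <- c(rep(0L, 26), 1L, 1L)  # support items run 1..7
  base <- new_ggm_spec(P, labels, comm, thresholds, level_min,
                       n_per_group[1], derive_seed(seed, 7L))
  attr(base, "scales") <- scales
  planted <- data.frame(
    node_i = c("PHQ9", "GAD4", "GAD4", "IES3", "IES1", "PHQ5"),
    node_j = c("GAD1", "GAD7", "IES4", "SSFr", "PHY", "FFC"),
    delta = c(0.07, 0.16, 0.085, 0.045, 0.13, 0.064),
    stringsAsFactors = FALSE
  )
  spec2 <- two_group_ggm(base, strength_multiplier = strength_multiplier,
                         planted_edge_diffs = planted,
                         group_sizes = n_per_group)
  table <- sample_two_group_responses(spec2, seed = derive_seed(seed, 41L))
  list(table = table, spec = spec2)
}

#' @export
print.ggm_spec <- function(x, ...) {
  p <- length(x$node_labels)
  ne <- sum(x$true_partial[upper.tri(x$true_partial)] != 0)
  cat("Gaussian graphical model spec:", p, "nodes,", ne, "true edges,",
      length(unique(x$community_assignment)), "communities\n")
  cat("default sample size:", x$n_respondents, " seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate responses from a graphical-model spec
#'
#' `simulate()` method wrapper around [sample_ordinal_responses()].
#'
#' @param object a `ggm_spec`.
#' @param nsim number of datasets.
#' @param seed RNG seed for the first dataset.
#' @param ... passed to [sample_ordinal_responses()].
#' @export
simulate.ggm_spec <- function(object, nsim = 1, seed = object$seed, ...) {
  out <- lapply(seq_len(nsim), function(i)
    sample_ordinal_responses(object, seed = seed + i - 1L, ...))
  if (nsim == 1) out[[1]] else out
}

#' Serialize a graphical-model spec to JSON
#'
#' @param spec a `ggm_spec`.
#' @param path output file.
#' @export
write_ggm_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ggm_spec"))
  obj <- list(
    n_respondents = spec$n_respondents,
    node_labels = spec$node_labels,
    true_partial = as.vector(t(spec$true_partial)),  # row-major
    community_assignment = unname(spec$community_assignment),
    thresholds = unname(spec$thresholds),
    level_min = unname(spec$level_min),
    seed = spec$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a graphical-model spec from JSON
#'
#' @param path JSON file written by [write_ggm_spec()].
#' @export
read_ggm_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$node_labels)
  P <- matrix(obj$true_partial, p, p, byrow = TRUE)
  thr <- if (is.matrix(obj$thresholds)) {
    lapply(seq_len(nrow(obj$thresholds)), function(i) obj$thresholds[i, ])
  } else as.list(obj$thresholds)
  new_ggm_spec(P, obj$node_labels, obj$community_assignment, thr,
               obj$level_min, obj$n_respondents, obj$seed)
}
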