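#' Bonferroni-Holm step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th by `m - i + 1`, enforces
#' monotonicity, caps at 1 and returns the adjusted values in the original
#' order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "holm")
}

#' Permutation network comparison test (NCT)
#'
#' Tests whether two groups share the same network by re-estimating both
#' group networks under random permutations of the group labels (group sizes
#' preserved) with the identical EBIC graphical lasso pipeline used for the
#' observed networks. Three invariances are examined in one permutation
#' pass:
#' \itemize{
#'   \item network structure: `M`, the maximum absolute edge-weight
#'     difference;
#'   \item global strength: `S`, the absolute difference of the sums of
#'     absolute edge weights;
#'   \item individual edges: per-edge absolute differences over the family of
#'     edges present in at least one observed group network, with
#'     Bonferroni-Holm correction.
#' }
#' P-values use the permutation-inclusive estimator
#' `(1 + #\{perm >= observed\}) / (1 + n_perm)`, which is never zero and valid
#' under label exchangeability. Permutations whose estimation fails are
#' redrawn (bounded retries) and counted.
#'
#' @param data_g1,data_g2 respondent x node matrices of the two groups
#'   (identical node sets).
#' @param n_perm number of permutations.
#' @param seed RNG seed (123 by convention for this test).
#' @param gamma EBIC hyperparameter.
#' @param edge_tests run the per-edge invariance tests.
#' @param min_n minimal group size accepted.
#' @param ... further arguments to [ebic_glasso()].
#' @return object of class `nct_result`: observed `M`, `S`, permutation
#'   p-values `p_M`, `p_S`, per-group global strengths, per-edge table
#'   (observed |difference|, raw and Holm-adjusted p), the group fits and
#'   permutation counts.
#' @export
nct <- function(data_g1, data_g2, n_perm = 1000, seed = 123, gamma = 0.5,
                edge_tests = TRUE, min_n = 20, ...) {
  X1 <- as.matrix(unclass(data_g1))
  X2 <- as.matrix(unclass(data_g2))
  if (!identical(colnames(X1), colnames(X2)))
    stop("the two groups must share the same node set")
  if (nrow(X1) < min_n || nrow(X2) < min_n)
    stop("each group needs at least ", min_n, " respondents")
  n1 <- nrow(X1)
  pooled <- rbind(X1, X2)
  n <- nrow(pooled)

  fit1 <- ebic_glasso(X1, gamma = gamma, ...)
  fit2 <- ebic_glasso(X2, gamma = gamma, ...)
  W1 <- fit1$weights
  W2 <- fit2$weights
  p <- nrow(W1)
  pairs <- edge_pairs(p)
  diff_obs <- abs(W1 - W2)[pairs]
  M_obs <- if (length(diff_obs)) max(diff_obs) else 0
  gs1 <- global_strength(W1)
  gs2 <- global_strength(W2)
  S_obs <- abs(gs1 - gs2)

  family <- which(W1[pairs] != 0 | W2[pairs] != 0)

  set.seed(as.integer(seed))
  M_perm <- numeric(n_perm)
  S_perm <- numeric(n_perm)
  ge_edge <- if (edge_tests && length(family))
    integer(length(family)) else integer(0)
  n_retried <- 0L
  for (b in seq_len(n_perm)) {
    ok <- FALSE
    for (try in 1:10) {
      idx <- sample.int(n, n1, replace = FALSE)
      f1 <- tryCatch(ebic_glasso(pooled[idx, , drop = FALSE],
                                 gamma = gamma, ...),
                     error = function(e) NULL)
      f2 <- tryCatch(ebic_glasso(pooled[-idx, , drop = FALSE],
                                 gamma = gamma, ...),
                     error = function(e) NULL)
      if (!is.null(f1) && !is.null(f2)) {
        ok <- TRUE
        break
      }
      n_retried <- n_retried + 1L
    }
    if (!ok) stop("permutation estimation kept failing after 10 retries")
    dperm <- abs(f1$weights - f2$weights)[pairs]
    M_perm[b] <- if (length(dperm)) max(dperm) else 0
    S_perm[b] <- abs(global_strength(f1$weights) - global_strength(f2$weights))
    if (length(ge_edge))
      ge_edge <- ge_edge + as.integer(dperm[family] >= diff_obs[family])
  }
  p_M <- (1 + sum(M_perm >= M_obs)) / (1 + n_perm)
  p_S <- (1 + sum(S_perm >= S_obs)) / (1 + n_perm)

  edge_table <- NULL
  if (edge_tests) {
    raw <- (1 + ge_edge) / (1 + n_perm)
    edge_table <- data.frame(
      node_i = rownames(W1)[pairs[family, 1]],
      node_j = colnames(W1)[pairs[family, 2]],
      weight_g1 = W1[pairs[family, , drop = FALSE]],
      weight_g2 = W2[pairs[family, , drop = FALSE]],
      abs_difference = diff_obs[family],
      p_raw = raw,
      p_holm = if (length(raw)) holm_adjust(raw) else numeric(0),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    observed_M = M_obs, observed_S = S_obs,
    p_M = p_M, p_S = p_S,
    global_strength_g1 = gs1, global_strength_g2 = gs2,
    edge_table = edge_table,
    fit_g1 = fit1, fit_g2 = fit2,
    n_permutations = n_perm, seed = as.integer(seed),
    n_retried = n_retried,
    M_perm = M_perm, S_perm = S_perm
  ), class = "nct_result")
}

#' @export
print.nct_result <- function(x, digits = 3, ...) {
  cat("Permutation network comparison test (", x$n_permutations,
      "permutations, seed", x$seed, ")\n")
  cat(sprintf("  global strength: %.2f vs %.2f;  S = %.2f, p = %.3g\n",
              x$global_strength_g1, x$global_strength_g2,
              x$observed_S, x$p_S))
  cat(sprintf("  network structure: M = %.2f, p = %.3g\n",
              x$observed_M, x$p_M))
  if (!is.null(x$edge_table)) {
    ns <- sum(x$edge_table$p_holm <= 0.05)
    cat("  per-edge tests:", nrow(x$edge_table), "edges in family,",
        ns, "significant after Holm correction\n")
  }
  invisible(x)
}

#' Significant edge differences between the two group networks
#'
#' Table of edges whose Holm-adjusted permutation p-value is at most
#' `alpha`, with the partial correlation of the edge in each group.
#'
#' @param result an `nct_result` fitted with `edge_tests = TRUE`.
#' @param alpha significance level.
#' @export
edge_difference_report <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "nct_result"))
  if (is.null(result$edge_table))
    stop("per-edge tests were not run")
  tab <- result$edge_table
  out <- tab[tab$p_holm <= alpha,
             c("node_i", "node_j", "weight_g1", "weight_g2", "p_holm"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an NCT result as JSON (+ optional edge-table CSV)
#'
#' @param result an `nct_result`.
#' @param path JSON output path.
#' @param edge_csv optional CSV path for the per-edge table.
#' @export
write_nct <- function(result, path, edge_csv = NULL) {
  stopifnot(inherits(result, "nct_result"))
  obj <- list(observed_M = result$observed_M, observed_S = result$observed_S,
              p_M = result$p_M, p_S = result$p_S,
              global_strength_g1 = result$global_strength_g1,
              global_strength_g2 = result$global_strength_g2,
              n_permutations = result$n_permutations, seed = result$seed,
              n_retried = result$n_retried)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(edge_csv) && !is.null(result$edge_table))
    write.csv(result$edge_table, edge_csv, row.names = FALSE)
  invisible(path)
}
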