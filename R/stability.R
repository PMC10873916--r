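#' Nonparametric bootstrap of the network estimate
#'
#' Resamples respondents with replacement `B` times and re-runs the full
#' estimation pipeline (Spearman correlations, positive-definiteness repair,
#' EBIC graphical lasso with the same settings as the original fit) on each
#' replicate, collecting edge weights and node expected influence. Replicates
#' whose estimation fails are excluded and counted.
#'
#' @param data respondent x node matrix.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed (replicate index streams derive from it).
#' @param gamma EBIC hyperparameter.
#' @param indices optional list of row-index vectors overriding the random
#'   resampling (used for exactness checks).
#' @param ... further arguments to [ebic_glasso()].
#' @return object of class `network_bootstrap`: full-sample `fit`, arrays
#'   `weights` (p x p x B) and `ei` (p x B), `n_failed`, `B`, `seed`.
#' @export
bootstrap_networks <- function(data, B = 1000, seed = 1, gamma = 0.5,
                               indices = NULL, ...) {
  stopifnot(B >= 1)
  X <- as.matrix(unclass(data))
  full <- ebic_glasso(X, gamma = gamma, ...)
  p <- length(full$labels)
  weights <- array(NA_real_, dim = c(p, p, B),
                   dimnames = list(full$labels, full$labels, NULL))
  ei <- matrix(NA_real_, p, B, dimnames = list(full$labels, NULL))
  failed <- logical(B)
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    idx <- if (is.null(indices)) sample.int(nrow(X), replace = TRUE)
           else indices[[b]]
    rep_fit <- tryCatch(ebic_glasso(X[idx, , drop = FALSE], gamma = gamma, ...),
                        error = function(e) NULL)
    if (is.null(rep_fit)) {
      failed[b] <- TRUE
      next
    }
    weights[, , b] <- rep_fit$weights
    ei[, b] <- expected_influence(rep_fit)
  }
  structure(list(fit = full, weights = weights, ei = ei,
                 n_failed = sum(failed), B = B, seed = as.integer(seed),
                 gamma = gamma),
            class = "network_bootstrap")
}

#' @export
print.network_bootstrap <- function(x, ...) {
  cat("Network bootstrap:", x$B, "replicates (", x$n_failed, "failed ),",
      length(x$fit$labels), "nodes\n")
  invisible(x)
}

#' Bootstrap percentile confidence intervals for edge weights
#'
#' @param ensemble a `network_bootstrap`.
#' @param level confidence level (percentile rule, e.g. 2.5/97.5 at 0.95).
#' @return data.frame with `node_i`, `node_j`, `estimate` (full sample),
#'   `boot_mean`, `lower`, `upper`.
#' @export
edge_ci <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "network_bootstrap"))
  ok <- !is.na(ensemble$ei[1, ])
  if (!any(ok)) stop("no successful bootstrap replicates")
  W <- ensemble$weights[, , ok, drop = FALSE]
  p <- dim(W)[1]
  pairs <- edge_pairs(p)
  a <- (1 - level) / 2
  out <- data.frame(
    node_i = rownames(W)[pairs[, 1]],
    node_j = colnames(W)[pairs[, 2]],
    estimate = ensemble$fit$weights[pairs],
    boot_mean = NA_real_, lower = NA_real_, upper = NA_real_,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(pairs))) {
    v <- W[pairs[r, 1], pairs[r, 2], ]
    out$boot_mean[r] <- mean(v)
    q <- quantile(v, c(a, 1 - a), names = FALSE)
    out$lower[r] <- q[1]
    out$upper[r] <- q[2]
  }
  out
}

#' Bootstrapped difference test between two edges or two nodes
#'
#' Two elements differ significantly when the bootstrap percentile interval
#' of their difference excludes zero.
#'
#' @param ensemble a `network_bootstrap`.
#' @param a,b the two elements: for `type = "edge"`, length-2 vectors of node
#'   names (or indices); for `type = "ei"`, single node names.
#' @param type compare edge weights or node expected influence.
#' @param level confidence level.
#' @return list with `significant`, `ci`, `observed_difference`.
#' @export
difference_test <- function(ensemble, a, b, type = c("edge", "ei"),
                            level = 0.95) {
  stopifnot(inherits(ensemble, "network_bootstrap"))
  type <- match.arg(type)
  ok <- !is.na(ensemble$ei[1, ])
  if (type == "edge") {
    va <- ensemble$weights[a[1], a[2], ok]
    vb <- ensemble$weights[b[1], b[2], ok]
    obs <- ensemble$fit$weights[a[1], a[2]] - ensemble$fit$weights[b[1], b[2]]
  } else {
    ei_full <- expected_influence(ensemble$fit)
    va <- ensemble$ei[a, ok]
    vb <- ensemble$ei[b, ok]
    obs <- ei_full[a] - ei_full[b]
  }
  alpha <- (1 - level) / 2
  ci <- quantile(va - vb, c(alpha, 1 - alpha), names = FALSE)
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       observed_difference = unname(obs))
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion, repeatedly re-estimates the network on random
#' subsets containing `(1 - proportion)` of the respondents (sampling
#' without replacement) and records the correlation between the subset and
#' full-sample expected-influence vectors.
#'
#' @param data respondent x node matrix.
#' @param proportions strictly increasing drop proportions in (0, 1).
#' @param B subsamples per proportion.
#' @param seed RNG seed.
#' @param gamma EBIC hyperparameter.
#' @param method correlation between subset and full-sample centrality
#'   (`"spearman"` rank stability by default).
#' @param ... further arguments to [ebic_glasso()].
#' @return object of class `case_drop_profile`: matrix `correlations`
#'   (proportions x B), `proportions`, `B`, counts of failed fits.
#' @export
case_dropping_bootstrap <- function(data, proportions = seq(0.05, 0.75, by = 0.05),
                                    B = 100, seed = 1, gamma = 0.5,
                                    method = c("spearman", "pearson"), ...) {
  method <- match.arg(method)
  stopifnot(all(diff(proportions) > 0), all(proportions > 0),
            max(proportions) < 1, B >= 1)
  X <- as.matrix(unclass(data))
  n <- nrow(X)
  full_ei <- expected_influence(ebic_glasso(X, gamma = gamma, ...))
  cors <- matrix(NA_real_, length(proportions), B,
                 dimnames = list(paste0("drop_", proportions), NULL))
  failed <- integer(length(proportions))
  set.seed(as.integer(seed))
  for (i in seq_along(proportions)) {
    m <- floor((1 - proportions[i]) * n)
    if (m < ncol(X) + 2) {
      failed[i] <- B
      next
    }
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = FALSE)
      fit <- tryCatch(ebic_glasso(X[idx, , drop = FALSE], gamma = gamma, ...),
                      error = function(e) NULL)
      if (is.null(fit)) {
        failed[i] <- failed[i] + 1L
        next
      }
      ei <- expected_influence(fit)
      cors[i, b] <- suppressWarnings(cor(ei, full_ei, method = method))
    }
  }
  structure(list(correlations = cors, proportions = proportions, B = B,
                 n_failed = failed, full_ei = full_ei, seed = as.integer(seed),
                 method = method),
            class = "case_drop_profile")
}

#' @export
print.case_drop_profile <- function(x, ...) {
  med <- apply(x$correlations, 1, stats::median, na.rm = TRUE)
  cat("Case-dropping stability profile (", x$B, "subsamples per proportion )\n")
  print(round(setNames(med, paste0(x$proportions)), 3))
  invisible(x)
}

#' Correlation stability (CS) coefficient
#'
#' The largest tested drop proportion at which, with probability at least
#' `certainty`, the subset centrality still correlates at least
#' `cor_threshold` with the full-sample centrality; 0 when no tested
#' proportion qualifies. Values above 0.5 indicate good stability, values
#' above 0.25 moderate stability.
#'
#' @param profile a `case_drop_profile`.
#' @param cor_threshold correlation that must be retained (0.7 by default).
#' @param certainty required share of subsamples retaining it.
#' @export
cs_coefficient <- function(profile, cor_threshold = 0.7, certainty = 0.95) {
  stopifnot(inherits(profile, "case_drop_profile"))
  share <- apply(profile$correlations >= cor_threshold, 1, mean, na.rm = TRUE)
  ok <- !is.na(share) & share >= certainty
  if (!any(ok)) return(0)
  max(profile$proportions[ok])
}

#' Write bootstrap edge summaries / stability profile as CSV
#'
#' @param x a `network_bootstrap` or `case_drop_profile`.
#' @param path CSV file path.
#' @export
write_stability_csv <- function(x, path) {
  if (inherits(x, "network_bootstrap")) {
    write.csv(edge_ci(x), path, row.names = FALSE)
  } else if (inherits(x, "case_drop_profile")) {
    qs <- t(apply(x$correlations, 1, quantile,
                  probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
    df <- data.frame(proportion = x$proportions, qs, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
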