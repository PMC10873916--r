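#' Penalty grid for the graphical lasso path
#'
#' Log-spaced, strictly decreasing grid from `lambda_max` (the largest
#' absolute off-diagonal correlation, above which the estimated network is
#' empty) down to `lambda_max * min_ratio`.
#'
#' @param S correlation matrix.
#' @param n_lambda grid length.
#' @param min_ratio ratio of the smallest to the largest penalty.
#' @export
lambda_grid <- function(S, n_lambda = 100, min_ratio = 0.01) {
  S <- unclass(S)
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max == 0) {
    warning("all off-diagonal correlations are zero; single lambda = 0 grid")
    return(0)
  }
  if (n_lambda == 1) return(lam_max)
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
}

#' Graphical lasso estimate at a single penalty
#'
#' Maximizes `log det K - tr(SK) - lambda * sum_{i != j} |K_ij|` over
#' positive-definite matrices (diagonal unpenalized) by blockwise coordinate
#' descent, returning exact zeros on shrunk entries. With `lambda = 0` the
#' unpenalized maximum-likelihood estimate `solve(S)` is returned directly.
#'
#' @param S positive-definite correlation/covariance matrix.
#' @param lambda penalty (>= 0).
#' @param tol relative convergence tolerance.
#' @param maxit maximum outer sweeps.
#' @return estimated precision matrix.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-8, maxit = 500) {
  S <- unclass(S)
  S <- (S + t(S)) / 2
  stopifnot(lambda >= 0)
  if (lambda == 0) {
    K <- chol2inv(chol(S))
    dimnames(K) <- dimnames(S)
    return(K)
  }
  res <- glasso_path_cpp(S, lambda, tol, maxit, maxit)
  if (!res$converged[1])
    stop("graphical lasso did not converge within ", maxit,
         " sweeps (lambda = ", signif(lambda, 4), ")")
  K <- res$precisions[, , 1]
  dimnames(K) <- dimnames(S)
  K
}

#' Gaussian log-likelihood of a precision matrix
#'
#' `L = (n/2) * (log det K - tr(S K))`, additive constants dropped.
#'
#' @param S sample correlation/covariance matrix.
#' @param K positive-definite precision matrix.
#' @param n sample size.
#' @export
gaussian_loglik <- function(S, K, n) {
  S <- unclass(S)
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) stop("precision matrix must be positive definite")
  (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
}

# number of nonzero off-diagonal upper-triangle entries (numerical zero 1e-10)
count_edges <- function(K, zero_tol = 1e-10) {
  sum(abs(K[upper.tri(K)]) > zero_tol)
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 L + E log n + 4 E gamma log p`, where `E` counts nonzero
#' off-diagonal upper-triangle entries of the regularized precision matrix.
#' `gamma = 0` recovers the ordinary BIC penalty; `gamma = 0.5` (the default
#' used throughout) trades goodness of fit for sparsity to suppress false
#' positive edges.
#'
#' @param L Gaussian log-likelihood ([gaussian_loglik()] convention).
#' @param K regularized precision matrix.
#' @param n sample size.
#' @param gamma EBIC hyperparameter (>= 0).
#' @export
ebic <- function(L, K, n, gamma = 0.5) {
  stopifnot(gamma >= 0)
  p <- nrow(K)
  E <- count_edges(K)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Fit a regularized partial-correlation network (EBIC graphical lasso)
#'
#' The central fitting function: estimates a sparse Gaussian graphical model
#' by running the graphical lasso over a decreasing penalty path and
#' selecting the penalty minimizing the EBIC. Edge weights are the partial
#' correlations implied by the selected precision matrix.
#'
#' @param x either a respondent x node data matrix (Spearman correlations
#'   are computed, with positive-definiteness repair) or an already-computed
#'   correlation matrix (then `n` is required).
#' @param n sample size (only when `x` is a correlation matrix).
#' @param gamma EBIC hyperparameter; 0.5 by default.
#' @param n_lambda,lambda_min_ratio penalty path controls
#'   (see [lambda_grid()]).
#' @param node_groups optional per-node scale membership (used by plots and
#'   community summaries); inferred from a `node_matrix` input.
#' @param tol,maxit optimizer controls, see [glasso_fit()].
#' @return an object of class `ggm_fit` with components `weights` (partial
#'   correlation matrix, zero diagonal), `precision`, `labels`,
#'   `node_groups`, `correlation`, `n`, `gamma`, and `path`
#'   (lambdas, log-likelihoods, EBIC values, edge counts, selected index).
#' @examples
#' spec <- random_sparse_ggm(p = 8, edge_density = 0.25, seed = 7)
#' tab <- sample_ordinal_responses(spec, n = 500)
#' fit <- ebic_glasso(tab$values)
#' fit
#' @export
ebic_glasso <- function(x, n = NULL, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01, node_groups = NULL,
                        tol = 1e-4, maxit = 200) {
  if (inherits(x, "item_response_table")) x <- x$values
  if (is.null(node_groups) && !is.null(attr(x, "node_groups")))
    node_groups <- attr(x, "node_groups")
  if (is_symmetric_num(unclass(x)) && all(abs(diag(unclass(x)) - 1) < 1e-8)) {
    S <- unclass(x)
    if (is.null(n)) stop("sample size n is required with a correlation input")
  } else {
    S <- spearman_matrix(x)
    n <- attr(S, "n_effective")
    perfect <- which(abs(S) >= 1 - 1e-12 & upper.tri(S), arr.ind = TRUE)
    if (nrow(perfect))
      stop("perfectly correlated columns: ",
           paste(rownames(S)[perfect[1, 1]], colnames(S)[perfect[1, 2]],
                 sep = " / "))
    S <- unclass(nearest_positive_definite(S))
  }
  S <- (S + t(S)) / 2
  p <- nrow(S)
  labels <- colnames(S)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  dimnames(S) <- list(labels, labels)
  lambdas <- lambda_grid(S, n_lambda = n_lambda, min_ratio = lambda_min_ratio)
  if (identical(lambdas, 0)) {
    Ks <- array(diag(1 / diag(S)), dim = c(p, p, 1))
  } else {
    res <- glasso_path_cpp(S, lambdas, tol, maxit, maxit)
    Ks <- res$precisions
  }
  nl <- length(lambdas)
  logliks <- numeric(nl)
  ebics <- numeric(nl)
  n_edges <- integer(nl)
  for (l in seq_len(nl)) {
    K <- Ks[, , l]
    logliks[l] <- gaussian_loglik(S, K, n)
    ebics[l] <- ebic(logliks[l], K, n, gamma)
    n_edges[l] <- count_edges(K)
  }
  sel <- which.min(ebics)
  K <- Ks[, , sel]
  K[abs(K) < 1e-10 & row(K) != col(K)] <- 0
  dimnames(K) <- list(labels, labels)
  W <- precision_to_partial(K)
  structure(list(
    weights = W,
    precision = K,
    labels = labels,
    node_groups = node_groups,
    correlation = S,
    n = n,
    gamma = gamma,
    path = list(lambdas = lambdas, logliks = logliks, ebics = ebics,
                n_edges = n_edges, selected = sel,
                lambda = lambdas[sel])
  ), class = "ggm_fit")
}

#' Estimate a network directly from a node data matrix
#'
#' Convenience composition: Spearman correlations, positive-definiteness
#' repair, EBIC graphical lasso.
#'
#' @inheritParams ebic_glasso
#' @param data respondent x node matrix.
#' @export
estimate_network <- function(data, gamma = 0.5, ...) {
  ebic_glasso(data, gamma = gamma, ...)
}
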