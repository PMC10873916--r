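#' @useDynLib symptomnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor quantile var lm pnorm qnorm rnorm runif setNames
#'   p.adjust chisq.test coef residuals predict simulate
#' @importFrom utils write.csv head
NULL

# coerce a ggm_fit / weighted matrix argument to a plain symmetric weight
# matrix with zero diagonal and node labels
as_weight_matrix <- function(x) {
  if (inherits(x, "ggm_fit")) x <- x$weights
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("expected a square weight matrix or a 'ggm_fit' object")
  if (max(abs(x - t(x))) > 1e-8) stop("weight matrix must be symmetric")
  diag(x) <- 0
  if (is.null(rownames(x))) {
    lab <- paste0("V", seq_len(nrow(x)))
    dimnames(x) <- list(lab, lab)
  }
  x
}

# upper-triangle edge index pairs of a p x p matrix
edge_pairs <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

is_symmetric_num <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol
}

min_eigenvalue <- function(x) min(eigen(x, symmetric = TRUE, only.values = TRUE)$values)

# sub-seed derivation so that independent stages draw from independent streams
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1009L
}
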