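#' Spearman correlation matrix of the node data
#'
#' Rank correlations (midrank tie handling) over complete cases, the input
#' to regularized network estimation. Spearman is preferred over Pearson for
#' ordinal Likert items because it is invariant to monotone transforms and
#' more stable under skewed margins.
#'
#' @param data numeric respondent x node matrix (a `node_matrix` or plain
#'   matrix / data.frame) without missing values.
#' @return symmetric correlation matrix with unit diagonal and attributes
#'   `n_effective` (rows used) and class `correlation_matrix`.
#' @export
spearman_matrix <- function(data) {
  x <- as.matrix(unclass(data))
  storage.mode(x) <- "double"
  if (nrow(x) < 3) stop("need at least 3 observations")
  if (anyNA(x)) stop("missing values present; filter complete cases first")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  C <- cor(x, method = "spearman")
  C <- (C + t(C)) / 2
  diag(C) <- 1
  attr(C, "n_effective") <- nrow(x)
  class(C) <- c("correlation_matrix", "matrix")
  C
}

#' Nearest positive-definite correlation matrix
#'
#' Returns the input unchanged when its smallest eigenvalue already reaches
#' `eps`; otherwise projects to the nearest correlation matrix (Higham
#' alternating projections, via [Matrix::nearPD()]) and, if needed, blends
#' with the identity so the smallest eigenvalue is at least `eps`. The unit
#' diagonal is always restored.
#'
#' @param C symmetric matrix with unit diagonal.
#' @param eps lower bound for the smallest eigenvalue.
#' @export
nearest_positive_definite <- function(C, eps = 1e-8) {
  C <- unclass(C)
  if (!is_symmetric_num(C)) stop("input must be symmetric")
  atts <- attributes(C)["n_effective"]
  if (min_eigenvalue(C) >= eps) {
    out <- C
  } else {
    out <- as.matrix(Matrix::nearPD(C, corr = TRUE, eig.tol = 1e-10,
                                    posd.tol = 1e-10)$mat)
    lmin <- min_eigenvalue(out)
    if (lmin < eps) {
      d <- (eps - lmin) / (1 - eps)
      out <- (out + d * diag(nrow(out))) / (1 + d)
    }
    dimnames(out) <- dimnames(C)
  }
  diag(out) <- 1
  attr(out, "n_effective") <- atts$n_effective
  class(out) <- c("correlation_matrix", "matrix")
  out
}

#' Write a labelled correlation matrix as CSV
#'
#' @param C correlation matrix.
#' @param path CSV file path.
#' @export
write_correlation_csv <- function(C, path) {
  write.csv(as.data.frame(unclass(C)), path, row.names = TRUE)
  invisible(path)
}
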