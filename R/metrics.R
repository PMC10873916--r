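#' Node expected influence
#'
#' One-step expected influence: the signed sum of a node's edge weights,
#' `EI_i = sum_{j != i} w_ij`. Unlike strength centrality it respects edge
#' valence, which matters in networks with protective (negative) edges.
#'
#' @param W a `ggm_fit` or symmetric weight matrix.
#' @return named numeric vector.
#' @export
expected_influence <- function(W) {
  W <- as_weight_matrix(W)
  rowSums(W)
}

#' Bridge expected influence
#'
#' One-step bridge expected influence: the signed sum of a node's edges to
#' nodes outside its own community, flagging symptoms that connect
#' communities (e.g. disorders).
#'
#' @param W a `ggm_fit` or symmetric weight matrix.
#' @param partition community membership: a `community_partition` or a named
#'   vector of community ids covering every node.
#' @return named numeric vector.
#' @export
bridge_expected_influence <- function(W, partition) {
  W <- as_weight_matrix(W)
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  if (!is.null(names(memb))) {
    if (!all(rownames(W) %in% names(memb)))
      stop("partition is missing nodes: ",
           paste(setdiff(rownames(W), names(memb)), collapse = ", "))
    memb <- memb[rownames(W)]
  } else if (length(memb) != nrow(W)) {
    stop("partition length does not match the number of nodes")
  }
  cross <- outer(memb, memb, "!=")
  out <- rowSums(W * cross)
  names(out) <- rownames(W)
  out
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over all unordered node pairs.
#'
#' @param W a `ggm_fit` or symmetric weight matrix.
#' @export
global_strength <- function(W) {
  W <- as_weight_matrix(W)
  sum(abs(W[upper.tri(W)]))
}

#' Nodewise predictability
#'
#' Share of each node's variance explained by its network neighbours: for
#' every node an ordinary least-squares regression on the nodes it shares a
#' nonzero edge with, reporting the in-sample R-squared. Isolated nodes have
#' predictability 0. Rank-deficient neighbour designs are handled by
#' pivoting (aliased columns dropped), flagged in attribute `aliased`.
#'
#' @param fit a `ggm_fit` (or weight matrix).
#' @param data respondent x node matrix the network was estimated from.
#' @return named vector of R-squared values in `[0, 1]`.
#' @export
predictability <- function(fit, data) {
  W <- as_weight_matrix(fit)
  X <- as.matrix(unclass(data))[, rownames(W), drop = FALSE]
  storage.mode(X) <- "double"
  r2 <- setNames(numeric(nrow(W)), rownames(W))
  aliased <- character(0)
  for (j in seq_len(nrow(W))) {
    nb <- which(W[j, ] != 0)
    if (!length(nb)) next
    fit_j <- lm(X[, j] ~ X[, nb, drop = FALSE])
    if (any(is.na(coef(fit_j)))) aliased <- c(aliased, rownames(W)[j])
    y <- X[, j]
    r2[j] <- 1 - sum(residuals(fit_j)^2) / sum((y - mean(y))^2)
  }
  r2 <- pmin(pmax(r2, 0), 1)
  if (length(aliased)) attr(r2, "aliased") <- aliased
  r2
}

#' Model-implied predictability
#'
#' For a Gaussian graphical model on unit-variance variables the population
#' R-squared of node j given all others is `1 - 1 / kappa_jj` where `kappa`
#' is the precision of the correlation-scale covariance. Used as a
#' closed-form cross-check of [predictability()].
#'
#' @param K precision matrix of a unit-variance (correlation-scale) model.
#' @export
implied_predictability <- function(K) {
  Sigma <- stats::cov2cor(chol2inv(chol(K)))
  Kc <- chol2inv(chol(Sigma))
  out <- 1 - 1 / diag(Kc)
  names(out) <- rownames(K)
  out
}

#' Node centrality table
#'
#' Expected influence, optional bridge expected influence and
#' predictability for every node, plus the network's global strength as an
#' attribute. Z-scored columns (the usual centrality-plot axis) can be added.
#'
#' @param fit a `ggm_fit` or weight matrix.
#' @param data optional data matrix; enables the predictability column.
#' @param partition optional community partition; enables the bridge column.
#' @param z_scores add z-standardized columns.
#' @return data.frame with one row per node; attribute `global_strength`.
#' @export
centrality_table <- function(fit, data = NULL, partition = NULL,
                             z_scores = FALSE) {
  W <- as_weight_matrix(fit)
  out <- data.frame(node = rownames(W),
                    expected_influence = expected_influence(W),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(partition))
    out$bridge_expected_influence <- bridge_expected_influence(W, partition)
  if (!is.null(data))
    out$predictability <- unname(predictability(W, data))
  if (z_scores) {
    for (cn in setdiff(names(out), c("node", "predictability")))
      out[[paste0(cn, "_z")]] <- as.numeric(scale(out[[cn]]))
  }
  attr(out, "global_strength") <- global_strength(W)
  out
}
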