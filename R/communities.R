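#' Walktrap community detection on a weighted network
#'
#' Runs the walktrap algorithm (short random walks over the network,
#' agglomerative merging, cut chosen to maximize weighted modularity) on the
#' absolute edge weights — negative partial correlations cannot serve as
#' transition probabilities, so connection strength is what drives the walk,
#' while edge signs remain available to bridge centrality. The algorithm is
#' deterministic: identical weight matrices give identical partitions.
#' Isolated nodes become singleton communities and are flagged.
#'
#' @param W a `ggm_fit` or symmetric weight matrix with at least one edge.
#' @param steps random-walk length (4 by convention).
#' @return object of class `community_partition`: named `membership`
#'   (contiguous ids from 1), `n_communities`, `modularity`, `merges`
#'   (dendrogram merge matrix), `isolated` node names.
#' @export
walktrap_communities <- function(W, steps = 4) {
  W <- as_weight_matrix(W)
  A <- abs(W)
  if (all(A == 0)) stop("network has no edges")
  deg <- rowSums(A)
  isolated <- rownames(A)[deg == 0]
  keep <- deg > 0
  g <- igraph::graph_from_adjacency_matrix(A[keep, keep, drop = FALSE],
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wt <- igraph::cluster_walktrap(g, steps = steps,
                                 merges = TRUE, modularity = TRUE)
  memb_core <- igraph::membership(wt)
  membership <- integer(nrow(A))
  names(membership) <- rownames(A)
  membership[keep] <- as.integer(memb_core)
  if (length(isolated))
    membership[!keep] <- max(memb_core) + seq_along(isolated)
  structure(list(
    membership = membership,
    n_communities = length(unique(membership)),
    modularity = net_modularity(W, membership),
    merges = wt$merges,
    isolated = isolated,
    steps = steps
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities, modularity",
      round(x$modularity, 3), "\n")
  for (cid in sort(unique(x$membership)))
    cat("  [", cid, "] ",
        paste(names(x$membership)[x$membership == cid], collapse = " "),
        "\n", sep = "")
  if (length(x$isolated))
    cat("  isolated nodes:", paste(x$isolated, collapse = ", "), "\n")
  invisible(x)
}

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c (e_cc - a_c^2)` on absolute edge weights, where `e_cc` is the
#' fraction of total weight inside community `c` and `a_c` the fraction of
#' weight attached to its nodes.
#'
#' @param W a `ggm_fit` or symmetric weight matrix.
#' @param partition a `community_partition` or membership vector.
#' @export
net_modularity <- function(W, partition) {
  W <- as_weight_matrix(W)
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  if (!is.null(names(memb))) memb <- memb[rownames(W)]
  stopifnot(length(memb) == nrow(W), !anyNA(memb))
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::modularity(g, as.integer(factor(memb)),
                     weights = igraph::E(g)$weight)
}

#' Exploratory graph analysis
#'
#' Composition of the estimation pipeline and walktrap community detection:
#' Spearman correlations, positive-definiteness repair, EBIC graphical lasso,
#' then walktrap on the estimated network. An empty estimated network yields
#' the all-singleton partition with a warning.
#'
#' @param data respondent x node matrix.
#' @param gamma EBIC hyperparameter.
#' @param steps walktrap random-walk length.
#' @param ... further arguments to [ebic_glasso()].
#' @return list with components `fit` (a `ggm_fit`) and `partition`
#'   (a `community_partition`).
#' @export
ega <- function(data, gamma = 0.5, steps = 4, ...) {
  fit <- ebic_glasso(data, gamma = gamma, ...)
  if (all(fit$weights == 0)) {
    warning("estimated network is empty; every node is its own community")
    membership <- setNames(seq_along(fit$labels), fit$labels)
    partition <- structure(list(membership = membership,
                                n_communities = length(membership),
                                modularity = 0, merges = NULL,
                                isolated = fit$labels, steps = steps),
                           class = "community_partition")
  } else {
    partition <- walktrap_communities(fit, steps = steps)
  }
  list(fit = fit, partition = partition)
}

#' Write a community partition as CSV
#'
#' @param partition a `community_partition`.
#' @param path CSV file path.
#' @export
write_partition_csv <- function(partition, path) {
  stopifnot(inherits(partition, "community_partition"))
  df <- data.frame(node = names(partition$membership),
                   community = unname(partition$membership))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
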