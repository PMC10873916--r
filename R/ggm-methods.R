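#' @export
print.ggm_fit <- function(x, ...) {
  p <- length(x$labels)
  ne <- count_edges(x$weights)
  cat("Regularized partial correlation network (EBIC graphical lasso)\n")
  cat(sprintf("  nodes: %d   edges: %d / %d possible   n = %d\n",
              p, ne, p * (p - 1) / 2, x$n))
  cat(sprintf("  gamma = %.2f   selected lambda = %.4g (path index %d/%d)\n",
              x$gamma, x$path$lambda, x$path$selected,
              length(x$path$lambdas)))
  cat(sprintf("  global strength = %.3f\n", global_strength(x)))
  invisible(x)
}

#' Summarize a fitted network
#'
#' Reports edge counts, global strength and the node centrality table
#' (expected influence, and predictability when the fitting data are
#' supplied).
#'
#' @param object a `ggm_fit`.
#' @param data optional data matrix for nodewise predictability.
#' @param ... unused.
#' @export
summary.ggm_fit <- function(object, data = NULL, ...) {
  ct <- centrality_table(object, data = data)
  out <- list(
    n_nodes = length(object$labels),
    n_edges = count_edges(object$weights),
    global_strength = global_strength(object),
    lambda = object$path$lambda,
    gamma = object$gamma,
    n = object$n,
    centrality = ct
  )
  class(out) <- "summary.ggm_fit"
  out
}

#' @export
print.summary.ggm_fit <- function(x, ...) {
  cat(sprintf("Network with %d nodes, %d edges, global strength %.3f\n",
              x$n_nodes, x$n_edges, x$global_strength))
  cat(sprintf("gamma = %.2f, lambda = %.4g, n = %d\n", x$gamma, x$lambda, x$n))
  cat("\nNode centrality:\n")
  print(x$centrality, digits = 3)
  invisible(x)
}

#' Edge weights of a fitted network
#'
#' @param object a `ggm_fit`.
#' @param ... unused.
#' @return the symmetric partial-correlation matrix (zero diagonal).
#' @export
coef.ggm_fit <- function(object, ...) object$weights

#' Conditional-mean predictions from a fitted network
#'
#' For standardized data, the Gaussian graphical model predicts each node by
#' the conditional mean given all others,
#' `xhat_j = -sum_{k != j} (kappa_jk / kappa_jj) x_k`. Inputs are
#' standardized internally (columnwise), so predictions are on the z-scale.
#'
#' @param object a `ggm_fit`.
#' @param newdata respondent x node matrix with columns matching the fit.
#' @param ... unused.
#' @export
predict.ggm_fit <- function(object, newdata, ...) {
  X <- scale(as.matrix(unclass(newdata))[, object$labels, drop = FALSE])
  K <- object$precision
  Bmat <- -sweep(K, 2, diag(K), "/")  # column j: coefficients for node j
  diag(Bmat) <- 0
  out <- X %*% Bmat
  colnames(out) <- object$labels
  out
}

#' @export
residuals.ggm_fit <- function(object, newdata, ...) {
  X <- scale(as.matrix(unclass(newdata))[, object$labels, drop = FALSE])
  X - predict(object, newdata)
}

#' Simulate latent Gaussian data from a fitted network
#'
#' Draws from the multivariate normal with precision equal to the fitted
#' (selected) precision matrix, standardized to unit variances.
#'
#' @param object a `ggm_fit`.
#' @param nsim number of observations to draw.
#' @param seed RNG seed.
#' @param ... unused.
#' @export
simulate.ggm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Sigma <- stats::cov2cor(chol2inv(chol(object$precision)))
  out <- MASS::mvrnorm(nsim, mu = rep(0, nrow(Sigma)), Sigma = Sigma)
  if (nsim == 1) out <- matrix(out, nrow = 1)
  colnames(out) <- object$labels
  out
}

#' Plot a fitted network
#'
#' igraph-based display: edge width proportional to |partial correlation|,
#' solid edges positive, dashed negative, nodes coloured by scale membership
#' when available.
#'
#' @param x a `ggm_fit`.
#' @param layout igraph layout function.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.ggm_fit <- function(x, layout = igraph::layout_with_fr, ...) {
  W <- x$weights
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  el <- igraph::as_edgelist(g)
  sgn <- W[cbind(el[, 1], el[, 2])]
  igraph::E(g)$lty <- ifelse(sgn < 0, 2, 1)
  igraph::E(g)$width <- 6 * abs(igraph::E(g)$weight)
  if (!is.null(x$node_groups)) {
    grp <- factor(x$node_groups[x$labels])
    igraph::V(g)$color <- grDevices::rainbow(nlevels(grp))[as.integer(grp)]
  }
  igraph::plot.igraph(g, layout = layout(g), ...)
  invisible(x)
}

#' Export a network as an edge list, adjacency CSV, or GraphML
#'
#' @param fit a `ggm_fit` (or weight matrix).
#' @param path output file path.
#' @param format one of `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @export
write_network <- function(fit, path, format = c("edgelist", "adjacency", "graphml")) {
  format <- match.arg(format)
  W <- as_weight_matrix(fit)
  if (format == "adjacency") {
    write.csv(as.data.frame(W), path, row.names = TRUE)
  } else if (format == "edgelist") {
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    df <- data.frame(node_i = rownames(W)[idx[, 1]],
                     node_j = colnames(W)[idx[, 2]],
                     weight = W[idx])
    write.csv(df[order(df$node_i, df$node_j), ], path, row.names = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    if (inherits(fit, "ggm_fit") && !is.null(fit$node_groups))
      igraph::V(g)$scale <- unname(fit$node_groups[rownames(W)])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
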