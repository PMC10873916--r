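# Independent oracles used to validate the package's own implementations.
# These deliberately share no code with the routines they check.

# penalized negative log-likelihood of the graphical lasso
# (diagonal unpenalized)
glasso_objective <- function(K, S, lam) {
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  -as.numeric(ld$modulus) + sum(S * K) +
    lam * (sum(abs(K)) - sum(abs(diag(K))))
}

# Proximal-gradient (FISTA) solver for the same convex objective: an
# independent first-order optimizer over the precision matrix, with
# backtracking line search and positive-definiteness safeguard.
fista_glasso <- function(S, lam, maxit = 20000, tol = 1e-13) {
  p <- nrow(S)
  soft_off <- function(M, t) {
    out <- sign(M) * pmax(abs(M) - t, 0)
    diag(out) <- diag(M)
    out
  }
  is_pd <- function(M) inherits(try(chol(M), silent = TRUE), "matrix")
  g_val <- function(K) {
    ld <- determinant(K, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    -as.numeric(ld$modulus) + sum(S * K)
  }
  K <- diag(1 / diag(S))
  Y <- K
  tk <- 1
  step <- 1
  obj_old <- glasso_objective(K, S, lam)
  for (it in seq_len(maxit)) {
    gY <- g_val(Y)
    if (!is.finite(gY)) {
      Y <- K
      tk <- 1
      gY <- g_val(Y)
    }
    grad <- S - solve(Y)
    repeat {
      cand <- soft_off(Y - step * grad, lam * step)
      if (is_pd(cand)) {
        dd <- cand - Y
        if (g_val(cand) <= gY + sum(grad * dd) + sum(dd^2) / (2 * step) + 1e-15)
          break
      }
      step <- step / 2
      if (step < 1e-14) break
    }
    K_new <- cand
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- K_new + ((tk - 1) / t_new) * (K_new - K)
    obj_new <- glasso_objective(K_new, S, lam)
    if (obj_new > obj_old) {          # restart momentum
      Y <- K_new
      tk <- 1
    } else {
      tk <- t_new
    }
    done <- abs(obj_old - obj_new) < tol && it > 50
    K <- K_new
    obj_old <- min(obj_old, obj_new)
    if (done) break
    step <- min(step * 2, 1)
  }
  K
}

# random correlation matrix (Wishart-style), exactly symmetric
random_correlation <- function(p, n_gen = 3 * p) {
  A <- matrix(rnorm(n_gen * p), n_gen, p)
  C <- stats::cov2cor(crossprod(A))
  (C + t(C)) / 2
}

# Higham alternating projections to the nearest correlation matrix
higham_nearest_corr <- function(C, iters = 1000, tol = 1e-12) {
  Y <- C
  D <- matrix(0, nrow(C), ncol(C))
  for (i in seq_len(iters)) {
    R <- Y - D
    e <- eigen(R, symmetric = TRUE)
    X <- e$vectors %*% diag(pmax(e$values, 0), nrow(C)) %*% t(e$vectors)
    D <- X - R
    Y_new <- X
    diag(Y_new) <- 1
    if (max(abs(Y_new - Y)) < tol) return(Y_new)
    Y <- Y_new
  }
  Y
}

# Bonferroni-Holm by literal step-down definition
holm_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# weighted Newman modularity by the literal double sum
modularity_bruteforce <- function(W, memb) {
  A <- abs(W)
  diag(A) <- 0
  two_m <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (memb[i] == memb[j])
        q <- q + A[i, j] / two_m - k[i] * k[j] / two_m^2
  as.numeric(q)
}

# partial correlation of nodes i, j given the rest, from the covariance,
# via the conditional-covariance (Schur complement) formula
partial_cor_conditioning <- function(Sigma, i, j) {
  rest <- setdiff(seq_len(nrow(Sigma)), c(i, j))
  S11 <- Sigma[c(i, j), c(i, j)]
  S12 <- Sigma[c(i, j), rest, drop = FALSE]
  S22 <- Sigma[rest, rest, drop = FALSE]
  Sc <- S11 - S12 %*% solve(S22) %*% t(S12)
  Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
}

# base spec used by the two-group comparison simulations: a realistic 8-node
# ordinal network (moderate density, mostly positive weights) with enough
# precision-eigenvalue headroom that a 1.3x connectivity multiplier remains
# a valid graphical model
nct_sim_base_spec <- function() {
  random_sparse_ggm(p = 8, edge_density = 0.3, weight_range = c(0.2, 0.35),
                    min_eig = 0.3, n_respondents = 300, seed = 11)
}
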