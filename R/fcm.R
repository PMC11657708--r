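#' Fuzzy C-means clustering
#'
#' Standard alternating fuzzy C-means: soft memberships are updated with
#' exponent `2 / (m - 1)` on inverse squared distances and centers as
#' membership-weighted means (weights raised to the fuzzifier power). The
#' objective `sum_ji u_ji^m ||x_j - c_i||^2` is non-increasing across
#' iterations; the run stops when its change drops below `tol` or after
#' `max_iter` iterations. Memberships are initialized at random (row-
#' stochastic) from `seed`.
#'
#' @param X Numeric matrix, one row per sample.
#' @param M Number of clusters (`1 <= M <= nrow(X)`).
#' @param m Fuzzifier (> 1), default 2.
#' @param tol Convergence tolerance on the objective, default 1e-6.
#' @param max_iter Maximum iterations, default 200.
#' @param seed Integer seed for the membership initialization.
#' @return An `fcm_result`: list with `memberships` (n x M, rows sum to 1),
#'   `centers` (M x d) and `objective_history`.
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
#' fit <- fcm_fit(X, M = 2, seed = 1)
#' round(fit$centers)
#' @export
fcm_fit <- function(X, M, m = 2, tol = 1e-6, max_iter = 200L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (M < 1 || M > n) abort("`M` must satisfy 1 <= M <= nrow(X).")
  if (m <= 1) abort("fuzzifier `m` must be > 1.")
  n_distinct <- nrow(unique(X))
  if (n_distinct < M) {
    warn(sprintf("only %d distinct points for %d clusters; clusters will collapse.",
                 n_distinct, M))
  }
  if (M == 1L) {
    center <- matrix(colMeans(X), 1, ncol(X))
    d2 <- rowSums(sweep(X, 2, center[1, ])^2)
    return(structure(
      list(memberships = matrix(1, n, 1), centers = center,
           objective_history = sum(d2)),
      class = "fcm_result"
    ))
  }
  U <- with_seed(seed, {
    U0 <- matrix(runif(n * M), n, M)
    U0 / rowSums(U0)
  })
  history <- numeric(0)
  J_prev <- Inf
  for (it in seq_len(max_iter)) {
    Um <- U^m
    centers <- (t(Um) %*% X) / colSums(Um)
    # squared distances sample x cluster
    d2 <- outer(rowSums(X^2), rep(1, M)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    J <- sum(Um * d2)
    history <- c(history, J)
    if (is.finite(J_prev) && J_prev - J < tol) break
    J_prev <- J
    # membership update; samples coinciding with a center get full weight there
    inv <- 1 / pmax(d2, .Machine$double.eps)^(1 / (m - 1))
    U <- inv / rowSums(inv)
    zero <- d2 <= .Machine$double.eps
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      U[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
  }
  structure(
    list(memberships = U, centers = centers, objective_history = history),
    class = "fcm_result"
  )
}

#' RBF centers and widths from fuzzy memberships
#'
#' Recomputes each hidden unit's center as the plain membership-weighted mean
#' of the data, `c_i = sum_j u_ji x_j / sum_j u_ji`, and its kernel width as
#' the membership-weighted mean squared distance to that center,
#' `delta_i = sum_j u_ji ||x_j - c_i||^2 / sum_j u_ji`. Widths are floored at
#' 1e-8 so degenerate clusters keep a valid Gaussian.
#'
#' @param X Numeric matrix of training samples.
#' @param fcm An `fcm_result` for `X`.
#' @return An `rbf_layer`: list with `centers` (M x d) and `widths`
#'   (length M, positive).
#' @export
rbf_parameters <- function(X, fcm) {
  X <- as.matrix(X)
  U <- fcm$memberships
  colw <- colSums(U)
  centers <- (t(U) %*% X) / colw
  d2 <- outer(rowSums(X^2), rep(1, ncol(U))) - 2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  d2 <- pmax(d2, 0)
  widths <- pmax(colSums(U * d2) / colw, 1e-8)
  structure(list(centers = centers, widths = as.numeric(widths)),
            class = "rbf_layer")
}

#' Gaussian hidden-layer mapping
#'
#' Maps each sample through the radial basis units:
#' entry (j, i) is `exp(-||x_j - c_i||^2 / delta_i)`, in (0, 1], equal to 1
#' exactly when the sample coincides with center i.
#'
#' @param X Numeric matrix of samples (columns matching the centers).
#' @param layer An `rbf_layer`.
#' @return The n x M matrix of hidden activations.
#' @export
hidden_map <- function(X, layer) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(layer$centers)) {
    abort(sprintf("X has %d columns but the layer expects %d.",
                  ncol(X), ncol(layer$centers)))
  }
  d2 <- outer(rowSums(X^2), rep(1, nrow(layer$centers))) -
    2 * X %*% t(layer$centers) +
    outer(rep(1, nrow(X)), rowSums(layer$centers^2))
  exp(sweep(pmax(d2, 0), 2, layer$widths, "/") * -1)
}
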