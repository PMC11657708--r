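#' Dual kernel matrix of the epsilon-insensitive QP
#'
#' Builds the Gaussian kernel `K_ij = exp(-gamma ||xh_i - xh_j||^2)` on the
#' hidden-layer vectors and assembles the 2n x 2n block matrix
#' `rbind(cbind(K + (mu n / lambda) I, -K), cbind(-K, K + (mu n / lambda) I))`
#' that defines the quadratic form of the dual training problem. The result
#' is symmetric positive definite (Gaussian kernel PSD plus a positive
#' diagonal shift).
#'
#' @param Xh n x M matrix of hidden-layer activations.
#' @param lambda Structural-risk trade-off (> 0).
#' @param mu Equilibrium (slack penalty) factor (> 0).
#' @param gamma Gaussian kernel bandwidth (> 0).
#' @return The 2n x 2n matrix, with the plain kernel `K` attached as
#'   attribute `"K"`.
#' @export
build_dual_kernel <- function(Xh, lambda, mu, gamma) {
  if (lambda <= 0 || mu <= 0 || gamma <= 0) {
    abort("`lambda`, `mu` and `gamma` must all be positive.")
  }
  Xh <- as.matrix(Xh)
  n <- nrow(Xh)
  d2 <- outer(rowSums(Xh^2), rep(1, n)) - 2 * Xh %*% t(Xh) +
    outer(rep(1, n), rowSums(Xh^2))
  K <- exp(-gamma * pmax(d2, 0))
  shift <- (mu * n / lambda) * diag(n)
  Kt <- rbind(cbind(K + shift, -K), cbind(-K, K + shift))
  Kt <- (Kt + t(Kt)) / 2
  attr(Kt, "K") <- K
  Kt
}

# Euclidean projection onto the probability simplex {z >= 0, sum z = 1}.
proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - 1) / seq_along(u)))
  pmax(v - (css[rho] - 1) / rho, 0)
}

#' Solve the epsilon-insensitive dual training problem
#'
#' Maximizes `t(c) %*% z - t(z) %*% Ktilde %*% z` over the simplex
#' `z = c(alpha, alpha_star) >= 0, sum(z) = 1`, where
#' `c = (2/lambda) * c(y, -y)`. The solver is an accelerated projected
#' gradient (FISTA with restart) on the negated objective; the feasible set
#' always contains the uniform point, and the quadratic form is strongly
#' convex, so convergence is geometric. Iterations stop once the
#' Karush-Kuhn-Tucker residual falls below `tol`. Slack variables are
#' recovered as `xi = alpha * mu * n` and `xi_star = alpha_star * mu * n`.
#'
#' @param Ktilde The 2n x 2n matrix from [build_dual_kernel()].
#' @param y Numeric vector of binary targets in {-1, +1}.
#' @param lambda Structural-risk trade-off used to build `Ktilde`.
#' @param mu Equilibrium factor used to build `Ktilde` (for slack recovery).
#' @param tol KKT residual tolerance, default 1e-8.
#' @param max_iter Iteration cap, default 200000.
#' @return A `dual_solution`: list with `alpha`, `alpha_star` (nonnegative,
#'   summing to 1 jointly), `xi`, `xi_star`, `objective` (the maximized dual
#'   value), `kkt_residual` and `iterations`.
#' @export
solve_dual <- function(Ktilde, y, lambda, mu, tol = 1e-8, max_iter = 200000L) {
  n <- length(y)
  if (nrow(Ktilde) != 2L * n) {
    abort("`Ktilde` must be 2n x 2n for n = length(y).")
  }
  if (!all(y %in% c(-1, 1))) abort("`y` must contain only -1 and +1.")
  cc <- (2 / lambda) * c(y, -y)
  L <- 2 * max(eigen(Ktilde, symmetric = TRUE, only.values = TRUE)$values)
  scale <- max(1, max(abs(cc)))
  grad <- function(z) 2 * as.numeric(Ktilde %*% z) - cc
  kkt <- function(z, g) {
    nu <- min(g)
    max(z * (g - nu)) # complementarity: active coordinates must sit at min g
  }
  z <- rep(1 / (2 * n), 2 * n)
  zv <- z
  tt <- 1
  res <- Inf
  it <- 0L
  f <- function(z) sum(z * as.numeric(Ktilde %*% z)) - sum(cc * z)
  f_prev <- f(z)
  while (it < max_iter) {
    it <- it + 1L
    g <- grad(zv)
    z_new <- proj_simplex(zv - g / L)
    t_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
    zv <- z_new + ((tt - 1) / t_new) * (z_new - z)
    f_new <- f(z_new)
    if (f_new > f_prev) { # restart momentum on objective increase
      zv <- z_new
      t_new <- 1
    }
    z <- z_new
    tt <- t_new
    f_prev <- f_new
    if (it %% 10L == 0L) {
      gz <- grad(z)
      res <- kkt(z, gz) / scale
      if (res <= tol) break
    }
  }
  gz <- grad(z)
  res <- kkt(z, gz) / scale
  if (res > tol) {
    warn(sprintf("dual solver stopped at KKT residual %.3g after %d iterations.",
                 res, it))
  }
  alpha <- z[seq_len(n)]
  alpha_star <- z[n + seq_len(n)]
  structure(
    list(alpha = alpha, alpha_star = alpha_star,
         xi = alpha * mu * n, xi_star = alpha_star * mu * n,
         objective = -f(z), kkt_residual = res, iterations = it),
    class = "dual_solution"
  )
}

default_hyper <- function(M = 20L, m = 2, lambda = 1, mu = 0.1,
                          gamma = NULL, seed = 1L) {
  list(M = as.integer(M), m = m, lambda = lambda, mu = mu, gamma = gamma,
       seed = as.integer(seed))
}

#' Fit the fast RBF network classifier
#'
#' Trains the classifier on a feature table: the (optionally masked) feature
#' columns are standardized, fuzzy C-means supplies the shared hidden layer
#' (centers and widths via [rbf_parameters()]), and one binary
#' epsilon-insensitive dual problem ([solve_dual()]) is solved per class in a
#' one-vs-rest scheme with +1/-1 targets. The Gaussian dual kernel operates
#' on the hidden-layer activations.
#'
#' @param table Feature table tibble (`label` column plus feature columns).
#' @param mask Optional 0/1 vector over the feature columns (e.g. from
#'   [select_features()]); `NULL` keeps all features.
#' @param M Number of hidden units (fuzzy C-means clusters), default 20.
#' @param m Fuzzy C-means fuzzifier, default 2.
#' @param lambda Structural-risk trade-off, default 1.
#' @param mu Equilibrium (slack penalty) factor, default 0.1.
#' @param gamma Gaussian kernel bandwidth on the hidden activations; default
#'   `1 / M`.
#' @param seed Integer seed (fuzzy C-means initialization).
#' @param classes Class labels the model must cover; default the sorted
#'   labels present. An absent requested class is an error.
#' @return A `fast_rbfnn` model object.
#' @examples
#' \donttest{
#' tbl <- generate_feature_table(planted_table_spec(n_per_class = 20, seed = 1))
#' fit <- fit_fast_rbfnn(tbl$table, M = 10, seed = 1)
#' mean(predict(fit, tbl$table) == tbl$table$label)
#' }
#' @export
fit_fast_rbfnn <- function(table, mask = NULL, M = 20L, m = 2, lambda = 1,
                           mu = 0.1, gamma = NULL, seed = 1L,
                           classes = NULL) {
  y <- table$label
  if (is.null(classes)) classes <- sort(unique(y))
  missing_cl <- setdiff(classes, y)
  if (length(missing_cl)) {
    abort(sprintf("class %s absent from training data.",
                  paste(missing_cl, collapse = ", ")))
  }
  if (length(classes) < 2L) abort("need at least two classes to fit.")
  X <- feature_matrix(table)
  if (is.null(mask)) mask <- rep(1L, ncol(X))
  if (sum(mask) < 1L) abort("mask must select at least one feature.")
  keep <- which(mask == 1L)
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  M <- min(as.integer(M), n)
  if (is.null(gamma)) gamma <- 1 / M
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  fcm <- fcm_fit(Xs, M, m = m, seed = derive_seed(seed, 2L))
  layer <- rbf_parameters(Xs, fcm)
  Xh <- hidden_map(Xs, layer)
  Kt <- build_dual_kernel(Xh, lambda, mu, gamma)
  K <- attr(Kt, "K")
  duals <- lapply(classes, function(cl) {
    yb <- ifelse(y == cl, 1, -1)
    d <- solve_dual(Kt, yb, lambda, mu)
    # post-hoc diagnostic: largest residual among in-band (inactive) samples
    fx <- lambda * as.numeric(K %*% (d$alpha - d$alpha_star))
    inactive <- d$alpha < 1e-8 & d$alpha_star < 1e-8
    d$eps_effective <- if (any(inactive)) max(abs(yb - fx)[inactive]) else 0
    d
  })
  names(duals) <- as.character(classes)
  structure(
    list(layer = layer, Xh = Xh, duals = duals, classes = classes,
         mask = mask, feature_names = colnames(feature_matrix(table)),
         center = center, scale = scale,
         hyper = list(M = M, m = m, lambda = lambda, mu = mu, gamma = gamma,
                      seed = as.integer(seed))),
    class = "fast_rbfnn"
  )
}

# Hidden activations of new raw feature rows under a trained model.
model_hidden <- function(model, X) {
  if (ncol(X) != length(model$mask)) {
    abort(sprintf("expected %d feature columns, got %d.",
                  length(model$mask), ncol(X)))
  }
  Xm <- X[, which(model$mask == 1L), drop = FALSE]
  Xs <- sweep(sweep(Xm, 2, model$center), 2, model$scale, "/")
  hidden_map(Xs, model$layer)
}

gaussian_cross_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) - 2 * A %*% t(B) +
    outer(rep(1, nrow(A)), rowSums(B^2))
  exp(-gamma * pmax(d2, 0))
}

# Per-class decision values for a matrix of raw feature rows.
decision_matrix <- function(model, X) {
  if (nrow(X) == 0L) abort("`new_data` has no rows.")
  Xh_new <- model_hidden(model, X)
  Kx <- gaussian_cross_kernel(model$Xh, Xh_new, model$hyper$gamma)
  vals <- vapply(model$duals, function(d) {
    model$hyper$lambda * as.numeric(crossprod(Kx, d$alpha - d$alpha_star))
  }, numeric(nrow(X)))
  matrix(vals, nrow = nrow(X),
         dimnames = list(NULL, as.character(model$classes)))
}

#' Decision value of one class for one sample
#'
#' Maps the raw feature vector through the trained hidden layer and evaluates
#' `lambda * sum_i (alpha_i - alpha_star_i) K(xh_i, xh_test)` for the
#' requested one-vs-rest machine.
#'
#' @param model A fitted `fast_rbfnn`.
#' @param class_index Position of the class in `model$classes`.
#' @param x Raw feature vector (all original feature columns; the model
#'   applies its own mask).
#' @return The scalar decision value.
#' @export
decision_value <- function(model, class_index, x) {
  if (!inherits(model, "fast_rbfnn")) abort("`model` must be a fast_rbfnn.")
  dm <- decision_matrix(model, matrix(x, nrow = 1))
  unname(dm[1, class_index])
}

#' Predict plane classes
#'
#' @param object A fitted `fast_rbfnn`.
#' @param new_data Feature table tibble or numeric feature matrix with the
#'   original (unmasked) feature columns.
#' @param type `"class"` (default) for hard labels via the one-vs-rest argmax
#'   (ties broken toward the lowest class index) or `"decision"` for the
#'   matrix of per-class decision values.
#' @param ... Unused.
#' @return Integer labels or the decision matrix.
#' @export
predict.fast_rbfnn <- function(object, new_data, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(new_data)) feature_matrix(new_data)
       else as.matrix(new_data)
  dm <- decision_matrix(object, X)
  if (type == "decision") return(dm)
  object$classes[max.col(dm, ties.method = "first")]
}

#' @export
print.fast_rbfnn <- function(x, ...) {
  cat(sprintf(
    "<fast_rbfnn> %d classes, %d/%d features, M = %d hidden units, lambda = %g, mu = %g, gamma = %g\n",
    length(x$classes), sum(x$mask), length(x$mask), x$hyper$M,
    x$hyper$lambda, x$hyper$mu, x$hyper$gamma
  ))
  invisible(x)
}

#' Tidy a fitted fast RBF network
#'
#' @param x A fitted `fast_rbfnn`.
#' @param ... Unused.
#' @return One row per class: `class`, `n_active` (dual coefficients above
#'   1e-8), `dual_objective`, `kkt_residual`, `eps_effective`.
#' @export
tidy.fast_rbfnn <- function(x, ...) {
  purrr::map2_dfr(x$duals, x$classes, function(d, cl) {
    tibble(class = cl,
           n_active = sum(d$alpha > 1e-8 | d$alpha_star > 1e-8),
           dual_objective = d$objective,
           kkt_residual = d$kkt_residual,
           eps_effective = d$eps_effective)
  })
}

#' @rdname tidy.fast_rbfnn
#' @return `glance()` returns a one-row tibble with the hyperparameters and
#'   model dimensions.
#' @export
glance.fast_rbfnn <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_features = sum(x$mask),
         M = x$hyper$M, lambda = x$hyper$lambda, mu = x$hyper$mu,
         gamma = x$hyper$gamma, n_train = nrow(x$Xh))
}

#' Serialize a fitted model to JSON
#'
#' Numbers are written at full precision, so writing and re-reading a model
#' reproduces it bit-exactly.
#'
#' @param model A fitted `fast_rbfnn`.
#' @param path Output JSON path.
#' @return `read_model()` returns the `fast_rbfnn` object.
#' @export
write_model <- function(model, path) {
  payload <- list(
    classes = model$classes,
    mask = model$mask,
    feature_names = model$feature_names,
    center = model$center,
    scale = model$scale,
    centers = model$layer$centers,
    widths = model$layer$widths,
    Xh = model$Xh,
    hyper = model$hyper,
    duals = lapply(model$duals, function(d) {
      d[c("alpha", "alpha_star", "xi", "xi_star", "objective",
          "kkt_residual", "iterations", "eps_effective")]
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  duals <- lapply(p$duals, function(d) {
    structure(as.list(d), class = "dual_solution")
  })
  structure(
    list(
      layer = structure(list(centers = p$centers, widths = p$widths),
                        class = "rbf_layer"),
      Xh = p$Xh, duals = duals, classes = p$classes,
      mask = as.integer(p$mask), feature_names = p$feature_names,
      center = setNames(as.numeric(p$center), p$feature_names[p$mask == 1L]),
      scale = setNames(as.numeric(p$scale), p$feature_names[p$mask == 1L]),
      hyper = p$hyper
    ),
    class = "fast_rbfnn"
  )
}
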