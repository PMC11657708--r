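test_that("fuzzy C-means has closed-form and recovery behavior", {
  withr::with_seed(1, {
    X <- matrix(rnorm(40), 20, 2)
    one <- fcm_fit(X, M = 1)
    expect_equal(one$centers[1, ], colMeans(X))
    expect_true(all(one$memberships == 1))

    clouds <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
                    matrix(rnorm(200, 10, 0.1), 100, 2))
    fit <- fcm_fit(clouds, M = 2, seed = 5)
    centers <- fit$centers[order(fit$centers[, 1]), ]
    expect_lt(max(abs(centers[1, ] - colMeans(clouds[1:100, ]))), 0.2)
    expect_lt(max(abs(centers[2, ] - colMeans(clouds[101:200, ]))), 0.2)

    expect_equal(rowSums(fit$memberships), rep(1, 200), tolerance = 1e-9)
    expect_true(all(diff(fit$objective_history) <= 1e-9))
  })
})

test_that("fuzzy C-means centers agree with an independent implementation", {
  withr::with_seed(2, {
    clouds <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
                    matrix(rnorm(100, 6, 0.3), 50, 2))
    own <- fcm_fit(clouds, M = 2, seed = 3)
    ref <- e1071::cmeans(clouds, centers = 2, m = 2)
    own_c <- own$centers[order(own$centers[, 1]), ]
    ref_c <- ref$centers[order(ref$centers[, 1]), ]
    expect_equal(own_c, ref_c, tolerance = 0.05, ignore_attr = TRUE)
  })
})

test_that("RBF centers and widths follow the membership-weighted formulas", {
  X <- rbind(c(0, 0), c(2, 0))
  fcm <- list(memberships = matrix(0.5, 2, 1), centers = matrix(c(1, 0), 1))
  layer <- rbf_parameters(X, fcm)
  expect_equal(layer$centers[1, ], c(1, 0))
  expect_equal(layer$widths, 1)

  same <- matrix(3, 5, 2)
  fcm2 <- list(memberships = matrix(1, 5, 1))
  layer2 <- rbf_parameters(same, fcm2)
  expect_equal(layer2$centers[1, ], c(3, 3))
  expect_equal(layer2$widths, 1e-8)

  withr::with_seed(3, {
    Xr <- matrix(rnorm(60), 20, 3)
    f <- fcm_fit(Xr, 4, seed = 1)
    expect_true(all(rbf_parameters(Xr, f)$widths > 0))
  })
})

test_that("the Gaussian hidden map evaluates exactly", {
  layer <- structure(list(centers = matrix(c(0, 0), 1), widths = 2),
                     class = "rbf_layer")
  expect_equal(hidden_map(matrix(c(0, 0), 1), layer)[1, 1], 1)
  expect_equal(hidden_map(matrix(c(sqrt(2), 0), 1), layer)[1, 1], exp(-1))
  expect_equal(hidden_map(matrix(c(1, 0), 1), layer)[1, 1], exp(-0.5))
  withr::with_seed(4, {
    H <- hidden_map(matrix(rnorm(30), 10, 3),
                    structure(list(centers = matrix(rnorm(9), 3),
                                   widths = c(1, 2, 3)),
                              class = "rbf_layer"))
    expect_true(all(H > 0 & H <= 1))
  })
})

test_that("the dual kernel has the printed block structure and is PSD", {
  Kt <- build_dual_kernel(matrix(0.5, 1, 3), lambda = 1, mu = 0.1, gamma = 1)
  expect_equal(unclass(Kt), matrix(c(1.1, -1, -1, 1.1), 2), ignore_attr = TRUE)

  withr::with_seed(5, {
    Xh <- matrix(runif(40), 8, 5)
    Kt2 <- build_dual_kernel(Xh, lambda = 2, mu = 0.3, gamma = 0.5)
    expect_equal(unclass(Kt2), t(unclass(Kt2)), ignore_attr = TRUE)
    expect_gte(min(eigen(Kt2, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  })

  # duplicated hidden rows: unit off-diagonal kernel entries
  Kt3 <- build_dual_kernel(rbind(c(1, 2), c(1, 2)), 1, 0.1, 1)
  expect_equal(attr(Kt3, "K"), matrix(1, 2, 2))
})

test_that("the dual solver matches a generic QP oracle and its constraints", {
  withr::with_seed(6, {
    for (rep in 1:3) {
      n <- 5
      Xh <- matrix(runif(n * 4), n, 4)
      y <- sample(c(-1, 1), n, replace = TRUE)
      Kt <- build_dual_kernel(Xh, lambda = 1, mu = 0.1, gamma = 0.5)
      sol <- solve_dual(Kt, y, lambda = 1, mu = 0.1)
      expect_equal(sol$objective, qp_oracle_objective(Kt, y, 1),
                   tolerance = 1e-6)
      expect_equal(sum(sol$alpha) + sum(sol$alpha_star), 1, tolerance = 1e-6)
      expect_true(all(sol$alpha >= 0) && all(sol$alpha_star >= 0))
      expect_equal(sol$xi, sol$alpha * 0.1 * n)
    }
  })
})

test_that("the n = 1 dual matches a grid search and saturates on alpha", {
  # defaults: interior optimum, checked against a 1-D grid over the simplex
  Kt <- build_dual_kernel(matrix(0.7, 1, 2), lambda = 1, mu = 0.1, gamma = 1)
  sol <- solve_dual(Kt, y = 1, lambda = 1, mu = 0.1)
  obj <- function(a, K, lam) {
    z <- c(a, 1 - a)
    sum((2 / lam) * c(1, -1) * z) - sum(z * (K %*% z))
  }
  grid <- seq(0, 1, by = 1e-4)
  best <- grid[which.max(vapply(grid, obj, numeric(1), K = Kt, lam = 1))]
  expect_equal(sol$alpha, best, tolerance = 1e-3)

  # a dominant linear term (small lambda) pushes all mass onto alpha
  Kt2 <- build_dual_kernel(matrix(0.7, 1, 2), lambda = 0.1, mu = 0.1,
                           gamma = 1)
  sol2 <- solve_dual(Kt2, y = 1, lambda = 0.1, mu = 0.1)
  best2 <- grid[which.max(vapply(grid, obj, numeric(1), K = Kt2, lam = 0.1))]
  expect_equal(best2, 1)
  expect_equal(sol2$alpha, 1, tolerance = 1e-6)
  expect_equal(sol2$alpha_star, 0, tolerance = 1e-6)
})

test_that("decision values are linear in the dual differences", {
  tbl <- blob_table(n = 30, sep = 6, seed = 7)
  fit <- fit_fast_rbfnn(tbl, M = 5, seed = 1)

  # equal alpha and alpha_star cancel to a zero decision everywhere
  fit0 <- fit
  for (cl in names(fit0$duals)) {
    fit0$duals[[cl]]$alpha <- rep(0.25, nrow(fit0$Xh)) / nrow(fit0$Xh)
    fit0$duals[[cl]]$alpha_star <- fit0$duals[[cl]]$alpha
  }
  x <- as.numeric(tbl[1, -1])
  expect_equal(decision_value(fit0, 1, x), 0)

  # flipping the sign of (alpha - alpha_star) flips the decision value
  fit1 <- fit
  d <- fit1$duals[[1]]
  fit1$duals[[1]]$alpha <- d$alpha_star
  fit1$duals[[1]]$alpha_star <- d$alpha
  expect_equal(decision_value(fit1, 1, x), -decision_value(fit, 1, x))

  # hand-computable n = 2 case
  hand <- fit
  hand$Xh <- matrix(c(0.2, 0.8), 2, 1)
  hand$layer <- structure(list(centers = matrix(0, 1, ncol(fit$layer$centers)),
                               widths = 1), class = "rbf_layer")
  hand$duals <- list(`0` = list(alpha = c(0.6, 0), alpha_star = c(0, 0.4)))
  hand$classes <- 0
  hand$hyper$gamma <- 1
  hand$hyper$lambda <- 2
  xh_test <- hidden_map(
    sweep(sweep(matrix(x[fit$mask == 1L], 1), 2, hand$center), 2, hand$scale, "/"),
    hand$layer
  )
  expected <- 2 * (0.6 * exp(-(0.2 - xh_test[1, 1])^2) -
                     0.4 * exp(-(0.8 - xh_test[1, 1])^2))
  expect_equal(decision_value(hand, 1, x), expected)
})

test_that("training separates well-separated blobs and is deterministic", {
  tbl <- blob_table(n = 100, sep = 6, seed = 8)
  fit <- fit_fast_rbfnn(tbl, M = 10, seed = 2)
  pred <- predict(fit, tbl)
  expect_gte(mean(pred == tbl$label), 0.98)

  fit2 <- fit_fast_rbfnn(tbl, M = 10, seed = 2)
  for (cl in names(fit$duals)) {
    expect_equal(fit$duals[[cl]]$alpha, fit2$duals[[cl]]$alpha,
                 tolerance = 1e-10)
  }

  expect_error(fit_fast_rbfnn(tbl, classes = c(0, 1, 2)), "absent")
  expect_error(predict(fit, matrix(0, 1, 5)), "feature columns")
})

test_that("prediction takes the argmax with ties to the lowest class", {
  tbl <- blob_table(n = 20, sep = 6, seed = 9)
  fit <- fit_fast_rbfnn(tbl, M = 4, seed = 1)
  # force identical duals for both classes: every decision ties
  fit$duals[[2]] <- fit$duals[[1]]
  dm <- predict(fit, tbl, type = "decision")
  expect_equal(dm[, 1], dm[, 2])
  expect_true(all(predict(fit, tbl) == fit$classes[1]))
})

test_that("looser slack penalties never reduce out-of-band residual counts", {
  tbl <- blob_table(n = 30, sep = 3, seed = 10)
  count_viol <- function(mu) {
    fit <- fit_fast_rbfnn(tbl, M = 6, mu = mu, seed = 3)
    dm <- predict(fit, tbl, type = "decision")
    yb <- ifelse(tbl$label == fit$classes[1], 1, -1)
    sum(abs(yb - dm[, 1]) > 0.5)
  }
  expect_gte(count_viol(1), count_viol(0.01))
})

test_that("six-class texture features are classified accurately", {
  ds <- generate_dataset(n_per_class = 20, seed = 11)
  ds$image <- purrr::map(ds$image, preprocess_image,
                         stages = c("equalize", "despeckle", "normalize"))
  tbl <- build_feature_table(ds)
  split <- withr::with_seed(11, fetalplanes:::stratified_split(tbl$label, 0.3))
  fit <- fit_fast_rbfnn(dplyr::slice(tbl, split$train), M = 20, seed = 4)
  pred <- predict(fit, dplyr::slice(tbl, split$test))
  rep <- macro_report(tbl$label[split$test], pred, classes = 0:5)
  expect_gte(rep$macro[["accuracy"]], 0.9)
})

test_that("models survive a bit-exact JSON round-trip", {
  tbl <- blob_table(n = 25, sep = 5, seed = 12)
  fit <- fit_fast_rbfnn(tbl, M = 5, seed = 5)
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(back$duals[["0"]]$alpha, fit$duals[["0"]]$alpha)
  expect_identical(back$layer$widths, fit$layer$widths)
  expect_identical(predict(back, tbl), predict(fit, tbl))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$M, 5)
  unlink(path)
})
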