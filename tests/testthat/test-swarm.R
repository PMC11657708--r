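test_that("binarization saturates, repairs empty masks, and is fair at zero", {
  withr::with_seed(1, {
    expect_equal(binarize(rep(20, 45)), rep(1L, 45))
    expect_equal(sum(binarize(rep(-20, 45))), 1L)
    mean_bits <- mean(replicate(10000, sum(binarize(rep(0, 45)))))
    expect_lt(abs(mean_bits - 22.5), 1)
  })
})

test_that("selection fitness combines accuracy and sparsity as declared", {
  pt <- generate_feature_table(planted_table_spec(n_per_class = 20, seed = 2))
  cfg <- select_config(seed = 7)
  split <- withr::with_seed(7, fetalplanes:::stratified_split(pt$table$label, 0.3))
  mask <- rep(1L, 45)
  # independent accuracy on the same split
  X <- as.matrix(pt$table[, -1])
  y <- pt$table$label
  acc <- mean(as.integer(as.character(
    class::knn(X[split$train, ], X[split$test, ], factor(y[split$train]), k = 1)
  )) == y[split$test])
  expect_equal(selection_fitness(mask, pt$table, cfg, split = split),
               0.9 * acc + 0.1 * 0)

  sparse <- c(rep(1L, 25), rep(0L, 20))
  acc_s <- mean(as.integer(as.character(
    class::knn(X[split$train, sparse == 1], X[split$test, sparse == 1],
               factor(y[split$train]), k = 1)
  )) == y[split$test])
  expect_equal(selection_fitness(sparse, pt$table, cfg, split = split),
               0.9 * acc_s + 0.1 * (20 / 45))

  # equal accuracy, fewer features -> strictly larger fitness
  expect_gt(0.9 * 1 + 0.1 * (20 / 45), 0.9 * 1)

  # with weight_feature = 0, fitness is the holdout accuracy exactly
  cfg0 <- select_config(weight_acc = 1, weight_feature = 0, seed = 7)
  expect_equal(selection_fitness(mask, pt$table, cfg0, split = split), acc)

  one_class <- dplyr::filter(pt$table, label == 0)
  expect_error(selection_fitness(mask, one_class, cfg), "two classes")
})

test_that("the PSO update follows the velocity kinematics exactly", {
  # zero acceleration: positions advance by their unchanged velocities
  pos <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2)
  vel <- matrix(0.5, 4, 2)
  st <- make_state(pos, vel, iterations = 10L)
  cfg <- select_config("pso", pop_size = 4, c1 = 0, c2 = 0, w = c(1, 1))
  st2 <- withr::with_seed(1, pso_update(st, cfg))
  expect_equal(st2$positions, pos + vel)
  expect_equal(st2$velocities, vel)

  # a particle at its own personal and global best with zero velocity stays
  same <- matrix(1.5, 4, 3)
  st <- make_state(same, evaluate = function(p, m) 0)
  st$pbest_pos <- same
  st$gbest$position <- same[1, ]
  st3 <- withr::with_seed(2, pso_update(st, select_config("pso", pop_size = 4)))
  expect_equal(st3$positions, same)
})

test_that("the GWO update collapses onto the leader mean when a = 0", {
  withr::with_seed(3, {
    pos <- matrix(rnorm(12), 4, 3)
    st <- make_state(pos, iterations = 10L, t = 9L)  # next update is the last
    leaders <- st$leader_pos
    st2 <- gwo_update(st, select_config("gwo", pop_size = 4))
    target <- matrix(colMeans(leaders), 4, 3, byrow = TRUE)
    expect_equal(st2$positions, target, tolerance = 1e-12)
  })
})

test_that("a wolf at the leaders' shared point is stationary when C is pinned", {
  point <- matrix(2, 4, 3)
  st <- make_state(point, evaluate = function(p, m) 0, iterations = 10L)
  st$leader_pos <- matrix(2, 3, 3)
  st2 <- withr::with_seed(4, gwo_update(st, select_config("gwo", pop_size = 4),
                                        pin_C = 1))
  expect_equal(st2$positions, point)
})

test_that("the hybrid update reduces to a damped personal-best pull and freezes at zero weights", {
  withr::with_seed(5, {
    pos <- matrix(rnorm(12), 4, 3)
    vel <- matrix(rnorm(12, sd = 0.1), 4, 3)
  })
  st <- make_state(pos, vel, iterations = 10L)
  pb <- st$pbest_pos
  guides <- list(pb, st$positions, st$positions)  # x1 = personal best
  cfg <- select_config("psogwo", pop_size = 4, c2 = 0, c3 = 0, w = c(0.7, 0.7))
  st2 <- withr::with_seed(6, hybrid_update(st, cfg, guide_override = guides))
  r1 <- withr::with_seed(6, matrix(runif(12), 4, 3))
  expected_v <- pmin(pmax(0.7 * (vel + 2 * r1 * (pb - pos)), -6), 6)
  expect_equal(st2$velocities, expected_v)
  expect_equal(st2$positions, pos + expected_v)

  # w = 0 and all pulls off: completely frozen
  cfg0 <- select_config("psogwo", pop_size = 4, c1 = 0, c2 = 0, c3 = 0,
                        w = c(0, 0))
  st3 <- withr::with_seed(7, hybrid_update(st, cfg0))
  expect_equal(st3$positions, pos)
})

test_that("all three algorithms minimize the 5-D sphere and keep monotone history", {
  sphere <- function(position, mask) -sum(position^2)
  for (alg in c("pso", "gwo", "psogwo")) {
    res <- swarm_optimize(5, sphere,
                          select_config(alg, pop_size = 20, iterations = 100,
                                        seed = 1))
    expect_lt(-res$fitness, 1e-3)
    expect_false(is.unsorted(res$history))
  }
  # same order of magnitude as an independent reference PSO
  ref <- reference_pso_sphere(seed = 1)
  own <- -swarm_optimize(5, sphere, select_config("pso", iterations = 100,
                                                  seed = 1))$fitness
  expect_lt(log10(own) - log10(ref), 4)
})

test_that("the hybrid matches or beats plain PSO on the sphere in most seeds", {
  sphere <- function(position, mask) -sum(position^2)
  wins <- sapply(1:10, function(s) {
    h <- -swarm_optimize(5, sphere, select_config("psogwo", iterations = 100,
                                                  seed = s))$fitness
    p <- -swarm_optimize(5, sphere, select_config("pso", iterations = 100,
                                                  seed = s))$fitness
    h <= p
  })
  expect_gte(mean(wins), 0.6)
})

test_that("feature selection recovers planted features and keeps its books", {
  pt <- generate_feature_table(planted_table_spec(n_per_class = 50,
                                                  effect_size = 3, seed = 1))
  cfg <- select_config("psogwo", iterations = 30, seed = 1)
  sel <- select_features(pt$table, cfg)
  expect_gte(sum(sel$mask[pt$informative]), 4)
  expect_length(sel$history, 30)
  expect_equal(max(sel$history), sel$fitness)
  expect_false(is.unsorted(sel$history))
  expect_gte(sum(sel$mask), 1)

  sel2 <- select_features(pt$table, cfg)
  expect_identical(sel$mask, sel2$mask)
})

test_that("selected subsets keep accuracy while using fewer features", {
  deltas <- sapply(1:5, function(s) {
    pt <- generate_feature_table(planted_table_spec(n_per_class = 30,
                                                    effect_size = 3, seed = s))
    cfg <- select_config("psogwo", iterations = 20, seed = s)
    split <- withr::with_seed(s + 1000L,
                              fetalplanes:::stratified_split(pt$table$label, 0.3))
    sel <- select_features(pt$table, cfg)
    acc_all <- fetalplanes:::holdout_accuracy(
      as.matrix(pt$table[, -1]), pt$table$label, rep(1L, 45), split)
    acc_sel <- fetalplanes:::holdout_accuracy(
      as.matrix(pt$table[, -1]), pt$table$label, sel$mask, split)
    c(delta = acc_sel - acc_all, frac = mean(sel$mask))
  })
  expect_gte(mean(deltas["delta", ]), -0.02)
  expect_lt(mean(deltas["frac", ]), 0.6)
})

test_that("target-k mode reports the best mask of the requested size", {
  pt <- generate_feature_table(planted_table_spec(n_per_class = 20, seed = 3))
  cfg <- select_config("psogwo", iterations = 15, target_k = 25, seed = 3)
  sel <- select_features(pt$table, cfg)
  if (!is.null(sel$mask_k)) {
    expect_equal(sum(sel$mask_k), 25)
    expect_lte(sel$fitness_k, sel$fitness + 1e-12)
  }
  expect_s3_class(tidy(sel), "tbl_df")
  expect_equal(nrow(tidy(sel)), 45)
  expect_equal(glance(sel)$n_selected, sum(sel$mask))
})

test_that("selection results serialize to JSON and back", {
  pt <- generate_feature_table(planted_table_spec(n_per_class = 15, seed = 4))
  sel <- select_features(pt$table, select_config(iterations = 5, seed = 4))
  path <- tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_identical(back$mask, sel$mask)
  expect_equal(back$fitness, sel$fitness)
  expect_equal(back$history, sel$history)
  unlink(path)
})
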