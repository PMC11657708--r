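#' Feature selection configuration
#'
#' Settings for the binary wrapper selection metaheuristics. The fitness of a
#' candidate mask is `weight_acc * accuracy + weight_feature * (n_total -
#' n_selected) / n_total`, where accuracy is the holdout accuracy of the
#' internal evaluator trained on the masked columns only.
#'
#' @param algorithm One of `"pso"`, `"gwo"`, `"psogwo"`.
#' @param pop_size Population size (>= 4), default 20.
#' @param iterations Number of update iterations, default 50.
#' @param w Inertia weight range `c(start, end)`, linearly decayed, default
#'   `c(0.9, 0.4)`.
#' @param c1,c2 PSO acceleration coefficients, default 2.
#' @param c3 Hybrid grey-wolf pull coefficient, default 0.5.
#' @param weight_acc,weight_feature Fitness weights (must sum to 1), default
#'   0.9 / 0.1.
#' @param evaluator Internal classifier scoring a mask: `"1nn"` (default,
#'   1-nearest-neighbor) or `"fastrbf"` (slower, [fit_fast_rbfnn()]).
#' @param holdout_fraction Fraction of rows held out for the accuracy term,
#'   default 0.3 (stratified).
#' @param v_max Velocity clamp (PSO and hybrid), default 6.
#' @param target_k Optional subset size: additionally track the best mask with
#'   exactly `target_k` features seen during the search.
#' @param seed Integer seed.
#' @return A `select_config` list.
#' @export
select_config <- function(algorithm = c("psogwo", "pso", "gwo"),
                          pop_size = 20L, iterations = 50L,
                          w = c(0.9, 0.4), c1 = 2, c2 = 2, c3 = 0.5,
                          weight_acc = 0.9, weight_feature = 0.1,
                          evaluator = c("1nn", "fastrbf"),
                          holdout_fraction = 0.3, v_max = 6,
                          target_k = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  evaluator <- match.arg(evaluator)
  if (pop_size < 4) abort("`pop_size` must be >= 4.")
  if (abs(weight_acc + weight_feature - 1) > 1e-12) {
    abort("`weight_acc` + `weight_feature` must equal 1.")
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    abort("`holdout_fraction` must be in (0, 1).")
  }
  structure(
    list(algorithm = algorithm, pop_size = as.integer(pop_size),
         iterations = as.integer(iterations), w = w, c1 = c1, c2 = c2,
         c3 = c3, weight_acc = weight_acc, weight_feature = weight_feature,
         evaluator = evaluator, holdout_fraction = holdout_fraction,
         v_max = v_max, target_k = target_k, seed = as.integer(seed)),
    class = "select_config"
  )
}

#' Binarize a continuous position into a selection mask
#'
#' Stochastic S-shaped transfer: bit j is set when
#' `sigmoid(position[j]) > u[j]` with `u[j] ~ Uniform(0, 1)`. If no bit comes
#' out set, the bit with the largest sigmoid value is forced on so every mask
#' selects at least one feature.
#'
#' @param position Numeric position vector.
#' @return Integer 0/1 mask of the same length.
#' @export
binarize <- function(position) {
  s <- 1 / (1 + exp(-position))
  mask <- as.integer(s > runif(length(position)))
  if (!any(mask == 1L)) mask[which.max(s)] <- 1L
  mask
}

# Inertia weight and grey-wolf control scalar schedules at iteration t of T.
inertia_at <- function(w, t, iters) {
  if (iters <= 1L) return(w[1])
  w[1] - (w[1] - w[2]) * (t - 1) / (iters - 1)
}

a_at <- function(t, iters) {
  if (iters <= 1L) return(0)
  2 * (1 - (t - 1) / (iters - 1))
}

# A swarm state is a list: positions/velocities (pop x dim), masks, fitness,
# pbest_pos/pbest_fit, gbest (pos, mask, fitness), leaders (3 best-so-far
# positions + fitnesses), t, iterations, evaluate(position, mask) -> fitness.
init_swarm <- function(dim, pop_size, iterations, evaluate) {
  positions <- matrix(runif(pop_size * dim, -1, 1), pop_size, dim)
  state <- list(
    positions = positions,
    velocities = matrix(0, pop_size, dim),
    masks = matrix(0L, pop_size, dim),
    fitness = rep(-Inf, pop_size),
    pbest_pos = positions,
    pbest_fit = rep(-Inf, pop_size),
    gbest = list(position = positions[1, ], mask = NULL, fitness = -Inf),
    leader_pos = matrix(0, 3, dim),
    leader_fit = rep(-Inf, 3),
    t = 0L,
    iterations = as.integer(iterations),
    evaluate = evaluate
  )
  evaluate_swarm(state)
}

# Re-binarize, re-score every agent and refresh personal/global bests and the
# alpha/beta/delta leader records.
evaluate_swarm <- function(state) {
  pop <- nrow(state$positions)
  for (i in seq_len(pop)) {
    pos <- state$positions[i, ]
    mask <- binarize(pos)
    fit <- state$evaluate(pos, mask)
    state$masks[i, ] <- mask
    state$fitness[i] <- fit
    if (fit > state$pbest_fit[i]) {
      state$pbest_fit[i] <- fit
      state$pbest_pos[i, ] <- pos
    }
    if (fit > state$gbest$fitness) {
      state$gbest <- list(position = pos, mask = mask, fitness = fit)
    }
  }
  # merge current agents with the stored leaders, keep the three best
  cand_fit <- c(state$leader_fit, state$fitness)
  cand_pos <- rbind(state$leader_pos, state$positions)
  top <- order(cand_fit, decreasing = TRUE)[1:3]
  state$leader_fit <- cand_fit[top]
  state$leader_pos <- cand_pos[top, , drop = FALSE]
  state
}

#' One particle swarm optimization iteration
#'
#' Velocity update `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with
#' fresh uniform `r1`, `r2` per dimension, followed by the position update
#' `x <- x + v`. Velocities are clamped to `[-v_max, v_max]`; masks, fitness
#' and bests are then refreshed.
#'
#' @param state A swarm state (internal; created by the driver in
#'   [select_features()] / [swarm_optimize()]).
#' @param cfg A [select_config()].
#' @return The updated state.
#' @export
pso_update <- function(state, cfg) {
  state$t <- state$t + 1L
  w <- inertia_at(cfg$w, state$t, state$iterations)
  pop <- nrow(state$positions)
  dim <- ncol(state$positions)
  r1 <- matrix(runif(pop * dim), pop, dim)
  r2 <- matrix(runif(pop * dim), pop, dim)
  gb <- matrix(state$gbest$position, pop, dim, byrow = TRUE)
  v <- w * state$velocities +
    cfg$c1 * r1 * (state$pbest_pos - state$positions) +
    cfg$c2 * r2 * (gb - state$positions)
  v <- pmin(pmax(v, -cfg$v_max), cfg$v_max)
  state$velocities <- v
  state$positions <- state$positions + v
  evaluate_swarm(state)
}

# Grey-wolf guide points x1, x2, x3 for every agent from the current leaders.
# A = 2 a r - a and C = 2 r with fresh uniforms per agent, dimension and
# leader; pins are test hooks fixing A or C to a constant.
gwo_guides <- function(state, a, pin_A = NULL, pin_C = NULL) {
  pop <- nrow(state$positions)
  dim <- ncol(state$positions)
  guides <- vector("list", 3)
  for (k in 1:3) {
    A <- if (is.null(pin_A)) 2 * a * matrix(runif(pop * dim), pop, dim) - a
         else matrix(pin_A, pop, dim)
    C <- if (is.null(pin_C)) 2 * matrix(runif(pop * dim), pop, dim)
         else matrix(pin_C, pop, dim)
    lead <- matrix(state$leader_pos[k, ], pop, dim, byrow = TRUE)
    D <- abs(C * lead - state$positions)
    guides[[k]] <- lead - A * D
  }
  guides
}

#' One grey wolf optimizer iteration
#'
#' The control scalar `a` decays linearly from 2 to 0 over the iterations.
#' Per wolf and dimension, `A = 2 a r - a` and `C = 2 r` with fresh uniforms;
#' the distances to the three leaders are `D = |C x_leader - x|`, the guide
#' points `x_k = x_leader_k - A_k D_k`, and the new position is their mean.
#'
#' @inheritParams pso_update
#' @param pin_A,pin_C Optional constants replacing the random `A` / `C`
#'   coefficients (testing hooks).
#' @return The updated state.
#' @export
gwo_update <- function(state, cfg, pin_A = NULL, pin_C = NULL) {
  state$t <- state$t + 1L
  a <- a_at(state$t, state$iterations)
  g <- gwo_guides(state, a, pin_A = pin_A, pin_C = pin_C)
  state$positions <- (g[[1]] + g[[2]] + g[[3]]) / 3
  evaluate_swarm(state)
}

#' One hybrid PSO-GWO iteration
#'
#' The grey-wolf guide points `x1, x2, x3` (from the alpha/beta/delta leaders
#' with the decayed-`a` coefficients) replace the personal/global attractors
#' in a three-term particle velocity, damped as a whole by the inertia
#' weight (the published hybrid form):
#' `v <- w * (v + c1 r1 (x1 - x) + c2 r2 (x2 - x) + c3 r3 (x3 - x))`, then
#' `x <- x + v`. The global best is additionally compared against the leaders
#' every iteration.
#'
#' @inheritParams gwo_update
#' @param guide_override Optional list of three `pop x dim` matrices replacing
#'   the computed guide points (testing hook).
#' @return The updated state.
#' @export
hybrid_update <- function(state, cfg, pin_A = NULL, pin_C = NULL,
                          guide_override = NULL) {
  state$t <- state$t + 1L
  a <- a_at(state$t, state$iterations)
  g <- if (is.null(guide_override)) {
    gwo_guides(state, a, pin_A = pin_A, pin_C = pin_C)
  } else {
    guide_override
  }
  w <- inertia_at(cfg$w, state$t, state$iterations)
  pop <- nrow(state$positions)
  dim <- ncol(state$positions)
  r1 <- matrix(runif(pop * dim), pop, dim)
  r2 <- matrix(runif(pop * dim), pop, dim)
  r3 <- matrix(runif(pop * dim), pop, dim)
  v <- w * (state$velocities +
    cfg$c1 * r1 * (g[[1]] - state$positions) +
    cfg$c2 * r2 * (g[[2]] - state$positions) +
    cfg$c3 * r3 * (g[[3]] - state$positions))
  v <- pmin(pmax(v, -cfg$v_max), cfg$v_max)
  state$velocities <- v
  state$positions <- state$positions + v
  state <- evaluate_swarm(state)
  if (state$leader_fit[1] > state$gbest$fitness) {
    state$gbest <- list(position = state$leader_pos[1, ],
                        mask = binarize(state$leader_pos[1, ]),
                        fitness = state$leader_fit[1])
  }
  state
}

#' Run a swarm optimizer on an arbitrary objective
#'
#' Maximizes `evaluate(position, mask)` over continuous positions in `dim`
#' dimensions with the configured algorithm, from a seeded uniform U(-1, 1)
#' initialization with zero velocities. The mask passed to `evaluate` is the
#' stochastic binarization of the position; continuous objectives may ignore
#' it.
#'
#' @param dim Number of dimensions.
#' @param evaluate Function `(position, mask) -> fitness` (maximized).
#' @param cfg A [select_config()].
#' @return List with `position`, `mask`, `fitness` of the best agent ever
#'   evaluated, and `history`, the best-so-far fitness after each iteration
#'   (length `cfg$iterations`, non-decreasing).
#' @export
swarm_optimize <- function(dim, evaluate, cfg = select_config()) {
  updater <- switch(cfg$algorithm,
    pso = pso_update, gwo = gwo_update, psogwo = hybrid_update
  )
  with_seed(cfg$seed, {
    state <- init_swarm(dim, cfg$pop_size, cfg$iterations, evaluate)
    history <- numeric(cfg$iterations)
    for (t in seq_len(cfg$iterations)) {
      state <- updater(state, cfg)
      history[t] <- state$gbest$fitness
    }
    list(position = state$gbest$position, mask = state$gbest$mask,
         fitness = state$gbest$fitness, history = history)
  })
}
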