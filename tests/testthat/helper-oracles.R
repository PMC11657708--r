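# Strip gray_image attributes down to a plain matrix.
as_mat <- function(img) {
  m <- unclass(img)
  attr(m, "range") <- NULL
  m
}

# Independent double-loop implementation of the nine GLCM descriptors,
# deliberately written scalar-by-scalar so it shares no code with the package.
oracle_haralick <- function(P) {
  ng <- nrow(P)
  contrast <- dissim <- homog <- energy <- asm <- entropy <- 0
  mu_i <- mu_j <- 0
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      p <- P[i, j]
      iv <- i - 1
      jv <- j - 1
      contrast <- contrast + p * (iv - jv)^2
      dissim <- dissim + p * abs(iv - jv)
      homog <- homog + p / (1 + (iv - jv)^2)
      energy <- energy + p^2
      asm <- asm + p^4
      if (p > 0) entropy <- entropy - p * log10(p)
      mu_i <- mu_i + iv * p
      mu_j <- mu_j + jv * p
    }
  }
  var_i <- var_j <- cross <- 0
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      p <- P[i, j]
      var_i <- var_i + p * (i - 1 - mu_i)^2
      var_j <- var_j + p * (j - 1 - mu_j)^2
      cross <- cross + (i - 1) * (j - 1) * p
    }
  }
  corr <- if (var_i > 0 && var_j > 0) {
    (cross - mu_i * mu_j) / (sqrt(var_i) * sqrt(var_j))
  } else 0
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    energy = energy, asm = asm, correlation = corr, entropy = entropy,
    mean = mu_i, variance = var_i)
}

# Random normalized symmetric co-occurrence matrix.
random_glcm <- function(ng) {
  M <- matrix(runif(ng * ng), ng, ng)
  M <- M + t(M)
  M / sum(M)
}

# Generic-QP oracle for the dual training problem: maximize c'z - z'Kt z over
# the simplex, via quadprog (min 1/2 z'D z - d'z, equality row first).
qp_oracle_objective <- function(Kt, y, lambda) {
  n <- length(y)
  cc <- (2 / lambda) * c(y, -y)
  D <- 2 * Kt
  A <- cbind(rep(1, 2 * n), diag(2 * n))
  sol <- quadprog::solve.QP(D, cc, A, c(1, rep(0, 2 * n)), meq = 1)
  sum(cc * sol$solution) -
    sum(sol$solution * as.numeric(Kt %*% sol$solution))
}

# Minimal self-contained reference PSO (sphere-style minimization), sharing
# no code with the package implementation.
reference_pso_sphere <- function(dim = 5, pop = 20, iters = 100, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(pop * dim, -1, 1), pop, dim)
    v <- matrix(0, pop, dim)
    f <- rowSums(x^2)
    pb <- x
    pbf <- f
    g <- x[which.min(f), ]
    gf <- min(f)
    for (t in seq_len(iters)) {
      w <- 0.9 - 0.5 * (t - 1) / (iters - 1)
      r1 <- matrix(runif(pop * dim), pop, dim)
      r2 <- matrix(runif(pop * dim), pop, dim)
      v <- w * v + 2 * r1 * (pb - x) + 2 * r2 * (matrix(g, pop, dim, byrow = TRUE) - x)
      v <- pmin(pmax(v, -6), 6)
      x <- x + v
      f <- rowSums(x^2)
      imp <- f < pbf
      pb[imp, ] <- x[imp, ]
      pbf[imp] <- f[imp]
      if (min(f) < gf) {
        gf <- min(f)
        g <- x[which.min(f), ]
      }
    }
    gf
  })
}

# Small swarm state around a fixed position matrix, for direct update tests.
make_state <- function(positions, velocities = NULL,
                       evaluate = function(position, mask) -sum(position^2),
                       iterations = 10L, t = 0L) {
  pop <- nrow(positions)
  dim <- ncol(positions)
  state <- list(
    positions = positions,
    velocities = if (is.null(velocities)) matrix(0, pop, dim) else velocities,
    masks = matrix(0L, pop, dim),
    fitness = rep(-Inf, pop),
    pbest_pos = positions,
    pbest_fit = rep(-Inf, pop),
    gbest = list(position = positions[1, ], mask = NULL, fitness = -Inf),
    leader_pos = matrix(0, 3, dim),
    leader_fit = rep(-Inf, 3),
    t = as.integer(t),
    iterations = as.integer(iterations),
    evaluate = evaluate
  )
  fetalplanes:::evaluate_swarm(state)
}

# Small ready-made feature tables for classifier tests.
blob_table <- function(n = 100, sep = 6, d = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * d, 0), n), matrix(rnorm(n * d, sep), n))
    colnames(X) <- sprintf("x%d", seq_len(d))
    dplyr::bind_cols(tibble::tibble(label = rep(0:1, each = n)),
                     tibble::as_tibble(X))
  })
}
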