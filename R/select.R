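# Stratified train/holdout split: returns list(train, test) row indices.
stratified_split <- function(labels, holdout_fraction) {
  idx <- split(seq_along(labels), labels)
  test <- unlist(lapply(idx, function(rows) {
    n_test <- max(1L, round(length(rows) * holdout_fraction))
    n_test <- min(n_test, length(rows) - 1L)
    sample(rows, n_test)
  }), use.names = FALSE)
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# Holdout accuracy of the internal evaluator on the masked feature columns.
# 1-NN runs in the raw feature space: per-column standardization would shrink
# class-informative columns (whose sd includes the between-class spread)
# relative to noise columns and defeat the wrapper.
holdout_accuracy <- function(X, y, mask, split, evaluator = "1nn",
                             hyper = list()) {
  cols <- which(mask == 1L)
  Xtr <- X[split$train, cols, drop = FALSE]
  Xte <- X[split$test, cols, drop = FALSE]
  ytr <- y[split$train]
  yte <- y[split$test]
  pred <- if (evaluator == "1nn") {
    as.integer(as.character(class::knn(Xtr, Xte, factor(ytr), k = 1)))
  } else {
    tr <- dplyr::bind_cols(tibble(label = ytr), as_tibble(Xtr))
    te <- dplyr::bind_cols(tibble(label = yte), as_tibble(Xte))
    model <- do.call(fit_fast_rbfnn, c(list(table = tr), hyper))
    predict(model, te)
  }
  mean(pred == yte)
}

#' Wrapper fitness of a feature mask
#'
#' `weight_acc * accuracy + weight_feature * (n_total - n_selected) /
#' n_total`: holdout accuracy of the internal evaluator on the masked columns,
#' plus a sparsity reward proportional to the fraction of features dropped.
#'
#' @param mask Integer 0/1 mask over the feature columns.
#' @param table Feature table tibble (column `label` + features).
#' @param cfg A [select_config()].
#' @param split Optional precomputed `list(train, test)` row indices; by
#'   default a stratified split is drawn from `cfg$seed`.
#' @return The scalar fitness.
#' @export
selection_fitness <- function(mask, table, cfg = select_config(),
                              split = NULL) {
  y <- table$label
  if (length(unique(y)) < 2L) {
    abort("feature table must contain at least two classes.")
  }
  if (sum(mask) < 1L) abort("mask must select at least one feature.")
  X <- feature_matrix(table)
  if (is.null(split)) {
    split <- with_seed(cfg$seed, stratified_split(y, cfg$holdout_fraction))
  }
  acc <- holdout_accuracy(X, y, mask, split, cfg$evaluator)
  n_tot <- ncol(X)
  cfg$weight_acc * acc + cfg$weight_feature * (n_tot - sum(mask)) / n_tot
}

#' Select texture features with a swarm metaheuristic
#'
#' Runs the configured algorithm (PSO, GWO or the hybrid PSOGWO) over binary
#' feature masks, scoring each candidate by [selection_fitness()] on a
#' stratified holdout split fixed for the whole run. Returns the best mask
#' ever evaluated.
#'
#' @param table Feature table tibble (column `label` plus feature columns, at
#'   least two classes).
#' @param cfg A [select_config()].
#' @return A `feature_selection` object: list with `mask` (named 0/1 integer
#'   vector), `fitness`, `history` (best fitness per iteration,
#'   non-decreasing), `algorithm`, `config`, `seed`, and -- when
#'   `cfg$target_k` is set -- `mask_k`, the best mask of exactly `target_k`
#'   features seen during the search.
#' @examples
#' \donttest{
#' tbl <- generate_feature_table(planted_table_spec(n_per_class = 20, seed = 1))
#' sel <- select_features(tbl$table, select_config("psogwo", iterations = 10))
#' sum(sel$mask)
#' }
#' @export
select_features <- function(table, cfg = select_config()) {
  y <- table$label
  if (length(unique(y)) < 2L) {
    abort("feature table must contain at least two classes.")
  }
  X <- feature_matrix(table)
  split <- with_seed(derive_seed(cfg$seed, 1L),
                     stratified_split(y, cfg$holdout_fraction))
  tracker <- new.env(parent = emptyenv())
  tracker$mask_k <- NULL
  tracker$fit_k <- -Inf
  evaluate <- function(position, mask) {
    fit <- {
      acc <- holdout_accuracy(X, y, mask, split, cfg$evaluator)
      cfg$weight_acc * acc +
        cfg$weight_feature * (ncol(X) - sum(mask)) / ncol(X)
    }
    if (!is.null(cfg$target_k) && sum(mask) == cfg$target_k &&
        fit > tracker$fit_k) {
      tracker$fit_k <- fit
      tracker$mask_k <- mask
    }
    fit
  }
  res <- swarm_optimize(ncol(X), evaluate, cfg)
  out <- list(
    algorithm = cfg$algorithm,
    mask = setNames(res$mask, colnames(X)),
    fitness = res$fitness,
    history = res$history,
    config = cfg,
    seed = cfg$seed
  )
  if (!is.null(cfg$target_k)) {
    if (is.null(tracker$mask_k)) {
      warn(sprintf("no mask of exactly %d features was encountered.",
                   cfg$target_k))
    } else {
      out$mask_k <- setNames(tracker$mask_k, colnames(X))
      out$fitness_k <- tracker$fit_k
    }
  }
  structure(out, class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf(
    "<feature_selection> %s: %d/%d features, fitness %.4f (%d iterations)\n",
    x$algorithm, sum(x$mask), length(x$mask), x$fitness, length(x$history)
  ))
  invisible(x)
}

#' Tidy a feature selection result
#'
#' @param x A `feature_selection` object.
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature`, `selected`.
#' @export
tidy.feature_selection <- function(x, ...) {
  tibble(feature = names(x$mask), selected = as.logical(x$mask))
}

#' @rdname tidy.feature_selection
#' @return `glance()` returns a one-row tibble with `algorithm`,
#'   `n_selected`, `n_features`, `fitness`, `iterations`.
#' @export
glance.feature_selection <- function(x, ...) {
  tibble(algorithm = x$algorithm, n_selected = sum(x$mask),
         n_features = length(x$mask), fitness = x$fitness,
         iterations = length(x$history))
}

#' Plot the fitness history of a selection run
#'
#' @param object A `feature_selection` object.
#' @param ... Unused.
#' @return A ggplot of best-so-far fitness per iteration.
#' @export
autoplot.feature_selection <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$history),
               fitness = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      title = sprintf("%s feature selection", object$algorithm),
      x = "Iteration", y = "Best fitness"
    )
}

#' Serialize a selection result to JSON
#'
#' @param sel A `feature_selection` object.
#' @param path Output JSON path.
#' @return `read_selection()` returns the `feature_selection` object.
#' @export
write_selection <- function(sel, path) {
  payload <- list(
    algorithm = sel$algorithm,
    mask = unname(sel$mask),
    features = names(sel$mask),
    fitness = sel$fitness,
    history = sel$history,
    seed = sel$seed,
    config = sel$config[c("pop_size", "iterations", "w", "c1", "c2", "c3",
                          "weight_acc", "weight_feature", "evaluator",
                          "holdout_fraction", "v_max")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(algorithm = p$algorithm,
         mask = setNames(as.integer(p$mask), p$features),
         fitness = p$fitness, history = p$history, config = p$config,
         seed = p$seed),
    class = "feature_selection"
  )
}
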