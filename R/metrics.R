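#' One-vs-rest confusion counts for one class
#'
#' Binarizes the labels against class `c` (positive = `c`) and counts true
#' positives, true negatives, false positives and false negatives.
#'
#' @param truth,pred Equal-length label vectors.
#' @param c The positive class.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_per_class <- function(truth, pred, c) {
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have the same length.")
  }
  tp <- sum(truth == c & pred == c)
  tn <- sum(truth != c & pred != c)
  fp <- sum(truth != c & pred == c)
  fn <- sum(truth == c & pred != c)
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# 0/0 ratios are defined as 0 throughout.
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from a confusion
#'
#' Computes accuracy `(TP+TN)/n`, specificity `TN/(TN+FP)`, sensitivity
#' `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1
#' `2 * precision * sensitivity / (precision + sensitivity)`, the Matthews
#' correlation coefficient
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the false
#' rejection rate `FN/(TP+FN)` and the false acceptance rate `FP/(TN+FP)`.
#' Any 0/0 ratio is defined as 0.
#'
#' @param conf Named counts `c(TP, TN, FP, FN)` from
#'   [confusion_per_class()].
#' @return Named numeric vector of the eight metrics.
#' @export
metrics_from_confusion <- function(conf) {
  tp <- conf[["TP"]]; tn <- conf[["TN"]]
  fp <- conf[["FP"]]; fn <- conf[["FN"]]
  n <- tp + tn + fp + fn
  if (n == 0) abort("empty confusion: all counts are zero.")
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  prec <- safe_ratio(tp, tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  c(accuracy = (tp + tn) / n, specificity = spec, sensitivity = sens,
    precision = prec, f1 = f1, mcc = mcc, frr = 1 - sens, far = 1 - spec)
}

#' Per-class and macro-averaged classification report
#'
#' Computes the eight metrics of [metrics_from_confusion()] for every class
#' in one-vs-rest view, plus their unweighted arithmetic mean (macro
#' average). A requested class absent from `truth` is kept in the per-class
#' table with `NA` metrics and excluded from the macro average with a
#' warning.
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Classes to report; default the sorted union of labels.
#' @return A `metrics_report`: list with `per_class` (tibble, one row per
#'   class) and `macro` (named numeric vector).
#' @examples
#' rep <- macro_report(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' rep$macro[["accuracy"]]
#' @export
macro_report <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  if (!all(truth %in% classes)) {
    abort("`classes` must cover all labels present in `truth`.")
  }
  rows <- purrr::map(classes, function(cl) {
    if (!any(truth == cl)) {
      warn(sprintf("class %s absent from truth; excluded from the macro average.", cl))
      return(setNames(rep(NA_real_, 8), names(metrics_from_confusion(
        c(TP = 0, TN = 1, FP = 0, FN = 0)
      ))))
    }
    metrics_from_confusion(confusion_per_class(truth, pred, cl))
  })
  per_class <- dplyr::bind_cols(
    tibble(class = classes),
    as_tibble(do.call(rbind, rows))
  )
  macro <- colMeans(per_class[, -1], na.rm = TRUE)
  structure(list(per_class = per_class, macro = macro),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_class, n = Inf)
  cat("macro: ",
      paste(sprintf("%s %.4f", names(x$macro), x$macro), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble with columns `class`, `metric`, `value`; macro rows
#'   carry class `"macro"`.
#' @export
tidy.metrics_report <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(x$per_class, class = as.character(.data$class)),
    -"class", names_to = "metric", values_to = "value"
  )
  macro <- tibble(class = "macro", metric = names(x$macro),
                  value = as.numeric(x$macro))
  dplyr::bind_rows(long, macro)
}

#' @rdname tidy.metrics_report
#' @return `glance()` returns the macro metrics as a one-row tibble.
#' @export
glance.metrics_report <- function(x, ...) {
  as_tibble(as.list(x$macro))
}

#' Plot per-class metrics
#'
#' @param object A `metrics_report`.
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot bar chart of per-class metric values.
#' @export
autoplot.metrics_report <- function(object,
                                    metrics = c("accuracy", "sensitivity",
                                                "specificity", "f1"),
                                    ...) {
  df <- dplyr::filter(tidy(object),
                      .data$metric %in% metrics, .data$class != "macro")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Class", y = "Value", fill = "Metric")
}

#' Write a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    per_class = report$per_class,
    macro = as.list(report$macro)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
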