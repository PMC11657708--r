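#' Texture extraction configuration
#'
#' Bundles the GLCM hyperparameters: pixel offset distance, angle set, number
#' of quantized gray levels and the ordered descriptor list. Under the
#' defaults (5 angles x 9 descriptors) each image yields 45 features.
#'
#' @param distance Pixel offset distance (default 5).
#' @param angles Offset angles in degrees (default `c(0, 30, 45, 90, 135)`).
#' @param levels Number of gray levels after quantization (default 8).
#' @param descriptors Ordered descriptor names; a subset of
#'   [haralick_names()].
#' @return A `texture_config` list.
#' @export
texture_config <- function(distance = 5L, angles = c(0, 30, 45, 90, 135),
                           levels = 8L, descriptors = haralick_names()) {
  if (distance < 1) abort("`distance` must be >= 1.")
  if (levels < 2) abort("`levels` must be >= 2.")
  bad <- setdiff(descriptors, haralick_names())
  if (length(bad)) {
    abort(sprintf("unknown descriptor(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(distance = as.integer(distance), angles = as.numeric(angles),
         levels = as.integer(levels), descriptors = descriptors),
    class = "texture_config"
  )
}

#' @rdname texture_config
#' @export
haralick_names <- function() {
  c("contrast", "dissimilarity", "homogeneity", "energy", "asm",
    "correlation", "entropy", "mean", "variance")
}

feature_names <- function(cfg = texture_config()) {
  as.vector(t(outer(cfg$angles, cfg$descriptors,
                    function(a, d) sprintf("a%g_%s", a, d))))
}

#' Quantize a normalized image to discrete gray levels
#'
#' Uniformly bins \[0, 1\] intensities into `levels` integer levels
#' `0 .. levels - 1`; the value 1.0 is assigned to the top bin.
#'
#' @param image A `gray_image` with range `"unit"` (a `"uint8"` image is
#'   accepted and divided by 255 first).
#' @param levels Number of gray levels (>= 2).
#' @return An integer matrix of levels.
#' @export
quantize_levels <- function(image, levels = 8L) {
  assert_gray_image(image)
  if (levels < 2) abort("`levels` must be >= 2.")
  px <- as_pixel_matrix(image)
  if (img_range(image) == "uint8") px <- px / 255
  lv <- pmin(floor(px * levels), levels - 1L)
  storage.mode(lv) <- "integer"
  lv
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels separated by the displacement
#' `(dr, dc) = round(d * (-sin(angle), cos(angle)))` (angle counter-clockwise,
#' 0 degrees = rightward neighbor). Each pair is accumulated in both orders,
#' making the matrix symmetric, and counts are divided by the total number of
#' accumulated pairs so entries sum to 1.
#'
#' @param levels Integer level matrix from [quantize_levels()].
#' @param d Offset distance in pixels.
#' @param angle Offset angle in degrees.
#' @param n_levels Number of gray levels; defaults to `max(levels) + 1`.
#' @return A `glcm` object: an `n_levels` x `n_levels` probability matrix with
#'   attributes `d` and `angle`.
#' @examples
#' lv <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
#' compute_glcm(lv, 1, 0, n_levels = 2)
#' @export
compute_glcm <- function(levels, d, angle, n_levels = max(levels) + 1L) {
  if (!is.matrix(levels)) abort("`levels` must be an integer matrix.")
  theta <- angle * pi / 180
  dr <- round(d * -sin(theta))
  dc <- round(d * cos(theta))
  h <- nrow(levels)
  w <- ncol(levels)
  r_lo <- max(1L, 1L - dr)
  r_hi <- min(h, h - dr)
  c_lo <- max(1L, 1L - dc)
  c_hi <- min(w, w - dc)
  if (r_lo > r_hi || c_lo > c_hi) {
    abort(sprintf(
      "image %dx%d too small for displacement (%d, %d).", h, w, dr, dc
    ))
  }
  r1 <- seq.int(r_lo, r_hi)
  c1 <- seq.int(c_lo, c_hi)
  g1 <- levels[r1, c1, drop = FALSE]
  g2 <- levels[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate(g1 * n_levels + g2 + 1L, nbins = n_levels^2)
  M <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P <- (M + t(M)) / (2 * length(g1))
  structure(P, class = c("glcm", "matrix", "array"), d = d, angle = angle)
}

#' Haralick texture descriptors of a GLCM
#'
#' Computes nine scalar texture summaries of a normalized symmetric GLCM
#' \eqn{p(i,j)} with gray values \eqn{i, j = 0, \dots, N_g - 1}:
#' contrast \eqn{\sum p(i,j)(i-j)^2}, dissimilarity \eqn{\sum p(i,j)|i-j|},
#' homogeneity \eqn{\sum p(i,j)/(1+(i-j)^2)}, energy \eqn{\sum p(i,j)^2},
#' angular second moment \eqn{\sum p(i,j)^4}, correlation
#' \eqn{(\sum ij\, p(i,j) - \mu_i\mu_j)/(\sigma_i\sigma_j)} (0 when a marginal
#' standard deviation vanishes), entropy \eqn{-\sum p \log_{10} p} (with
#' \eqn{0\log 0 := 0}), the marginal mean \eqn{\mu_i} and marginal variance
#' \eqn{\sigma_i^2}. The symmetric matrix makes the row and column marginals
#' identical. Note the angular second moment is the fourth-power sum, not the
#' classical second-power form (which is reported as energy).
#'
#' @param glcm A normalized symmetric GLCM matrix.
#' @param log_base Base of the entropy logarithm, default 10.
#' @return Named numeric vector of the nine descriptors, in the order of
#'   [haralick_names()].
#' @export
haralick_descriptors <- function(glcm, log_base = 10) {
  P <- unclass(glcm)
  ng <- nrow(P)
  i <- matrix(0:(ng - 1), ng, ng)          # row value
  j <- t(i)                                 # column value
  mu <- sum(i * P)
  sig2 <- sum(P * (i - mu)^2)
  sig <- sqrt(sig2)
  corr <- if (sig > 0) (sum(i * j * P) - mu * mu) / (sig * sig) else 0
  pos <- P > 0
  c(
    contrast      = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity   = sum(P / (1 + (i - j)^2)),
    energy        = sum(P^2),
    asm           = sum(P^4),
    correlation   = corr,
    entropy       = -sum(P[pos] * log(P[pos], base = log_base)),
    mean          = mu,
    variance      = sig2
  )
}

#' Extract the texture feature vector of one image
#'
#' For each configured angle the image is quantized, a GLCM is built at the
#' configured distance, and the nine Haralick descriptors are computed. The
#' concatenation is angle-major: all descriptors for the first angle, then the
#' second, and so on -- 45 values under the defaults.
#'
#' @param image A preprocessed `gray_image`.
#' @param cfg A [texture_config()].
#' @return Named numeric vector of length
#'   `length(cfg$angles) * length(cfg$descriptors)`.
#' @export
extract_feature_vector <- function(image, cfg = texture_config()) {
  assert_gray_image(image)
  lv <- quantize_levels(image, cfg$levels)
  vals <- purrr::map(cfg$angles, function(a) {
    g <- compute_glcm(lv, cfg$distance, a, n_levels = cfg$levels)
    haralick_descriptors(g)[cfg$descriptors]
  })
  setNames(unlist(vals, use.names = FALSE), feature_names(cfg))
}

#' Build a feature table from a labeled dataset
#'
#' Applies [extract_feature_vector()] to every image and assembles a tibble of
#' one row per image: the `label` column followed by the named texture
#' features (`a{angle}_{descriptor}`).
#'
#' @param data A labeled dataset tibble (columns `image`, `label`).
#' @param cfg A [texture_config()].
#' @return A tibble with `label` plus one column per feature.
#' @export
build_feature_table <- function(data, cfg = texture_config()) {
  if (!is.data.frame(data) || !all(c("image", "label") %in% names(data))) {
    abort("`data` must have columns `image` and `label`.")
  }
  if (nrow(data) == 0L) abort("`data` is empty.")
  rows <- purrr::imap(data$image, function(img, i) {
    tryCatch(extract_feature_vector(img, cfg),
             error = function(e) structure(conditionMessage(e), failed = TRUE))
  })
  failed <- which(purrr::map_lgl(rows, ~ isTRUE(attr(.x, "failed"))))
  if (length(failed)) {
    abort(sprintf(
      "feature extraction failed for image(s) %s: %s",
      paste(failed, collapse = ", "), rows[[failed[1]]]
    ))
  }
  X <- do.call(rbind, rows)
  dplyr::bind_cols(tibble(label = as.integer(data$label)), as_tibble(X))
}

feature_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
}

#' Read and write feature tables
#'
#' CSV round-trip for feature tables (header `label,a0_contrast,...`). Values
#' are written with full precision so a written table reloads bit-equal.
#'
#' @param table A feature table tibble.
#' @param path CSV file path.
#' @return `read_feature_table()` returns the feature table tibble.
#' @export
write_feature_table <- function(table, path) {
  out <- as.data.frame(lapply(table, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$label <- as.integer(df$label)
  as_tibble(df)
}
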