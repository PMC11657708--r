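#' Resize an image to a target resolution
#'
#' Resamples by exact area averaging: each output pixel is the overlap-weighted
#' mean of the source pixels it covers, so constant images are invariant and
#' mean intensity is preserved. With `preserve_aspect = TRUE` the image is
#' scaled by the largest factor that fits inside the target and centred on a
#' zero (black) canvas.
#'
#' @param image A `gray_image`.
#' @param target_h,target_w Target height and width in pixels (>= 8).
#' @param preserve_aspect Keep the aspect ratio and pad with zeros?
#' @return A `gray_image` of dimension `target_h` x `target_w` in the same
#'   intensity range as the input.
#' @examples
#' img <- gray_image(matrix(128, 32, 48), "uint8")
#' dim(resize_to(img, 24, 24))
#' @export
resize_to <- function(image, target_h, target_w, preserve_aspect = TRUE) {
  assert_gray_image(image)
  if (target_h < 1 || target_w < 1) {
    abort("target dimensions must be positive.")
  }
  px <- as_pixel_matrix(image)
  h <- nrow(px)
  w <- ncol(px)
  if (preserve_aspect) {
    s <- min(target_h / h, target_w / w)
    inner_h <- max(1L, round(h * s))
    inner_w <- max(1L, round(w * s))
    inner <- area_resample(px, inner_h, inner_w)
    out <- matrix(0, target_h, target_w)
    r0 <- floor((target_h - inner_h) / 2)
    c0 <- floor((target_w - inner_w) / 2)
    out[r0 + seq_len(inner_h), c0 + seq_len(inner_w)] <- inner
  } else {
    out <- area_resample(px, target_h, target_w)
  }
  if (img_range(image) == "uint8") out <- round(out)
  restore_image(out, image)
}

# Box-filter resampling via interval-overlap weight matrices: out = Wr %*% px
# %*% t(Wc), where row r of Wr holds the fractional overlap of output row r's
# source interval with each input row. Rows of the weight matrices sum to 1.
area_resample <- function(px, out_h, out_w) {
  overlap_weights <- function(n_in, n_out) {
    scale <- n_in / n_out
    W <- matrix(0, n_out, n_in)
    for (r in seq_len(n_out)) {
      lo <- (r - 1) * scale
      hi <- r * scale
      cells <- seq.int(floor(lo) + 1L, min(ceiling(hi), n_in))
      wts <- pmin(hi, cells) - pmax(lo, cells - 1)
      W[r, cells] <- wts / sum(wts)
    }
    W
  }
  Wr <- overlap_weights(nrow(px), out_h)
  Wc <- overlap_weights(ncol(px), out_w)
  Wr %*% px %*% t(Wc)
}

#' Crop a rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the crop covers columns
#' `[x, x + w)` and rows `[y, y + h)` of the image.
#'
#' @param image A `gray_image`.
#' @param x,y Top-left corner (0-based column and row offsets).
#' @param h,w Height and width of the crop.
#' @return A `gray_image` of dimension `h` x `w`.
#' @export
crop_roi <- function(image, x, y, h, w) {
  assert_gray_image(image)
  H <- nrow(image)
  W <- ncol(image)
  if (x < 0 || x + w > W) {
    abort(sprintf("crop x-extent [%d, %d) exceeds image width %d.", x, x + w, W))
  }
  if (y < 0 || y + h > H) {
    abort(sprintf("crop y-extent [%d, %d) exceeds image height %d.", y, y + h, H))
  }
  if (h < 1 || w < 1) abort("crop height and width must be positive.")
  px <- as_pixel_matrix(image)
  restore_image(px[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE], image)
}

#' Histogram equalization
#'
#' Standard 256-bin CDF-mapping contrast enhancement for 8-bit images: each
#' intensity v is mapped to `round(255 * cdf(v))`, a monotone transform that
#' flattens the intensity histogram. Must run before [normalize_intensity()]
#' (it requires integer intensities).
#'
#' @param image A `gray_image` with range `"uint8"`.
#' @return An equalized `gray_image`, range `"uint8"`.
#' @export
equalize_histogram <- function(image) {
  assert_gray_image(image)
  if (img_range(image) != "uint8") {
    abort("equalize_histogram() requires an integer 0-255 image; run it before normalization.")
  }
  px <- as_pixel_matrix(image)
  counts <- tabulate(px + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(px)
  lut <- round(255 * cdf)
  restore_image(matrix(lut[px + 1L], nrow(px), ncol(px)), image)
}

#' Speckle suppression by median filtering
#'
#' Applies a square median filter with edge replication. The median is a rank
#' order statistic, so the output range never exceeds the input range, and
#' isolated speckle impulses are removed without blurring edges the way a
#' linear smoother would.
#'
#' @param image A `gray_image`.
#' @param window Odd window side length (>= 3), default 3.
#' @return The filtered `gray_image`, same range.
#' @export
despeckle <- function(image, window = 3L) {
  assert_gray_image(image)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 3.")
  }
  px <- as_pixel_matrix(image)
  restore_image(median_filter(px, window), image)
}

# Median filter with replicated edges, vectorized as a stack of shifted copies.
median_filter <- function(px, window) {
  h <- nrow(px)
  w <- ncol(px)
  k <- (window - 1L) %/% 2L
  offs <- seq.int(-k, k)
  ridx <- pmin(pmax(outer(seq_len(h), offs, `+`), 1L), h)
  cidx <- pmin(pmax(outer(seq_len(w), offs, `+`), 1L), w)
  stack <- matrix(0, h * w, window * window)
  s <- 0L
  for (dc in seq_len(window)) {
    for (dr in seq_len(window)) {
      s <- s + 1L
      stack[, s] <- px[ridx[, dr], cidx[, dc]]
    }
  }
  # median of each row; window^2 is odd so this is an order statistic
  mid <- (window * window + 1L) %/% 2L
  med <- apply(stack, 1L, function(v) sort.int(v, partial = mid)[mid])
  matrix(med, h, w)
}

#' Min-max intensity normalization
#'
#' Maps intensities affinely to \[0, 1\]: `(p - min) / (max - min)`. A constant
#' image maps to all zeros (declared convention for the degenerate case).
#'
#' @param image A `gray_image`.
#' @return A `gray_image` with range `"unit"`.
#' @export
normalize_intensity <- function(image) {
  assert_gray_image(image)
  px <- as_pixel_matrix(image)
  lo <- min(px)
  hi <- max(px)
  out <- if (hi > lo) (px - lo) / (hi - lo) else matrix(0, nrow(px), ncol(px))
  gray_image(out, "unit")
}

#' Rebalance class counts by random over/undersampling
#'
#' Forces every class to exactly `target_per_class` records: classes above the
#' target are randomly subsampled without replacement; classes below it are
#' topped up by randomly duplicating their existing records. No synthetic
#' samples are created. Original record order is preserved among kept samples,
#' with duplicates appended after the originals of their class.
#'
#' @param data A tibble with a `label` column (e.g. a labeled dataset or a
#'   feature table).
#' @param target_per_class Target number of records per class.
#' @param seed Integer seed making the resampling reproducible.
#' @return A tibble with identical columns and exactly `target_per_class`
#'   records per class.
#' @examples
#' tbl <- tibble::tibble(label = rep(0:1, c(8, 3)), x = rnorm(11))
#' table(balance_classes(tbl, 5, seed = 1)$label)
#' @export
balance_classes <- function(data, target_per_class, seed = 1L) {
  if (!is.data.frame(data) || !"label" %in% names(data)) {
    abort("`data` must be a data frame with a `label` column.")
  }
  if (target_per_class < 1) abort("`target_per_class` must be >= 1.")
  labs <- data$label
  if (nrow(data) == 0L) abort("`data` has no records.")
  classes <- sort(unique(labs))
  counts <- table(factor(labs, levels = classes))
  if (any(counts == 0)) {
    abort(sprintf("class %s has no records.", names(counts)[counts == 0][1]))
  }
  idx <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      own <- which(labs == cl)
      n <- length(own)
      if (n > target_per_class) {
        sort(sample(own, target_per_class))
      } else if (n < target_per_class) {
        c(own, sample(own, target_per_class - n, replace = TRUE))
      } else {
        own
      }
    }), use.names = FALSE)
  })
  dplyr::slice(data, idx)
}

#' Run the full preprocessing chain on one image
#'
#' Applies, in order: resize, crop, histogram equalization, despeckling and
#' normalization. Each stage can be disabled; the stage order is fixed.
#'
#' @param image A `gray_image` with range `"uint8"`.
#' @param target_h,target_w Resize target (default 224 x 224).
#' @param crop Optional crop as `c(x, y, h, w)` (0-based, applied after
#'   resizing); `NULL` keeps the whole frame.
#' @param despeckle_window Median filter window (odd, >= 3).
#' @param stages Character vector of enabled stages, any subset of
#'   `c("resize", "crop", "equalize", "despeckle", "normalize")`.
#' @return The preprocessed `gray_image` (range `"unit"` when the normalize
#'   stage is enabled).
#' @export
preprocess_image <- function(image, target_h = 224L, target_w = 224L,
                             crop = NULL, despeckle_window = 3L,
                             stages = c("resize", "crop", "equalize",
                                        "despeckle", "normalize")) {
  assert_gray_image(image)
  stages <- match.arg(stages, several.ok = TRUE)
  if ("resize" %in% stages) {
    image <- resize_to(image, target_h, target_w)
  }
  if ("crop" %in% stages && !is.null(crop)) {
    image <- crop_roi(image, crop[1], crop[2], crop[3], crop[4])
  }
  if ("equalize" %in% stages) {
    image <- equalize_histogram(image)
  }
  if ("despeckle" %in% stages) {
    image <- despeckle(image, despeckle_window)
  }
  if ("normalize" %in% stages) {
    image <- normalize_intensity(image)
  }
  image
}
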