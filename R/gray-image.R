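#' Grayscale image objects
#'
#' A `gray_image` is a numeric matrix of pixel intensities with a declared
#' range: `"uint8"` for integer intensities in 0--255 (the state images are in
#' when read from file) or `"unit"` for real intensities in \[0, 1\] (the state
#' after [normalize_intensity()]). Rows index image height (y), columns width
#' (x).
#'
#' @param pixels Numeric matrix of intensities.
#' @param range `"uint8"` or `"unit"`.
#' @return A `gray_image` object.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), "uint8")
#' dim(img)
#' @export
gray_image <- function(pixels, range = c("uint8", "unit")) {
  range <- match.arg(range)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort("`pixels` must not contain missing or non-finite values.")
  }
  lim <- if (range == "uint8") c(0, 255) else c(0, 1)
  if (min(pixels) < lim[1] || max(pixels) > lim[2]) {
    abort(sprintf(
      "intensities outside the declared '%s' range [%g, %g].",
      range, lim[1], lim[2]
    ))
  }
  structure(pixels, class = c("gray_image", "matrix", "array"), range = range)
}

img_range <- function(image) attr(image, "range", exact = TRUE)

as_pixel_matrix <- function(image) {
  m <- unclass(image)
  attr(m, "range") <- NULL
  m
}

restore_image <- function(pixels, template, range = img_range(template)) {
  gray_image(pixels, range)
}

assert_gray_image <- function(image, arg = "image") {
  if (!inherits(image, "gray_image")) {
    abort(sprintf("`%s` must be a gray_image (see `gray_image()`).", arg))
  }
  invisible(image)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, range %s, intensities [%g, %g]\n",
    nrow(x), ncol(x), img_range(x), min(x), max(x)
  ))
  invisible(x)
}

#' Read and write grayscale images
#'
#' Reads PNG, TIFF or JPEG files as 8-bit grayscale `gray_image` objects.
#' Color inputs are converted by averaging the color channels (luminance
#' average). `write_gray_image()` writes PNG or TIFF.
#'
#' @param path File path; format inferred from the extension.
#' @param image A `gray_image`.
#' @return `read_gray_image()` returns a `gray_image` with range `"uint8"`;
#'   `write_gray_image()` returns `path` invisibly.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    abort(sprintf("unsupported image format '.%s' (use png/tiff/jpeg).", ext))
  )
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    arr <- apply(arr[, , seq_len(min(nch, 3)), drop = FALSE], c(1, 2), mean)
  }
  gray_image(round(arr * 255), "uint8")
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(image, path) {
  assert_gray_image(image)
  px <- as_pixel_matrix(image)
  if (img_range(image) == "uint8") px <- px / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    abort(sprintf("unsupported output format '.%s' (use png/tiff).", ext))
  )
  invisible(path)
}

#' Labeled image datasets
#'
#' A labeled dataset is a tibble with a list-column `image` of `gray_image`
#' objects and an integer `label` column in 0--5. The label encoding follows
#' the six ultrasound plane classes: 0 brain, 1 abdomen, 2 femur, 3 thorax,
#' 4 maternal cervix, 5 other.
#'
#' @param images List of `gray_image` objects.
#' @param labels Integer labels, one per image, each in 0--5.
#' @return A tibble with columns `image` (list) and `label` (integer).
#' @export
labeled_dataset <- function(images, labels) {
  labels <- as.integer(labels)
  if (length(images) != length(labels)) {
    abort("`images` and `labels` must have the same length.")
  }
  if (any(labels < 0L | labels > 5L)) {
    abort("labels must be integers in 0..5.")
  }
  purrr::walk(images, assert_gray_image)
  tibble(image = images, label = labels)
}

#' Plane class names
#'
#' @return Character vector naming classes 0--5.
#' @export
plane_classes <- function() {
  c("brain", "abdomen", "femur", "thorax", "maternal cervix", "other")
}

#' Read a dataset manifest
#'
#' Loads a CSV manifest with columns `path,label` (header required) and reads
#' every referenced image.
#'
#' @param manifest Path to the CSV manifest.
#' @param base_dir Directory image paths are resolved against (defaults to the
#'   manifest's directory).
#' @return A labeled dataset tibble (see [labeled_dataset()]).
#' @export
read_manifest <- function(manifest, base_dir = dirname(manifest)) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df))) {
    abort("manifest must have columns `path` and `label`.")
  }
  paths <- ifelse(
    grepl("^(/|[A-Za-z]:)", df$path), df$path, file.path(base_dir, df$path)
  )
  labeled_dataset(purrr::map(paths, read_gray_image), df$label)
}
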