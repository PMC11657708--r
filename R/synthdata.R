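#' Texture class specification
#'
#' Parameters of one synthetic texture class: a Gaussian random field with an
#' anisotropic correlation structure, multiplied by speckle-like noise. The
#' correlation length sets how coarse the texture is (short lengths give
#' high-contrast fine grain at a fixed co-occurrence distance), the
#' anisotropy angle orients the grain, the contrast scale sets the intensity
#' amplitude around mid-gray, and the speckle variance sets the multiplicative
#' noise level (the standard ultrasound noise model).
#'
#' @param correlation_length Correlation length in pixels (>= 1).
#' @param anisotropy_angle Orientation of the long correlation axis, degrees.
#' @param contrast_scale Intensity amplitude (gray levels per unit field).
#' @param speckle_variance Variance of the zero-mean multiplicative noise
#'   (>= 0).
#' @return A `texture_class_spec` list.
#' @export
texture_class_spec <- function(correlation_length = 4, anisotropy_angle = 0,
                               contrast_scale = 45, speckle_variance = 0.3) {
  if (correlation_length < 1) abort("`correlation_length` must be >= 1.")
  if (speckle_variance < 0) abort("`speckle_variance` must be >= 0.")
  structure(
    list(correlation_length = correlation_length,
         anisotropy_angle = anisotropy_angle,
         contrast_scale = contrast_scale,
         speckle_variance = speckle_variance),
    class = "texture_class_spec"
  )
}

#' Default six-class texture specifications
#'
#' One spec per plane class, with correlation lengths 2, 4, 6, 8, 10, 12
#' pixels, anisotropy angles 0-150 degrees in 30-degree steps and slightly
#' increasing contrast scales, so every class carries a distinct GLCM
#' signature.
#'
#' @param speckle_variance Speckle variance shared by all classes,
#'   default 0.3.
#' @return List of six `texture_class_spec` objects.
#' @export
default_class_specs <- function(speckle_variance = 0.3) {
  purrr::pmap(
    list(len = c(2, 4, 6, 8, 10, 12),
         ang = c(0, 30, 60, 90, 120, 150),
         con = c(40, 45, 50, 55, 60, 65)),
    function(len, ang, con) {
      texture_class_spec(len, ang, con, speckle_variance)
    }
  )
}

# Anisotropic Gaussian smoothing kernel: sd `len` along the orientation axis,
# `len / 3` across it.
anisotropic_kernel <- function(len, angle_deg) {
  s_major <- len
  s_minor <- max(len / 3, 0.6)
  k <- ceiling(2.5 * s_major)
  coords <- seq.int(-k, k)
  X <- matrix(coords, 2 * k + 1, 2 * k + 1, byrow = TRUE) # x (column offset)
  Y <- matrix(coords, 2 * k + 1, 2 * k + 1)               # y (row offset)
  th <- angle_deg * pi / 180
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  ker <- exp(-0.5 * ((u / s_major)^2 + (v / s_minor)^2))
  ker / sum(ker)
}

# Smooth white noise with `ker` via FFT, returning an h x w field free of
# wrap-around artifacts (the noise is generated with a margin of the kernel
# radius on every side).
smoothed_field <- function(h, w, ker) {
  k <- (nrow(ker) - 1L) %/% 2L
  H <- h + 2L * k
  W <- w + 2L * k
  noise <- matrix(rnorm(H * W), H, W)
  kpad <- matrix(0, H, W)
  kpad[seq_len(2 * k + 1), seq_len(2 * k + 1)] <- ker
  # center the kernel at (1, 1) by circular shift
  kpad <- kpad[c((k + 1):H, seq_len(k)), c((k + 1):W, seq_len(k))]
  conv <- Re(fft(fft(noise) * fft(kpad), inverse = TRUE)) / (H * W)
  conv[k + seq_len(h), k + seq_len(w)]
}

#' Generate one synthetic textured image
#'
#' Draws a Gaussian random field by smoothing white noise with an anisotropic
#' Gaussian kernel, standardizes it, scales it by the contrast scale around
#' mid-gray (127.5), multiplies by `(1 + s)` with `s` zero-mean Gaussian
#' speckle of the requested variance, and clips to \[0, 255\].
#'
#' @param spec A [texture_class_spec()].
#' @param h,w Image dimensions (>= 32).
#' @param seed Integer seed; the generator is bit-reproducible.
#' @return A `gray_image` with range `"uint8"`.
#' @examples
#' img <- generate_texture_image(texture_class_spec(4, 45), 64, 64, seed = 1)
#' @export
generate_texture_image <- function(spec, h = 64L, w = 64L, seed = 1L) {
  if (h < 32 || w < 32) abort("`h` and `w` must be >= 32.")
  with_seed(seed, {
    field <- if (spec$contrast_scale == 0) {
      matrix(0, h, w)
    } else {
      z <- smoothed_field(h, w, anisotropic_kernel(spec$correlation_length,
                                                   spec$anisotropy_angle))
      sdz <- sd(as.numeric(z))
      if (sdz > 0) (z - mean(z)) / sdz else z
    }
    img <- 127.5 + spec$contrast_scale * field
    if (spec$speckle_variance > 0) {
      img <- img * (1 + matrix(rnorm(h * w, 0, sqrt(spec$speckle_variance)),
                               h, w))
    }
    gray_image(round(pmin(pmax(img, 0), 255)), "uint8")
  })
}

#' Generate a labeled synthetic dataset
#'
#' Produces textured images for the six plane classes. Either every class
#' gets `n_per_class` images, or `imbalance_counts` supplies one count per
#' class -- e.g. `table2_counts() / 10` for a 1/10-scale replica of the
#' real-data class imbalance.
#'
#' @param specs List of six [texture_class_spec()] objects.
#' @param n_per_class Images per class (ignored when `imbalance_counts` is
#'   given).
#' @param imbalance_counts Optional integer vector of six per-class counts.
#' @param h,w Image dimensions.
#' @param seed Integer seed.
#' @return A labeled dataset tibble (columns `image`, `label`).
#' @export
generate_dataset <- function(specs = default_class_specs(), n_per_class = 30L,
                             imbalance_counts = NULL, h = 64L, w = 64L,
                             seed = 1L) {
  if (length(specs) != 6L) abort("`specs` must contain six class specs.")
  counts <- if (is.null(imbalance_counts)) rep(n_per_class, 6L)
            else as.integer(imbalance_counts)
  if (length(counts) != 6L) abort("`imbalance_counts` must have length 6.")
  images <- list()
  labels <- integer(0)
  idx <- 0L
  for (cl in 0:5) {
    for (i in seq_len(counts[cl + 1L])) {
      idx <- idx + 1L
      images[[idx]] <- generate_texture_image(
        specs[[cl + 1L]], h, w, seed = derive_seed(seed, idx)
      )
      labels[idx] <- cl
    }
  }
  labeled_dataset(images, labels)
}

#' Class counts of the real ultrasound dataset
#'
#' The per-class image counts of the six-class maternal-fetal ultrasound
#' collection the package's defaults emulate: brain 3092, abdomen 711, femur
#' 1040, thorax 1718, maternal cervix 1626, other 4213.
#'
#' @param scale Divisor applied to the counts (rounded), default 1.
#' @return Integer vector of six counts.
#' @export
table2_counts <- function(scale = 1) {
  as.integer(round(c(3092, 711, 1040, 1718, 1626, 4213) / scale))
}

#' Planted feature table specification
#'
#' @param n_per_class Rows per class, default 50.
#' @param n_informative Number of class-informative columns, default 5.
#' @param n_noise Number of pure-noise columns, default 40 (so that
#'   `n_informative + n_noise = 45` by default).
#' @param effect_size Class-mean separation in noise-sd units, default 3.
#' @param n_classes Number of classes, default 6.
#' @param seed Integer seed.
#' @return A `planted_table_spec` list.
#' @export
planted_table_spec <- function(n_per_class = 50L, n_informative = 5L,
                               n_noise = 40L, effect_size = 3,
                               n_classes = 6L, seed = 1L) {
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise), effect_size = effect_size,
         n_classes = as.integer(n_classes), seed = as.integer(seed)),
    class = "planted_table_spec"
  )
}

#' Generate a feature table with planted informative columns
#'
#' Informative columns are drawn Normal(class mean, 1) with class means
#' spaced `effect_size` apart; noise columns are Normal(0, 1) independent of
#' class. Each informative column carries a shifted, saturating ramp of class
#' means (`effect_size * min(max(k - j + 2, 0), 3)` for column j and class
#' k), so the columns are complementary: every column is the main separator
#' of a different stretch of adjacent classes, and no strict subset carries
#' the full class signal. (Giving all columns one identical ramp would make
#' them mutually redundant, and a sparsity-rewarding wrapper fitness would
#' then be maximized by dropping planted columns.) Column positions of the
#' informative features are randomized from the seed, and the ground-truth
#' mask is returned for recovery scoring.
#'
#' @param spec A [planted_table_spec()].
#' @return List with `table` (tibble: `label` + feature columns
#'   `f01, f02, ...`) and `informative` (named logical ground-truth mask).
#' @export
generate_feature_table <- function(spec = planted_table_spec()) {
  p <- spec$n_informative + spec$n_noise
  n <- spec$n_per_class * spec$n_classes
  labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_per_class)
  with_seed(spec$seed, {
    inf_cols <- sort(sample(p, spec$n_informative))
    X <- matrix(rnorm(n * p), n, p)
    for (j in seq_along(inf_cols)) {
      lvl <- pmin(pmax(labels - j + 2L, 0L), 3L)
      X[, inf_cols[j]] <- X[, inf_cols[j]] + spec$effect_size * lvl
    }
    colnames(X) <- sprintf("f%02d", seq_len(p))
    informative <- setNames(seq_len(p) %in% inf_cols, colnames(X))
    list(
      table = dplyr::bind_cols(tibble(label = labels), as_tibble(X)),
      informative = informative
    )
  })
}

#' Write a synthetic image dataset to disk
#'
#' Writes each image as a PNG plus a `manifest.csv` with columns
#' `path,label`, the format [read_manifest()] loads.
#'
#' @param data A labeled dataset tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("img%04d_class%d.png", seq_len(nrow(data)), data$label)
  purrr::walk2(data$image, paths,
               function(img, p) write_gray_image(img, file.path(dir, p)))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(path = paths, label = data$label),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
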