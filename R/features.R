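#' Map a frequency band to FFT bins
#'
#' Returns the inclusive bin range used to crop bispectra before image
#' conversion.  The lower edge is always the first non-DC bin (`k_lo = 1`,
#' about 0.49 Hz at 250 Hz / 512 bins); the upper edge is
#' `k_hi = floor(f_hi * nfft / fs)`.  This is the rule under which a
#' 0.5-12 Hz band at 250 Hz with a 512-point FFT yields bins 1..24 (a 24 x 24
#' crop) and 0.5-14 Hz yields bins 1..28.
#'
#' @param f_lo_hz,f_hi_hz Band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @param fs_hz Sampling rate in Hz.
#' @param nfft FFT length.
#' @return Named integer vector `c(k_lo = 1, k_hi = ...)`.
#' @export
#' @examples
#' band_bins(0.5, 12, 250, 512)  # 1..24
#' band_bins(0.5, 14, 250, 512)  # 1..28
band_bins <- function(f_lo_hz, f_hi_hz, fs_hz, nfft) {
  if (!(f_lo_hz >= 0 && f_lo_hz < f_hi_hz && f_hi_hz <= fs_hz / 2)) {
    abort("band must satisfy 0 <= f_lo < f_hi <= fs/2",
          class = "ecgbispec_invalid_parameter")
  }
  k_hi <- as.integer(floor(f_hi_hz * nfft / fs_hz))
  if (k_hi < 1L) {
    abort("band contains no non-DC bin", class = "ecgbispec_invalid_parameter")
  }
  c(k_lo = 1L, k_hi = k_hi)
}

minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

new_bispectrum_image <- function(pixels, kind, band_hz, bin_range, source) {
  structure(list(pixels = pixels, kind = kind, band_hz = band_hz,
                 bin_range = bin_range, source = source),
            class = "bispectrum_image")
}

#' Convert a bispectrum crop into a normalized gray image
#'
#' Crops the stored bispectrum quadrant to the square sub-matrix over the
#' given bin range on both axes and min-max normalizes it into \[0, 1\]
#' ("conversion into a gray image").  `amplitude_image()` uses `|B|`,
#' `phase_image()` the principal-value phase angle.  Normalization is per
#' image, over the cropped area only; a constant crop maps to all zeros.
#'
#' @param bisp A [bispectrum()].
#' @param band Inclusive bin range as returned by [band_bins()]; default is
#'   the 0.5-12 Hz band of the stored sampling rate (the 24 x 24 network
#'   input at fs = 250, nfft = 512).
#' @param source Optional provenance (e.g. segment id + label) carried on the
#'   image.
#' @param gray_levels Optional integer: quantize pixels to this many evenly
#'   spaced gray levels (e.g. 256 for 8-bit images).  `NULL` (default) keeps
#'   continuous values.
#' @return A `bispectrum_image`: list with `pixels` (square matrix in
#'   \[0, 1\], rows = `k1`), `kind`, `band_hz`, `bin_range`, `source`.
#' @export
#' @examples
#' seg <- generate_segment(rhythm_model("AFIB"), seed = 5)
#' b <- bispectrum(seg$samples[[1]], fs_hz = 250)
#' img <- amplitude_image(b)
#' dim(img$pixels)  # 24 x 24
amplitude_image <- function(bisp, band = NULL, source = NULL,
                            gray_levels = NULL) {
  crop_image(bisp, band, source, kind = "amplitude", gray_levels)
}

#' @rdname amplitude_image
#' @export
phase_image <- function(bisp, band = NULL, source = NULL,
                        gray_levels = NULL) {
  crop_image(bisp, band, source, kind = "phase", gray_levels)
}

crop_image <- function(bisp, band, source, kind, gray_levels = NULL) {
  stopifnot(inherits(bisp, "bispectrum"))
  band <- band %||% band_bins(0.5, 12, bisp$fs_hz, bisp$nfft)
  k_lo <- band[[1]]; k_hi <- band[[2]]
  q <- nrow(bisp$values)
  if (k_lo > k_hi) {
    abort("empty band", class = "ecgbispec_invalid_parameter")
  }
  if (k_lo < 0L || k_hi > q - 1L) {
    abort("band outside the stored bin quadrant",
          class = "ecgbispec_invalid_parameter")
  }
  idx <- (k_lo:k_hi) + 1L
  crop <- bisp$values[idx, idx, drop = FALSE]
  m <- if (kind == "amplitude") Mod(crop) else Arg(crop)
  px <- minmax01(m)
  if (!is.null(gray_levels)) {
    L <- as.integer(gray_levels)
    if (L < 2L) abort("`gray_levels` must be >= 2",
                      class = "ecgbispec_invalid_parameter")
    px <- round(px * (L - 1L)) / (L - 1L)
  }
  new_bispectrum_image(
    px, kind,
    band_hz = c(k_lo, k_hi) * bisp$fs_hz / bisp$nfft,
    bin_range = c(k_lo = k_lo, k_hi = k_hi),
    source = source
  )
}

#' @export
print.bispectrum_image <- function(x, ...) {
  cat("<bispectrum_image> ", x$kind, " | ", nrow(x$pixels), "x",
      ncol(x$pixels), " | band ", signif(x$band_hz[1], 3), "-",
      signif(x$band_hz[2], 4), " Hz\n", sep = "")
  invisible(x)
}

#' @describeIn amplitude_image tidy an image into a long tibble of pixels.
#' @param x A `bispectrum_image`.
#' @param ... Unused.
#' @export
tidy.bispectrum_image <- function(x, ...) {
  ks <- x$bin_range[[1]]:x$bin_range[[2]]
  g <- expand.grid(k1 = ks, k2 = ks)
  tibble(k1 = g$k1, k2 = g$k2, value = as.vector(x$pixels))
}

#' @describeIn amplitude_image raster plot of the gray image.
#' @param object A `bispectrum_image`.
#' @export
autoplot.bispectrum_image <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$k1, .data$k2, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "gray") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "k1 (bin)", y = "k2 (bin)",
                  title = paste("Bispectrum", object$kind, "image"))
}

#' Tile a 28 x 28 image into a 224 x 224 x 3 RGB array
#'
#' Prepares the input of an ImageNet-sized network from a 28 x 28 bispectrum
#' crop: the image is replicated 64 times in an 8 x 8 block grid and copied
#' identically to each of the three colour channels.
#'
#' @param img A `bispectrum_image` (or bare matrix) of size exactly 28 x 28.
#' @return A numeric array of dimension `c(224, 224, 3)`.
#' @export
tile_for_gnn <- function(img) {
  px <- if (inherits(img, "bispectrum_image")) img$pixels else img
  if (!is.matrix(px) || any(dim(px) != c(28L, 28L))) {
    abort("input must be exactly 28 x 28",
          class = "ecgbispec_invalid_parameter")
  }
  tiled <- px[rep(seq_len(28), 8), rep(seq_len(28), 8)]
  array(tiled, dim = c(224L, 224L, 3L))
}

#' Compute bispectrum images for a segment dataset
#'
#' Maps each segment of a [generate_dataset()]-style tibble through the
#' bispectrum estimator and image conversion, carrying label and provenance.
#'
#' @param segments Segment tibble (list-column `samples`).
#' @param config An [estimator_config()].
#' @param band_hz Frequency band `c(lo, hi)` in Hz (default 0.5-12).
#' @param kind `"amplitude"` or `"phase"`.
#' @return The input tibble minus the waveform columns, with a list-column
#'   `image` of `bispectrum_image` objects.
#' @export
segments_to_images <- function(segments, config = estimator_config(),
                               band_hz = c(0.5, 12),
                               kind = c("amplitude", "phase")) {
  kind <- match.arg(kind)
  imgf <- if (kind == "amplitude") amplitude_image else phase_image
  images <- purrr::pmap(
    list(segments$samples, segments$fs_hz, segments$id, segments$label),
    function(x, fs, id, label) {
      b <- bispectrum(x, config, fs_hz = fs)
      imgf(b, band = band_bins(band_hz[1], band_hz[2], fs, config$nfft),
           source = list(id = id, label = label))
    }
  )
  out <- segments[, setdiff(names(segments),
                            c("samples", "onset_s", "rr_s")), drop = FALSE]
  out$image <- images
  as_tibble(out)
}
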