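#' Configuration for the non-parametric bispectrum estimators
#'
#' @param method `"direct"` (averaged FFT triple products) or `"indirect"`
#'   (2-D transform of averaged cumulant lags).
#' @param nfft FFT length (default 512).
#' @param record_len Samples per sub-record (default `nfft`, capped at `nfft`).
#' @param overlap_fraction Overlap between consecutive sub-records, in
#'   \[0, 1) (default 0.5).
#' @param window Taper applied to each sub-record for the direct method:
#'   `"hanning"` or `"rect"`.
#' @param max_lag Maximum cumulant lag for the indirect method; must satisfy
#'   `record_len > 2 * max_lag`.
#' @param lag_window 2-D lag window for the indirect method: `"none"` or
#'   `"parzen"` (product-type window `w(t1) w(t2) w(t1 - t2)`, which keeps all
#'   bispectral symmetries).
#' @param smoothing Optional frequency-domain smoothing for the direct
#'   method: an integer lag half-width `M`; the averaged estimate is
#'   multiplied in the lag domain by the Parzen product window of half-width
#'   `M` (Blackman-Tukey-style smoothing, the frequency-resolution match of
#'   an indirect estimate with `max_lag = M`).  `NULL` (default) disables
#'   smoothing.
#'
#' @return An object of class `estimator_config` (a list).
#' @export
#' @examples
#' estimator_config()
#' estimator_config("indirect", max_lag = 32)
estimator_config <- function(method = c("direct", "indirect"), nfft = 512L,
                             record_len = NULL, overlap_fraction = 0.5,
                             window = c("hanning", "rect"),
                             max_lag = 64L,
                             lag_window = c("none", "parzen"),
                             smoothing = NULL) {
  method <- match.arg(method)
  window <- match.arg(window)
  lag_window <- match.arg(lag_window)
  nfft <- as.integer(nfft)
  record_len <- as.integer(record_len %||% nfft)
  max_lag <- as.integer(max_lag)
  if (nfft < 2L || nfft %% 2L != 0L) {
    abort("`nfft` must be a positive even integer",
          class = "ecgbispec_invalid_parameter")
  }
  if (record_len < 4L || record_len > nfft) {
    abort("`record_len` must satisfy 4 <= record_len <= nfft",
          class = "ecgbispec_invalid_parameter")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must lie in [0, 1)",
          class = "ecgbispec_invalid_parameter")
  }
  if (method == "indirect" && record_len <= 2L * max_lag) {
    abort("indirect method needs record_len > 2 * max_lag",
          class = "ecgbispec_invalid_parameter")
  }
  if (!is.null(smoothing)) {
    smoothing <- as.integer(smoothing)
    if (smoothing < 1L || smoothing >= nfft %/% 2L) {
      abort("`smoothing` must be an integer in [1, nfft/2)",
            class = "ecgbispec_invalid_parameter")
    }
  }
  structure(list(method = method, nfft = nfft, record_len = record_len,
                 overlap_fraction = overlap_fraction, window = window,
                 max_lag = max_lag, lag_window = lag_window,
                 smoothing = smoothing),
            class = "estimator_config")
}

#' @export
print.estimator_config <- function(x, ...) {
  cat("<estimator_config>", x$method, "| nfft", x$nfft, "| record_len",
      x$record_len, "| overlap", x$overlap_fraction,
      if (x$method == "direct") paste("| window", x$window)
      else paste("| max_lag", x$max_lag, "| lag_window", x$lag_window), "\n")
  invisible(x)
}

record_offsets <- function(n, record_len, overlap_fraction) {
  step <- max(1L, as.integer(round(record_len * (1 - overlap_fraction))))
  if (n < record_len) {
    abort("signal shorter than one sub-record",
          class = "ecgbispec_invalid_parameter")
  }
  seq(0L, n - record_len, by = step)
}

taper_vector <- function(window, len) {
  switch(window,
    rect = rep(1, len),
    # periodic Hann taper
    hanning = 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / len)
  )
}

#' Estimate the bispectrum of a time series
#'
#' The bispectrum `B(f1, f2)` is the double Fourier transform of the
#' third-order cumulant sequence; for a zero-mean series it measures
#' third-order (quadratic phase) structure and vanishes in expectation for
#' Gaussian processes.  Two conventional non-parametric estimators are
#' provided:
#'
#' * **direct**: the signal is split into overlapping sub-records; each is
#'   mean-subtracted, tapered and transformed (FFT of length `nfft`), the
#'   triple products `X(k1) X(k2) conj(X(k1 + k2))` are accumulated on the
#'   bifrequency grid and averaged over sub-records;
#' * **indirect**: per-record third-order cumulant lag grids are averaged,
#'   multiplied by a 2-D lag window, and transformed by a 2-D DFT on the
#'   `nfft` grid.
#'
#' The estimate is stored on the full non-negative bin quadrant
#' `[0, nfft/2] x [0, nfft/2]`; bin `k` maps to frequency `k * fs_hz / nfft`.
#' The triangular non-redundant region can be obtained with
#' [nonredundant_mask()].
#'
#' @param x Numeric vector (a single-channel ECG segment, typically 1250
#'   samples = 5 s at 250 Hz).
#' @param config An [estimator_config()].
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `bispectrum`: list with `values` (complex
#'   `(nfft/2 + 1)` square matrix, bin 0 = DC in row/column 1), `nfft`,
#'   `fs_hz`, `config`, `n_records_averaged`.
#' @export
#' @examples
#' seg <- generate_segment(rhythm_model("N"), seed = 3)
#' b <- bispectrum(seg$samples[[1]], estimator_config(), fs_hz = 250)
#' b
bispectrum <- function(x, config = estimator_config(), fs_hz = 1) {
  stopifnot(inherits(config, "estimator_config"))
  if (config$method == "direct") {
    bispectrum_direct(x, config, fs_hz)
  } else {
    bispectrum_indirect(x, config, fs_hz)
  }
}

#' @rdname bispectrum
#' @export
bispectrum_direct <- function(x, config = estimator_config(), fs_hz = 1) {
  nfft <- config$nfft
  rl <- config$record_len
  offs <- record_offsets(length(x), rl, config$overlap_fraction)
  w <- taper_vector(config$window, rl)
  half <- nfft %/% 2L
  q <- half + 1L
  full <- !is.null(config$smoothing)  # lag-window smoothing needs all bins
  ks <- if (full) 0:(nfft - 1L) else 0:half
  sum_idx <- (outer(ks, ks, `+`) %% nfft) + 1L   # bin (k1+k2) wrapped
  acc <- matrix(0 + 0i, length(ks), length(ks))
  for (off in offs) {
    xr <- x[(off + 1L):(off + rl)]
    xr <- (xr - mean(xr)) * w
    X <- fft(c(xr, numeric(nfft - rl)))
    Xs <- X[seq_along(ks)]
    acc <- acc + outer(Xs, Xs) * Conj(X[sum_idx]) / rl
  }
  B <- acc / length(offs)
  if (full) {
    c3 <- fft(B, inverse = TRUE) / nfft^2
    taus <- 0:(nfft - 1L)
    taus <- ifelse(taus > half, taus - nfft, taus)
    M <- config$smoothing
    p1 <- function(tau) {
      a <- abs(tau) / (M + 1)
      ifelse(a <= 0.5, 1 - 6 * a^2 + 6 * a^3,
             ifelse(a <= 1, 2 * (1 - a)^3, 0))
    }
    W <- outer(p1(taus), p1(taus)) * outer(taus, taus,
                                           function(a, b) p1(a - b))
    B <- fft(c3 * W)[1:q, 1:q]
  }
  new_bispectrum(B, nfft, fs_hz, config, length(offs))
}

lag_window_matrix <- function(kind, L) {
  taus <- -L:L
  if (kind == "none") return(matrix(1, 2L * L + 1L, 2L * L + 1L))
  # Parzen 1-D lag window, applied as the product window w(t1) w(t2) w(t1-t2).
  parzen1 <- function(tau) {
    a <- abs(tau) / (L + 1)
    ifelse(a <= 0.5, 1 - 6 * a^2 + 6 * a^3,
           ifelse(a <= 1, 2 * (1 - a)^3, 0))
  }
  w1 <- parzen1(taus)
  outer(w1, w1) * outer(taus, taus, function(a, b) parzen1(a - b))
}

#' @rdname bispectrum
#' @export
bispectrum_indirect <- function(x, config = estimator_config("indirect"),
                                fs_hz = 1) {
  nfft <- config$nfft
  rl <- config$record_len
  L <- config$max_lag
  offs <- record_offsets(length(x), rl, config$overlap_fraction)
  acc <- matrix(0, 2L * L + 1L, 2L * L + 1L)
  for (off in offs) {
    xr <- x[(off + 1L):(off + rl)]
    acc <- acc + third_order_cumulant_sequence(xr, L, fs_hz)$values
  }
  c3 <- (acc / length(offs)) * lag_window_matrix(config$lag_window, L)
  # Embed the lag grid on the nfft x nfft circle (negative lags wrap) and
  # take the 2-D DFT: B(k1,k2) = sum C3(t1,t2) exp(-2i pi (k1 t1 + k2 t2)/nfft)
  M <- matrix(0, nfft, nfft)
  wrap <- ((-L:L) %% nfft) + 1L
  M[wrap, wrap] <- c3
  Bfull <- fft(M)
  q <- nfft %/% 2L + 1L
  new_bispectrum(Bfull[1:q, 1:q], nfft, fs_hz, config, length(offs))
}

new_bispectrum <- function(values, nfft, fs_hz, config, n_records) {
  structure(list(values = values, nfft = as.integer(nfft), fs_hz = fs_hz,
                 config = config, n_records_averaged = as.integer(n_records)),
            class = "bispectrum")
}

#' @export
print.bispectrum <- function(x, ...) {
  cat("<bispectrum> ", x$config$method, " estimator | nfft ", x$nfft,
      " | fs ", x$fs_hz, " Hz | ", x$n_records_averaged,
      " record(s) averaged | peak |B| ", signif(max(Mod(x$values)), 4),
      "\n", sep = "")
  invisible(x)
}

#' Non-redundant triangular bifrequency region
#'
#' Because of the symmetries of the third-order cumulant, the bispectrum is
#' fully determined by its values on the triangle
#' `f2 >= 0, f1 >= f2, f1 + f2 <= fs/2`, realized on FFT bins as
#' `k2 >= 0 & k1 >= k2 & k1 + k2 <= nfft/2` (the `k1 >= k2` half of the
#' exchange symmetry is taken as canonical).
#'
#' @param nfft Even positive FFT length.
#' @param fs_hz Sampling rate (metadata; the mask itself is bin-based).
#' @return Logical `(nfft/2 + 1)` square matrix over the non-negative bin
#'   quadrant, `TRUE` inside the non-redundant triangle; rows index `k1`,
#'   columns `k2`, bin 0 in row/column 1.
#' @export
#' @examples
#' sum(nonredundant_mask(8))
nonredundant_mask <- function(nfft, fs_hz = 1) {
  nfft <- as.integer(nfft)
  if (nfft <= 0L || nfft %% 2L != 0L) {
    abort("`nfft` must be even and positive",
          class = "ecgbispec_invalid_parameter")
  }
  half <- nfft %/% 2L
  ks <- 0:half
  outer(ks, ks, function(k1, k2) k1 >= k2 & (k1 + k2) <= half)
}

#' @describeIn bispectrum tidy a bispectrum into a long tibble with bin
#'   indices, frequencies (Hz), amplitude, phase and the non-redundant flag.
#' @param ... Unused.
#' @export
tidy.bispectrum <- function(x, ...) {
  half <- x$nfft %/% 2L
  ks <- 0:half
  g <- expand.grid(k1 = ks, k2 = ks)
  tibble(
    k1 = g$k1, k2 = g$k2,
    f1_hz = g$k1 * x$fs_hz / x$nfft,
    f2_hz = g$k2 * x$fs_hz / x$nfft,
    amplitude = as.vector(Mod(x$values)),
    phase = as.vector(Arg(x$values)),
    nonredundant = as.vector(nonredundant_mask(x$nfft))
  )
}

#' @describeIn bispectrum amplitude map of the bispectrum as a ggplot raster.
#' @param object A `bispectrum`.
#' @param band_hz Optional frequency band `c(lo, hi)` to restrict the plot to.
#' @export
autoplot.bispectrum <- function(object, band_hz = NULL, ...) {
  d <- tidy(object)
  if (!is.null(band_hz)) {
    d <- dplyr::filter(d, .data$f1_hz <= band_hz[2], .data$f2_hz <= band_hz[2])
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$f1_hz, .data$f2_hz,
                                  fill = log1p(.data$amplitude))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log(1+|B|)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "f1 [Hz]", y = "f2 [Hz]",
                  title = sprintf("Bispectrum amplitude (%s estimator)",
                                  object$config$method))
}
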