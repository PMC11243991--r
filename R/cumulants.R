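#' Sample joint cumulants
#'
#' Second- and third-order joint cumulants of equal-length samples, with
#' expectations estimated by arithmetic means.  The second-order joint
#' cumulant is the (uncentred-product) covariance
#' `E(XY) - E(X)E(Y)`; the third-order joint cumulant uses the five-term
#' moment expansion
#' `E(XYZ) - E(X)E(YZ) - E(Y)E(XZ) - E(Z)E(XY) + 2 E(X)E(Y)E(Z)`,
#' the order-three case of the Leonov-Shiryaev partition formula.  For
#' mean-subtracted inputs both reduce to plain product moments.
#'
#' @param x,y,z Numeric vectors of equal length (>= 2).
#' @return A single number.
#' @export
#' @examples
#' x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
#' joint_cumulant2(x, y)
joint_cumulant2 <- function(x, y) {
  check_equal_lengths(x, y)
  mean(x * y) - mean(x) * mean(y)
}

#' @rdname joint_cumulant2
#' @export
joint_cumulant3 <- function(x, y, z) {
  check_equal_lengths(x, y, z)
  mean(x * y * z) -
    mean(x) * mean(y * z) -
    mean(y) * mean(x * z) -
    mean(z) * mean(x * y) +
    2 * mean(x) * mean(y) * mean(z)
}

check_equal_lengths <- function(...) {
  ls <- lengths(list(...))
  if (length(unique(ls)) != 1L) {
    abort("input sequences must have equal lengths",
          class = "ecgbispec_length_mismatch")
  }
  if (ls[1] < 2L) {
    abort("input sequences must have length >= 2",
          class = "ecgbispec_invalid_parameter")
  }
  invisible(TRUE)
}

#' Third-order cumulant sequence of a time series
#'
#' Biased (1/N-normalized) sample estimate of
#' `C3(tau1, tau2) = E(x(t) x(t + tau1) x(t + tau2))` for every lag pair on
#' the square grid `tau in [-max_lag, max_lag]^2`.  The series is
#' mean-subtracted internally, so the plain triple-product estimator applies.
#' The estimate is symmetric under exchange of the two lags.
#'
#' @param x Numeric vector, `length(x) > 2 * max_lag`.
#' @param max_lag Maximum lag (samples).
#' @param fs_hz Sampling rate stored with the grid (metadata only).
#' @return An object of class `cumulant_grid`: a list with `values`
#'   (a `(2*max_lag+1)` square matrix, lag 0 at the centre), `max_lag`,
#'   `fs_hz`.
#' @export
#' @examples
#' g <- third_order_cumulant_sequence(rnorm(256), max_lag = 4)
#' g$values[5, 5]  # C3(0,0): the third central moment estimate
third_order_cumulant_sequence <- function(x, max_lag, fs_hz = 1) {
  max_lag <- as.integer(max_lag)
  n <- length(x)
  if (max_lag < 0L || n <= 2L * max_lag) {
    abort("`max_lag` must satisfy length(x) > 2 * max_lag",
          class = "ecgbispec_invalid_parameter")
  }
  x <- x - mean(x)
  L <- max_lag
  vals <- matrix(0, 2L * L + 1L, 2L * L + 1L)
  # C3(t1,t2): sum over t with t, t+t1, t+t2 all in range; biased 1/n norm.
  for (t1 in -L:L) {
    for (t2 in -L:t1) {  # fill lower triangle, mirror by symmetry
      lo <- max(0L, -t1, -t2)
      hi <- n - 1L - max(0L, t1, t2)
      if (hi >= lo) {
        idx <- lo:hi
        v <- sum(x[idx + 1L] * x[idx + t1 + 1L] * x[idx + t2 + 1L]) / n
      } else v <- 0
      vals[t1 + L + 1L, t2 + L + 1L] <- v
      vals[t2 + L + 1L, t1 + L + 1L] <- v
    }
  }
  structure(list(values = vals, max_lag = L, fs_hz = fs_hz),
            class = "cumulant_grid")
}

#' @export
print.cumulant_grid <- function(x, ...) {
  cat("<cumulant_grid> lags [-", x$max_lag, ", ", x$max_lag, "], C3(0,0) = ",
      signif(x$values[x$max_lag + 1, x$max_lag + 1], 5), "\n", sep = "")
  invisible(x)
}

#' @describeIn third_order_cumulant_sequence tidy the grid into a long tibble
#'   with columns `tau1`, `tau2` (lags in samples) and `c3`.
#' @param x A `cumulant_grid`.
#' @param ... Unused.
#' @export
tidy.cumulant_grid <- function(x, ...) {
  L <- x$max_lag
  g <- expand.grid(tau1 = -L:L, tau2 = -L:L)
  tibble(tau1 = g$tau1, tau2 = g$tau2, c3 = as.vector(x$values))
}
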