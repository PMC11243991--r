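#' The AFIB-NET architecture
#'
#' Builds the layer table of the compact serial CNN used to classify 24 x 24
#' bispectrum amplitude images: five convolution blocks (3 x 3 kernels with
#' 8, 16, 32, 64, 128 filters, stride 1, same padding), each followed by
#' batch normalization and a rectifier, with 2 x 2 max pooling after the
#' first four blocks (strides 1, 1, 2, 2), then a fully connected layer to
#' the two rhythm classes, softmax, and the classification output.  The
#' spatial size follows 24 -> 24 -> 23 -> 23 -> 22 -> 22 -> 11 -> 11 -> 5 ->
#' 5 -> 1.
#'
#' @param input_size Side of the square single-channel input image
#'   (default 24).
#' @param n_classes Number of output classes (default 2).
#' @return A tibble of class `afibnet_spec` with one row per layer: `layer`,
#'   `type`, `filter_size`, `n_filters`, `stride`, `activation` (character
#'   "S x S x C"), `s`, `channels`, `n_learnables`.
#' @export
#' @examples
#' spec <- build_afibnet()
#' spec[spec$layer == 13, ]
#' sum(spec$n_learnables)
build_afibnet <- function(input_size = 24L, n_classes = 2L) {
  filters <- c(8L, 16L, 32L, 64L, 128L)
  pool_stride <- c(1L, 1L, 2L, 2L)
  s <- as.integer(input_size)
  cin <- 1L
  rows <- list(layer_row(1L, "image_input", s = s, channels = 1L))
  li <- 1L
  for (b in seq_along(filters)) {
    cout <- filters[b]
    li <- li + 1L
    rows[[length(rows) + 1L]] <- layer_row(
      li, "convolution", filter_size = "3 x 3", n_filters = cout,
      stride = "[1 1]", s = s, channels = cout,
      n_learnables = 9L * cin * cout + cout
    )
    li <- li + 1L
    rows[[length(rows) + 1L]] <- layer_row(
      li, "batch_norm", s = s, channels = cout, n_learnables = 2L * cout
    )
    li <- li + 1L
    rows[[length(rows) + 1L]] <- layer_row(li, "relu", s = s, channels = cout)
    if (b <= 4L) {
      st <- pool_stride[b]
      s <- (s - 2L) %/% st + 1L
      li <- li + 1L
      rows[[length(rows) + 1L]] <- layer_row(
        li, "max_pool", stride = sprintf("[%d %d]", st, st),
        s = s, channels = cout
      )
    }
    cin <- cout
  }
  fan_in <- s * s * cin
  li <- li + 1L
  rows[[length(rows) + 1L]] <- layer_row(
    li, "fully_connected", s = 1L, channels = n_classes,
    n_learnables = fan_in * n_classes + n_classes
  )
  rows[[length(rows) + 1L]] <- layer_row(li + 1L, "softmax", s = 1L,
                                         channels = n_classes)
  rows[[length(rows) + 1L]] <- layer_row(li + 2L, "classification", s = 1L,
                                         channels = n_classes)
  out <- bind_rows(rows)
  class(out) <- c("afibnet_spec", class(out))
  out
}

layer_row <- function(layer, type, filter_size = NA_character_,
                      n_filters = NA_integer_, stride = NA_character_,
                      s, channels, n_learnables = 0L) {
  tibble(
    layer = as.integer(layer), type = type, filter_size = filter_size,
    n_filters = n_filters, stride = stride,
    activation = sprintf("%d x %d x %d", s, s, channels),
    s = as.integer(s), channels = as.integer(channels),
    n_learnables = as.integer(n_learnables)
  )
}

#' Learnable-parameter accounting for a network spec
#'
#' Recomputes per-layer learnable counts from the structural fields alone
#' (convolution: `k*k*C_in*C_out + C_out`; batch normalization: `2*C`; fully
#' connected: `fan_in*n_classes + n_classes`) and totals them.
#'
#' @param spec An `afibnet_spec` as returned by [build_afibnet()].
#' @return A tibble `layer`, `type`, `n_learnables` plus an attribute
#'   `total`; `glance()`-style total also returned via `attr(x, "total")`.
#' @export
#' @examples
#' cl <- count_learnables(build_afibnet())
#' attr(cl, "total")  # 105138
count_learnables <- function(spec) {
  stopifnot(inherits(spec, "afibnet_spec"))
  counts <- integer(nrow(spec))
  prev_channels <- 1L
  prev_s <- spec$s[1]
  for (i in seq_len(nrow(spec))) {
    type <- spec$type[i]
    if (type == "convolution") {
      counts[i] <- 9L * prev_channels * spec$n_filters[i] + spec$n_filters[i]
    } else if (type == "batch_norm") {
      counts[i] <- 2L * spec$channels[i]
    } else if (type == "fully_connected") {
      counts[i] <- prev_s^2 * prev_channels * spec$channels[i] +
        spec$channels[i]
    }
    prev_channels <- spec$channels[i]
    prev_s <- spec$s[i]
  }
  out <- tibble(layer = spec$layer, type = spec$type, n_learnables = counts)
  attr(out, "total") <- sum(counts)
  out
}

init_params <- function(seed, input_size = 24L, n_classes = 2L) {
  filters <- c(8L, 16L, 32L, 64L, 128L)
  withr::with_seed(as.integer(seed), {
    p <- list()
    cin <- 1L
    for (l in seq_along(filters)) {
      cout <- filters[l]
      fan_in <- 9L * cin
      p[[paste0("W", l)]] <- matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                                    fan_in, cout)
      p[[paste0("b", l)]] <- numeric(cout)
      p[[paste0("g", l)]] <- rep(1, cout)
      p[[paste0("be", l)]] <- numeric(cout)
      cin <- cout
    }
    spec <- build_afibnet(input_size, n_classes)
    fc_fan <- spec$s[nrow(spec) - 3L]^2 * filters[length(filters)]
    p$Wfc <- matrix(rnorm(n_classes * fc_fan, 0, sqrt(2 / fc_fan)),
                    n_classes, fc_fan)
    p$bfc <- numeric(n_classes)
    p
  })
}

init_run_stats <- function() {
  filters <- c(8L, 16L, 32L, 64L, 128L)
  rs <- list()
  for (l in seq_along(filters)) {
    rs[[paste0("rm", l)]] <- numeric(filters[l])
    rs[[paste0("rv", l)]] <- rep(1, filters[l])
  }
  rs
}

image_list <- function(images) {
  lapply(images, function(im) {
    px <- if (inherits(im, "bispectrum_image")) im$pixels else im
    storage.mode(px) <- "double"
    px
  })
}

#' Train AFIB-NET on bispectrum images
#'
#' Minimizes the softmax cross-entropy by mini-batch stochastic gradient
#' descent with momentum.  The initial learning rate defaults to
#' `0.1 * mini_batch / 128` (0.025 at the default mini-batch of 32).  Batch
#' normalization uses mini-batch moments during training and exponentially
#' averaged running moments at prediction time.  Given identical inputs and
#' `seed`, training is deterministic (single-threaded numerical kernels).
#'
#' @param images List of 24 x 24 matrices (or `bispectrum_image` objects), or
#'   a tibble with an `image` list-column and a `label` column as produced by
#'   [segments_to_images()].
#' @param labels Character/factor vector in `{"AFIB", "N"}`; ignored when
#'   `images` is a tibble carrying labels.
#' @param epochs Training epochs (default 40).
#' @param mini_batch Mini-batch size (default 32).
#' @param ilr Initial learning rate; default `0.1 * mini_batch / 128`.
#' @param momentum SGD momentum (default 0.9).
#' @param seed Integer seed for weight initialization and shuffling.
#' @param validation Optional list `list(images =, labels =)` evaluated once
#'   per epoch.
#' @param verbose Print per-epoch progress?
#' @return An object of class `afibnet_fit`: parameters, running BN moments,
#'   the architecture table, the training `history` tibble and the training
#'   configuration.
#' @export
afibnet_train <- function(images, labels = NULL, epochs = 40L,
                          mini_batch = 32L, ilr = 0.1 * mini_batch / 128,
                          momentum = 0.9, seed = 1L, validation = NULL,
                          verbose = FALSE) {
  if (is.data.frame(images)) {
    labels <- labels %||% images$label
    images <- images$image
  }
  if (length(images) == 0L) {
    abort("empty training set", class = "ecgbispec_invalid_parameter")
  }
  xs <- image_list(images)
  dims <- vapply(xs, dim, integer(2))
  if (any(dims != dims[, 1])) {
    abort("all images must share the same (square) size",
          class = "ecgbispec_shape_error")
  }
  input_size <- dims[1, 1]
  y <- as.integer(factor(as.character(labels), levels = c("AFIB", "N"))) - 1L
  if (anyNA(y)) abort("labels must be 'AFIB' or 'N'",
                      class = "ecgbispec_invalid_parameter")
  n <- length(xs)
  params <- init_params(seed, input_size = input_size)
  run_stats <- init_run_stats()
  vel <- lapply(params, function(p) p * 0)
  hist_rows <- vector("list", epochs)
  bn_momentum <- 0.9
  withr::with_seed(as.integer(seed) + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L; nb <- 0L
      for (start in seq(1L, n, by = mini_batch)) {
        idx <- ord[start:min(start + mini_batch - 1L, n)]
        res <- cnn_pass(params, xs[idx], y[idx], TRUE, run_stats)
        g <- res$grads
        for (nm in names(params)) {
          vel[[nm]] <- momentum * vel[[nm]] - ilr * g[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        for (l in 1:5) {
          run_stats[[paste0("rm", l)]] <-
            bn_momentum * run_stats[[paste0("rm", l)]] +
            (1 - bn_momentum) * res$batch_means[[l]]
          run_stats[[paste0("rv", l)]] <-
            bn_momentum * run_stats[[paste0("rv", l)]] +
            (1 - bn_momentum) * res$batch_vars[[l]]
        }
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_correct <- ep_correct +
          sum((res$probs[, 1] >= 0.5) == (y[idx] == 0L))
        nb <- nb + length(idx)
      }
      row <- tibble(epoch = ep, loss = ep_loss / nb,
                    accuracy = ep_correct / nb,
                    val_accuracy = NA_real_)
      if (!is.null(validation)) {
        vp <- predict_probs(params, run_stats, image_list(validation$images))
        vy <- as.integer(factor(as.character(validation$labels),
                                levels = c("AFIB", "N"))) - 1L
        row$val_accuracy <- mean((vp[, 1] >= 0.5) == (vy == 0L))
      }
      hist_rows[[ep]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", ep, row$loss,
                        row$accuracy,
                        if (is.na(row$val_accuracy)) ""
                        else sprintf("  val_acc %.3f", row$val_accuracy)))
      }
    }
  })
  structure(list(
    params = params, run_stats = run_stats, spec = build_afibnet(input_size),
    history = bind_rows(hist_rows),
    config = list(epochs = epochs, mini_batch = mini_batch, ilr = ilr,
                  momentum = momentum, seed = seed, n_train = n)
  ), class = "afibnet_fit")
}

predict_probs <- function(params, run_stats, xs, batch = 256L) {
  out <- matrix(NA_real_, length(xs), 2)
  for (start in seq(1L, length(xs), by = batch)) {
    idx <- start:min(start + batch - 1L, length(xs))
    out[idx, ] <- cnn_pass(params, xs[idx], integer(0), FALSE, run_stats)$probs
  }
  out
}

#' @export
print.afibnet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("<afibnet_fit> ", x$config$epochs, " epochs | mini-batch ",
      x$config$mini_batch, " | ilr ", x$config$ilr, " | final loss ",
      signif(h$loss, 4), " | train acc ", signif(h$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Predict AFIB scores for bispectrum images
#'
#' @param object An `afibnet_fit`.
#' @param images List of image matrices / `bispectrum_image`s, or a tibble
#'   with an `image` column.
#' @param threshold Decision threshold on the AFIB softmax score
#'   (default 0.5).
#' @param ... Unused.
#' @return A tibble with `score_afib` (softmax probability of the AFIB
#'   class), `score_n` and `label` (`"AFIB"` iff `score_afib >= threshold`).
#' @export
predict.afibnet_fit <- function(object, images, threshold = 0.5, ...) {
  if (is.data.frame(images)) images <- images$image
  xs <- image_list(images)
  sz <- object$spec$s[1]
  bad <- vapply(xs, function(m) !all(dim(m) == c(sz, sz)), logical(1))
  if (any(bad)) {
    abort(sprintf("images must be %d x %d", sz, sz),
          class = "ecgbispec_shape_error")
  }
  p <- predict_probs(object$params, object$run_stats, xs)
  tibble(
    score_afib = p[, 1], score_n = p[, 2],
    label = ifelse(p[, 1] >= threshold, "AFIB", "N")
  )
}

#' @describeIn afibnet_train per-epoch training history as a tibble.
#' @param x An `afibnet_fit`.
#' @param ... Unused.
#' @export
tidy.afibnet_fit <- function(x, ...) x$history

#' @describeIn afibnet_train one-row model summary (final loss/accuracy,
#'   learnable total, configuration).
#' @export
glance.afibnet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(
    epochs = x$config$epochs, mini_batch = x$config$mini_batch,
    ilr = x$config$ilr, n_train = x$config$n_train,
    final_loss = h$loss, final_accuracy = h$accuracy,
    final_val_accuracy = h$val_accuracy,
    n_learnables = attr(count_learnables(x$spec), "total")
  )
}

#' @describeIn afibnet_train loss/accuracy learning curves.
#' @param object An `afibnet_fit`.
#' @export
autoplot.afibnet_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "measure", values_to = "value")
  d <- dplyr::filter(d, !is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "AFIB-NET training history")
}
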