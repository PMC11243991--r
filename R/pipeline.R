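#' Balanced subsampling of a labelled segment set
#'
#' Samples `n_total / 2` segments per class without replacement,
#' reproducibly for a given seed ("half and half" class balance).
#'
#' @param segments Segment (or image) tibble with a `label` column.
#' @param n_total Total number of rows to keep (even).
#' @param seed Integer seed.
#' @param classes The two class labels (default `c("AFIB", "N")`).
#' @return The subsampled tibble (AFIB rows first).
#' @export
sample_balanced <- function(segments, n_total, seed = 1,
                            classes = c("AFIB", "N")) {
  if (n_total < 2 || n_total %% 2 != 0) {
    abort("`n_total` must be a positive even number",
          class = "ecgbispec_invalid_parameter")
  }
  per <- n_total %/% 2L
  withr::with_seed(as.integer(seed), {
    parts <- lapply(classes, function(cl) {
      idx <- which(segments$label == cl)
      if (length(idx) < per) {
        abort(sprintf("class %s has only %d segments, %d requested",
                      cl, length(idx), per),
              class = "ecgbispec_insufficient_class")
      }
      segments[sort(sample(idx, per)), , drop = FALSE]
    })
    bind_rows(parts)
  })
}

#' Train / validation / test split
#'
#' Randomly partitions a dataset into disjoint, exhaustive subsets with the
#' given fractions (default 70/10/20).  In `"segment"` mode rows are split
#' independently; in `"record"` mode all rows sharing a record id (the part
#' of `id` before the first `-ch`) stay in the same subset, which prevents
#' information leakage between training and test data from one recording.
#'
#' @param data Tibble with an `id` column.
#' @param fractions Named numeric vector summing to 1
#'   (default `c(train = 0.7, val = 0.1, test = 0.2)`).
#' @param seed Integer seed.
#' @param mode `"segment"` or `"record"`.
#' @return The input tibble with an added `split` factor column.
#' @export
split_dataset <- function(data,
                          fractions = c(train = 0.7, val = 0.1, test = 0.2),
                          seed = 1, mode = c("segment", "record")) {
  mode <- match.arg(mode)
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    abort("`fractions` must be non-negative and sum to 1",
          class = "ecgbispec_invalid_parameter")
  }
  n <- nrow(data)
  part_sizes <- function(n) {
    sz <- floor(n * fractions)
    rem <- n - sum(sz)
    if (rem > 0) {
      frac_part <- n * fractions - sz
      give <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
      sz[give] <- sz[give] + 1L
    }
    sz
  }
  withr::with_seed(as.integer(seed), {
    if (mode == "segment") {
      sz <- part_sizes(n)
      lab <- rep(names(fractions), sz)
      data$split <- factor(sample(lab), levels = names(fractions))
    } else {
      rid <- sub("-ch.*$", "", data$id)
      ids <- sample(unique(rid))
      target <- part_sizes(n)
      assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
      filled <- stats::setNames(numeric(length(fractions)), names(fractions))
      counts <- table(rid)
      for (id in ids) {
        deficit <- (target - filled) / pmax(target, 1)
        pick <- names(fractions)[which.max(deficit)]
        assigned[id] <- pick
        filled[pick] <- filled[pick] + counts[[id]]
      }
      data$split <- factor(unname(assigned[rid]), levels = names(fractions))
    }
  })
  data
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run.  Two profiles are shipped:
#' `"desk"` (synthetic data, 1000 images, 10 epochs - the scale used
#' throughout the package's own tests) and `"paper"` (a WFDB database
#' directory, 18,000 images, 40 epochs).
#'
#' @param source `"synthetic"` or `"wfdb"`.
#' @param db_dir WFDB database directory (for `source = "wfdb"`).
#' @param n_images Total images, split half and half between classes.
#' @param band_hz Bispectrum crop band in Hz (default 0.5-12, the 24 x 24
#'   network input).
#' @param estimator An [estimator_config()].
#' @param epochs,mini_batch,ilr Training schedule; `ilr = NULL` uses the
#'   `0.1 * mini_batch / 128` default.
#' @param split_fractions Train/validation/test fractions.
#' @param split_mode `"segment"` or `"record"` (see [split_dataset()]).
#' @param seed Master seed; every random stage derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = c("synthetic", "wfdb"), db_dir = NULL,
                            n_images = 1000, band_hz = c(0.5, 12),
                            estimator = estimator_config(), epochs = 10L,
                            mini_batch = 32L, ilr = NULL,
                            split_fractions = c(train = 0.7, val = 0.1,
                                                test = 0.2),
                            split_mode = "segment", seed = 1L) {
  source <- match.arg(source)
  cfg <- list(source = source, db_dir = db_dir, n_images = as.integer(n_images),
              band_hz = band_hz, estimator = estimator,
              epochs = as.integer(epochs), mini_batch = as.integer(mini_batch),
              ilr = ilr %||% 0.1 * mini_batch / 128,
              split_fractions = split_fractions, split_mode = split_mode,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param profile `"desk"` or `"paper"`.
#' @param ... Overrides passed to [pipeline_config()].
#' @export
pipeline_profile <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    desk = list(source = "synthetic", n_images = 1000, epochs = 10L),
    paper = list(source = "wfdb", n_images = 18000, epochs = 40L)
  )
  do.call(pipeline_config, utils::modifyList(defaults, list(...)))
}

stage_record <- function(name, t0, ...) {
  c(list(stage = name, wall_s = as.numeric(Sys.time()) - t0), list(...))
}

#' Run the full AFIB-detection pipeline
#'
#' Orchestrates data preparation -> bispectrum estimation -> image
#' conversion -> class-balanced sampling -> 70/10/20 split -> network
#' training -> evaluation, recording every stage (counts, seeds, wall time,
#' config digest) in a manifest so a run can be reproduced exactly from the
#' manifest alone.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress?
#' @return An object of class `afib_pipeline_run`: list with `images`
#'   (tibble incl. `split` and `image` columns), `fit` (the trained
#'   [afibnet_train()] model), `report` (test-set [metrics_report()]),
#'   `roc` (test-set [roc_curve()]), `predictions`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_profile("desk"), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(config = unclass(config),
                   config_digest = digest::digest(unclass(config)),
                   stages = list())
  push <- function(rec) manifest$stages[[rec$stage]] <<- rec

  # 1. data preparation
  t0 <- as.numeric(Sys.time())
  n_per_class <- config$n_images %/% 2L
  if (config$source == "synthetic") {
    segments <- generate_dataset(n_per_class, seed = config$seed)
    omitted <- NULL
  } else {
    if (is.null(config$db_dir) || !dir.exists(config$db_dir)) {
      abort("prepare stage: `db_dir` must name an existing WFDB directory",
            class = "ecgbispec_stage_error")
    }
    db <- read_wfdb_database(config$db_dir)
    if (length(db$records) == 0L) {
      abort("prepare stage: no usable records in db_dir",
            class = "ecgbispec_stage_error")
    }
    pieces <- lapply(db$records, function(rec) {
      atr <- file.path(config$db_dir, paste0(rec$record_id, ".atr"))
      if (!file.exists(atr)) {
        abort(paste0("prepare stage: missing annotation file for record ",
                     rec$record_id),
              class = "ecgbispec_stage_error")
      }
      eps <- read_rhythm_episodes(atr, rec$n_samples)
      segment_episodes(rec, eps)
    })
    segments <- bind_rows(lapply(pieces, `[[`, "segments"))
    omitted <- bind_rows(lapply(pieces, `[[`, "omitted")) |>
      group_by(.data$label) |>
      summarise(omitted = sum(.data$omitted), .groups = "drop")
    segments <- sample_balanced(segments, config$n_images,
                                seed = config$seed + 1L)
  }
  push(stage_record("prepare", t0, n_segments = nrow(segments),
                    per_label = table(segments$label), seed = config$seed))
  say("prepare: %d segments", nrow(segments))

  # 2. bispectra -> images
  t0 <- as.numeric(Sys.time())
  images <- segments_to_images(segments, config$estimator,
                               band_hz = config$band_hz)
  push(stage_record("featurize", t0, n_images = nrow(images),
                    band_hz = config$band_hz,
                    estimator = unclass(config$estimator)))
  say("featurize: %d images", nrow(images))

  # 3. split
  t0 <- as.numeric(Sys.time())
  images <- split_dataset(images, config$split_fractions,
                          seed = config$seed + 2L, mode = config$split_mode)
  push(stage_record("split", t0, sizes = table(images$split),
                    mode = config$split_mode, seed = config$seed + 2L))

  # 4. train
  t0 <- as.numeric(Sys.time())
  tr <- images[images$split == "train", ]
  va <- images[images$split == "val", ]
  fit <- afibnet_train(tr$image, tr$label, epochs = config$epochs,
                       mini_batch = config$mini_batch, ilr = config$ilr,
                       seed = config$seed + 3L,
                       validation = if (nrow(va))
                         list(images = va$image, labels = va$label),
                       verbose = verbose)
  push(stage_record("train", t0, n_train = nrow(tr), n_val = nrow(va),
                    epochs = config$epochs, ilr = config$ilr,
                    seed = config$seed + 3L))

  # 5. evaluate
  t0 <- as.numeric(Sys.time())
  te <- images[images$split == "test", ]
  pred <- predict(fit, te$image)
  cm <- confusion(te$label, pred$label)
  report <- metrics_report(cm, scores = pred$score_afib, labels = te$label)
  roc <- roc_curve(pred$score_afib, te$label)
  push(stage_record("evaluate", t0, n_test = nrow(te),
                    confusion = unclass(cm),
                    auc = attr(roc, "auc")))
  say("evaluate: test AUC %.3f", attr(roc, "auc"))

  structure(list(images = images, fit = fit, predictions = pred,
                 report = report, roc = roc, omitted = omitted,
                 manifest = manifest),
            class = "afib_pipeline_run")
}

#' @export
print.afib_pipeline_run <- function(x, ...) {
  r <- round_report(x$report)
  cat("<afib_pipeline_run> ", nrow(x$images), " images | test AUC ",
      sprintf("%.3f", attr(x$roc, "auc")),
      " | sens ", r$sensitivity, " | spec ", r$specificity, "\n", sep = "")
  invisible(x)
}

#' @describeIn run_pipeline one-row summary of the run (counts and test
#'   metrics).
#' @param x An `afib_pipeline_run`.
#' @param ... Unused.
#' @export
glance.afib_pipeline_run <- function(x, ...) {
  s <- x$manifest$stages
  dplyr::bind_cols(
    tibble(n_images = s$featurize$n_images,
           n_train = s$train$n_train, n_test = s$evaluate$n_test),
    as_tibble(x$report)
  )
}
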