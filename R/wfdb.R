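#' Read a PhysioNet-style WFDB record
#'
#' Parses the `.hea` header and the format-212 `.dat` signal file (the format
#' of the MIT-BIH Atrial Fibrillation Database: two channels, 250 Hz, 12-bit
#' samples over +/- 10 mV) and converts samples to millivolts via each
#' signal's gain and baseline.
#'
#' @param path Record path without extension (or the `.hea` path).
#' @return An object of class `ecg_record`: list with `record_id`, `fs_hz`,
#'   `n_samples`, `signal` (numeric matrix, one column per channel, mV).
#' @export
read_wfdb_record <- function(path) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) {
    abort(paste0("header not found: ", hea),
          class = "ecgbispec_record_unavailable")
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- top[1]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  n_samples <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- lines[1 + seq_len(nsig)]
  sig <- lapply(sig_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_spec <- f[3]
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
    } else 0
    gain <- as.numeric(sub("[(/].*", "", gain_spec))
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[1], format = f[2], gain = gain, baseline = baseline)
  })
  fmt <- unique(vapply(sig, `[[`, character(1), "format"))
  if (!identical(fmt, "212")) {
    abort(paste0("unsupported signal format: ", paste(fmt, collapse = ", ")),
          class = "ecgbispec_format_error")
  }
  dat <- file.path(dirname(hea), sig[[1]]$file)
  if (!file.exists(dat)) {
    abort(paste0("signal file not provided: ", dat),
          class = "ecgbispec_record_unavailable")
  }
  raw <- readBin(dat, "raw", n = file.size(dat))
  adc <- unpack_212(raw)
  need <- n_samples * nsig
  if (length(adc) < need) {
    abort(sprintf("truncated signal file: %s has %d samples, header says %d",
                  dat, length(adc) %/% nsig, n_samples),
          class = "ecgbispec_consistency_error")
  }
  adc <- adc[seq_len(need)]
  m <- matrix(adc, ncol = nsig, byrow = TRUE)
  for (ch in seq_len(nsig)) {
    m[, ch] <- (m[, ch] - sig[[ch]]$baseline) / sig[[ch]]$gain
  }
  structure(list(record_id = record_id, fs_hz = fs,
                 n_samples = n_samples, signal = m),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("<ecg_record> ", x$record_id, " | ", ncol(x$signal), " channel(s) | ",
      x$n_samples, " samples @ ", x$fs_hz, " Hz (",
      signif(x$n_samples / x$fs_hz, 6), " s)\n", sep = "")
  invisible(x)
}

unpack_212 <- function(raw) {
  nb <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(nb)])
  b1 <- b[seq(1, nb, 3)]; b2 <- b[seq(2, nb, 3)]; b3 <- b[seq(3, nb, 3)]
  s1 <- b1 + (b2 %% 16L) * 256L
  s2 <- b3 + (b2 %/% 16L) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

pack_212 <- function(adc) {
  if (length(adc) %% 2L == 1L) adc <- c(adc, 0L)
  adc <- pmin(pmax(as.integer(adc), -2048L), 2047L)
  u <- ifelse(adc < 0L, adc + 4096L, adc)
  s1 <- u[seq(1, length(u), 2)]; s2 <- u[seq(2, length(u), 2)]
  as.raw(rbind(s1 %% 256L, (s1 %/% 256L) + 16L * (s2 %/% 256L), s2 %% 256L))
}

#' Write a WFDB-compatible record (format 212)
#'
#' Quantizes millivolt signals with the given gain (12-bit clamp) and writes
#' `.hea`/`.dat` files readable by [read_wfdb_record()]; used to build
#' test databases and to export synthetic data in the field's exchange
#' format.
#'
#' @param signal Numeric matrix (samples x channels) in mV, or a vector.
#' @param dir Output directory.
#' @param record_id Record name.
#' @param fs_hz Sampling rate (default 250).
#' @param gain ADC units per mV (default 200, the AFDB calibration).
#' @param baseline ADC value of 0 mV (default 0).
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(signal, dir, record_id, fs_hz = 250,
                              gain = 200, baseline = 0) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  nsig <- ncol(signal)
  n <- nrow(signal)
  adc <- round(signal * gain + baseline)
  dat_name <- paste0(record_id, ".dat")
  interleaved <- as.integer(t(adc))
  writeBin(pack_212(interleaved), file.path(dir, dat_name))
  hdr <- c(
    sprintf("%s %d %g %d", record_id, nsig, fs_hz, n),
    vapply(seq_len(nsig), function(ch) {
      sprintf("%s 212 %g(%g)/mV 12 0 0 0 0 ECG%d",
              dat_name, gain, baseline, ch)
    }, character(1))
  )
  writeLines(hdr, file.path(dir, paste0(record_id, ".hea")))
  invisible(file.path(dir, record_id))
}

# ---- MIT annotation files -------------------------------------------------

ANN_RHYTHM <- 28L   # '+' rhythm change
ANN_SKIP <- 59L
ANN_NUM <- 60L
ANN_SUB <- 61L
ANN_CHN <- 62L
ANN_AUX <- 63L

RHYTHM_LABELS <- c("(AFIB" = "AFIB", "(AFL" = "AFL", "(J" = "J", "(N" = "N")

#' Read rhythm episodes from a WFDB annotation file
#'
#' Parses the MIT annotation format, keeps the rhythm-change markers (aux
#' strings `"(AFIB"`, `"(AFL"`, `"(J"`, `"(N"`), and reconstructs episodes:
#' each marker opens an episode that runs to the next rhythm marker or the
#' record end.  Sample indices are 0-based and intervals half-open.  Markers
#' with an unknown rhythm string produce a warning; the episode they open is
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param path Annotation file path (e.g. `record.atr`).
#' @param n_samples Record length in samples (closes the final episode).
#' @param record_id Identifier stored on the episodes (default: file stem).
#' @return A tibble with columns `record_id`, `label`, `start_sample`,
#'   `end_sample` (exclusive), ordered and non-overlapping; attribute
#'   `n_skipped` counts episodes dropped for unknown labels.
#' @export
read_rhythm_episodes <- function(path, n_samples,
                                 record_id = sub("\\.[^.]*$", "",
                                                 basename(path))) {
  ann <- read_mit_annotations(path)
  rhythm <- ann[!is.na(ann$aux) & startsWith(ann$aux, "("), , drop = FALSE]
  if (nrow(rhythm) == 0L) {
    out <- tibble(record_id = character(0), label = character(0),
                  start_sample = integer(0), end_sample = integer(0))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  starts <- rhythm$sample
  ends <- c(rhythm$sample[-1], as.integer(n_samples))
  labels <- unname(RHYTHM_LABELS[rhythm$aux])
  unknown <- is.na(labels)
  if (any(unknown)) {
    warn(sprintf("skipped %d episode(s) with unknown rhythm label(s): %s",
                 sum(unknown),
                 paste(unique(rhythm$aux[unknown]), collapse = ", ")))
  }
  keep <- !unknown & ends > starts
  out <- tibble(
    record_id = record_id,
    label = labels[keep],
    start_sample = as.integer(starts[keep]),
    end_sample = as.integer(ends[keep])
  )
  attr(out, "n_skipped") <- sum(unknown)
  out
}

read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  b <- as.integer(raw)
  i <- 1L
  time <- 0L
  samples <- integer(0); codes <- integer(0); auxs <- character(0)
  pending <- 0
  while (i + 1L <= length(b)) {
    w <- b[i] + 256L * b[i + 1L]
    i <- i + 2L
    code <- w %/% 1024L
    interval <- w %% 1024L
    if (code == 0L && interval == 0L) break
    if (code == ANN_SKIP) {
      if (i + 3L > length(b)) break
      hi <- b[i] + 256L * b[i + 1L]
      lo <- b[i + 2L] + 256L * b[i + 3L]
      i <- i + 4L
      pending <- pending + hi * 65536 + lo
    } else if (code == ANN_AUX) {
      len <- interval
      aux <- rawToChar(raw[i:(i + len - 1L)])
      aux <- trimws(aux)
      i <- i + len + (len %% 2L)  # pad byte keeps words aligned
      if (length(auxs)) auxs[length(auxs)] <- aux
    } else if (code %in% c(ANN_NUM, ANN_SUB, ANN_CHN)) {
      # modifier fields are not needed for rhythm accounting
    } else {
      time <- time + pending + interval
      pending <- 0
      samples <- c(samples, as.integer(time))
      codes <- c(codes, code)
      auxs <- c(auxs, NA_character_)
    }
  }
  tibble(sample = samples, code = codes, aux = auxs)
}

#' Write rhythm-change annotations in the MIT format
#'
#' Emits one rhythm annotation (`+`, code 28) per marker with its aux label
#' string, using SKIP words for intervals longer than 1023 samples.
#' Round-trips through [read_rhythm_episodes()].
#'
#' @param path Output file.
#' @param samples 0-based marker sample indices (non-decreasing).
#' @param labels Aux strings, e.g. `"(AFIB"`, `"(N"`.
#' @return `path`, invisibly.
#' @export
write_rhythm_annotations <- function(path, samples, labels) {
  stopifnot(length(samples) == length(labels), !is.unsorted(samples))
  out <- raw(0)
  word <- function(code, interval) {
    w <- code * 1024L + interval
    as.raw(c(w %% 256L, w %/% 256L))
  }
  prev <- 0
  for (k in seq_along(samples)) {
    delta <- samples[k] - prev
    prev <- samples[k]
    if (delta > 1023) {
      out <- c(out, word(ANN_SKIP, 0L))
      hi <- floor(delta / 65536); lo <- delta - hi * 65536
      out <- c(out, as.raw(c(hi %% 256, hi %/% 256, lo %% 256, lo %/% 256)))
      out <- c(out, word(ANN_RHYTHM, 0L))
    } else {
      out <- c(out, word(ANN_RHYTHM, as.integer(delta)))
    }
    aux <- labels[k]
    len <- nchar(aux)
    out <- c(out, word(ANN_AUX, len), charToRaw(aux))
    if (len %% 2L == 1L) out <- c(out, as.raw(0L))
  }
  out <- c(out, as.raw(c(0L, 0L)))
  writeBin(out, path)
  invisible(path)
}

#' Per-label episode duration accounting
#'
#' Summarizes rhythm episodes the way database accounting tables do:
#' count, minimum, maximum, mean and total duration in seconds per label.
#'
#' @param episodes Episode tibble (possibly pooled over records) as returned
#'   by [read_rhythm_episodes()].
#' @param fs_hz Sampling rate (durations = (end - start) / fs).
#' @return A tibble `label`, `count`, `min_s`, `max_s`, `mean_s`, `total_s`.
#' @export
summarize_episodes <- function(episodes, fs_hz = 250) {
  if (nrow(episodes) == 0L) {
    return(tibble(label = character(0), count = integer(0), min_s = numeric(0),
                  max_s = numeric(0), mean_s = numeric(0), total_s = numeric(0)))
  }
  episodes |>
    mutate(dur_s = (.data$end_sample - .data$start_sample) / fs_hz) |>
    group_by(.data$label) |>
    summarise(count = n(), min_s = min(.data$dur_s), max_s = max(.data$dur_s),
              mean_s = mean(.data$dur_s), total_s = sum(.data$dur_s),
              .groups = "drop") |>
    arrange(.data$label)
}

#' Cut rhythm episodes into fixed-length labelled segments
#'
#' Implements the data-preparation rule for classifier input: each kept-label
#' episode is cut, independently on each ECG channel, into consecutive
#' non-overlapping windows of `round(seg_len_s * fs)` samples starting at the
#' episode start.  The trailing remainder shorter than a window (including
#' whole episodes shorter than `seg_len_s`) yields no segment and is counted
#' as one omitted fragment per (episode, channel).
#'
#' @param record An `ecg_record`.
#' @param episodes Episode tibble for this record.
#' @param keep_labels Labels to segment (default `c("AFIB", "N")`).
#' @param seg_len_s Window length in seconds (default 5).
#' @return A list with `segments` (tibble in the [generate_segment()] column
#'   layout: `id`, `label`, `channel`, `fs_hz`, `n_samples`, `samples`) and
#'   `omitted` (tibble `label`, `omitted`).
#' @export
segment_episodes <- function(record, episodes, keep_labels = c("AFIB", "N"),
                             seg_len_s = 5) {
  stopifnot(inherits(record, "ecg_record"), seg_len_s > 0)
  w <- round(seg_len_s * record$fs_hz)
  eps <- episodes[episodes$label %in% keep_labels, , drop = FALSE]
  seg_rows <- list()
  omitted <- stats::setNames(rep(0L, length(keep_labels)), keep_labels)
  for (e in seq_len(nrow(eps))) {
    len <- eps$end_sample[e] - eps$start_sample[e]
    k <- len %/% w
    rem <- len - k * w
    for (ch in seq_len(ncol(record$signal))) {
      if (rem > 0) {
        omitted[eps$label[e]] <- omitted[eps$label[e]] + 1L
      }
      if (k > 0) {
        for (j in seq_len(k)) {
          a <- eps$start_sample[e] + (j - 1L) * w
          seg_rows[[length(seg_rows) + 1L]] <- tibble(
            id = sprintf("%s-ch%d-e%d-s%d", record$record_id, ch, e, j),
            label = eps$label[e],
            channel = ch,
            fs_hz = record$fs_hz,
            n_samples = w,
            samples = list(record$signal[(a + 1L):(a + w), ch])
          )
        }
      }
    }
  }
  segments <- if (length(seg_rows)) bind_rows(seg_rows) else
    tibble(id = character(0), label = character(0), channel = integer(0),
           fs_hz = numeric(0), n_samples = integer(0), samples = list())
  list(segments = segments,
       omitted = tibble(label = names(omitted), omitted = unname(omitted)))
}

#' Read all usable records of a WFDB database directory
#'
#' Reads every record listed in the `RECORDS` file (or every `.hea` file when
#' no list exists).  Records whose signal files are not provided - as for
#' two records of the MIT-BIH Atrial Fibrillation Database - are skipped
#' with a message and reported in `skipped`.
#'
#' @param dir Database directory.
#' @return List with `records` (named list of `ecg_record`) and `skipped`
#'   (character vector of unavailable record ids).
#' @export
read_wfdb_database <- function(dir) {
  rec_file <- file.path(dir, "RECORDS")
  ids <- if (file.exists(rec_file)) {
    trimws(readLines(rec_file, warn = FALSE))
  } else {
    sub("\\.hea$", "", basename(Sys.glob(file.path(dir, "*.hea"))))
  }
  ids <- ids[nzchar(ids)]
  records <- list()
  skipped <- character(0)
  for (id in ids) {
    rec <- tryCatch(read_wfdb_record(file.path(dir, id)),
                    ecgbispec_record_unavailable = function(e) NULL)
    if (is.null(rec)) {
      message("record unavailable, skipping: ", id)
      skipped <- c(skipped, id)
    } else {
      records[[id]] <- rec
    }
  }
  list(records = records, skipped = skipped)
}
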