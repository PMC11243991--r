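#' Rhythm models for the synthetic ECG generator
#'
#' A rhythm model bundles the statistical structure that distinguishes the two
#' rhythm classes on the ECG: the RR-interval distribution, the presence of a
#' P wave before each QRS complex, and (for atrial fibrillation) continuous
#' fibrillatory baseline waves in the 4-9 Hz band.
#'
#' Defaults encode the textbook electrophysiology: normal sinus rhythm ("N")
#' has quasi-regular RR intervals (Normal, mean 0.8 s, sd 0.03 s, truncated to
#' \[0.5, 1.2\] s) and present P waves; atrial fibrillation ("AFIB") has
#' irregularly irregular RR intervals (Uniform on \[0.35, 1.1\] s), absent
#' P waves, and fibrillatory waves modelled as a sum of three sinusoids with
#' frequencies drawn uniformly from 4-9 Hz.
#'
#' @param label Rhythm class, `"AFIB"` or `"N"`.
#' @param fwave_amplitude_mv Amplitude (mV) of each fibrillatory sinusoid;
#'   forced to 0 for the N model.
#' @param noise_sd_mv Standard deviation (mV) of additive white Gaussian noise.
#'
#' @return An object of class `rhythm_model`: a list with fields `label`,
#'   `rr_distribution`, `p_wave`, `fwave_band_hz`, `fwave_amplitude_mv`,
#'   `noise_sd_mv`.
#' @export
#' @examples
#' rhythm_model("AFIB")
#' rhythm_model("N")$p_wave
rhythm_model <- function(label = c("N", "AFIB"),
                         fwave_amplitude_mv = if (label == "AFIB") 0.05 else 0,
                         noise_sd_mv = 0.02) {
  label <- match.arg(label)
  stopifnot(fwave_amplitude_mv >= 0, noise_sd_mv >= 0)
  if (label == "AFIB") {
    m <- list(
      label = "AFIB",
      rr_distribution = list(kind = "uniform", min_s = 0.35, max_s = 1.1),
      p_wave = FALSE,
      fwave_band_hz = c(4, 9),
      fwave_amplitude_mv = fwave_amplitude_mv,
      noise_sd_mv = noise_sd_mv
    )
  } else {
    m <- list(
      label = "N",
      rr_distribution = list(kind = "truncnorm", mean_s = 0.8, sd_s = 0.03,
                             lo_s = 0.5, hi_s = 1.2),
      p_wave = TRUE,
      fwave_band_hz = numeric(0),
      fwave_amplitude_mv = 0,
      noise_sd_mv = noise_sd_mv
    )
  }
  structure(m, class = "rhythm_model")
}

#' @export
print.rhythm_model <- function(x, ...) {
  cat("<rhythm_model> label:", x$label,
      "| p_wave:", x$p_wave,
      "| f-waves:", if (length(x$fwave_band_hz))
        sprintf("%g-%g Hz @ %g mV", x$fwave_band_hz[1], x$fwave_band_hz[2],
                x$fwave_amplitude_mv) else "none",
      "| noise sd:", x$noise_sd_mv, "mV\n")
  invisible(x)
}

default_morphology <- function() {
  # Gaussian-bump P-QRS-T morphology; times in seconds, amplitudes in mV.
  list(
    r_amp = 1.0,  r_sd = 0.012,
    q_amp = -0.10, q_sd = 0.010, q_offset = -0.035,
    s_amp = -0.15, s_sd = 0.010, s_offset = 0.035,
    p_amp = 0.15, p_sd = 0.025, p_offset = -0.16,
    t_amp = 0.30, t_sd = 0.055, t_offset = 0.30,
    r_frac = 0.35  # R-peak position as a fraction of the cycle
  )
}

gauss_bump <- function(t, centre, amp, sd) amp * exp(-0.5 * ((t - centre) / sd)^2)

#' Synthesize one cardiac cycle
#'
#' Builds a single beat of `round(rr_s * fs_hz)` samples from Gaussian bumps:
#' a dominant narrow positive R deflection with small Q and S troughs, a T
#' wave, and (optionally) a smaller P bump preceding the QRS complex.
#'
#' @param rr_s Cycle length in seconds; must lie in \[0.2, 2\].
#' @param p_wave Logical; draw a P wave before the QRS complex?
#' @param morphology Named list of bump amplitudes (mV), widths and offsets
#'   (s); see `default_morphology()` (unexported, returned defaults are used
#'   when `morphology` is `NULL`).
#' @param fs_hz Sampling rate in Hz.
#'
#' @return Numeric vector of millivolt samples, one cardiac cycle long.
#' @export
#' @examples
#' length(make_beat(0.8))  # 200 samples at 250 Hz
make_beat <- function(rr_s, p_wave = TRUE, morphology = NULL, fs_hz = 250) {
  if (!is.numeric(rr_s) || length(rr_s) != 1 || is.na(rr_s) ||
      rr_s < 0.2 || rr_s > 2.0) {
    abort("`rr_s` must be a single number in [0.2, 2.0] seconds.",
          class = "ecgbispec_invalid_parameter")
  }
  m <- morphology %||% default_morphology()
  n <- round(rr_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  r_t <- m$r_frac * rr_s
  y <- gauss_bump(t, r_t, m$r_amp, m$r_sd) +
    gauss_bump(t, r_t + m$q_offset, m$q_amp, m$q_sd) +
    gauss_bump(t, r_t + m$s_offset, m$s_amp, m$s_sd) +
    gauss_bump(t, r_t + m$t_offset, m$t_amp, m$t_sd)
  if (isTRUE(p_wave)) {
    y <- y + gauss_bump(t, r_t + m$p_offset, m$p_amp, m$p_sd)
  }
  y
}

draw_rr <- function(dist, n) {
  switch(dist$kind,
    uniform = runif(n, dist$min_s, dist$max_s),
    truncnorm = {
      x <- rnorm(n, dist$mean_s, dist$sd_s)
      pmin(pmax(x, dist$lo_s), dist$hi_s)
    },
    abort(paste0("unknown RR distribution kind: ", dist$kind))
  )
}

#' Generate one labelled synthetic ECG segment
#'
#' Draws RR intervals from the model's distribution, concatenates synthetic
#' beats, adds fibrillatory waves (AFIB only) and white Gaussian noise, and
#' crops to exactly `round(duration_s * fs_hz)` samples.  The generator keeps
#' a ground-truth log of beat-onset times and RR draws so that downstream
#' rhythm statistics can be verified without a QRS detector.
#'
#' @param model A [rhythm_model()].
#' @param duration_s Segment duration in seconds (default 5).
#' @param fs_hz Sampling rate in Hz (default 250, the AFDB rate).
#' @param seed Integer seed; the segment is a deterministic function of
#'   `(model, duration_s, fs_hz, seed)`.
#' @param id Optional segment identifier (text).
#' @param channel Channel index recorded in the output (default 1).
#'
#' @return A one-row tibble with columns `id`, `label`, `channel`, `fs_hz`,
#'   `n_samples`, and list-columns `samples` (mV), `onset_s` (ground-truth
#'   beat-onset times in seconds) and `rr_s` (the RR draws).
#' @export
#' @examples
#' seg <- generate_segment(rhythm_model("AFIB"), seed = 1)
#' length(seg$samples[[1]])  # 1250
generate_segment <- function(model, duration_s = 5, fs_hz = 250, seed = 1,
                             id = NULL, channel = 1L) {
  stopifnot(inherits(model, "rhythm_model"), duration_s > 0, fs_hz > 0)
  n <- round(duration_s * fs_hz)
  withr::with_seed(as.integer(seed), {
    # Draw more beats than can fit, then crop.
    n_max <- ceiling(duration_s / 0.2) + 2
    rr <- draw_rr(model$rr_distribution, n_max)
    onsets <- cumsum(c(0, rr))
    keep <- which(onsets[-length(onsets)] < duration_s)
    rr <- rr[keep]
    onsets <- onsets[keep]
    y <- unlist(lapply(rr, make_beat, p_wave = model$p_wave, fs_hz = fs_hz),
                use.names = FALSE)
    y <- y[seq_len(min(n, length(y)))]
    if (length(y) < n) y <- c(y, numeric(n - length(y)))
    if (model$fwave_amplitude_mv > 0 && length(model$fwave_band_hz) == 2) {
      t <- (seq_len(n) - 1) / fs_hz
      f <- runif(3, model$fwave_band_hz[1], model$fwave_band_hz[2])
      ph <- runif(3, 0, 2 * pi)
      for (k in 1:3) {
        y <- y + model$fwave_amplitude_mv * sin(2 * pi * f[k] * t + ph[k])
      }
    }
    if (model$noise_sd_mv > 0) y <- y + rnorm(n, 0, model$noise_sd_mv)
    tibble(
      id = id %||% sprintf("synth-%s-%d", model$label, as.integer(seed)),
      label = model$label,
      channel = as.integer(channel),
      fs_hz = fs_hz,
      n_samples = n,
      samples = list(y),
      onset_s = list(onsets),
      rr_s = list(rr)
    )
  })
}

#' Generate a class-balanced labelled segment dataset
#'
#' Produces `n_per_class` AFIB and `n_per_class` N segments.  Per-segment
#' seeds are derived reproducibly from the master seed, so two calls with the
#' same arguments return identical datasets.
#'
#' @param n_per_class Number of segments per rhythm class (>= 1).
#' @param seed Master integer seed.
#' @param duration_s,fs_hz Passed to [generate_segment()].
#' @param afib_model,n_model Rhythm models; defaults are
#'   `rhythm_model("AFIB")` and `rhythm_model("N")`.
#'
#' @return A tibble of `2 * n_per_class` rows in the [generate_segment()]
#'   format, AFIB rows first.
#' @export
#' @examples
#' ds <- generate_dataset(5, seed = 42)
#' table(ds$label)
generate_dataset <- function(n_per_class, seed = 1, duration_s = 5,
                             fs_hz = 250,
                             afib_model = rhythm_model("AFIB"),
                             n_model = rhythm_model("N")) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    abort("`n_per_class` must be >= 1.", class = "ecgbispec_invalid_parameter")
  }
  n_per_class <- as.integer(n_per_class)
  seed <- as.integer(seed)
  sub_seed <- function(i) (abs(seed) * 977L + i * 7919L) %% 2147483629L
  rows <- vector("list", 2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    rows[[i]] <- generate_segment(
      afib_model, duration_s, fs_hz, seed = sub_seed(i),
      id = sprintf("synth-AFIB-%04d", i)
    )
    rows[[n_per_class + i]] <- generate_segment(
      n_model, duration_s, fs_hz, seed = sub_seed(n_per_class + i),
      id = sprintf("synth-N-%04d", i)
    )
  }
  bind_rows(rows)
}

#' Write / read a segment dataset as a plain-text fixture
#'
#' One CSV-like row per segment: `id,label,channel,fs_hz` followed by the
#' samples, onset times and RR draws serialized as comma-separated values in
#' three quoted fields.  Round-trips the generator's ground-truth logs
#' unchanged (to the printed precision of 15 significant digits).
#'
#' @param segments Segment tibble as returned by [generate_dataset()].
#' @param path File path.
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   returns the segment tibble.
#' @export
write_segments <- function(segments, path) {
  pack <- function(v) paste(format(v, digits = 15, trim = TRUE,
                                   scientific = TRUE), collapse = ",")
  lines <- vapply(seq_len(nrow(segments)), function(i) {
    paste(
      segments$id[i], segments$label[i], segments$channel[i],
      format(segments$fs_hz[i], digits = 15),
      paste0('"', pack(segments$samples[[i]]), '"'),
      paste0('"', pack(segments$onset_s[[i]]), '"'),
      paste0('"', pack(segments$rr_s[[i]]), '"'),
      sep = ";"
    )
  }, character(1))
  writeLines(c("id;label;channel;fs_hz;samples;onset_s;rr_s", lines), path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1] != "id;label;channel;fs_hz;samples;onset_s;rr_s") {
    abort("not a segment fixture file", class = "ecgbispec_format_error")
  }
  unpack <- function(s) as.numeric(strsplit(gsub('"', "", s), ",")[[1]])
  rows <- lapply(lines[-1], function(l) {
    f <- strsplit(l, ";", fixed = TRUE)[[1]]
    y <- unpack(f[5])
    tibble(
      id = f[1], label = f[2], channel = as.integer(f[3]),
      fs_hz = as.numeric(f[4]), n_samples = length(y),
      samples = list(y), onset_s = list(unpack(f[6])), rr_s = list(unpack(f[7]))
    )
  })
  bind_rows(rows)
}
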