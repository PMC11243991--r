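# Shared fixtures: quadratically phase-coupled (QPC) test signals and small
# independent oracles used across the suite.

FS <- 250
NFFT <- 512

# Triple cosine at exact FFT bins (f1 = 35 fs/nfft, f2 = 20 fs/nfft).
# coupled: third component's phase = phi1 + phi2 (QPC); otherwise random.
# per_record_phase: redraw phases for every 512-sample record (a stochastic
# QPC process); else one global phase set (deterministic, 512-periodic).
qpc_signal <- function(n_records, coupled = TRUE, seed = 1,
                       per_record_phase = FALSE, noise_sd = 0) {
  set.seed(seed)
  gen <- function(t, p1, p2, p3) {
    f1 <- 35 * FS / NFFT; f2 <- 20 * FS / NFFT
    cos(2 * pi * f1 * t / FS + p1) + cos(2 * pi * f2 * t / FS + p2) +
      cos(2 * pi * (f1 + f2) * t / FS + p3)
  }
  if (per_record_phase) {
    x <- unlist(lapply(seq_len(n_records), function(k) {
      p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
      gen(0:(NFFT - 1), p1, p2, p3)
    }))
  } else {
    p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
    p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
    x <- gen(0:(n_records * NFFT - 1), p1, p2, p3)
  }
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  x
}

# Exhaustive argmax of |B| over the non-redundant region; returns 0-based bins.
peak_bins <- function(bisp) {
  m <- nonredundant_mask(bisp$nfft)
  A <- Mod(bisp$values)
  A[!m] <- -Inf
  ij <- which(A == max(A), arr.ind = TRUE)
  c(k1 = ij[1, 1] - 1L, k2 = ij[1, 2] - 1L)
}

# Mann-Whitney AUC oracle: pair counting over all positive/negative pairs,
# ties counted 1/2.
mw_auc <- function(scores, labels, positive = "AFIB") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Flat separable toy images for network tests.
toy_images <- function(n_per_class, size = 24, seed = 1, sd = 0.02) {
  set.seed(seed)
  imgs <- c(
    lapply(seq_len(n_per_class), function(i)
      pmin(pmax(matrix(0.9 + rnorm(size^2, 0, sd), size, size), 0), 1)),
    lapply(seq_len(n_per_class), function(i)
      pmin(pmax(matrix(0.1 + rnorm(size^2, 0, sd), size, size), 0), 1))
  )
  list(images = imgs,
       labels = rep(c("AFIB", "N"), each = n_per_class))
}

# Synthetic two-channel WFDB database written into dir; returns the episode
# plan used, for oracle comparisons.
write_synthetic_afdb <- function(dir, seed = 1) {
  set.seed(seed)
  plans <- list(
    r01 = tibble::tibble(
      label = c("N", "AFIB", "N", "AFL", "AFIB"),
      dur_s = c(12, 4.9, 10, 7.3, 23.6)
    ),
    r02 = tibble::tibble(
      label = c("AFIB", "J", "N"),
      dur_s = c(15.2, 6, 31)
    )
  )
  for (id in names(plans)) {
    plan <- plans[[id]]
    n <- as.integer(round(sum(plan$dur_s) * 250))
    sig <- cbind(0.8 * sin(2 * pi * 1.1 * (0:(n - 1)) / 250),
                 0.6 * sin(2 * pi * 1.3 * (0:(n - 1)) / 250))
    write_wfdb_record(sig, dir, id)
    starts <- as.integer(round(cumsum(c(0, plan$dur_s[-nrow(plan)])) * 250))
    write_rhythm_annotations(file.path(dir, paste0(id, ".atr")),
                             starts, paste0("(", plan$label))
  }
  plans
}
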