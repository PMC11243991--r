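test_that("degenerate inputs and symmetry of both estimators", {
  cfg <- estimator_config(record_len = 256, nfft = 256)
  z <- numeric(1024)
  expect_true(all(bispectrum_direct(z, cfg)$values == 0))
  cfgI <- estimator_config("indirect", record_len = 256, nfft = 256,
                           max_lag = 16)
  expect_true(all(bispectrum_indirect(z, cfgI)$values == 0))

  set.seed(3)
  x <- rnorm(1024)
  bd <- bispectrum_direct(x, cfg)
  scale <- max(Mod(bd$values))
  expect_lt(max(Mod(bd$values - t(bd$values))), 1e-10 * scale)
  bi <- bispectrum_indirect(x, cfgI)
  expect_lt(max(Mod(bi$values - t(bi$values))), 1e-10 * max(Mod(bi$values)))
})

test_that("QPC fixture peaks at the coupled bin pair (both estimators, argmax oracle)", {
  x <- qpc_signal(16, coupled = TRUE, seed = 1)
  bd <- bispectrum_direct(x, estimator_config(), FS)
  expect_equal(unname(peak_bins(bd)), c(35L, 20L))

  bi <- bispectrum_indirect(x, estimator_config("indirect", max_lag = 64), FS)
  expect_equal(unname(peak_bins(bi)), c(35L, 20L))
})

test_that("uncoupled third component suppresses the bispectral peak", {
  cfg <- estimator_config(overlap_fraction = 0)
  bc <- bispectrum_direct(qpc_signal(64, TRUE, seed = 2,
                                     per_record_phase = TRUE), cfg, FS)
  bu <- bispectrum_direct(qpc_signal(64, FALSE, seed = 2,
                                     per_record_phase = TRUE), cfg, FS)
  ratio <- Mod(bc$values[36, 21]) / Mod(bu$values[36, 21])
  expect_gte(ratio, 5)
})

test_that("non-redundant mask equals exhaustive triangle enumeration", {
  for (nfft in c(8L, 16L)) {
    m <- nonredundant_mask(nfft)
    half <- nfft %/% 2
    oracle <- matrix(FALSE, half + 1, half + 1)
    for (k1 in 0:half) for (k2 in 0:half) {
      oracle[k1 + 1, k2 + 1] <- (k2 >= 0) && (k1 >= k2) && (k1 + k2 <= half)
    }
    expect_identical(m, oracle)
  }
  m8 <- nonredundant_mask(8)
  expect_true(m8[1, 1])        # (0,0) inside
  expect_false(m8[5, 5])       # (nfft/2, nfft/2) outside
  expect_error(nonredundant_mask(7), class = "ecgbispec_invalid_parameter")
})

test_that("cubic amplitude scaling and time-shift invariance (direct estimator)", {
  x <- qpc_signal(8, seed = 4)
  cfg <- estimator_config()
  b1 <- bispectrum_direct(x, cfg, FS)
  b3 <- bispectrum_direct(3 * x, cfg, FS)
  expect_equal(b3$values, 27 * b1$values, tolerance = 1e-12)

  # the fixture is nfft-periodic: any integer delay leaves |B| at the peak
  peak0 <- Mod(b1$values[36, 21])
  for (shift in c(1, 37, 129)) {
    xs <- c(x[-seq_len(shift)], x[seq_len(shift)])
    bs <- bispectrum_direct(xs, cfg, FS)
    expect_lt(abs(Mod(bs$values[36, 21]) - peak0) / peak0, 1e-6)
  }
})

test_that("Gaussian suppression: mean |B| falls as records accumulate", {
  m <- nonredundant_mask(NFFT)
  cfg <- estimator_config(overlap_fraction = 0)
  ks <- c(4, 16, 64)
  meanB <- vapply(ks, function(K) {
    set.seed(99)
    mean(Mod(bispectrum_direct(rnorm(K * NFFT), cfg, FS)$values)[m])
  }, numeric(1))
  expect_lt(unname(stats::coef(stats::lm(meanB ~ ks))[2]), 0)
  expect_true(all(diff(meanB) < 0))
})

test_that("direct and indirect estimators agree at matched resolution", {
  x <- qpc_signal(16, coupled = TRUE, seed = 1, per_record_phase = TRUE)
  bd <- bispectrum_direct(
    x, estimator_config(window = "rect", overlap_fraction = 0,
                        smoothing = 64), FS)
  bi <- bispectrum_indirect(
    x, estimator_config("indirect", max_lag = 64, lag_window = "parzen",
                        overlap_fraction = 0), FS)
  expect_equal(unname(peak_bins(bd)), unname(peak_bins(bi)))
  m <- nonredundant_mask(NFFT)
  rho <- stats::cor(Mod(bd$values)[m], Mod(bi$values)[m], method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("estimator config validation", {
  expect_error(estimator_config(nfft = 511),
               class = "ecgbispec_invalid_parameter")
  expect_error(estimator_config(record_len = 1024),
               class = "ecgbispec_invalid_parameter")
  expect_error(estimator_config(overlap_fraction = 1),
               class = "ecgbispec_invalid_parameter")
  expect_error(estimator_config("indirect", record_len = 100, max_lag = 64),
               class = "ecgbispec_invalid_parameter")
  expect_error(estimator_config(smoothing = 300),
               class = "ecgbispec_invalid_parameter")
  expect_error(bispectrum_direct(rnorm(100), estimator_config()),
               class = "ecgbispec_invalid_parameter")
})
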