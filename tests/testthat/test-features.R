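test_that("band-to-bin mapping reproduces the network input sizes", {
  b <- band_bins(0.5, 12, 250, 512)
  expect_equal(unname(b), c(1L, 24L))          # 24 x 24 input
  b <- band_bins(0.5, 14, 250, 512)
  expect_equal(unname(b), c(1L, 28L))          # 28 x 28 pre-tile crop
  b <- band_bins(0.5, 125, 250, 512)
  expect_equal(unname(b["k_hi"]), 256L)        # Nyquist boundary accepted
  expect_error(band_bins(0.5, 126, 250, 512),
               class = "ecgbispec_invalid_parameter")
  expect_error(band_bins(12, 0.5, 250, 512),
               class = "ecgbispec_invalid_parameter")
})

fake_bisp <- function(values, nfft = 512, fs = 250) {
  structure(list(values = values, nfft = nfft, fs_hz = fs,
                 config = estimator_config(), n_records_averaged = 1L),
            class = "bispectrum")
}

test_that("min-max normalization: affine map, constant crop, idempotence", {
  q <- 257
  v <- matrix(0 + 0i, q, q)
  v[2:4, 2:4] <- c(2, 4, 6, 4, 6, 2, 6, 2, 4)   # values {2,4,6}
  img <- amplitude_image(fake_bisp(v), band = c(k_lo = 1, k_hi = 3))
  expect_equal(sort(unique(as.vector(img$pixels))), c(0, 0.5, 1))
  expect_equal(img$pixels[1, 1], 0)              # |B|=2 -> 0
  expect_equal(dim(img$pixels), c(3, 3))

  const <- amplitude_image(fake_bisp(matrix(5 + 0i, q, q)),
                           band = c(1, 24))
  expect_true(all(const$pixels == 0))

  # idempotence: normalizing an already-normalized image changes nothing
  mm <- function(m) if (diff(range(m)) == 0) m * 0 else
    (m - min(m)) / (max(m) - min(m))
  expect_equal(mm(img$pixels), img$pixels)
})

test_that("image geometry and range invariants across random bispectra", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(1250)
    b <- bispectrum(x, estimator_config(), fs_hz = 250)
    img <- amplitude_image(b)
    expect_equal(dim(img$pixels), c(24, 24))
    expect_equal(min(img$pixels), 0)
    expect_equal(max(img$pixels), 1)
    pimg <- phase_image(b)
    expect_equal(dim(pimg$pixels), c(28, 28) - 4)
    expect_true(all(pimg$pixels >= 0 & pimg$pixels <= 1))
  }
})

test_that("QPC peak survives cropping as the brightest pixel", {
  # coupled pair at bins (14, 8): inside the 1..24 crop
  set.seed(11)
  t <- 0:(16 * 512 - 1)
  f1 <- 14 * 250 / 512; f2 <- 8 * 250 / 512
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  x <- cos(2 * pi * f1 * t / 250 + p1) + cos(2 * pi * f2 * t / 250 + p2) +
    cos(2 * pi * (f1 + f2) * t / 250 + p1 + p2)
  b <- bispectrum_direct(x, estimator_config(), 250)
  img <- amplitude_image(b)
  ij <- which(img$pixels == 1, arr.ind = TRUE)
  # bins (14,8)/(8,14): row index = k - k_lo + 1
  hits <- apply(ij, 1, function(r) all(sort(r) == c(8, 14)))
  expect_true(any(hits))
})

test_that("phase image equals the principal-angle oracle before normalization", {
  x <- qpc_signal(8, seed = 3)
  b <- bispectrum_direct(x, estimator_config(), FS)
  band <- band_bins(0.5, 12, FS, NFFT)
  img <- phase_image(b, band)
  crop <- b$values[2:25, 2:25]
  oracle <- atan2(Im(crop), Re(crop))       # independent complex-argument scan
  normalized <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  expect_equal(img$pixels, normalized, tolerance = 1e-12)

  # purely real positive crop -> constant phase -> all-zero image
  q <- 257
  realb <- fake_bisp(matrix(2 + 0i, q, q))
  expect_true(all(phase_image(realb, band)$pixels == 0))
})

test_that("8x8 tiling to the RGB input shape", {
  set.seed(4)
  px <- matrix(runif(28 * 28), 28, 28)
  arr <- tile_for_gnn(px)
  expect_equal(dim(arr), c(224, 224, 3))
  for (bi in c(1, 3, 8)) for (bj in c(1, 5)) {
    block <- arr[(bi - 1) * 28 + 1:28, (bj - 1) * 28 + 1:28, 1]
    expect_equal(block, px)
  }
  expect_equal(arr[, , 1], arr[, , 2])
  expect_equal(arr[, , 1], arr[, , 3])
  expect_error(tile_for_gnn(matrix(0, 24, 24)),
               class = "ecgbispec_invalid_parameter")
})

test_that("optional gray-level quantization snaps pixels to the level grid", {
  seg <- generate_segment(rhythm_model("N"), seed = 21)
  b <- bispectrum(seg$samples[[1]], estimator_config(), fs_hz = 250)
  img8 <- amplitude_image(b, gray_levels = 256)
  expect_true(all(abs(img8$pixels * 255 - round(img8$pixels * 255)) < 1e-9))
  img2 <- amplitude_image(b, gray_levels = 2)
  expect_true(all(img2$pixels %in% c(0, 1)))
  # quantization never moves a pixel by more than half a level
  img <- amplitude_image(b)
  expect_lte(max(abs(img$pixels - img8$pixels)), 0.5 / 255 + 1e-12)
  expect_error(amplitude_image(b, gray_levels = 1),
               class = "ecgbispec_invalid_parameter")
})

test_that("labels and provenance survive the segment -> image chain", {
  ds <- generate_dataset(2, seed = 12)
  imgs <- segments_to_images(ds)
  expect_equal(imgs$label, ds$label)
  expect_equal(imgs$id, ds$id)
  srcs <- vapply(imgs$image, function(im) im$source$label, character(1))
  expect_equal(srcs, ds$label)
  expect_true(all(vapply(imgs$image, function(im)
    all(dim(im$pixels) == c(24, 24)), logical(1))))
})
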