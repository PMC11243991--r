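test_that("WFDB record round-trips within quantization tolerance", {
  dir <- withr::local_tempdir()
  seg1 <- generate_segment(rhythm_model("AFIB"), duration_s = 8, seed = 1)
  seg2 <- generate_segment(rhythm_model("N"), duration_s = 8, seed = 2)
  sig <- cbind(seg1$samples[[1]], seg2$samples[[1]])
  write_wfdb_record(sig, dir, "rt01")
  rec <- read_wfdb_record(file.path(dir, "rt01"))
  expect_s3_class(rec, "ecg_record")
  expect_equal(rec$fs_hz, 250)
  expect_equal(rec$n_samples, nrow(sig))
  # 12-bit over +-10 mV at gain 200: quantization step 1/200 mV
  expect_lt(max(abs(rec$signal - sig)), 0.5 / 200 + 1e-12)
})

test_that("missing and truncated signal files raise typed errors", {
  dir <- withr::local_tempdir()
  write_wfdb_record(matrix(rnorm(1000), ncol = 2), dir, "bad01")
  file.remove(file.path(dir, "bad01.dat"))
  expect_error(read_wfdb_record(file.path(dir, "bad01")),
               class = "ecgbispec_record_unavailable")

  write_wfdb_record(matrix(rnorm(1000), ncol = 2), dir, "bad02")
  raw <- readBin(file.path(dir, "bad02.dat"), "raw", 10000)
  writeBin(raw[1:(length(raw) %/% 2)], file.path(dir, "bad02.dat"))
  expect_error(read_wfdb_record(file.path(dir, "bad02")),
               class = "ecgbispec_consistency_error")
})

test_that("database reader skips unavailable records (as for AFDB's missing pair)", {
  dir <- withr::local_tempdir()
  for (id in c("a", "b", "c")) {
    write_wfdb_record(matrix(rnorm(500), ncol = 1), dir, id)
  }
  file.remove(file.path(dir, "b.dat"))
  expect_message(db <- read_wfdb_database(dir), "unavailable")
  expect_named(db$records, c("a", "c"))
  expect_equal(db$skipped, "b")
})

test_that("rhythm episode reconstruction from annotation markers", {
  dir <- withr::local_tempdir()
  atr <- file.path(dir, "e1.atr")

  # two markers -> two half-open episodes
  write_rhythm_annotations(atr, c(0L, 1000L), c("(N", "(AFIB"))
  eps <- read_rhythm_episodes(atr, n_samples = 2000)
  expect_equal(eps$label, c("N", "AFIB"))
  expect_equal(eps$start_sample, c(0L, 1000L))
  expect_equal(eps$end_sample, c(1000L, 2000L))

  # single marker covers the whole record
  write_rhythm_annotations(atr, 0L, "(AFIB")
  eps <- read_rhythm_episodes(atr, n_samples = 5000)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$end_sample - eps$start_sample, 5000L)

  # unknown labels: warning, skipped, counted
  write_rhythm_annotations(atr, c(0L, 300L, 700L), c("(N", "(SVTA", "(AFIB"))
  expect_warning(eps <- read_rhythm_episodes(atr, n_samples = 1000),
                 "unknown")
  expect_equal(eps$label, c("N", "AFIB"))
  expect_equal(attr(eps, "n_skipped"), 1L)
})

test_that("episode durations equal a boundary-difference oracle; parsing idempotent", {
  dir <- withr::local_tempdir()
  atr <- file.path(dir, "e2.atr")
  starts <- c(0L, 1250L, 5000L, 125000L, 300000L)  # includes >1023 SKIP deltas
  labels <- c("(N", "(AFIB", "(N", "(AFL", "(AFIB")
  n_samples <- 450000L
  write_rhythm_annotations(atr, starts, labels)
  eps <- read_rhythm_episodes(atr, n_samples)
  # oracle: durations are first differences of the marker boundaries
  oracle <- diff(c(starts, n_samples))
  expect_equal(eps$end_sample - eps$start_sample, oracle)
  expect_equal(eps$start_sample, starts)
  # idempotence: serialize the parsed episodes and re-read
  atr2 <- file.path(dir, "e2b.atr")
  write_rhythm_annotations(atr2, eps$start_sample, paste0("(", eps$label))
  eps2 <- read_rhythm_episodes(atr2, n_samples)
  expect_equal(eps2[c("label", "start_sample", "end_sample")],
               eps[c("label", "start_sample", "end_sample")])
})

test_that("episode summaries: counts, extremes, means and totals", {
  eps <- tibble::tibble(
    record_id = "x", label = c("AFIB", "AFIB", "N"),
    start_sample = c(0L, 1000L, 3000L),
    end_sample = c(500L, 2000L, 3500L)
  )
  s <- summarize_episodes(eps, fs_hz = 250)
  afib <- s[s$label == "AFIB", ]
  expect_equal(afib$count, 2L)
  expect_equal(afib$min_s, 2)
  expect_equal(afib$max_s, 4)
  expect_equal(afib$mean_s, 3)
  expect_equal(afib$total_s, 6)
  # mean * count == total
  expect_equal(s$mean_s * s$count, s$total_s, tolerance = 1e-6)
})

test_that("segmentation rules: window counts, omission, duration conservation", {
  dir <- withr::local_tempdir()
  n <- 250 * 40
  sig <- cbind(rnorm(n), rnorm(n))
  write_wfdb_record(sig, dir, "s1")
  rec <- read_wfdb_record(file.path(dir, "s1"))

  mk_eps <- function(dur_s, label = "AFIB") {
    tibble::tibble(record_id = "s1", label = label, start_sample = 0L,
                   end_sample = as.integer(round(dur_s * 250)))
  }
  # 12 s episode, 2 channels -> 4 segments, 2 omitted fragments
  out <- segment_episodes(rec, mk_eps(12))
  expect_equal(nrow(out$segments), 4)
  expect_equal(out$omitted$omitted[out$omitted$label == "AFIB"], 2L)
  # 4.9 s episode -> nothing but omissions
  out <- segment_episodes(rec, mk_eps(4.9))
  expect_equal(nrow(out$segments), 0)
  expect_equal(out$omitted$omitted[out$omitted$label == "AFIB"], 2L)
  # exact division -> no omission
  out <- segment_episodes(rec, mk_eps(10))
  expect_equal(nrow(out$segments), 4)
  expect_equal(sum(out$omitted$omitted), 0L)
  # non-kept labels are ignored
  out <- segment_episodes(rec, mk_eps(12, "AFL"))
  expect_equal(nrow(out$segments), 0)
  expect_equal(sum(out$omitted$omitted), 0L)

  # duration conservation over random episodes:
  # seg_count * w + remainder == episode length, remainder < w
  set.seed(42)
  for (i in 1:20) {
    dur <- runif(1, 0, 35)
    out <- segment_episodes(rec, mk_eps(dur))
    len <- round(dur * 250)
    w <- 1250
    k_per_ch <- nrow(out$segments) / 2
    rem <- len - k_per_ch * w
    expect_gte(rem, 0)
    expect_lt(rem, w)
    expect_equal(sum(out$omitted$omitted), 2L * (rem > 0))
  }
})

test_that("segment content matches the record samples at the cut points", {
  dir <- withr::local_tempdir()
  n <- 250 * 11
  sig <- cbind(seq_len(n) / 1000, -seq_len(n) / 1000)
  write_wfdb_record(sig, dir, "s2", gain = 100)
  rec <- read_wfdb_record(file.path(dir, "s2"))
  eps <- tibble::tibble(record_id = "s2", label = "N", start_sample = 250L,
                        end_sample = 250L + 2500L)
  out <- segment_episodes(rec, eps)
  seg <- out$segments
  expect_equal(nrow(seg), 4)
  first_ch1 <- seg[seg$channel == 1, ][1, ]
  expect_equal(first_ch1$samples[[1]], rec$signal[251:1500, 1])
})
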