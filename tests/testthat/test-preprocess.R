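# Preprocessing contracts: channel rejection, transition trimming,
# resampling, zero-phase filtering, standardization, lag embedding and
# row labeling.

test_that("default peripheral rejection keeps 39 of 64 montage channels", {
  eeg <- eeg_recording(matrix(rnorm(64 * 50), 64), montage_1020(64), 100)
  kept <- reject_peripheral(eeg)
  expect_equal(nrow(kept$data), 39)
  expect_length(peripheral_channels(), 25)
  # survivor order preserved
  expect_identical(kept$channel_labels,
                   setdiff(eeg$channel_labels, peripheral_channels()))
})

test_that("rejection edge cases behave", {
  eeg <- eeg_recording(matrix(rnorm(4 * 30), 4), c("Cz", "Pz", "Fz", "Oz"),
                       100)
  expect_identical(reject_peripheral(eeg, character(0)), eeg)
  expect_error(reject_peripheral(eeg, c("Cz", "Pz", "Fz", "Oz")),
               "preprocessing error")
  expect_warning(out <- reject_peripheral(eeg, c("Oz", "Nope")), "Nope")
  expect_equal(nrow(out$data), 3)
})

test_that("transition trimming shrinks both segment ends", {
  sched <- event_schedule(data.frame(
    start_s = c(0, 10), end_s = c(10, 20),
    action = c("neutral", "do"), factor = c("none", "Time"),
    element = c("none", "quick")))
  tr <- trim_transitions(sched, 500)
  expect_equal(tr$segments$start_s, c(0.5, 10.5))
  expect_equal(tr$segments$end_s, c(9.5, 19.5))
  expect_identical(trim_transitions(sched, 0), sched)
  short <- event_schedule(data.frame(start_s = 0, end_s = 0.8,
                                     action = "neutral", factor = "none",
                                     element = "none"))
  expect_warning(tr2 <- trim_transitions(short, 500), "dropped")
  expect_equal(nrow(tr2$segments), 0)
})

test_that("polyphase resampling preserves length arithmetic, DC and tones", {
  n <- 10000
  eeg <- eeg_recording(rbind(rep(3.7, n), sin(2 * pi * 2 * (0:(n - 1)) / 1000)),
                       c("Cz", "Pz"), 1000)
  out <- resample_eeg(eeg, 100)
  expect_equal(ncol(out$data), 1000)
  expect_equal(out$rate, 100)
  # DC preserved essentially exactly (unit-DC-gain taps, edge padding)
  expect_lt(max(abs(out$data[1, ] - 3.7)), 1e-9)
  # 2 Hz tone: compare interior against the analytic sinusoid
  expected <- sin(2 * pi * 2 * (0:999) / 100)
  mid <- 100:900
  expect_lt(max(abs(out$data[2, mid] - expected[mid])), 0.01)
  # upsampling refused
  expect_error(resample_eeg(eeg, 2000), "usage error")
  # equal rate is the identity
  expect_identical(resample_eeg(eeg, 1000), eeg)
})

test_that("non-integer rate ratios resample correctly", {
  n <- 1280
  x <- sin(2 * pi * 1 * (0:(n - 1)) / 128)
  eeg <- eeg_recording(matrix(x, 1), "Cz", 128)
  out <- resample_eeg(eeg, 100)
  expect_equal(ncol(out$data), 1000)
  expected <- sin(2 * pi * 1 * (0:999) / 100)
  mid <- 150:850
  expect_lt(max(abs(out$data[1, mid] - expected[mid])), 0.02)
})

test_that("delta band-pass is zero-phase with the designed attenuation", {
  n <- 3000
  t <- (0:(n - 1)) / 100
  x1 <- sin(2 * pi * 1 * t)
  eeg <- eeg_recording(matrix(x1, 1), "Cz", 100)
  y <- bandpass_delta(eeg)$data[1, ]
  # zero-phase: cross-correlation peak at lag 0
  cc <- ccf(x1, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # stop-band: analytic squared magnitude response of the cascaded
  # (forward-backward) filter at 20 Hz is the oracle for the output RMS
  bf <- signal::butter(3, c(0.2, 4) / 50, "pass")
  H20 <- abs(signal::polyval(rev(bf$b), exp(1i * 2 * pi * 20 / 100)) /
               signal::polyval(rev(bf$a), exp(1i * 2 * pi * 20 / 100)))^2
  x20 <- sin(2 * pi * 20 * t)
  y20 <- bandpass_delta(eeg_recording(matrix(x20, 1), "Cz", 100))$data[1, ]
  r <- sqrt(mean(y20[500:2500]^2)) / sqrt(mean(x20[500:2500]^2))
  expect_lt(r, 0.05)
  # deep in the interior the analytic cascaded response is approached,
  # up to a residual edge-transient floor
  r_mid <- sqrt(mean(y20[1300:1700]^2)) / sqrt(mean(x20[1300:1700]^2))
  expect_lt(r_mid, H20 + 5e-4)
  # DC rejection through the high-pass edge
  ydc <- bandpass_delta(eeg_recording(matrix(rep(10, n), 1), "Cz",
                                      100))$data[1, ]
  expect_lt(abs(mean(ydc)), 1e-3 * 10)
  # too-short signals are refused
  expect_error(bandpass_delta(eeg_recording(matrix(1:10, 1), "Cz", 100)),
               "preprocessing error")
})

test_that("standardization follows the population-SD convention", {
  eeg <- eeg_recording(matrix(c(1, 2, 3), 1), "Cz", 100)
  z <- standardize_eeg(eeg)$data[1, ]
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  # idempotence
  z2 <- standardize_eeg(standardize_eeg(eeg))$data[1, ]
  expect_equal(z2, z, tolerance = 1e-12)
  expect_error(standardize_eeg(eeg_recording(matrix(rep(2, 5), 1), "Cz", 100)),
               "Cz")
})

test_that("lag embedding produces the stated rows and columns", {
  eeg <- eeg_recording(matrix(1:5, 1), "Cz", 100)
  fm <- embed_lags(eeg, 3)
  expect_equal(unname(fm$X),
               matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 3, byrow = TRUE))
  expect_equal(nrow(fm$X), 5 - 3 + 1)
  # 39 channels x 10 lags -> 390 columns
  eeg39 <- eeg_recording(matrix(rnorm(39 * 30), 39),
                         setdiff(montage_1020(64), peripheral_channels()),
                         100)
  expect_equal(ncol(embed_lags(eeg39, 10)$X), 390)
  # l = 1 is the transpose identity
  expect_equal(unname(embed_lags(eeg39, 1)$X), unname(t(eeg39$data)))
  expect_error(embed_lags(eeg, 6), "preprocessing error")
})

test_that("row labeling respects segments and schemes", {
  sched <- event_schedule(data.frame(
    start_s = c(0, 1), end_s = c(1, 2),
    action = c("think", "do"), factor = c("Flow", "Flow"),
    element = c("free", "free")))
  eeg <- eeg_recording(matrix(rnorm(2 * 200), 2), c("Cz", "Pz"), 100)
  fm <- label_rows(embed_lags(eeg, 10), sched, "effort")
  expect_setequal(unique(fm$y), c("think-free-flow", "do-free-flow"))
  # no row carries both labels; the split point is the segment boundary
  expect_true(all(fm$row_time[fm$y == "think-free-flow"] < 1))
  expect_true(all(fm$row_time[fm$y == "do-free-flow"] >= 1))
  # action scheme on a full 17-class schedule gives exactly 3 labels
  s <- generate_session(small_session_config())
  fma <- preprocess_session(s$eeg, s$schedule, "action",
                            reject = character(0))
  expect_setequal(unique(fma$y), c("neutral", "think", "do"))
  expect_error(
    label_rows(embed_lags(eeg, 10),
               suppressWarnings(trim_transitions(sched, 900)), "effort"),
    "preprocessing error")
})

test_that("row-count bookkeeping is exact and stages commute only at l=1", {
  s <- generate_session(small_session_config())
  eeg <- reject_peripheral(s$eeg, character(0))
  b <- standardize_eeg(bandpass_delta(eeg))
  l <- 10
  fm <- embed_lags(b, l)
  expect_equal(nrow(fm$X), ncol(b$data) - l + 1)
  # standardize-then-embed == embed at l = 1 (columns are the channels)
  f1 <- embed_lags(standardize_eeg(bandpass_delta(eeg)), 1)
  expect_equal(unname(f1$X), unname(t(standardize_eeg(b)$data)),
               tolerance = 1e-12)
})
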