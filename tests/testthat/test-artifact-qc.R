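# Motion-artifact QC: acceleration PCA, cross-correlation maps,
# spectrograms, Welch coherence and the F1-vs-correlation audit.

test_that("acceleration PCA variance fractions behave", {
  # all variance on one sensor -> PC1 fraction 1
  accel <- array(0, dim = c(3, 3, 500))
  accel[1, 1, ] <- sin(2 * pi * (1:500) / 50)
  m <- marg_recording(accel, c("head", "torso", "lumbar"), 50)
  p <- pca_acceleration(m)
  expect_equal(p$var_frac[1], 1, tolerance = 1e-9)
  # fractions always sum to 1
  s <- generate_session(small_session_config())
  p2 <- pca_acceleration(s$marg, s$schedule)
  expect_equal(sum(p2$var_frac), 1, tolerance = 1e-9)
  expect_true(all(names(p2$pc1_kurtosis) != "")) # per-class breakdown
})

test_that("kurtosis uses the plain (Gaussian = 3) convention", {
  x <- mobidecode:::with_seed(5, rnorm(10000))
  expect_equal(mobidecode:::.kurtosis(x), 3, tolerance = 0.2)
})

test_that("cross-correlation maps return the textbook extremes", {
  n <- 400
  ref <- mobidecode:::with_seed(6, rnorm(n))
  eeg <- eeg_recording(rbind(ref, -ref, mobidecode:::with_seed(7, rnorm(n))),
                       c("Cz", "Pz", "Fz"), 100)
  sched <- event_schedule(data.frame(start_s = 0, end_s = 4,
                                     action = "think", factor = "Flow",
                                     element = "free"))
  mp <- crosscorr_map(eeg, ref, sched, "think-free-flow")
  expect_equal(mp$rho[1], 1, tolerance = 1e-12)
  expect_equal(mp$rho[2], -1, tolerance = 1e-12)
  expect_equal(mp$rho2[1:2], c(1, 1), tolerance = 1e-12)
  expect_error(crosscorr_map(eeg, ref, sched, "do-free-flow"),
               "usage error")
  expect_error(crosscorr_map(eeg, ref[-1], sched, "think-free-flow"),
               "usage error")
})

test_that("independent channels show null-level correlations", {
  # |rho| < 0.05 in at least 99% of runs at n = 5000 (null SD ~ 0.014)
  hits <- vapply(1:100, function(s) {
    xy <- mobidecode:::with_seed(1000 + s, matrix(rnorm(10000), ncol = 2))
    abs(cor(xy[, 1], xy[, 2])) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("spectrograms localize tones and count frames correctly", {
  rate <- 100
  n <- 10000
  x <- sin(2 * pi * 5 * (0:(n - 1)) / rate)
  sg <- eeg_spectrogram(x, rate)
  peak_freq <- sg$freq[apply(sg$power, 2, which.max)]
  expect_true(all(abs(peak_freq - 5) < rate / 1024))
  hop <- max(1, round(1024 * (1 - 0.93)))
  expect_equal(ncol(sg$power), floor((n - 1024) / hop) + 1)
  expect_true(all(sg$freq >= 0.1 & sg$freq <= 40))
  # silence in, zero power out
  expect_equal(max(eeg_spectrogram(numeric(2048), rate)$power), 0)
  expect_error(eeg_spectrogram(numeric(100), rate), "usage error")
})

test_that("Welch coherence is 1 for a linear system and low for noise", {
  rate <- 100
  n <- 20000
  x <- mobidecode:::with_seed(9, rnorm(n))
  # fixed linear filtering plus gain keeps coherence at 1 in-band
  y <- 3 * stats::filter(x, rep(1 / 4, 4), sides = 1)
  y[is.na(y)] <- 0
  co <- msc_coherence(x, as.numeric(y), rate)
  inband <- co$freq > 2 & co$freq < 20
  expect_gt(min(co$coherence[inband]), 0.99)
  expect_true(all(co$coherence >= 0 & co$coherence <= 1))
  # self-coherence is 1 wherever there is power
  cs <- msc_coherence(x, x, rate)
  expect_equal(max(abs(cs$coherence - 1)), 0, tolerance = 1e-9)
  # independent noise averages down to the segment-count bias level
  z <- mobidecode:::with_seed(10, rnorm(n))
  cn <- msc_coherence(x, z, rate)
  expect_lt(mean(cn$coherence), 0.1)
  expect_error(msc_coherence(x[1:1500], z[1:1500], rate), "usage error")
})

test_that("Welch coherence agrees with smoothed-periodogram coherency", {
  # independent oracle: stats::spec.pgram coherency on a strongly
  # coupled pair should match the in-band Welch estimate closely
  rate <- 100
  n <- 8192
  x <- mobidecode:::with_seed(12, rnorm(n))
  y <- as.numeric(stats::filter(x, c(0.7, 0.3), sides = 1))
  y[is.na(y)] <- 0
  y <- y + 0.3 * mobidecode:::with_seed(13, rnorm(n))
  co <- msc_coherence(x, y, rate, nseg = 512)
  sp <- stats::spec.pgram(cbind(x, y), spans = 31, plot = FALSE)
  f_sp <- sp$freq * rate
  # compare on a mid-band grid away from edges
  grid <- seq(10, 40, by = 5)
  welch_g <- approx(co$freq, co$coherence, grid)$y
  ref_g <- approx(f_sp, sp$coh[, 1], grid)$y
  expect_lt(max(abs(welch_g - ref_g)), 0.1)
})

test_that("qc_maps assembles per-class, per-channel correlations", {
  cfg <- small_session_config(artifact_coupling = 0.6, seed = 51)
  s <- generate_session(cfg)
  eeg100 <- resample_eeg(s$eeg, 100)
  qc <- qc_maps(eeg100, s$marg, s$schedule)
  expect_equal(dim(qc$rho), c(8, 17))
  expect_true(all(qc$rho >= -1 & qc$rho <= 1))
  expect_equal(qc$rho2, qc$rho^2)
  # coupled sessions show clearly higher correlation than uncoupled
  qc0 <- qc_maps(resample_eeg(generate_session(
    small_session_config(artifact_coupling = 0, seed = 51))$eeg, 100),
    s$marg, s$schedule)
  expect_gt(median(qc$rho), median(qc0$rho) + 0.1)
})

test_that("median class correlation rises monotonically with coupling", {
  meds <- vapply(c(0, 0.2, 0.5, 0.8), function(k) {
    s <- generate_session(small_session_config(artifact_coupling = k,
                                               seed = 61))
    qc <- qc_maps(resample_eeg(s$eeg, 100), s$marg, s$schedule)
    median(qc$rho)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("the F1-vs-correlation audit pairs classes and tests rank order", {
  s <- generate_session(small_session_config(seed = 71))
  qc <- qc_maps(resample_eeg(s$eeg, 100), s$marg, s$schedule)
  classes <- qc$classes
  fake_metrics <- data.frame(class = classes,
                             sensitivity = 0.5, precision = 0.5,
                             F = mobidecode:::with_seed(1,
                                                        runif(length(classes))))
  out <- f1_vs_correlation(fake_metrics, qc, n_perm = 2000, seed = 3)
  expect_equal(nrow(out$table), 17)
  expect_true(out$p_value > 0 && out$p_value <= 1)
  # degenerate constant F: rank correlation 0 by convention
  fake_metrics$F <- 0.5
  out0 <- f1_vs_correlation(fake_metrics, qc, n_perm = 100, seed = 3)
  expect_equal(out0$spearman_rho, 0)
  expect_error(f1_vs_correlation(fake_metrics[-1, ], qc), "usage error")
})
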