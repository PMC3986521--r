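# Motion-artifact audit: accelerometer PCA, EEG-acceleration
# cross-correlation maps, spectrograms, Welch coherence, and the
# F1-versus-correlation check that classification success is not driven
# by mechanically contaminated classes.

#' Per-sensor acceleration magnitude
#'
#' @param marg A [marg_recording()].
#' @return `samples x sensors` matrix of Euclidean acceleration
#'   magnitudes.
#' @export
accel_magnitude <- function(marg) {
  stopifnot(inherits(marg, "marg_recording"))
  t(sqrt(apply(marg$accel^2, c(1, 3), sum)))
}

# moment kurtosis, Gaussian = 3
.kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2
}

#' PCA of the acceleration magnitudes
#'
#' Principal component analysis of the mean-centered per-sensor
#' acceleration-magnitude time series. When a schedule is supplied, the
#' kurtosis (plain convention, Gaussian = 3) of the first PC is reported
#' per class, summarizing how heavy-tailed each class's movement is.
#'
#' @param marg A [marg_recording()].
#' @param schedule Optional [event_schedule()] for per-class kurtosis.
#' @param scheme Labeling scheme for the per-class split.
#' @return List with `scores` (samples x PCs), `var_frac` (variance
#'   fractions, summing to 1), `rotation`, and `pc1_kurtosis` (named per
#'   class, or overall when no schedule is given).
#' @export
pca_acceleration <- function(marg, schedule = NULL,
                             scheme = c("effort", "action")) {
  scheme <- match.arg(scheme)
  M <- accel_magnitude(marg)
  if (nrow(M) < 2) {
    stop("usage error: need at least 2 time samples", call. = FALSE)
  }
  if (all(apply(M, 2, stats::var) < 1e-24)) {
    stop("numeric error: acceleration magnitudes are constant", call. = FALSE)
  }
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  pc1 <- p$x[, 1]
  kurt <- if (is.null(schedule)) {
    c(overall = .kurtosis(pc1))
  } else {
    lab <- schedule_to_labels(schedule, marg$rate, scheme,
                              n_samples = nrow(M))
    vapply(split(pc1, lab), .kurtosis, numeric(1))
  }
  list(scores = p$x, var_frac = var_frac, rotation = p$rotation,
       pc1_kurtosis = kurt)
}

# Linear interpolation of a reference series onto the EEG sample grid.
resample_reference <- function(x, from_rate, to_rate, n_out) {
  t_in <- (seq_along(x) - 1) / from_rate
  t_out <- (seq_len(n_out) - 1) / to_rate
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Per-channel EEG-reference cross-correlation for one class
#'
#' Zero-lag Pearson correlation between each EEG channel and a reference
#' time series (head-acceleration magnitude or an acceleration PC) over
#' the concatenated samples of one class. rho^2 is reported as the
#' coefficient of determination.
#'
#' @param eeg An [eeg_recording()] -- for the artifact audit, the raw
#'   recording resampled to the analysis rate but unfiltered.
#' @param reference Numeric vector at the EEG rate, same length as the
#'   recording.
#' @param schedule An [event_schedule()].
#' @param class Class label whose samples are correlated.
#' @param scheme `"effort"` or `"action"`.
#' @return `data.frame` with columns `channel`, `rho`, `rho2`.
#' @export
crosscorr_map <- function(eeg, reference, schedule, class,
                          scheme = c("effort", "action")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(eeg, "eeg_recording"))
  n <- ncol(eeg$data)
  if (length(reference) != n) {
    stop("usage error: reference length ", length(reference),
         " does not match EEG samples ", n, call. = FALSE)
  }
  lab <- schedule_to_labels(schedule, eeg$rate, scheme, n_samples = n)
  idx <- which(lab == class)
  if (!length(idx)) {
    stop("usage error: class '", class, "' not present in schedule",
         call. = FALSE)
  }
  rho <- apply(eeg$data[, idx, drop = FALSE], 1, stats::cor,
               y = reference[idx])
  data.frame(channel = eeg$channel_labels, rho = rho, rho2 = rho^2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full motion-artifact QC maps
#'
#' Computes, for every class in the scheme, the per-channel zero-lag
#' correlation between the (raw, resampled) EEG and the head-sensor
#' acceleration magnitude (or the first acceleration PC), together with
#' the acceleration PCA summary. The accelerometer stream is linearly
#' interpolated onto the EEG sample grid.
#'
#' @param eeg Raw [eeg_recording()] at the analysis rate (unfiltered).
#' @param marg A [marg_recording()].
#' @param schedule An [event_schedule()].
#' @param reference `"head"` (head-sensor magnitude) or `"pc1"` (first
#'   acceleration synergy).
#' @param scheme `"effort"` or `"action"`.
#' @return An object of class `qc_maps`: matrices `rho` and `rho2`
#'   (channels x classes), `pca` (see [pca_acceleration()]), and the
#'   reference series used.
#' @export
qc_maps <- function(eeg, marg, schedule, reference = c("head", "pc1"),
                    scheme = c("effort", "action")) {
  reference <- match.arg(reference)
  scheme <- match.arg(scheme)
  pca <- pca_acceleration(marg, schedule, scheme)
  ref_raw <- if (reference == "head") {
    if (!"head" %in% marg$sensor_roles) {
      stop("usage error: no 'head' sensor in recording", call. = FALSE)
    }
    accel_magnitude(marg)[, match("head", marg$sensor_roles)]
  } else {
    pca$scores[, 1]
  }
  ref <- resample_reference(ref_raw, marg$rate, eeg$rate, ncol(eeg$data))
  lab <- schedule_to_labels(schedule, eeg$rate, scheme,
                            n_samples = ncol(eeg$data))
  classes <- sort(setdiff(unique(lab), "unlabeled"))
  rho <- vapply(classes, function(cl) {
    crosscorr_map(eeg, ref, schedule, cl, scheme)$rho
  }, numeric(nrow(eeg$data)))
  rho <- matrix(rho, nrow = nrow(eeg$data),
                dimnames = list(eeg$channel_labels, classes))
  structure(list(rho = rho, rho2 = rho^2, pca = pca, reference = ref,
                 reference_type = reference, classes = classes),
            class = "qc_maps")
}

#' @export
print.qc_maps <- function(x, ...) {
  cat(sprintf("<qc_maps> %d channels x %d classes (%s reference); ",
              nrow(x$rho), ncol(x$rho), x$reference_type))
  cat(sprintf("median |rho| = %.3f\n", stats::median(abs(x$rho))))
  invisible(x)
}

#' Short-time Fourier spectrogram
#'
#' Magnitude-squared short-time Fourier transform restricted to an
#' analysis band, with the long-window/high-overlap setting used for
#' side-by-side EEG and head-acceleration displays.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate, Hz.
#' @param window Window length in samples (default 1024).
#' @param overlap Fractional overlap between windows (default 0.93).
#' @param band Frequency band to retain, Hz.
#' @return List with `power` (freq x frames), `freq`, `time`.
#' @export
eeg_spectrogram <- function(x, rate, window = 1024, overlap = 0.93,
                            band = c(0.1, 40)) {
  if (length(x) < window) {
    stop("usage error: signal shorter than the analysis window",
         call. = FALSE)
  }
  hop <- max(1, round(window * (1 - overlap)))
  sg <- signal::specgram(x, n = window, Fs = rate,
                         overlap = window - hop)
  keep <- sg$f >= band[1] & sg$f <= band[2]
  list(power = abs(sg$S[keep, , drop = FALSE])^2, freq = sg$f[keep],
       time = sg$t)
}

#' Magnitude-squared coherence by Welch's method
#'
#' Overlapped-segment averaging with Hann-windowed segments; the
#' cross- and auto-spectra are averaged across segments and combined
#' into `|Sxy|^2 / (Sxx Syy)`, which lies in \[0, 1\] per frequency bin.
#'
#' @param x,y Equal-length signals.
#' @param rate Sampling rate, Hz.
#' @param nseg Segment length in samples (default 1024).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return `data.frame` with columns `freq`, `coherence`.
#' @export
msc_coherence <- function(x, y, rate, nseg = 1024, overlap = 0.5) {
  if (length(x) != length(y)) {
    stop("usage error: x and y differ in length", call. = FALSE)
  }
  hop <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  if (length(x) < nseg || length(starts) < 2) {
    stop("usage error: coherence undefined with fewer than 2 segments",
         call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  Sxx <- Syy <- numeric(nseg)
  Sxy <- complex(nseg)
  for (s in starts) {
    xs <- x[s:(s + nseg - 1)] * w
    ys <- y[s:(s + nseg - 1)] * w
    X <- stats::fft(xs)
    Y <- stats::fft(ys)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  half <- seq_len(floor(nseg / 2) + 1)
  coh <- Mod(Sxy[half])^2 / (Sxx[half] * Syy[half])
  coh[!is.finite(coh)] <- 0
  data.frame(freq = (half - 1) * rate / nseg,
             coherence = pmin(pmax(coh, 0), 1))
}

#' F1 score versus motion-correlation audit
#'
#' Pairs each class's median channel correlation with the accelerometer
#' reference against its classification F1 score; if decoding were
#' driven by motion artifact, strongly contaminated classes would be the
#' best classified. Reports the Spearman rank correlation with a
#' permutation p-value (one-sided, positive association).
#'
#' @param metrics Per-class metrics from [class_metrics()].
#' @param qc A `qc_maps` object over the same class set.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation draw.
#' @return List with the per-class `table` (`class`, `median_rho`, `F`),
#'   `spearman_rho`, and `p_value`.
#' @export
f1_vs_correlation <- function(metrics, qc, n_perm = 10000, seed = 1L) {
  stopifnot(inherits(qc, "qc_maps"))
  if (!setequal(metrics$class, qc$classes)) {
    stop("usage error: metric classes and QC classes differ", call. = FALSE)
  }
  med_rho <- apply(qc$rho, 2, stats::median)
  tab <- data.frame(class = qc$classes, median_rho = med_rho[qc$classes],
                    F = metrics$F[match(qc$classes, metrics$class)],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (stats::sd(tab$F) == 0 || stats::sd(tab$median_rho) == 0) {
    # degenerate: no rank variation, correlation 0 by convention
    return(list(table = tab, spearman_rho = 0, p_value = 1))
  }
  obs <- stats::cor(tab$median_rho, tab$F, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(tab$median_rho, sample(tab$F), method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  list(table = tab, spearman_rho = obs, p_value = p)
}
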