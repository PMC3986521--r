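# Raw EEG -> standardized, lag-embedded delta-band feature matrix.
# Fixed pipeline order: reject peripherals -> resample -> zero-phase
# band-pass (which also detrends via the high-pass edge) -> standardize
# -> lag-embed -> label rows against the trimmed schedule.

#' Reject peripheral EEG channels
#'
#' Drops channels heavily corrupted by motion and scalp-muscle artifact.
#' The default list is the 25 peripheral electrodes of the extended 10-20
#' montage (see [peripheral_channels()]); matching is case-insensitive and
#' unknown labels warn rather than fail.
#'
#' @param eeg An [eeg_recording()].
#' @param reject Character vector of labels to remove.
#' @return An [eeg_recording()] with the surviving channels, order
#'   preserved.
#' @export
reject_peripheral <- function(eeg, reject = peripheral_channels()) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (length(reject) == 0) return(eeg)
  unknown <- setdiff(tolower(reject), tolower(eeg$channel_labels))
  if (length(unknown)) {
    warning("reject labels not present in recording: ",
            paste(reject[tolower(reject) %in% unknown], collapse = ", "))
  }
  keep <- !(tolower(eeg$channel_labels) %in% tolower(reject))
  if (!any(keep)) {
    stop("preprocessing error: channel rejection removed every channel",
         call. = FALSE)
  }
  eeg_recording(eeg$data[keep, , drop = FALSE], eeg$channel_labels[keep],
                eeg$rate)
}

#' Trim condition transitions from a schedule
#'
#' Shrinks every segment by `trim_ms` at both onset and offset so samples
#' contaminated by condition-transition effects are never labeled.
#' Segments shorter than `2 * trim_ms` are dropped with a warning.
#'
#' @param schedule An [event_schedule()].
#' @param trim_ms Milliseconds removed at each end (default 500).
#' @return A trimmed [event_schedule()].
#' @export
trim_transitions <- function(schedule, trim_ms = 500) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (!is.numeric(trim_ms) || length(trim_ms) != 1 || trim_ms < 0) {
    stop("usage error: trim_ms must be nonnegative", call. = FALSE)
  }
  segs <- schedule$segments
  tr <- trim_ms / 1000
  segs$start_s <- segs$start_s + tr
  segs$end_s <- segs$end_s - tr
  drop <- segs$end_s <= segs$start_s
  if (any(drop)) {
    warning(sum(drop), " segment(s) shorter than 2*trim_ms dropped")
    segs <- segs[!drop, , drop = FALSE]
  }
  event_schedule(segs)
}

# Zero-phase polyphase FIR resampler. Linear-phase low-pass (Hamming
# window design) whose exact group delay is compensated, so pure delays
# are never introduced; taps normalized to unit DC gain so constant
# signals pass unchanged. Edges are handled by replicate-padding.
polyphase_resample <- function(x, p, q, taps_per_branch = 10) {
  n <- length(x)
  g <- .gcd(p, q)
  p <- p / g; q <- q / g
  if (p == 1 && q == 1) return(x)
  m <- max(p, q)
  half <- taps_per_branch * m
  h <- signal::fir1(2 * half, 1 / m, type = "low")
  h <- h / sum(h)                      # exact unit DC gain
  pad <- ceiling(half / p) + 1
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  if (p > 1) {
    up <- numeric(length(xp) * p)
    up[seq(1, length(up), by = p)] <- xp
    xp <- up
    h <- h * p                         # compensate interpolation loss
  }
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  # centers of output samples in the upsampled grid
  n_out <- round(n * p / q)
  centers <- pad * p + 1 + (seq_len(n_out) - 1) * q
  as.numeric(y[centers])
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Resample an EEG recording
#'
#' Anti-aliased zero-phase polyphase resampling to a lower rate (the
#' decoding pipeline uses 100 Hz). Output length is
#' `round(n * target_rate / rate)`.
#'
#' @param eeg An [eeg_recording()].
#' @param target_rate Target sampling rate in Hz, at most the current
#'   rate (upsampling is refused).
#' @return The resampled [eeg_recording()].
#' @export
resample_eeg <- function(eeg, target_rate = 100) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (target_rate > eeg$rate) {
    stop("usage error: target_rate ", target_rate, " exceeds recording rate ",
         eeg$rate, " (upsampling not supported)", call. = FALSE)
  }
  if (target_rate == eeg$rate) return(eeg)
  frac <- .as_fraction(target_rate / eeg$rate)
  out <- t(apply(eeg$data, 1, polyphase_resample, p = frac[1], q = frac[2]))
  eeg_recording(out, eeg$channel_labels, target_rate)
}

# Small-denominator rational approximation of a rate ratio.
.as_fraction <- function(r, max_den = 1000) {
  for (den in seq_len(max_den)) {
    num <- r * den
    if (abs(num - round(num)) < 1e-9) return(c(round(num), den))
  }
  stop("usage error: rate ratio has no small rational form", call. = FALSE)
}

#' Delta-band zero-phase Butterworth filter
#'
#' Forward-backward (zero-phase) band-pass filtering with a 3rd-order
#' Butterworth design. The 0.2 Hz high-pass edge also removes slow
#' trends and DC offsets.
#'
#' @param eeg An [eeg_recording()].
#' @param low,high Band edges in Hz (defaults 0.2 and 4).
#' @param order Butterworth prototype order (default 3).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_delta <- function(eeg, low = 0.2, high = 4, order = 3) {
  stopifnot(inherits(eeg, "eeg_recording"))
  nyq <- eeg$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("configuration error: band must satisfy 0 < low < high < rate/2",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  min_pad <- 3 * (length(bf$b) - 1)
  if (ncol(eeg$data) <= min_pad) {
    stop("preprocessing error: signal too short for zero-phase filtering (",
         ncol(eeg$data), " samples, needs > ", min_pad, ")", call. = FALSE)
  }
  # the high-pass edge has a transient lasting on the order of 1/low
  # seconds; reflect enough signal at each end for it to decay there
  pad <- min(ncol(eeg$data) - 1, ceiling(3 * eeg$rate / low))
  filt1 <- function(x) {
    # odd-reflection padding, then forward-backward filtering
    n <- length(x)
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[n - (1:pad)])
    y <- signal::filtfilt(bf, xp)
    y[(pad + 1):(pad + n)]
  }
  out <- t(apply(eeg$data, 1, filt1))
  eeg_recording(out, eeg$channel_labels, eeg$rate)
}

#' Standardize EEG channels
#'
#' Per-channel z-scoring over the whole trial: subtract the mean, divide
#' by the standard deviation. The population (1/n) SD convention is used
#' throughout the package.
#'
#' @param eeg An [eeg_recording()].
#' @return The standardized [eeg_recording()].
#' @export
standardize_eeg <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_recording"))
  mu <- rowMeans(eeg$data)
  centered <- eeg$data - mu
  sdev <- sqrt(rowMeans(centered^2))
  if (any(sdev == 0)) {
    stop("preprocessing error: zero-variance channel(s): ",
         paste(eeg$channel_labels[sdev == 0], collapse = ", "), call. = FALSE)
  }
  eeg_recording(centered / sdev, eeg$channel_labels, eeg$rate)
}

#' Time-lag embedding of an EEG recording
#'
#' Builds the feature matrix whose row for time `t_n` concatenates,
#' channel by channel, the `l` samples `t_n - (l-1), ..., t_n`. The first
#' row therefore corresponds to the `l`-th retained sample, and the
#' matrix has `samples - l + 1` rows and `N * l` columns for `N`
#' channels.
#'
#' @param eeg An [eeg_recording()].
#' @param l Number of lags (default 10, a 100 ms window at 100 Hz).
#' @return An object of class `feature_matrix` with fields `X` (rows x
#'   `N*l`), `y` (labels, `NA` until [label_rows()]), `row_time`,
#'   `channel_labels`, `l`, `rate`.
#' @export
embed_lags <- function(eeg, l = 10) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (!is.numeric(l) || length(l) != 1 || l < 1 || l != round(l)) {
    stop("usage error: l must be a positive integer", call. = FALSE)
  }
  n <- ncol(eeg$data)
  if (n < l) {
    stop("preprocessing error: ", n, " samples < ", l, " lags", call. = FALSE)
  }
  n_rows <- n - l + 1
  n_ch <- nrow(eeg$data)
  X <- matrix(0, n_rows, n_ch * l)
  cn <- character(n_ch * l)
  for (ch in seq_len(n_ch)) {
    for (j in seq_len(l)) {
      # column j of channel ch holds lag (l - j), so the last column of
      # each channel block is the current sample t_n
      X[, (ch - 1) * l + j] <- eeg$data[ch, j:(j + n_rows - 1)]
      cn[(ch - 1) * l + j] <- paste0(eeg$channel_labels[ch], ".lag",
                                     l - j)
    }
  }
  colnames(X) <- cn
  structure(list(X = X, y = rep(NA_character_, n_rows),
                 row_time = (seq_len(n_rows) + l - 2) / eeg$rate,
                 channel_labels = eeg$channel_labels, l = l,
                 rate = eeg$rate),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  lab <- x$y[!is.na(x$y) & x$y != "unlabeled"]
  cat(sprintf(
    "<feature_matrix> %d rows x %d cols (%d channels x %d lags), %d labeled\n",
    nrow(x$X), ncol(x$X), length(x$channel_labels), x$l, length(lab)))
  invisible(x)
}

#' Label feature-matrix rows from a schedule
#'
#' Each row is labeled by the (trimmed) segment containing its `t_n`
#' timestamp; rows outside every segment are dropped.
#'
#' @param fm A `feature_matrix` from [embed_lags()].
#' @param schedule An [event_schedule()], already passed through
#'   [trim_transitions()].
#' @param scheme `"effort"` or `"action"`.
#' @return The labeled `feature_matrix` (unlabeled rows removed).
#' @export
label_rows <- function(fm, schedule, scheme = c("effort", "action")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- rep("unlabeled", nrow(fm$X))
  segs <- schedule$segments
  for (i in seq_len(nrow(segs))) {
    inside <- fm$row_time >= segs$start_s[i] - 1e-9 &
      fm$row_time < segs$end_s[i] - 1e-9
    labels[inside] <- if (scheme == "action") segs$action[i] else
      class_label(segs$action[i], segs$factor[i], segs$element[i])
  }
  keep <- labels != "unlabeled"
  if (!any(keep)) {
    stop("preprocessing error: no labeled rows survive", call. = FALSE)
  }
  fm$X <- fm$X[keep, , drop = FALSE]
  fm$y <- labels[keep]
  fm$row_time <- fm$row_time[keep]
  fm
}

#' Full preprocessing pipeline
#'
#' Applies the fixed stage order: peripheral channel rejection,
#' resampling, zero-phase delta-band filtering, per-channel
#' standardization, time-lag embedding, and row labeling against the
#' transition-trimmed schedule. When `eeg` is a list of recordings
#' (separate trial blocks), each block is embedded separately -- lag
#' windows never span block boundaries -- and the rows are concatenated.
#'
#' @param eeg An [eeg_recording()] or list of them (one per trial block,
#'   assumed consecutive in session time).
#' @param schedule The session [event_schedule()].
#' @param scheme `"effort"` or `"action"`.
#' @param reject Channel labels to reject (default: the 25 peripherals).
#' @param target_rate Resampling target, Hz.
#' @param band Delta band edges, Hz.
#' @param filter_order Butterworth prototype order.
#' @param l Number of lags.
#' @param trim_ms Transition trim, milliseconds, applied at both ends.
#' @return A labeled `feature_matrix`.
#' @export
preprocess_session <- function(eeg, schedule, scheme = c("effort", "action"),
                               reject = peripheral_channels(),
                               target_rate = 100, band = c(0.2, 4),
                               filter_order = 3, l = 10, trim_ms = 500) {
  scheme <- match.arg(scheme)
  blocks <- if (inherits(eeg, "eeg_recording")) list(eeg) else eeg
  trimmed <- trim_transitions(schedule, trim_ms)
  offset <- 0
  fms <- lapply(blocks, function(b) {
    b <- reject_peripheral(b, reject)
    dur <- ncol(b$data) / b$rate
    b <- resample_eeg(b, target_rate)
    b <- bandpass_delta(b, band[1], band[2], filter_order)
    b <- standardize_eeg(b)
    fm <- embed_lags(b, l)
    fm$row_time <- fm$row_time + offset
    offset <<- offset + dur
    fm
  })
  fm <- fms[[1]]
  if (length(fms) > 1) {
    fm$X <- do.call(rbind, lapply(fms, `[[`, "X"))
    fm$row_time <- do.call(c, lapply(fms, `[[`, "row_time"))
    fm$y <- rep(NA_character_, nrow(fm$X))
  }
  label_rows(fm, trimmed, scheme)
}
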