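# Synthetic mobile-EEG + accelerometry session generator.
#
# Emulates the statistical structure the decoding analysis assumes:
# class-conditional delta-band EEG signatures mixed into class-specific
# scalp patterns on top of 1/f background activity, class-conditional
# movement-intensity envelopes on the body-worn sensors, and a tunable
# linear admixture of head acceleration into the EEG (motion artifact).

#' Laban effort factors and elements
#'
#' The four effort factors with their condensing and indulging elements.
#'
#' @return A `data.frame` with columns `factor`, `condensing`, `indulging`.
#' @export
laban_efforts <- function() {
  data.frame(
    factor     = c("Space", "Flow", "Weight", "Time"),
    condensing = c("direct", "bound", "strong", "quick"),
    indulging  = c("indirect", "free", "light", "sustained"),
    stringsAsFactors = FALSE
  )
}

# Default presentation order: within each factor the condensing element
# precedes the indulging (favored) one.
default_effort_sequence <- function() {
  ef <- laban_efforts()
  do.call(rbind, lapply(seq_len(nrow(ef)), function(i) {
    data.frame(factor = ef$factor[i],
               element = c(ef$condensing[i], ef$indulging[i]),
               stringsAsFactors = FALSE)
  }))
}

# Canonical class label: "neutral" or "<action>-<element>-<factor>",
# e.g. "think-free-flow".
class_label <- function(action, factor, element) {
  n <- max(length(action), length(factor), length(element))
  action <- rep_len(action, n)
  factor <- rep_len(factor, n)
  element <- rep_len(element, n)
  ifelse(action == "neutral", "neutral",
         paste(action, element, tolower(factor), sep = "-"))
}

#' All class labels of a classification scheme
#'
#' @param scheme `"action"` (3 classes) or `"effort"` (17 classes:
#'   neutral plus think/do crossed with the 8 effort elements).
#' @return Character vector of class labels in canonical (sorted) order.
#' @export
scheme_classes <- function(scheme = c("effort", "action")) {
  scheme <- match.arg(scheme)
  if (scheme == "action") return(c("do", "neutral", "think"))
  sq <- default_effort_sequence()
  sort(c("neutral",
         class_label("think", sq$factor, sq$element),
         class_label("do", sq$factor, sq$element)))
}

# Default per-class movement intensity (m/s^2 scale factors) mirroring the
# qualitative kinematics: enacted free-flow and quick-time cover the
# greatest range of motion, enacted light-weight and sustained-time the
# least; "think" classes continue moderate functional movement.
default_motion_scale <- function() {
  sq <- default_effort_sequence()
  cls <- scheme_classes("effort")
  scale <- setNames(rep(1, length(cls)), cls)
  scale["neutral"] <- 1
  scale[class_label("think", sq$factor, sq$element)] <- 0.8
  scale[paste0("do-", c("direct-space", "indirect-space"))] <- 1.4
  scale["do-bound-flow"] <- 0.7
  scale["do-free-flow"] <- 2.5
  scale["do-strong-weight"] <- 2.0
  scale["do-light-weight"] <- 0.3
  scale["do-quick-time"] <- 2.5
  scale["do-sustained-time"] <- 0.3
  scale
}

#' Session generator configuration
#'
#' Defaults reproduce the recording setup the pipeline targets: a
#' 64-channel 1000 Hz EEG montage, 10 body-worn inertial sensors at
#' 128 Hz, and three trial blocks each presenting a neutral segment
#' followed by think/do segments for all eight effort elements
#' (condensing before indulging within each factor), i.e. 17 classes.
#'
#' @param n_eeg_channels Number of EEG channels (labels drawn from the
#'   extended 10-20 montage, central channels first).
#' @param eeg_rate EEG sampling rate, Hz.
#' @param n_sensors Number of inertial sensors (head, torso, lumbar, 2 x
#'   arm, 2 x thigh, 2 x shank, 2 x foot).
#' @param marg_rate Accelerometer sampling rate, Hz.
#' @param n_trial_blocks Number of trial blocks.
#' @param segment_duration_s Duration of each condition segment, seconds.
#' @param effort_sequence `data.frame` with columns `factor`, `element`
#'   covering all 8 elements, condensing before indulging per factor.
#' @param class_snr Amplitude of each class's delta-band EEG signature,
#'   relative to the background SD. A single value is recycled to all 17
#'   classes; a named vector overrides per class.
#' @param artifact_coupling Per-class motion-to-EEG coupling kappa in
#'   \[0, 1\]; single value recycled, named vector overrides.
#' @param seed Integer seed; the generator is bit-identical for equal
#'   configurations and seeds.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_eeg_channels = 64, eeg_rate = 1000,
                           n_sensors = 10, marg_rate = 128,
                           n_trial_blocks = 3, segment_duration_s = 10,
                           effort_sequence = default_effort_sequence(),
                           class_snr = 2, artifact_coupling = 0,
                           seed = 1L) {
  bad <- function(field, why) {
    stop("configuration error: field '", field, "' ", why, call. = FALSE)
  }
  chk_pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      bad(field, "must be a positive scalar")
  }
  chk_pos(eeg_rate, "eeg_rate"); chk_pos(marg_rate, "marg_rate")
  chk_pos(segment_duration_s, "segment_duration_s")
  chk_pos(n_trial_blocks, "n_trial_blocks")
  chk_pos(n_sensors, "n_sensors")
  if (!is.numeric(n_eeg_channels) || length(n_eeg_channels) != 1 ||
      n_eeg_channels < 1 || n_eeg_channels > 64)
    bad("n_eeg_channels", "must be between 1 and 64")

  es <- as.data.frame(effort_sequence, stringsAsFactors = FALSE)
  if (!all(c("factor", "element") %in% names(es)))
    bad("effort_sequence", "needs columns 'factor' and 'element'")
  ef <- laban_efforts()
  if (nrow(es) != 8 || anyDuplicated(es$element) ||
      !setequal(es$element, c(ef$condensing, ef$indulging)))
    bad("effort_sequence", "must contain each of the 8 elements exactly once")
  for (i in seq_len(nrow(ef))) {
    ic <- match(ef$condensing[i], es$element)
    ii <- match(ef$indulging[i], es$element)
    if (es$factor[ic] != ef$factor[i] || es$factor[ii] != ef$factor[i])
      bad("effort_sequence", paste0("element assigned to wrong factor for ",
                                    ef$factor[i]))
    if (ic > ii)
      bad("effort_sequence",
          paste0("condensing element must precede indulging for ",
                 ef$factor[i]))
  }

  classes <- scheme_classes("effort")
  expand_map <- function(x, field, lo, hi) {
    if (is.null(names(x))) {
      if (!length(x) %in% c(1L, length(classes)))
        bad(field, paste0("must have length 1 or ", length(classes),
                          ", or be named by class"))
      x <- setNames(rep_len(unname(x), length(classes)), classes)
    } else {
      unknown <- setdiff(names(x), classes)
      if (length(unknown))
        bad(field, paste0("has unknown class label(s): ",
                          paste(unknown, collapse = ", ")))
      full <- setNames(rep(0, length(classes)), classes)
      full[names(x)] <- x
      x <- full
    }
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi))
      bad(field, sprintf("values must lie in [%g, %g]", lo, hi))
    x
  }
  class_snr <- expand_map(class_snr, "class_snr", 0, Inf)
  artifact_coupling <- expand_map(artifact_coupling, "artifact_coupling", 0, 1)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    bad("seed", "must be a finite integer")

  structure(list(
    n_eeg_channels = as.integer(n_eeg_channels), eeg_rate = eeg_rate,
    n_sensors = as.integer(n_sensors), marg_rate = marg_rate,
    n_trial_blocks = as.integer(n_trial_blocks),
    segment_duration_s = segment_duration_s,
    effort_sequence = es, class_snr = class_snr,
    artifact_coupling = artifact_coupling, seed = as.integer(seed)
  ), class = "session_config")
}

# Band-limited Gaussian noise via Fourier-domain shaping; `shape` maps
# |f| (Hz) to an amplitude gain. Output standardized to unit SD.
shaped_noise <- function(n, rate, shape) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)              # fold to |f|
  X <- X * shape(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else (y - mean(y)) / s
}

# Raised-cosine band-pass gain on [low, high] with soft edges.
band_gain <- function(f, low, high, tl = NULL, th = NULL) {
  if (is.null(tl)) tl <- max(low * 0.5, 0.02)
  if (is.null(th)) th <- max(high * 0.1, 0.1)
  g <- numeric(length(f))
  g[f >= low & f <= high] <- 1
  rl <- f >= low - tl & f < low
  g[rl] <- 0.5 * (1 + cos(pi * (low - f[rl]) / tl))
  rh <- f > high & f <= high + th
  g[rh] <- 0.5 * (1 + cos(pi * (f[rh] - high) / th))
  g
}

delta_noise <- function(n, rate, low = 0.2, high = 4) {
  high <- min(high, 0.45 * rate)
  shaped_noise(n, rate, function(f) band_gain(f, low, high))
}

pink_noise <- function(n, rate) {
  shaped_noise(n, rate, function(f) ifelse(f < 1e-9, 0, 1 / sqrt(pmax(f, 0.1))))
}

# Build the default trial-block schedule: per block one neutral segment
# then think/do segments for each effort in sequence.
build_schedule <- function(config) {
  segs <- list()
  t0 <- 0
  for (b in seq_len(config$n_trial_blocks)) {
    rows <- data.frame(action = "neutral", factor = "none", element = "none",
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(config$effort_sequence))) {
      fe <- config$effort_sequence[i, ]
      rows <- rbind(rows,
                    data.frame(action = c("think", "do"), factor = fe$factor,
                               element = fe$element, stringsAsFactors = FALSE))
    }
    rows$start_s <- t0 + (seq_len(nrow(rows)) - 1) * config$segment_duration_s
    rows$end_s <- rows$start_s + config$segment_duration_s
    t0 <- max(rows$end_s)
    segs[[b]] <- rows
  }
  event_schedule(do.call(rbind, segs))
}

# Sample indices (1-based) of a segment at a given rate, half-open.
segment_samples <- function(start_s, end_s, rate, n_total) {
  i0 <- floor(start_s * rate + 1e-9) + 1
  i1 <- ceiling(end_s * rate - 1e-9)
  if (i1 < i0) return(integer(0))
  seq.int(max(1, i0), min(n_total, i1))
}

#' Generate a synthetic EEG + accelerometry session
#'
#' EEG is 1/f-shaped background noise plus, within each class's segments,
#' a class-specific delta-band (0.2--4 Hz) Gaussian-process component
#' mixed into a class-specific random scalp pattern and scaled by
#' `class_snr`, plus `kappa` times the head-sensor acceleration magnitude
#' projected onto a fixed spatial pattern (motion artifact).
#' Accelerometer streams are band-limited noise under class-conditional
#' log-normal amplitude envelopes, so enacted-effort classes differ in
#' movement intensity and tail weight.
#'
#' @param config A [session_config()].
#' @return A list with elements `eeg` ([eeg_recording()]), `marg`
#'   ([marg_recording()]) and `schedule` ([event_schedule()]).
#' @export
generate_session <- function(config) {
  if (!inherits(config, "session_config")) {
    stop("configuration error: config must be a session_config", call. = FALSE)
  }
  schedule <- build_schedule(config)
  segs <- schedule$segments
  total_s <- max(segs$end_s)
  n_eeg <- round(total_s * config$eeg_rate)
  n_marg <- round(total_s * config$marg_rate)
  n_ch <- config$n_eeg_channels
  labels <- montage_1020(n_ch)
  classes <- scheme_classes("effort")
  sigma0 <- 10  # background EEG scale, microvolts

  with_seed(config$seed, {
    # --- class-specific fixed structure (drawn independently of snr/kappa)
    patterns <- vapply(classes, function(cl) {
      v <- stats::rnorm(n_ch); v / sqrt(sum(v^2))
    }, numeric(n_ch))
    artifact_pattern <- stats::runif(n_ch, 0.3, 1)

    # --- accelerometry -------------------------------------------------
    motion <- default_motion_scale()
    n_sens <- config$n_sensors
    roles <- c("head", "torso", "lumbar", "arm_l", "arm_r", "thigh_l",
               "thigh_r", "shank_l", "shank_r", "foot_l", "foot_r")
    roles <- if (n_sens <= length(roles)) roles[seq_len(n_sens)] else
      c(roles, paste0("extra_", seq_len(n_sens - length(roles))))
    # per-class slow intensity envelopes shared across sensors
    env <- matrix(1, n_marg, length(classes))
    colnames(env) <- classes
    for (cl in classes) {
      g <- shaped_noise(n_marg, config$marg_rate,
                        function(f) band_gain(f, 0.03, 0.3, tl = 0.02,
                                              th = 0.05))
      # log-normal modulation; heavier tails for the vigorous classes
      sdlog <- if (motion[cl] >= 2) 0.9 else 0.4
      env[, cl] <- motion[cl] * exp(sdlog * g - sdlog^2 / 2)
    }
    class_of_seg <- class_label(segs$action, segs$factor, segs$element)
    env_t <- numeric(n_marg)
    for (i in seq_len(nrow(segs))) {
      idx <- segment_samples(segs$start_s[i], segs$end_s[i],
                             config$marg_rate, n_marg)
      env_t[idx] <- env[idx, class_of_seg[i]]
    }
    accel <- array(0, dim = c(n_sens, 3, n_marg))
    base_amp <- 1.5  # m/s^2, moderate whole-body dance movement
    for (s in seq_len(n_sens)) {
      sens_gain <- stats::runif(1, 0.6, 1.4)
      for (a in 1:3) {
        b <- delta_noise(n_marg, config$marg_rate, low = 0.3, high = 8)
        accel[s, a, ] <- base_amp * sens_gain * env_t * b
      }
    }
    marg <- marg_recording(accel, roles, config$marg_rate)

    # --- EEG -----------------------------------------------------------
    eeg <- matrix(0, n_ch, n_eeg)
    for (ch in seq_len(n_ch)) {
      eeg[ch, ] <- sigma0 * pink_noise(n_eeg, config$eeg_rate)
    }
    class_sig <- vapply(classes, function(cl)
      delta_noise(n_eeg, config$eeg_rate), numeric(n_eeg))
    head_mag <- sqrt(colSums(accel[1, , ]^2))
    t_marg <- (seq_len(n_marg) - 1) / config$marg_rate
    t_eeg <- (seq_len(n_eeg) - 1) / config$eeg_rate
    head_mag_eeg <- stats::approx(t_marg, head_mag, xout = t_eeg,
                                  rule = 2)$y
    hm <- (head_mag_eeg - mean(head_mag_eeg)) / stats::sd(head_mag_eeg)
    for (i in seq_len(nrow(segs))) {
      cl <- class_of_seg[i]
      idx <- segment_samples(segs$start_s[i], segs$end_s[i],
                             config$eeg_rate, n_eeg)
      amp <- config$class_snr[[cl]] * sigma0
      if (amp > 0) {
        eeg[, idx] <- eeg[, idx] +
          amp * patterns[, cl] %o% class_sig[idx, cl]
      }
      kap <- config$artifact_coupling[[cl]]
      if (kap > 0) {
        eeg[, idx] <- eeg[, idx] +
          kap * sigma0 * artifact_pattern %o% hm[idx]
      }
    }
    list(eeg = eeg_recording(eeg, labels, config$eeg_rate),
         marg = marg, schedule = schedule)
  })
}

#' Per-sample class labels from an event schedule
#'
#' @param schedule An [event_schedule()].
#' @param rate Sampling rate (Hz) of the stream to label.
#' @param scheme `"effort"` (17 classes, all neutral segments collapsed)
#'   or `"action"` (neutral / think / do).
#' @param n_samples Number of samples to label; defaults to covering the
#'   last segment. Samples outside any segment are labeled `"unlabeled"`.
#' @return Character vector of length `n_samples`.
#' @export
schedule_to_labels <- function(schedule, rate, scheme = c("effort", "action"),
                               n_samples = NULL) {
  scheme <- match.arg(scheme)
  if (!inherits(schedule, "event_schedule")) {
    stop("schedule error: not an event_schedule", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("usage error: rate must be positive", call. = FALSE)
  }
  segs <- schedule$segments
  if (is.null(n_samples)) n_samples <- round(max(segs$end_s) * rate)
  labels <- rep("unlabeled", n_samples)
  for (i in seq_len(nrow(segs))) {
    idx <- segment_samples(segs$start_s[i], segs$end_s[i], rate, n_samples)
    labels[idx] <- if (scheme == "action") segs$action[i] else
      class_label(segs$action[i], segs$factor[i], segs$element[i])
  }
  labels
}
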