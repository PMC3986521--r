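# Core S3 containers shared by every module.

#' EEG recording container
#'
#' @param data Numeric matrix, channels x samples, microvolt scale.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param rate Sampling rate in Hz.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, rate) {
  data <- as.matrix(data)
  if (length(channel_labels) != nrow(data)) {
    stop("format error: ", length(channel_labels), " channel labels for ",
         nrow(data), " data rows", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("format error: duplicated channel label(s): ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("configuration error: rate must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("format error: EEG data contains non-finite values", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = as.character(channel_labels),
                 rate = rate),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Tri-axial accelerometry (MARG) recording container
#'
#' Gravity-compensated acceleration from a set of body-worn inertial
#' sensors. Stored as a 3-D array `sensors x 3 axes x samples` in m/s^2.
#'
#' @param accel Numeric array, sensors x 3 x samples.
#' @param sensor_roles Character vector naming each sensor's placement.
#' @param rate Sampling rate in Hz.
#' @return An object of class `marg_recording`.
#' @export
marg_recording <- function(accel, sensor_roles, rate) {
  if (length(dim(accel)) != 3 || dim(accel)[2] != 3) {
    stop("format error: accel must be a sensors x 3 x samples array",
         call. = FALSE)
  }
  if (length(sensor_roles) != dim(accel)[1]) {
    stop("format error: sensor_roles length does not match sensor count",
         call. = FALSE)
  }
  if (!all(is.finite(accel))) {
    stop("format error: acceleration contains non-finite values",
         call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("configuration error: rate must be a positive scalar", call. = FALSE)
  }
  dimnames(accel) <- list(sensor_roles, c("x", "y", "z"), NULL)
  structure(list(accel = accel, sensor_roles = as.character(sensor_roles),
                 rate = rate),
            class = "marg_recording")
}

#' @export
print.marg_recording <- function(x, ...) {
  cat(sprintf("<marg_recording> %d sensors x 3 axes x %d samples @ %g Hz\n",
              dim(x$accel)[1], dim(x$accel)[3], x$rate))
  invisible(x)
}

#' Event schedule of labeled condition segments
#'
#' Times are seconds from recording onset; each segment is the half-open
#' interval `[start_s, end_s)`. `action = "neutral"` segments carry
#' `factor = "none"` and `element = "none"`.
#'
#' @param segments `data.frame` with columns `start_s`, `end_s`, `action`,
#'   `factor`, `element`.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(segments) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "action", "factor", "element")
  if (!all(need %in% names(segments))) {
    stop("schedule error: missing column(s): ",
         paste(setdiff(need, names(segments)), collapse = ", "),
         call. = FALSE)
  }
  segments <- segments[need]
  if (nrow(segments)) {
    if (any(segments$end_s <= segments$start_s)) {
      stop("schedule error: segment with end_s <= start_s", call. = FALSE)
    }
    if (is.unsorted(segments$start_s)) {
      stop("schedule error: segments not sorted by start time", call. = FALSE)
    }
    if (any(segments$start_s[-1] < segments$end_s[-nrow(segments)] - 1e-12)) {
      stop("schedule error: overlapping segments", call. = FALSE)
    }
    bad_action <- !segments$action %in% c("neutral", "think", "do")
    if (any(bad_action)) {
      stop("schedule error: unknown action: ",
           paste(unique(segments$action[bad_action]), collapse = ", "),
           call. = FALSE)
    }
    neutral <- segments$action == "neutral"
    if (any(neutral & (segments$factor != "none" | segments$element != "none")) ||
        any(!neutral & (segments$factor == "none" | segments$element == "none"))) {
      stop("schedule error: action=neutral must pair with factor=none and ",
           "element=none (and only then)", call. = FALSE)
    }
  }
  structure(list(segments = segments), class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  n <- nrow(x$segments)
  cat(sprintf("<event_schedule> %d segments, %.1f s total\n", n,
              if (n) sum(x$segments$end_s - x$segments$start_s) else 0))
  invisible(x)
}

# Run a block of code under a fixed seed without disturbing the caller's
# RNG stream. Bit-identical re-runs for equal seeds.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629L)
}
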