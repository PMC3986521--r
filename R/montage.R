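#' @keywords internal
#' The 39 central channels retained after peripheral rejection, in a
#' roughly anterior-to-posterior scalp order, followed by the 25
#' peripheral channels. Ordering matters: montage_1020(n) takes the first
#' n labels, so small test montages are built from artifact-resistant
#' central sites.
.MONTAGE64 <- c(
  # retained (39)
  "Fz", "F1", "F2", "F3", "F4", "F5", "F6", "AF3", "AF4",
  "FC1", "FC2", "FC3", "FC4", "FC5", "FC6",
  "Cz", "C1", "C2", "C3", "C4", "C5", "C6",
  "CPz", "CP1", "CP2", "CP3", "CP4", "CP5", "CP6",
  "Pz", "P1", "P2", "P3", "P4", "P5", "P6",
  "POz", "PO3", "PO4",
  # peripheral (25), rejected by default
  "Fp1", "Fp2", "AF7", "AF8", "F7", "F8", "FT7", "FT8", "FT9", "FT10",
  "T7", "T8", "TP7", "TP8", "TP9", "TP10", "P7", "P8", "PO7", "PO8",
  "O1", "O2", "Oz", "PO9", "PO10"
)

#' Extended 10-20 montage labels
#'
#' Returns the first `n` labels of a 64-channel extended 10-20 montage
#' (FCz reference, AFz ground, so neither appears as a data channel).
#' The 39 channels that survive the default peripheral rejection come
#' first, so montages with `n < 64` consist of central sites only.
#'
#' @param n Number of channels (1--64).
#' @return Character vector of channel labels.
#' @export
#' @examples
#' montage_1020(4)
#' length(setdiff(montage_1020(64), peripheral_channels())) # 39
montage_1020 <- function(n = 64) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n > length(.MONTAGE64)) {
    stop("configuration error: n_eeg_channels must be between 1 and ",
         length(.MONTAGE64), call. = FALSE)
  }
  .MONTAGE64[seq_len(n)]
}

#' Default peripheral channel rejection list
#'
#' The 25 peripheral electrodes (frontal pole, anterior-frontal rim,
#' temporal chain, posterior rim and occiput) that are heavily corrupted
#' by motion and scalp-muscle artifact during whole-body movement and are
#' removed before feature construction.
#'
#' @return Character vector of 25 channel labels.
#' @export
peripheral_channels <- function() {
  c("Fp1", "Fp2", "AF7", "AF8", "F7", "F8", "FT7", "FT8", "FT9", "FT10",
    "T7", "T8", "TP7", "TP8", "TP9", "TP10", "P7", "P8", "PO7", "PO8",
    "O1", "O2", "Oz", "PO9", "PO10")
}

# Approximate 2-D scalp coordinates for plotting QC maps. Positions are
# parametric (row letter -> anterior/posterior, digit -> laterality), not
# digitised electrode locations; adequate for diagnostic maps only.
montage_positions <- function(labels) {
  rows <- c(Fp = 0.95, AF = 0.75, F = 0.55, FT = 0.35, FC = 0.35,
            T = 0, C = 0, TP = -0.35, CP = -0.35, P = -0.55,
            PO = -0.75, O = -0.95)
  pos <- t(vapply(labels, function(lb) {
    m <- regmatches(lb, regexec("^([A-Za-z]+)(z|[0-9]+)$", lb))[[1]]
    if (length(m) != 3) return(c(NA_real_, NA_real_))
    key <- toupper(m[2])
    key <- if (key == "FP") "Fp" else key
    y <- rows[[key]]
    if (m[3] == "z") x <- 0 else {
      d <- as.integer(m[3])
      side <- if (d %% 2 == 1) -1 else 1
      x <- side * min(1, ceiling(d / 2) / 5)
    }
    c(x, y)
  }, numeric(2)))
  data.frame(label = labels, x = pos[, 1], y = pos[, 2],
             stringsAsFactors = FALSE)
}
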