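# Readers and writers for the on-disk formats the pipeline touches:
# EEG as BrainVision triplets or headered CSV, accelerometry as CSV,
# schedules as TSV, configurations as YAML/JSON, and a report writer for
# run artifacts. CSV carries the sampling rate in a one-line sidecar
# header ("# rate_hz=..."), since plain CSV has no rate field.

.read_rate_header <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#\\s*rate_hz=([0-9.eE+-]+)", first))[[1]]
  if (length(m) != 2) {
    stop("format error: missing '# rate_hz=' header in ", path,
         call. = FALSE)
  }
  as.numeric(m[2])
}

#' Write an EEG recording
#'
#' `dialect = "csv"`: a `# rate_hz=` sidecar line, a header row of
#' channel labels, then one row per sample. `dialect = "brainvision"`:
#' a `.vhdr`/`.vmrk`/`.eeg` triplet (multiplexed IEEE float-32 binary,
#' microvolt units); `path` names the `.vhdr` file.
#'
#' @param eeg An [eeg_recording()].
#' @param path Output path.
#' @param dialect `"csv"` or `"brainvision"`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(eeg, path, dialect = c("csv", "brainvision")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(eeg, "eeg_recording"))
  if (dialect == "csv") {
    writeLines(sprintf("# rate_hz=%.10g", eeg$rate), path)
    dt <- data.table::as.data.table(t(eeg$data))
    data.table::setnames(dt, eeg$channel_labels)
    data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  } else {
    base <- sub("\\.vhdr$", "", path)
    vhdr <- paste0(base, ".vhdr")
    vmrk <- paste0(base, ".vmrk")
    dat <- paste0(base, ".eeg")
    nm <- basename(base)
    ch_lines <- sprintf("Ch%d=%s,,1,µV", seq_along(eeg$channel_labels),
                        eeg$channel_labels)
    writeLines(c(
      "Brain Vision Data Exchange Header File Version 1.0",
      "", "[Common Infos]", "Codepage=UTF-8",
      paste0("DataFile=", nm, ".eeg"),
      paste0("MarkerFile=", nm, ".vmrk"),
      "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
      paste0("NumberOfChannels=", length(eeg$channel_labels)),
      sprintf("SamplingInterval=%.10g", 1e6 / eeg$rate),
      "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
      "", "[Channel Infos]", ch_lines), vhdr)
    writeLines(c(
      "Brain Vision Data Exchange Marker File, Version 1.0",
      "", "[Common Infos]", "Codepage=UTF-8",
      paste0("DataFile=", nm, ".eeg"),
      "", "[Marker Infos]",
      "Mk1=New Segment,,1,1,0,0"), vmrk)
    con <- file(dat, "wb")
    on.exit(close(con))
    writeBin(as.numeric(eeg$data), con, size = 4)  # multiplexed: col-major
    path <- vhdr
  }
  invisible(path)
}

# Minimal INI-section parser for BrainVision headers.
.parse_vhdr <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln) && nchar(section)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Read an EEG recording
#'
#' @param path Path to a `.vhdr` header (BrainVision) or a headered CSV.
#' @param dialect `"brainvision"` or `"csv"`.
#' @return An [eeg_recording()]; channel labels are preserved verbatim
#'   and the rate is taken from the header (BrainVision) or the
#'   `# rate_hz=` sidecar line (CSV).
#' @export
read_eeg <- function(path, dialect = c("csv", "brainvision")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  if (dialect == "csv") {
    rate <- .read_rate_header(path)
    dt <- data.table::fread(path, skip = 1, header = TRUE)
    labels <- names(dt)
    return(eeg_recording(t(as.matrix(dt)), labels, rate))
  }
  hdr <- .parse_vhdr(readLines(path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) {
    stop("format error: no [Common Infos] section in ", path, call. = FALSE)
  }
  n_ch <- as.integer(ci$NumberOfChannels)
  rate <- 1e6 / as.numeric(ci$SamplingInterval)
  chinfo <- hdr[["Channel Infos"]]
  labels <- vapply(seq_len(n_ch), function(i) {
    entry <- chinfo[[paste0("Ch", i)]]
    if (is.null(entry)) {
      stop("format error: missing Ch", i, " in [Channel Infos]",
           call. = FALSE)
    }
    strsplit(entry, ",")[[1]][1]
  }, character(1))
  datafile <- file.path(dirname(path), ci$DataFile)
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  fmt <- toupper(ci$DataFormat %||% "BINARY")
  if (fmt == "BINARY") {
    binfmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||%
                        "IEEE_FLOAT_32")
    sz <- file.size(datafile)
    if (binfmt == "IEEE_FLOAT_32") {
      raw <- readBin(datafile, numeric(), n = sz / 4, size = 4)
    } else if (binfmt == "INT_16") {
      raw <- readBin(datafile, integer(), n = sz / 2, size = 2,
                     signed = TRUE)
    } else {
      stop("format error: unsupported BinaryFormat ", binfmt, call. = FALSE)
    }
    if (length(raw) %% n_ch != 0) {
      stop("format error: sample count not a multiple of channel count",
           call. = FALSE)
    }
    data <- if (orientation == "MULTIPLEXED") {
      matrix(raw, nrow = n_ch)
    } else {
      t(matrix(raw, ncol = n_ch))
    }
  } else if (fmt == "ASCII") {
    dt <- data.table::fread(datafile, header = FALSE)
    data <- if (orientation == "MULTIPLEXED") t(as.matrix(dt)) else
      as.matrix(dt)
    if (nrow(data) != n_ch && ncol(data) == n_ch) data <- t(data)
  } else {
    stop("format error: unsupported DataFormat ", fmt, call. = FALSE)
  }
  eeg_recording(data, labels, rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an event schedule (TSV)
#'
#' Tab-separated columns `start_s`, `end_s`, `action`, `factor`,
#' `element`; times are seconds, half-open `[start_s, end_s)`.
#'
#' @param schedule An [event_schedule()].
#' @param path File path.
#' @return `write_events`: `path` invisibly. `read_events`: an
#'   [event_schedule()] (malformed segment sets are schedule errors).
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  data.table::fwrite(schedule$segments, path, sep = "\t")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  event_schedule(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Write / read tri-axial accelerometry (CSV)
#'
#' A `# rate_hz=` sidecar line, then one column per sensor-axis pair
#' (named `<role>.<axis>`) and one row per sample, gravity-compensated
#' acceleration in m/s^2.
#'
#' @param marg A [marg_recording()].
#' @param path File path.
#' @return `write_kinematics`: `path` invisibly; `read_kinematics`: a
#'   [marg_recording()].
#' @export
write_kinematics <- function(marg, path) {
  stopifnot(inherits(marg, "marg_recording"))
  n_sens <- dim(marg$accel)[1]
  cols <- list()
  for (s in seq_len(n_sens)) {
    for (a in 1:3) {
      cols[[paste0(marg$sensor_roles[s], ".", c("x", "y", "z")[a])]] <-
        marg$accel[s, a, ]
    }
  }
  writeLines(sprintf("# rate_hz=%.10g", marg$rate), path)
  data.table::fwrite(data.table::as.data.table(cols), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_kinematics
#' @export
read_kinematics <- function(path) {
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  rate <- .read_rate_header(path)
  dt <- data.table::fread(path, skip = 1, header = TRUE)
  parts <- strsplit(names(dt), ".", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("format error: kinematics columns must be named <role>.<axis>",
         call. = FALSE)
  }
  roles <- unique(vapply(parts, `[`, "", 1))
  accel <- array(0, dim = c(length(roles), 3, nrow(dt)))
  for (s in seq_along(roles)) {
    for (a in 1:3) {
      col <- paste0(roles[s], ".", c("x", "y", "z")[a])
      if (!col %in% names(dt)) {
        stop("format error: missing column ", col, call. = FALSE)
      }
      accel[s, a, ] <- dt[[col]]
    }
  }
  marg_recording(accel, roles, rate)
}

#' Write / read a session configuration (YAML or JSON)
#'
#' Format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config A [session_config()].
#' @param path File path.
#' @return `write_config`: `path` invisibly; `read_config`: a validated
#'   [session_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  lst <- unclass(config)
  lst$effort_sequence <- as.list(lst$effort_sequence)
  lst$class_snr <- as.list(lst$class_snr)
  lst$artifact_coupling <- as.list(lst$artifact_coupling)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  lst$effort_sequence <- as.data.frame(lst$effort_sequence,
                                       stringsAsFactors = FALSE)
  lst$class_snr <- unlist(lst$class_snr)
  lst$artifact_coupling <- unlist(lst$artifact_coupling)
  do.call(session_config, lst)
}

#' Write a run report
#'
#' Persists evaluation artifacts under a directory: confusion matrices
#' (counts and row-normalized CSV), per-class metrics (CSV), QC maps
#' (CSV plus PNG figures), per-iteration accuracies, and a JSON run
#' manifest recording the configuration and seed.
#'
#' @param results Named list; recognized elements are `cv` (a
#'   `cv_result`), `metrics` (from [class_metrics()]), `qc` (a
#'   `qc_maps`), `config` (a [session_config()]) and `seed`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(x, name) {
    p <- file.path(dir, name)
    data.table::fwrite(data.table::as.data.table(x, keep.rownames = "class"),
                       p)
    written <<- c(written, p)
  }
  if (!is.null(results$cv)) {
    put(results$cv$confusion$counts, "confusion_counts.csv")
    put(results$cv$confusion$normalized, "confusion_normalized.csv")
    put(data.frame(iteration = seq_along(results$cv$accuracies),
                   accuracy = results$cv$accuracies),
        "cv_accuracies.csv")
    p <- file.path(dir, "confusion.png")
    grDevices::png(p, width = 800, height = 700)
    cm <- results$cv$confusion
    graphics::image(seq_along(cm$classes), seq_along(cm$classes),
                    t(cm$normalized[rev(seq_along(cm$classes)), ]),
                    axes = FALSE, xlab = "predicted", ylab = "actual",
                    main = "Row-normalized confusion (%)")
    graphics::axis(1, seq_along(cm$classes), cm$classes, las = 2,
                   cex.axis = 0.7)
    graphics::axis(2, seq_along(cm$classes), rev(cm$classes), las = 2,
                   cex.axis = 0.7)
    grDevices::dev.off()
    written <- c(written, p)
  }
  if (!is.null(results$metrics)) put(results$metrics, "class_metrics.csv")
  if (!is.null(results$qc)) {
    put(results$qc$rho, "qc_rho.csv")
    put(results$qc$rho2, "qc_rho2.csv")
    put(data.frame(pc = seq_along(results$qc$pca$var_frac),
                   var_frac = results$qc$pca$var_frac),
        "qc_pc_variance.csv")
    p <- file.path(dir, "qc_scalp_rho2.png")
    grDevices::png(p, width = 900, height = 700)
    pos <- montage_positions(rownames(results$qc$rho))
    med <- apply(results$qc$rho2, 1, stats::median)
    sc <- (med - min(med)) / max(1e-12, diff(range(med)))
    graphics::plot(pos$x, pos$y, cex = 1 + 4 * sc,
                   pch = 21, bg = grDevices::gray(1 - sc), xlab = "",
                   ylab = "", main = "Median rho^2 by channel",
                   axes = FALSE, asp = 1)
    graphics::text(pos$x, pos$y - 0.07, pos$label, cex = 0.6)
    grDevices::dev.off()
    written <- c(written, p)
  }
  manifest <- list(
    package = "mobidecode",
    seed = results$seed %||% results$config$seed %||% NA,
    config = if (!is.null(results$config)) {
      lst <- unclass(results$config)
      lst$effort_sequence <- as.list(lst$effort_sequence)
      lst
    },
    cv_params = if (!is.null(results$cv)) results$cv$params,
    written = basename(written)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  written <- c(written, mp)
  invisible(written)
}
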