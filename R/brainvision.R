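# BrainVision (.vhdr/.vmrk/.eeg) reader and writer.
#
# Implements the vendor triple: INI-style header, text marker file, and
# IEEE_FLOAT_32 multiplexed little-endian binary data in microvolts. Event
# rows round-trip through Stimulus marker descriptions of the form
# "phase:side:condition:trial".

#' Write a recording as a BrainVision triple
#'
#' @param rec An [eeg_recording()].
#' @param path Base path or `.vhdr` path; `.vhdr`, `.vmrk` and `.eeg` files
#'   are written next to each other.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- sub("\\.vhdr$", "", path)
  stem <- basename(base)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")

  nch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    paste0("Ch", seq_len(nch), "=", rownames(rec$data), ",,1,µV"))
  if (!is.null(rec$channel_positions)) {
    p <- rec$channel_positions
    r <- sqrt(rowSums(p^2))
    theta <- acos(pmin(pmax(p[, 3] / r, -1), 1)) * 180 / pi
    phi <- atan2(p[, 2], p[, 1]) * 180 / pi
    hdr <- c(hdr, "", "[Coordinates]",
             sprintf("Ch%d=%.6f,%.6f,%.6f", seq_len(nch), r, theta, phi))
  }
  writeLines(hdr, vhdr)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    paste0("Mk1=New Segment,,1,1,0,0"))
  if (!is.null(rec$events) && nrow(rec$events) > 0) {
    ev <- rec$events
    desc <- paste(ev$phase, ev$side %||% "", ev$condition %||% "",
                  ev$trial %||% "", sep = ":")
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(ev)) + 1L, desc, ev$sample))
  }
  writeLines(mk, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(vhdr)
}

parse_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && section != "") {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Read a BrainVision triple into a recording
#'
#' Supports the subset of the format this package writes: multiplexed
#' IEEE_FLOAT_32 or INT_16 binary data, text markers, optional spherical
#' coordinates.
#'
#' @param path Path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("header file not found: ", path),
                        class = c("freqtag_format", "error")))
  ini <- parse_ini(readLines(path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci) || is.null(ci$DataFile) || is.null(ci$NumberOfChannels))
    stop(errorCondition("header lacks [Common Infos] DataFile/NumberOfChannels",
                        class = c("freqtag_format", "error")))
  if (!identical(ci$DataOrientation %||% "MULTIPLEXED", "MULTIPLEXED"))
    stop(errorCondition("only MULTIPLEXED orientation is supported",
                        class = c("freqtag_format", "error")))
  dir <- dirname(path)
  eeg <- file.path(dir, ci$DataFile)
  vmrk <- if (!is.null(ci$MarkerFile)) file.path(dir, ci$MarkerFile)
  if (!file.exists(eeg))
    stop(errorCondition(paste0("data file not found: ", eeg),
                        class = c("freqtag_format", "error")))

  nch <- as.integer(ci$NumberOfChannels)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)
  chinfo <- ini[["Channel Infos"]]
  labels <- vapply(seq_len(nch), function(i) {
    v <- chinfo[[paste0("Ch", i)]] %||% paste0("Ch", i)
    strsplit(v, ",")[[1]][1]
  }, character(1))
  res <- vapply(seq_len(nch), function(i) {
    v <- chinfo[[paste0("Ch", i)]]
    if (is.null(v)) return(1)
    parts <- strsplit(v, ",")[[1]]
    if (length(parts) >= 3 && nzchar(parts[3])) as.numeric(parts[3]) else 1
  }, numeric(1))

  fmt <- bi$BinaryFormat %||% "IEEE_FLOAT_32"
  sz <- file.size(eeg)
  con <- file(eeg, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    n_val <- sz %/% 4L
    raw <- readBin(con, numeric(), n = n_val, size = 4L, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    n_val <- sz %/% 2L
    raw <- readBin(con, integer(), n = n_val, size = 2L, endian = "little")
    raw <- raw * rep(res, length.out = length(raw))
  } else {
    stop(errorCondition(paste0("unsupported BinaryFormat: ", fmt),
                        class = c("freqtag_format", "error")))
  }
  n_samp <- length(raw) %/% nch
  data <- matrix(raw[seq_len(n_samp * nch)], nrow = nch)
  rownames(data) <- labels

  positions <- NULL
  if (!is.null(ini[["Coordinates"]])) {
    co <- ini[["Coordinates"]]
    positions <- t(vapply(seq_len(nch), function(i) {
      v <- as.numeric(strsplit(co[[paste0("Ch", i)]], ",")[[1]])
      r <- v[1]; th <- v[2] * pi / 180; ph <- v[3] * pi / 180
      c(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
    }, numeric(3)))
    colnames(positions) <- c("x", "y", "z")
  }

  events <- NULL
  if (!is.null(vmrk)) {
    if (!file.exists(vmrk))
      stop(errorCondition(paste0("marker file not found: ", vmrk),
                          class = c("freqtag_format", "error")))
    mi <- parse_ini(readLines(vmrk, warn = FALSE))[["Marker Infos"]]
    if (!is.null(mi)) {
      rows <- lapply(mi, function(v) {
        parts <- strsplit(v, ",")[[1]]
        if (length(parts) < 3 || parts[1] != "Stimulus") return(NULL)
        d <- strsplit(parts[2], ":")[[1]]
        data.frame(sample = as.integer(parts[3]),
                   phase = d[1] %||% NA_character_,
                   side = if (length(d) > 1 && nzchar(d[2])) d[2] else NA,
                   condition = if (length(d) > 2 && nzchar(d[3])) d[3] else NA,
                   trial = if (length(d) > 3) as.integer(d[4]) else NA)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) events <- do.call(rbind, rows)
    }
  }

  eeg_recording(data, sfreq = sfreq, channel_labels = labels,
                channel_positions = positions, events = events)
}
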