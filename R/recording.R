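# Continuous-recording container and file readers/writers.
#
# Two on-disk forms are supported: the BrainVision Core triplet
# (.vhdr/.vmrk/.eeg) and a plain interchange format used by the synthetic
# generator (delimited channels x samples matrix + JSON sidecar + events TSV).

#' Construct a continuous EEG recording
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param rate Sampling rate in Hz (default 500).
#' @param channel_labels Character vector of unique 10-20 channel names,
#'   one per row of `data`.
#' @param events Data frame with columns `sample` (1-based sample index of
#'   stimulus onset) and `label` (condition string), or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate = 500, channel_labels = rownames(data),
                          events = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop_docnet("montage", "channel_labels length (%d) != number of rows (%d)",
                length(channel_labels), nrow(data))
  }
  if (anyDuplicated(channel_labels)) {
    stop_docnet("montage", "channel labels must be unique")
  }
  if (is.null(events)) {
    events <- data.frame(sample = integer(), label = character(),
                         stringsAsFactors = FALSE)
  }
  events$sample <- as.integer(events$sample)
  if (nrow(events) && (any(events$sample < 1L) || any(events$sample > ncol(data)))) {
    stop_docnet("data", "event sample indices must lie within the recording")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, rate = rate, channel_labels = channel_labels,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}

#' Write a recording in the plain interchange format
#'
#' Writes `<stem>_data.tsv` (channels x samples, tab-delimited, no header),
#' `<stem>.json` (rate and channel labels) and `<stem>_events.tsv`
#' (`sample`, `label`).
#'
#' @param rec An `eeg_recording`.
#' @param stem Path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_recording_plain <- function(rec, stem) {
  data.table::fwrite(data.table::as.data.table(rec$data), paste0(stem, "_data.tsv"),
                     sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(rate = rec$rate, channel_labels = rec$channel_labels, format = "docnet-plain-v1"),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.table(rec$events, paste0(stem, "_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' Read a recording in the plain interchange format
#'
#' @param stem Path stem used by [write_recording_plain()].
#' @return An `eeg_recording`.
#' @export
read_recording_plain <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dat <- as.matrix(data.table::fread(paste0(stem, "_data.tsv"), sep = "\t",
                                     header = FALSE))
  dimnames(dat) <- NULL
  ev_path <- paste0(stem, "_events.tsv")
  events <- if (file.exists(ev_path)) {
    utils::read.delim(ev_path, stringsAsFactors = FALSE)
  } else NULL
  eeg_recording(dat, rate = meta$rate, channel_labels = meta$channel_labels,
                events = events)
}

# Parse one INI-style BrainVision section into a named character vector.
parse_vhdr_ini <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      sections[[current]] <- character()
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      sections[[current]][key] <- val
    }
  }
  sections
}

#' Read a BrainVision Core Data Format recording
#'
#' Supports binary multiplexed data in `IEEE_FLOAT_32` or `INT_16` with
#' per-channel resolution scaling, and stimulus markers from the `.vmrk`
#' file. Vectorized (non-multiplexed) layouts are also handled.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An `eeg_recording` (microvolts; marker positions become `events`).
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop_docnet("io", "header not found: %s", vhdr_path)
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  ini <- parse_vhdr_ini(lines)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci)) stop_docnet("io", "missing [Common Infos] section")
  if (!identical(ci[["DataFormat"]], "BINARY")) {
    stop_docnet("io", "only BINARY DataFormat is supported")
  }
  orientation <- ci[["DataOrientation"]] %||% "MULTIPLEXED"
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  # SamplingInterval is in microseconds
  rate <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  fmt <- bi[["BinaryFormat"]] %||% "IEEE_FLOAT_32"

  chans <- ini[["Channel Infos"]]
  labels <- character(n_ch)
  resolution <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    entry <- chans[[paste0("Ch", i)]]
    if (is.null(entry) || is.na(entry)) {
      labels[i] <- paste0("Ch", i)
    } else {
      parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
      labels[i] <- trimws(parts[1])
      if (length(parts) >= 3 && nzchar(trimws(parts[3]))) {
        resolution[i] <- as.numeric(parts[3])
      }
    }
  }

  dir <- dirname(vhdr_path)
  eeg_file <- file.path(dir, ci[["DataFile"]])
  size <- file.info(eeg_file)$size
  raw_vals <- switch(
    fmt,
    IEEE_FLOAT_32 = readBin(eeg_file, "double", n = size / 4, size = 4, endian = "little"),
    INT_16 = readBin(eeg_file, "integer", n = size / 2, size = 2, signed = TRUE,
                     endian = "little"),
    stop_docnet("io", "unsupported BinaryFormat: %s", fmt)
  )
  n_samp <- length(raw_vals) %/% n_ch
  raw_vals <- raw_vals[seq_len(n_samp * n_ch)]
  dat <- if (toupper(orientation) == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_ch)            # channels fastest
  } else {
    t(matrix(raw_vals, nrow = n_samp))       # VECTORIZED: one channel at a time
  }
  dat <- dat * resolution

  events <- NULL
  if (!is.null(ci[["MarkerFile"]]) && !is.na(ci[["MarkerFile"]])) {
    vmrk <- file.path(dir, ci[["MarkerFile"]])
    if (file.exists(vmrk)) {
      mk <- parse_vhdr_ini(readLines(vmrk, warn = FALSE, encoding = "UTF-8"))
      mks <- mk[["Marker Infos"]]
      if (!is.null(mks)) {
        rows <- lapply(mks, function(entry) {
          parts <- trimws(strsplit(entry, ",", fixed = TRUE)[[1]])
          if (length(parts) < 3 || parts[1] != "Stimulus") return(NULL)
          data.frame(sample = as.integer(parts[3]), label = parts[2],
                     stringsAsFactors = FALSE)
        })
        rows <- rows[!vapply(rows, is.null, TRUE)]
        if (length(rows)) events <- do.call(rbind, rows)
      }
    }
  }
  eeg_recording(dat, rate = rate, channel_labels = labels, events = events)
}
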