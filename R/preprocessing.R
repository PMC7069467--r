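# Preprocessing: band-pass filtering, re-referencing, epoching, baseline
# correction, amplitude-based trial rejection and montage subsetting.

#' Default 27-channel analysis montage
#'
#' A symmetric 10-20 subset covering frontal, central, temporal, parietal and
#' occipital sites, used by the time-varying network analysis to limit the
#' impact of volume conduction.
#'
#' @return Character vector of 27 channel labels.
#' @export
default_montage27 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "O2")
}

#' Construct an epoch set
#'
#' @param data Numeric array trials x channels x samples, microvolts.
#' @param window_ms Length-2 numeric, epoch window in ms relative to stimulus
#'   onset (half-open: `[start, end)` on the sample grid).
#' @param rate Sampling rate, Hz.
#' @param condition Per-trial condition label, `"standard"` or `"deviant"`.
#' @param channel_labels Channel names (length = dim 2).
#' @param stimulus Optional per-trial raw stimulus label (e.g. happy/sad).
#' @param baseline_window Baseline window in ms once [baseline_correct()] has
#'   been applied, else `NULL`.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, window_ms, rate, condition, channel_labels,
                       stimulus = NULL, baseline_window = NULL) {
  stopifnot(length(dim(data)) == 3L)
  n_expected <- ms_to_samples(window_ms[2] - window_ms[1], rate)
  if (dim(data)[3] != n_expected) {
    stop_docnet("data", "epoch has %d samples; window %g..%g ms at %g Hz needs %d",
                dim(data)[3], window_ms[1], window_ms[2], rate, n_expected)
  }
  if (length(condition) != dim(data)[1]) {
    stop_docnet("data", "one condition label per trial required")
  }
  if (length(channel_labels) != dim(data)[2]) {
    stop_docnet("montage", "one channel label per channel required")
  }
  structure(list(data = data, window_ms = as.numeric(window_ms), rate = rate,
                 condition = as.character(condition),
                 stimulus = if (is.null(stimulus)) as.character(condition) else as.character(stimulus),
                 channel_labels = channel_labels,
                 baseline_window = baseline_window),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz [%g, %g) ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate,
              x$window_ms[1], x$window_ms[2]))
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of an epoch set
#'
#' @param ep An `eeg_epochs` object.
#' @return Numeric vector of sample times in ms relative to stimulus onset.
#' @export
epoch_times_ms <- function(ep) {
  n <- dim(ep$data)[3]
  ep$window_ms[1] + (seq_len(n) - 1) * 1000 / ep$rate
}

#' Zero-lag FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase band-pass, applied by FFT convolution
#' with group-delay compensation so the output is zero-lag. The filter order
#' is chosen from the narrower transition band (Hamming transition width is
#' approximately 3.3 / order in normalized frequency).
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < rate/2`.
#' @param transition_hz Length-2 transition widths at the low and high edge
#'   (defaults 0.1 and 7.5 Hz).
#' @return A filtered `eeg_recording`.
#' @export
bandpass_fir <- function(rec, low_hz = 0.1, high_hz = 30,
                         transition_hz = c(0.1, 7.5)) {
  nyq <- rec$rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop_docnet("parameter", "band (%g, %g) must satisfy 0 < low < high < %g",
                low_hz, high_hz, nyq)
  }
  ord <- ceiling(3.3 * rec$rate / min(transition_hz))
  if (ord %% 2 == 1) ord <- ord + 1          # even order -> integer group delay
  b <- signal::fir1(ord, c(low_hz, high_hz) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1, fir_apply_zero_lag, b = b))
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' FIR notch (band-stop) filter
#'
#' Available for recordings whose mains interference was not removed at
#' acquisition; not applied by default anywhere in the pipeline.
#'
#' @param rec An `eeg_recording`.
#' @param center_hz Center of the stop band (default 50 Hz).
#' @param width_hz Stop-band width (default 4 Hz).
#' @return A filtered `eeg_recording`.
#' @export
notch_fir <- function(rec, center_hz = 50, width_hz = 4) {
  nyq <- rec$rate / 2
  lo <- center_hz - width_hz / 2
  hi <- center_hz + width_hz / 2
  if (lo <= 0 || hi >= nyq) stop_docnet("parameter", "notch band outside (0, Nyquist)")
  ord <- ceiling(3.3 * rec$rate / 1)
  if (ord %% 2 == 1) ord <- ord + 1
  b <- signal::fir1(ord, c(lo, hi) / nyq, type = "stop")
  rec$data <- t(apply(rec$data, 1, fir_apply_zero_lag, b = b))
  rownames(rec$data) <- rec$channel_labels
  rec
}

# Full FFT convolution then removal of the (order/2)-sample group delay.
fir_apply_zero_lag <- function(x, b) {
  n <- length(x)
  delay <- (length(b) - 1) / 2
  y <- stats::convolve(c(x, numeric(length(b) - 1)), rev(b), type = "open")
  y[(delay + 1):(delay + n)]
}

#' Re-reference to the average of reference channels
#'
#' Subtracts the instantaneous mean of the reference channels (default: the
#' bilateral mastoids TP9 and TP10) from every channel.
#'
#' @param rec An `eeg_recording`.
#' @param ref_labels Reference channel labels present in the montage.
#' @return A re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, ref_labels = c("TP9", "TP10")) {
  miss <- setdiff(ref_labels, rec$channel_labels)
  if (length(miss)) {
    stop_docnet("montage", "reference channel(s) not in montage: %s",
                paste(miss, collapse = ", "))
  }
  ref <- colMeans(rec$data[ref_labels, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref, "-")
  rec
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' One trial per event on a half-open sample grid `[start, end)`, so a
#' -200..1000 ms window at 500 Hz yields 600 samples with stimulus onset at
#' 0-based index 100. Events whose window does not fit inside the recording
#' are dropped with a warning.
#'
#' Event labels `happy` and `sad` are classed as `deviant`; `standard` stays
#' `standard`; the raw label is kept in `$stimulus`.
#'
#' @param rec An `eeg_recording` with events.
#' @param window_ms Epoch window in ms relative to onset, default `c(-200, 1000)`.
#' @return An `eeg_epochs` object.
#' @export
epoch <- function(rec, window_ms = c(-200, 1000)) {
  if (nrow(rec$events) == 0L) stop_docnet("data", "recording has no events")
  off0 <- ms_to_samples(window_ms[1], rec$rate)
  n_samp <- ms_to_samples(window_ms[2] - window_ms[1], rec$rate)
  first <- rec$events$sample + off0
  ok <- first >= 1L & (first + n_samp - 1L) <= ncol(rec$data)
  if (any(!ok)) {
    warn_docnet("dropped %d event(s) whose epoch window falls outside the recording",
                sum(!ok))
  }
  ev <- rec$events[ok, , drop = FALSE]
  if (nrow(ev) == 0L) stop_docnet("data", "no event window fits inside the recording")
  dat <- array(0, dim = c(nrow(ev), nrow(rec$data), n_samp))
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$sample[i] + off0):(ev$sample[i] + off0 + n_samp - 1L)
    dat[i, , ] <- rec$data[, idx]
  }
  condition <- ifelse(ev$label %in% c("happy", "sad", "deviant"), "deviant",
                      "standard")
  eeg_epochs(dat, window_ms = window_ms, rate = rec$rate, condition = condition,
             channel_labels = rec$channel_labels, stimulus = ev$label)
}

#' Baseline-correct all trials
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (default -200..0 ms).
#'
#' @param ep An `eeg_epochs` object.
#' @param baseline_ms Baseline window in ms, inside the epoch window.
#' @return A baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(ep, baseline_ms = c(-200, 0)) {
  t_ms <- epoch_times_ms(ep)
  idx <- which(t_ms >= baseline_ms[1] & t_ms < baseline_ms[2])
  if (length(idx) == 0L) stop_docnet("parameter", "empty baseline window")
  if (baseline_ms[1] < ep$window_ms[1] || baseline_ms[2] > ep$window_ms[2]) {
    stop_docnet("parameter", "baseline window must lie inside the epoch window")
  }
  bl <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(bl, dim = dim(ep$data))  # bl recycles over samples
  ep$baseline_window <- baseline_ms
  ep
}

#' Reject high-amplitude trials
#'
#' Per-trial statistic: maximum absolute voltage over channels and samples
#' (`"absmax"`, default) or maximum per-channel peak-to-peak range (`"ptp"`).
#' Trials whose statistic strictly exceeds mean + `k` * SD (mean and SD taken
#' across trials) are removed. With zero across-trial SD the threshold equals
#' the mean and ties are kept.
#'
#' @param ep An `eeg_epochs` with at least 3 trials.
#' @param k SD multiplier (default 3; `Inf` disables rejection).
#' @param statistic `"absmax"` or `"ptp"`.
#' @return A list with `epochs` (the retained trials) and `log`, a data frame
#'   with per-trial `statistic`, `threshold` and `rejected`.
#' @export
reject_amplitude <- function(ep, k = 3, statistic = c("absmax", "ptp")) {
  statistic <- match.arg(statistic)
  n_tr <- dim(ep$data)[1]
  if (n_tr < 3L) stop_docnet("parameter", "need at least 3 trials for rejection")
  stat <- vapply(seq_len(n_tr), function(i) {
    x <- matrix(ep$data[i, , ], nrow = dim(ep$data)[2])
    if (statistic == "absmax") max(abs(x))
    else max(apply(x, 1, function(ch) diff(range(ch))))
  }, numeric(1))
  thr <- if (is.infinite(k)) Inf else mean(stat) + k * stats::sd(stat)
  rejected <- stat > thr
  if (all(rejected)) stop_docnet("pipeline", "amplitude rejection removed every trial")
  log <- data.frame(trial = seq_len(n_tr), statistic = stat, threshold = thr,
                    rejected = rejected)
  ep$data <- ep$data[!rejected, , , drop = FALSE]
  ep$condition <- ep$condition[!rejected]
  ep$stimulus <- ep$stimulus[!rejected]
  list(epochs = ep, log = log)
}

#' Subset and reorder channels
#'
#' @param ep An `eeg_epochs` object.
#' @param montage_subset Unique channel labels to keep, in the desired order
#'   (default: [default_montage27()]).
#' @return An `eeg_epochs` with the reduced channel axis.
#' @export
select_channels <- function(ep, montage_subset = default_montage27()) {
  if (anyDuplicated(montage_subset)) {
    stop_docnet("parameter", "duplicate label in channel subset")
  }
  miss <- setdiff(montage_subset, ep$channel_labels)
  if (length(miss)) {
    stop_docnet("montage", "channel(s) not in montage: %s",
                paste(miss, collapse = ", "))
  }
  idx <- match(montage_subset, ep$channel_labels)
  ep$data <- ep$data[, idx, , drop = FALSE]
  ep$channel_labels <- montage_subset
  ep
}

#' Subset an epoch set by trial index or condition
#'
#' @param ep An `eeg_epochs` object.
#' @param trials Integer trial indices, or a condition label such as
#'   `"deviant"`.
#' @return An `eeg_epochs` with the selected trials.
#' @export
subset_trials <- function(ep, trials) {
  if (is.character(trials)) trials <- which(ep$condition %in% trials)
  if (length(trials) == 0L) stop_docnet("selection", "no matching trials")
  ep$data <- ep$data[trials, , , drop = FALSE]
  ep$condition <- ep$condition[trials]
  ep$stimulus <- ep$stimulus[trials]
  ep
}

#' Write an epoch set in the plain interchange format
#'
#' Writes `<stem>_epochs.tsv` ((trial x channel) rows by samples, tab
#' delimited), `<stem>.json` (dimensions, window, rate, labels) and
#' `<stem>_trials.tsv` (per-trial condition and stimulus).
#'
#' @param ep An `eeg_epochs`.
#' @param stem Path stem.
#' @return `stem`, invisibly.
#' @export
write_epochs_plain <- function(ep, stem) {
  d <- dim(ep$data)
  flat <- matrix(aperm(ep$data, c(2, 1, 3)), nrow = d[1] * d[2])  # trial-major rows
  data.table::fwrite(data.table::as.data.table(flat), paste0(stem, "_epochs.tsv"),
                     sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
         window_ms = ep$window_ms, rate = ep$rate,
         channel_labels = ep$channel_labels,
         baseline_window = ep$baseline_window, format = "docnet-epochs-v1"),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.table(
    data.frame(trial = seq_len(d[1]), condition = ep$condition,
               stimulus = ep$stimulus),
    paste0(stem, "_trials.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(stem)
}

#' Read an epoch set written by [write_epochs_plain()]
#'
#' @param stem Path stem.
#' @return An `eeg_epochs`.
#' @export
read_epochs_plain <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(paste0(stem, "_epochs.tsv"), sep = "\t",
                                      header = FALSE))
  tr <- utils::read.delim(paste0(stem, "_trials.tsv"), stringsAsFactors = FALSE)
  dat <- aperm(array(flat, dim = c(meta$n_channels, meta$n_trials, meta$n_samples)),
               c(2, 1, 3))
  eeg_epochs(dat, window_ms = meta$window_ms, rate = meta$rate,
             condition = tr$condition, channel_labels = meta$channel_labels,
             stimulus = tr$stimulus,
             baseline_window = meta$baseline_window)
}
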