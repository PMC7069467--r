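# ERP condition averaging, component measurement (N1, P3a, LPP) and
# time-point-wise mass-univariate t-tests with FDR control.

#' Average trials of one condition into an ERP waveform
#'
#' @param ep An `eeg_epochs` object.
#' @param condition Condition label to average (e.g. `"deviant"`).
#' @return An `erp_waveform`: `data` (channels x samples, microvolts), the
#'   epoch window/rate, the condition, and `n_trials_averaged`.
#' @export
average_erp <- function(ep, condition) {
  idx <- which(ep$condition == condition)
  if (length(idx) == 0L) stop_docnet("selection", "no trials with condition '%s'", condition)
  dat <- apply(ep$data[idx, , , drop = FALSE], c(2, 3), mean)
  rownames(dat) <- ep$channel_labels
  structure(list(data = dat, rate = ep$rate, window_ms = ep$window_ms,
                 condition = condition, n_trials_averaged = length(idx),
                 channel_labels = ep$channel_labels),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> '%s': %d channels x %d samples (%d trials averaged)\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials_averaged))
  invisible(x)
}

erp_times_ms <- function(erp) {
  erp$window_ms[1] + (seq_len(ncol(erp$data)) - 1) * 1000 / erp$rate
}

#' Default ERP component definitions
#'
#' N1: 100-200 ms at Fz, negative (early auditory sensory processing).
#' P3a: 250-350 ms at Fz, positive (involuntary attention orienting).
#' LPP: 400-1000 ms over a centroparietal set, positive (sustained
#' emotional/cognitive elaboration).
#'
#' @return Named list of component definitions (`name`, `window_ms`,
#'   `electrodes`, `polarity`).
#' @export
erp_components <- function() {
  list(
    N1 = list(name = "N1", window_ms = c(100, 200), electrodes = "Fz",
              polarity = "negative"),
    P3a = list(name = "P3a", window_ms = c(250, 350), electrodes = "Fz",
               polarity = "positive"),
    LPP = list(name = "LPP", window_ms = c(400, 1000),
               electrodes = c("CP5", "CP1", "CP2", "CP6", "P3", "Pz", "P4"),
               polarity = "positive")
  )
}

#' Measure a component amplitude
#'
#' Mean amplitude (signed, microvolts) over the component window, averaged
#' over the component's electrodes. Polarity is reporting metadata only.
#'
#' @param erp An `erp_waveform`.
#' @param comp A component definition as in [erp_components()].
#' @return Mean amplitude in microvolts.
#' @export
measure_component <- function(erp, comp) {
  miss <- setdiff(comp$electrodes, erp$channel_labels)
  if (length(miss)) {
    stop_docnet("montage", "component electrode(s) not in montage: %s",
                paste(miss, collapse = ", "))
  }
  t_ms <- erp_times_ms(erp)
  if (comp$window_ms[1] < erp$window_ms[1] || comp$window_ms[2] > erp$window_ms[2]) {
    stop_docnet("parameter", "component window outside the ERP window")
  }
  tidx <- which(t_ms >= comp$window_ms[1] & t_ms <= comp$window_ms[2])
  mean(erp$data[match(comp$electrodes, erp$channel_labels), tidx, drop = FALSE])
}

# Stack a list of per-subject erp_waveforms into subjects x channels x samples.
stack_erps <- function(erps) {
  if (is.array(erps) && length(dim(erps)) == 3L) return(erps)
  arr <- array(0, dim = c(length(erps), nrow(erps[[1]]$data), ncol(erps[[1]]$data)))
  for (i in seq_along(erps)) arr[i, , ] <- erps[[i]]$data
  attr(arr, "channel_labels") <- erps[[1]]$channel_labels
  attr(arr, "window_ms") <- erps[[1]]$window_ms
  attr(arr, "rate") <- erps[[1]]$rate
  arr
}

#' Mass-univariate t-tests across channels and time
#'
#' A two-tailed t-test at every channel and time point inside the test
#' window, across subjects: paired (within-subject differences) or unpaired
#' (Welch). Points with zero variance yield `t = 0`, `p = 1` with a warning.
#' Benjamini-Hochberg FDR control is applied jointly over all tested points
#' (channels x time pooled).
#'
#' @param a,b Lists of per-subject `erp_waveform`s (matched order when
#'   paired), or 3-d arrays subjects x channels x samples.
#' @param paired If `TRUE`, test within-subject differences (`a[i] - b[i]`).
#' @param window_ms Test window relative to onset, default `c(0, 1000)`.
#' @param q FDR level for the significance mask, default 0.05.
#' @param rate,window_epoch_ms,channel_labels Metadata when `a`/`b` are bare
#'   arrays; taken from the waveforms otherwise.
#' @return A `mass_univariate_result`: `t`, `p` and logical `fdr_mask`
#'   matrices (channels x tested samples), `times_ms`, `q`, and the number of
#'   zero-variance points.
#' @export
mass_univariate_ttest <- function(a, b, paired = FALSE, window_ms = c(0, 1000),
                                  q = 0.05, rate = NULL, window_epoch_ms = NULL,
                                  channel_labels = NULL) {
  A <- stack_erps(a)
  B <- stack_erps(b)
  rate <- rate %||% attr(A, "rate")
  window_epoch_ms <- window_epoch_ms %||% attr(A, "window_ms")
  channel_labels <- channel_labels %||% attr(A, "channel_labels")
  if (is.null(rate) || is.null(window_epoch_ms)) {
    stop_docnet("parameter", "rate and epoch window metadata required for bare arrays")
  }
  if (!identical(dim(A)[2:3], dim(B)[2:3])) {
    stop_docnet("data", "groups have mismatched channel/sample dimensions")
  }
  nA <- dim(A)[1]; nB <- dim(B)[1]
  if (paired && nA != nB) stop_docnet("parameter", "paired test needs equal group sizes")
  if (!paired && (nA < 2 || nB < 2)) stop_docnet("parameter", "each group needs n >= 2")
  if (paired && nA < 2) stop_docnet("parameter", "paired test needs n >= 2 subjects")

  t_all <- window_epoch_ms[1] + (seq_len(dim(A)[3]) - 1) * 1000 / rate
  tidx <- which(t_all >= window_ms[1] & t_all <= window_ms[2])
  nc <- dim(A)[2]

  flatten <- function(X) matrix(X[, , tidx, drop = FALSE], nrow = dim(X)[1])
  if (paired) {
    D <- flatten(A) - flatten(B)
    m <- colMeans(D)
    v <- apply(D, 2, stats::var)
    se <- sqrt(v / nA)
    df <- rep(nA - 1, length(m))
  } else {
    XA <- flatten(A); XB <- flatten(B)
    mA <- colMeans(XA); mB <- colMeans(XB)
    vA <- apply(XA, 2, stats::var); vB <- apply(XB, 2, stats::var)
    m <- mA - mB
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1)))
  }
  zero <- se == 0 | !is.finite(se)
  tval <- ifelse(zero, 0, m / se)
  pval <- ifelse(zero, 1, 2 * stats::pt(-abs(tval), df))
  if (any(zero)) warn_docnet("%d time points had zero variance; p set to 1", sum(zero))

  tmat <- matrix(tval, nrow = nc)
  pmat <- matrix(pval, nrow = nc)
  rownames(tmat) <- rownames(pmat) <- channel_labels
  mask <- fdr_correct(pmat, q = q)
  structure(list(t = tmat, p = pmat, fdr_mask = mask, q = q,
                 times_ms = t_all[tidx], test_window_ms = window_ms,
                 channel_labels = channel_labels, paired = paired,
                 n_zero_variance = sum(zero)),
            class = "mass_univariate_result")
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR control applied jointly over all supplied p-values: a point
#' is flagged iff its BH-adjusted p-value is at most `q`, equivalent to the
#' step-up rule rejecting ranks `<= max{i : p_(i) <= i q / m}`.
#'
#' @param p_values Numeric vector, matrix or array of p-values in `[0, 1]`.
#' @param q FDR level, default 0.05.
#' @return Logical mask with the same shape as `p_values`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_docnet("parameter", "p-values must lie in [0, 1]")
  }
  mask <- stats::p.adjust(as.vector(p_values), method = "BH") <= q
  if (!is.null(dim(p_values))) dim(mask) <- dim(p_values)
  mask
}

#' Fraction of significant samples inside a component window
#'
#' Convenience summary used to decide whether a component "shows" in a
#' mass-univariate contrast: the share of FDR-significant time points inside
#' the component window at the component's electrodes.
#'
#' @param res A `mass_univariate_result`.
#' @param comp A component definition from [erp_components()].
#' @return Fraction in `[0, 1]`.
#' @export
component_significance <- function(res, comp) {
  tidx <- which(res$times_ms >= comp$window_ms[1] & res$times_ms <= comp$window_ms[2])
  cidx <- match(comp$electrodes, res$channel_labels)
  if (anyNA(cidx)) stop_docnet("montage", "component electrode(s) missing from result")
  mean(res$fdr_mask[cidx, tidx, drop = FALSE])
}

#' Serialize a mass-univariate result as a long TSV table
#'
#' @param res A `mass_univariate_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mass_univariate_tsv <- function(res, path) {
  df <- data.frame(
    channel = rep(res$channel_labels, times = ncol(res$t)),
    time_ms = rep(res$times_ms, each = nrow(res$t)),
    t = as.vector(res$t),
    p = as.vector(res$p),
    significant = as.vector(res$fdr_mask)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
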