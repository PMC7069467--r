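# Adaptive directed transfer function: spectral transfer matrix from
# time-varying MVAR coefficients, per-sink normalization, band integration,
# and trial averaging into a time-varying directed network.
#
# Conventions: entry (i, j) is the flow j -> i (sink i, source j); rows of a
# normalized ADTF matrix sum to 1 per sink.

#' Time-varying spectral transfer function
#'
#' Computes `Abar(f,t) = I - sum_k A_k(t) exp(-i 2 pi f k / rate)` and its
#' inverse `H(f,t)` on a frequency grid. Reference implementation in plain R;
#' the trial pipeline uses a compiled band-integrated path
#' ([adtf_network()]).
#'
#' @param model A `tv_mvaar` from [fit_kalman_mvaar()] or [ols_var()].
#' @param freqs_hz Frequency grid, strictly inside `(0, rate/2)`.
#' @param time_idx Time indices to evaluate (default: all).
#' @param ridge Diagonal loading applied when `Abar` is numerically singular;
#'   regularized points are counted in the result.
#' @return An `adtf_tf` object: complex array `values[t, f, i, j]`, the grid,
#'   and `n_regularized`.
#' @export
transfer_function <- function(model, freqs_hz, time_idx = NULL, ridge = 1e-8) {
  rate <- model$rate
  if (any(freqs_hz <= 0 | freqs_hz >= rate / 2)) {
    stop_docnet("parameter", "frequencies must lie inside (0, rate/2)")
  }
  n <- model$n
  p <- model$p
  time_idx <- time_idx %||% seq_len(dim(model$coeffs)[3])
  nt <- length(time_idx)
  nf <- length(freqs_hz)
  vals <- array(complex(real = 0), dim = c(nt, nf, n, n))
  n_reg <- 0L
  I_n <- diag(n)
  for (ti in seq_len(nt)) {
    A <- model$coeffs[, , time_idx[ti], drop = FALSE]
    dim(A) <- c(n, n * p)
    for (fi in seq_len(nf)) {
      w <- 2 * pi * freqs_hz[fi] / rate
      Abar <- I_n + 0i
      for (k in seq_len(p)) {
        Abar <- Abar - exp(-1i * w * k) * A[, ((k - 1) * n + 1):(k * n), drop = FALSE]
      }
      H <- tryCatch(solve(Abar), error = function(e) NULL)
      if (is.null(H) || !all(is.finite(Mod(H)))) {
        H <- solve(Abar + ridge * I_n)
        n_reg <- n_reg + 1L
      }
      vals[ti, fi, , ] <- H
    }
  }
  if (n_reg > 0) warn_docnet("regularized %d singular (f,t) points", n_reg)
  structure(list(values = vals, freqs_hz = freqs_hz, time_idx = time_idx,
                 rate = rate, n_regularized = n_reg,
                 channel_labels = model$channel_labels),
            class = "adtf_tf")
}

#' Normalize a transfer function into an ADTF matrix
#'
#' `gamma2[t,f,i,j] = |H[t,f,i,j]|^2 / sum_m |H[t,f,i,m]|^2` (sink-row
#' normalization, the standard DTF convention). An all-zero row is replaced
#' by a uniform row with a warning.
#'
#' @param H An `adtf_tf` from [transfer_function()].
#' @return An `adtf_matrix` object with `values[t, f, i, j]` in `[0, 1]`.
#' @export
normalize_adtf <- function(H) {
  g <- Mod(H$values)^2
  d <- dim(g)
  n_zero <- 0L
  for (ti in seq_len(d[1])) for (fi in seq_len(d[2])) {
    rs <- rowSums(g[ti, fi, , , drop = TRUE])
    zero <- rs == 0
    if (any(zero)) {
      n_zero <- n_zero + sum(zero)
      g[ti, fi, zero, ] <- 1 / d[4]
      rs[zero] <- 1
    }
    g[ti, fi, , ] <- g[ti, fi, , ] / rs
  }
  if (n_zero > 0) warn_docnet("replaced %d all-zero sink rows with uniform rows", n_zero)
  structure(list(values = g, freqs_hz = H$freqs_hz, time_idx = H$time_idx,
                 rate = H$rate, channel_labels = H$channel_labels),
            class = "adtf_matrix")
}

#' Integrate an ADTF (or transfer function) over a frequency band
#'
#' Ratio-of-sums integration, which preserves per-sink normalization:
#' `theta2[t,i,j] = sum_f x[t,f,i,j] / sum_f sum_m x[t,f,i,m]` where `x` is
#' `|H|^2` for a transfer function or `gamma^2` for an ADTF matrix.
#'
#' @param x An `adtf_tf` or `adtf_matrix`.
#' @param band_hz Length-2 band, inside the frequency grid.
#' @return Numeric array `n x n x nt` of band-integrated weights (rows sum
#'   to 1 per time step).
#' @export
integrate_band <- function(x, band_hz = c(1, 30)) {
  keep <- which(x$freqs_hz >= band_hz[1] & x$freqs_hz <= band_hz[2])
  if (length(keep) == 0L) stop_docnet("parameter", "band contains no grid frequencies")
  g <- if (inherits(x, "adtf_tf")) Mod(x$values)^2 else x$values
  d <- dim(g)
  out <- array(0, dim = c(d[3], d[4], d[1]))
  for (ti in seq_len(d[1])) {
    S <- apply(g[ti, keep, , , drop = FALSE], c(3, 4), sum)
    rs <- rowSums(S)
    rs[rs == 0] <- 1
    out[, , ti] <- S / rs
  }
  out
}

#' Trial ADTF network (fast path)
#'
#' Computes the band-integrated, sink-normalized ADTF of a fitted
#' time-varying MVAR model on a decimated time grid, returning a directed
#' time-varying network. This is the per-trial building block that
#' [average_trials()] aggregates into a subject network.
#'
#' @param model A `tv_mvaar`.
#' @param freqs_hz Frequency grid (default 1..30 Hz at 1 Hz; the 0.1 Hz edge
#'   of the acquisition band is unresolvable on epochs shorter than 10 s).
#' @param band_hz Integration band within the grid.
#' @param time_step_ms Spacing of the evaluated time grid (default 20 ms);
#'   `NULL` evaluates every sample.
#' @param t0_ms Epoch time of the first model sample, used to label the grid
#'   (e.g. -200 for a -200..1000 ms epoch).
#' @param ridge Diagonal loading for singular spectral matrices.
#' @return A `tv_network` object: `w` (`n x n x nt`, `w[i,j,t]` = flow
#'   j -> i), `times_ms`, `band_hz`, `n_trials_averaged = 1`.
#' @export
adtf_network <- function(model, freqs_hz = 1:30, band_hz = range(freqs_hz),
                         time_step_ms = 20, t0_ms = 0, ridge = 1e-8) {
  rate <- model$rate
  if (any(freqs_hz <= 0 | freqs_hz >= rate / 2)) {
    stop_docnet("parameter", "frequencies must lie inside (0, rate/2)")
  }
  keep <- freqs_hz[freqs_hz >= band_hz[1] & freqs_hz <= band_hz[2]]
  if (length(keep) == 0L) stop_docnet("parameter", "band contains no grid frequencies")
  Tn <- dim(model$coeffs)[3]
  step <- if (is.null(time_step_ms)) 1L else max(1L, ms_to_samples(time_step_ms, rate))
  tidx <- seq(1L, Tn, by = step)
  res <- adtf_band_cpp(model$coeffs, tidx - 1L, as.numeric(keep), rate, ridge)
  if (res$n_regularized > 0) {
    warn_docnet("regularized %d singular (f,t) points", res$n_regularized)
  }
  structure(list(w = res$theta,
                 times_ms = t0_ms + (tidx - 1) * 1000 / rate,
                 band_hz = as.numeric(band_hz),
                 n_trials_averaged = 1L,
                 channel_labels = model$channel_labels,
                 rate = rate),
            class = "tv_network")
}

#' @export
print.tv_network <- function(x, ...) {
  cat(sprintf("<tv_network> %d nodes, %d time points (%g..%g ms), band %g-%g Hz, %d trial(s) averaged\n",
              dim(x$w)[1], dim(x$w)[3], min(x$times_ms), max(x$times_ms),
              x$band_hz[1], x$band_hz[2], x$n_trials_averaged))
  invisible(x)
}

#' Average per-trial networks into a subject network
#'
#' Entrywise arithmetic mean across trials; averaging removes unstable
#' single-trial patterns while conserving the intrinsic time variation.
#'
#' @param nets List of `tv_network` objects with identical shape, time grid
#'   and band.
#' @return A `tv_network` with `n_trials_averaged` = total trials.
#' @export
average_trials <- function(nets) {
  if (inherits(nets, "tv_network")) return(nets)
  if (length(nets) == 0L) stop_docnet("aggregation", "no networks to average")
  ref <- nets[[1]]
  for (nt in nets[-1]) {
    if (!identical(dim(nt$w), dim(ref$w)) ||
        !isTRUE(all.equal(nt$times_ms, ref$times_ms)) ||
        !isTRUE(all.equal(nt$band_hz, ref$band_hz)) ||
        !identical(nt$channel_labels, ref$channel_labels)) {
      stop_docnet("aggregation", "networks have mismatched shape, grid or band")
    }
  }
  acc <- Reduce(`+`, lapply(nets, `[[`, "w")) / length(nets)
  ref$w <- acc
  ref$n_trials_averaged <- sum(vapply(nets, `[[`, 1L, "n_trials_averaged"))
  ref
}

#' Network snapshot at a latency
#'
#' @param net A `tv_network`.
#' @param time_ms Requested latency; the nearest grid point is used.
#' @return The `n x n` weight matrix at that time.
#' @export
network_at <- function(net, time_ms) {
  idx <- which.min(abs(net$times_ms - time_ms))
  w <- net$w[, , idx]
  dimnames(w) <- list(net$channel_labels, net$channel_labels)
  w
}

#' Time-averaged weight matrix over a window
#'
#' @param net A `tv_network`.
#' @param window_ms Averaging window (default 0..1000 ms).
#' @return The `n x n` mean weight matrix.
#' @export
network_window_mean <- function(net, window_ms = c(0, 1000)) {
  idx <- which(net$times_ms >= window_ms[1] & net$times_ms <= window_ms[2])
  if (length(idx) == 0L) stop_docnet("parameter", "window contains no grid points")
  w <- apply(net$w[, , idx, drop = FALSE], c(1, 2), mean)
  dimnames(w) <- list(net$channel_labels, net$channel_labels)
  w
}

#' Export a time-varying network as a long edge table
#'
#' @param net A `tv_network`.
#' @param times_ms Latencies to export (default: the full grid).
#' @return Data frame with `time_ms`, `source`, `sink`, `weight`.
#' @export
network_edges <- function(net, times_ms = net$times_ms) {
  labels <- net$channel_labels %||% paste0("ch", seq_len(dim(net$w)[1]))
  out <- do.call(rbind, lapply(times_ms, function(tm) {
    w <- network_at(net, tm)
    data.frame(time_ms = tm,
               sink = rep(labels, each = length(labels)),
               source = rep(labels, times = length(labels)),
               weight = as.vector(t(w)),   # w[sink, source]
               stringsAsFactors = FALSE)[c("time_ms", "source", "sink", "weight")]
  }))
  rownames(out) <- NULL
  out
}
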