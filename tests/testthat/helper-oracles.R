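# Independent brute-force oracles used to validate the implementation paths.

# Benjamini-Hochberg step-up by direct enumeration over the sorted list.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- ps <= seq_len(m) * q / m
  k <- if (any(ok)) max(which(ok)) else 0L
  mask <- logical(m)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  mask
}

# Floyd-Warshall all-pairs shortest paths on edge lengths 1/w.
fw_distances <- function(w, directed = FALSE) {
  n <- nrow(w)
  if (!directed) w <- (w + t(w)) / 2
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  d <- pmin(d, len)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Graph metrics by explicit enumeration (triangles) and Floyd-Warshall.
brute_metrics <- function(w) {
  n <- nrow(w)
  diag(w) <- 0
  ws <- (w + t(w)) / 2
  sc <- max(max(ws), 1)
  cvec <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(ws[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && h != j) {
        acc <- acc + ((ws[i, j] / sc) * (ws[i, h] / sc) * (ws[j, h] / sc))^(1 / 3)
      }
    }
    cvec[i] <- acc / (k * (k - 1))
  }
  d <- fw_distances(ws)
  off <- row(d) != col(d)
  dv <- d[off]
  L <- if (any(is.finite(dv))) mean(dv[is.finite(dv)]) else Inf
  Ge <- mean(ifelse(is.finite(dv), 1 / dv, 0))
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(ws[i, ] > 0)
    if (length(nb) < 2) next
    sub <- ws[nb, nb, drop = FALSE]
    ds <- fw_distances(sub)
    o2 <- row(ds) != col(ds)
    le[i] <- mean(ifelse(is.finite(ds[o2]), 1 / ds[o2], 0))
  }
  list(C = mean(cvec), L = L, Ge = Ge, Le = mean(le))
}

# Simulate a stationary VAR(1) trial (channels x samples) with unit-variance
# innovations and a burn-in.
var_sim <- function(A, T, sd = 1, burn = 200) {
  n <- nrow(A)
  x <- matrix(0, n, 1)
  out <- matrix(0, n, T)
  for (t in seq_len(burn)) x <- A %*% x + rnorm(n, 0, sd)
  for (t in seq_len(T)) {
    x <- A %*% x + rnorm(n, 0, sd)
    out[, t] <- x
  }
  out
}

# Wrap a constant coefficient matrix [A_1 ... A_p] (n x n*p) as a one-slice
# time-varying model.
mk_const_model <- function(A, rate = 500, labels = NULL) {
  n <- nrow(A)
  p <- ncol(A) / n
  structure(list(coeffs = array(A, dim = c(n, ncol(A), 1)), p = as.integer(p),
                 n = n, rate = rate, uc = 0, obs_noise = 1,
                 residual_cov = diag(n), channel_labels = labels,
                 config = NULL),
            class = "tv_mvaar")
}

# Single-time-slice tv_network from a weight matrix (for group tests).
mk_network <- function(w, times_ms = 0, labels = NULL) {
  n <- nrow(w)
  structure(list(w = array(w, dim = c(n, n, length(times_ms))),
                 times_ms = times_ms, band_hz = c(1, 30),
                 n_trials_averaged = 1L,
                 channel_labels = labels %||% paste0("ch", seq_len(n)),
                 rate = 500),
            class = "tv_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small recording with named channels and optional events.
mk_recording <- function(data, rate = 500, labels = NULL, events = NULL) {
  eeg_recording(data, rate = rate,
                channel_labels = labels %||% paste0("ch", seq_len(nrow(data))),
                events = events)
}

table1_path <- function() {
  system.file("extdata", "table1_cohort.tsv", package = "docnet")
}
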