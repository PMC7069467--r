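# Time-varying MVAR estimation with the Kalman filter, plus ordinary
# least-squares VAR fitting (the stationary reference) and stability/order
# helpers.

#' Kalman filter configuration for time-varying MVAR estimation
#'
#' @param p Model order (number of lags), default 5.
#' @param uc Update coefficient: the random-walk process-noise variance per
#'   coefficient per sample (`Q = uc * I`), and also the smoothing constant of
#'   the innovation-based observation-noise estimate. Larger values track
#'   faster at the price of noisier coefficients. Default 1e-3.
#' @param init_state_cov Initial state covariance scale (identity times this).
#' @param obs_noise_init Initial observation-noise variance; `NULL` (default)
#'   estimates it from the per-channel variance of the trial.
#' @param noise_mode `"scalar"` (one pooled observation-noise variance, all
#'   sink channels share one state covariance; fast, the default) or
#'   `"diagonal"` (independent noise variance and state covariance per sink).
#' @param smooth If `TRUE`, run a fixed-interval (RTS) smoothing pass over
#'   the filtered coefficients so estimates at time t use the whole trial
#'   rather than only past samples. Removes the causal tracking lag of the
#'   filter; scalar mode only.
#' @return A `kalman_config` list.
#' @export
kalman_config <- function(p = 5, uc = 1e-3, init_state_cov = 1,
                          obs_noise_init = NULL,
                          noise_mode = c("scalar", "diagonal"),
                          smooth = FALSE) {
  noise_mode <- match.arg(noise_mode)
  if (!(is_count(p) && p >= 1)) stop_docnet("parameter", "order p must be >= 1")
  if (uc < 0) stop_docnet("parameter", "uc must be >= 0")
  if (smooth && noise_mode == "diagonal") {
    stop_docnet("parameter", "smoothing is only available in scalar noise mode")
  }
  structure(list(p = as.integer(p), uc = uc, init_state_cov = init_state_cov,
                 obs_noise_init = obs_noise_init, noise_mode = noise_mode,
                 smooth = smooth),
            class = "kalman_config")
}

#' Fit a time-varying MVAR model to one trial
#'
#' Estimates time-varying coefficient matrices `A_k(t)` for a single trial by
#' treating the vectorized coefficients as a random-walk state observed
#' through the lagged data, with the standard Kalman predict/update recursion
#' and innovation-based observation-noise adaptation. Coefficients for
#' `t <= p` are back-filled with the first estimated value so the time axis
#' matches the trial.
#'
#' @param trial Numeric matrix, channels x samples (a single channel may be
#'   supplied as a vector). Must be finite.
#' @param cfg A [kalman_config()].
#' @param rate Sampling rate in Hz, carried into the model for the spectral
#'   transfer function.
#' @return A `tv_mvaar` object with `coeffs` (array channels x channels*p x
#'   samples; entry `[i, (k-1)*n + j, t]` is the lag-k influence of channel j
#'   on channel i), `obs_noise` (tracked innovation variance), pooled
#'   `residual_cov`, and the configuration.
#' @export
fit_kalman_mvaar <- function(trial, cfg = kalman_config(), rate = 500) {
  if (is.vector(trial)) trial <- matrix(trial, nrow = 1)
  trial <- as.matrix(trial)
  storage.mode(trial) <- "double"
  if (!all(is.finite(trial))) stop_docnet("data", "trial contains non-finite values")
  n <- nrow(trial)
  if (ncol(trial) <= cfg$p) {
    stop_docnet("parameter", "trial needs more samples (%d) than the order (%d)",
                ncol(trial), cfg$p)
  }
  res <- kalman_mvaar_cpp(trial, cfg$p, cfg$uc, cfg$init_state_cov,
                          cfg$obs_noise_init %||% -1, cfg$smooth, cfg$noise_mode)
  structure(list(coeffs = res$coeffs, p = cfg$p, n = n, rate = rate,
                 uc = cfg$uc, obs_noise = as.numeric(res$obs_noise),
                 residual_cov = res$residual_cov,
                 channel_labels = rownames(trial), config = cfg),
            class = "tv_mvaar")
}

#' @export
print.tv_mvaar <- function(x, ...) {
  cat(sprintf("<tv_mvaar> n=%d channels, order p=%d, %d time steps, uc=%g\n",
              x$n, x$p, dim(x$coeffs)[3], x$uc))
  invisible(x)
}

#' Extract coefficient matrices at one time step
#'
#' @param model A `tv_mvaar` (or the constant fit from [ols_var()]).
#' @param t Time index (defaults to the last).
#' @return Array `n x n x p`: `[, , k]` is `A_k(t)`.
#' @export
mvar_coef <- function(model, t = dim(model$coeffs)[3]) {
  n <- model$n
  out <- array(0, dim = c(n, n, model$p))
  for (k in seq_len(model$p)) {
    out[, , k] <- model$coeffs[, ((k - 1) * n + 1):(k * n), t]
  }
  out
}

#' Ordinary least-squares VAR fit
#'
#' Stationary multivariate autoregression fitted by least squares; used as
#' the stationary reference for the adaptive estimator and by the
#' order-selection helper. Returned in the same layout as
#' [fit_kalman_mvaar()] with a single (constant) time slice.
#'
#' @param trial Channels x samples matrix (or vector).
#' @param p Model order.
#' @param rate Sampling rate in Hz.
#' @return A `tv_mvaar` with one time step.
#' @export
ols_var <- function(trial, p, rate = 500) {
  if (is.vector(trial)) trial <- matrix(trial, nrow = 1)
  n <- nrow(trial)
  T <- ncol(trial)
  if (T <= p * n + p) stop_docnet("parameter", "trial too short for OLS fit")
  d <- n * p
  idx <- (p + 1):T
  X <- matrix(0, d, length(idx))
  for (k in seq_len(p)) X[((k - 1) * n + 1):(k * n), ] <- trial[, idx - k, drop = FALSE]
  Y <- trial[, idx, drop = FALSE]
  W <- t(solve(tcrossprod(X), X %*% t(Y)))   # n x d, rows = sinks
  E <- Y - W %*% X
  coeffs <- array(W, dim = c(n, d, 1))
  structure(list(coeffs = coeffs, p = p, n = n, rate = rate, uc = 0,
                 obs_noise = mean(diag(tcrossprod(E) / length(idx))),
                 residual_cov = tcrossprod(E) / length(idx),
                 channel_labels = rownames(trial), config = NULL),
            class = "tv_mvaar")
}

#' VAR model-order selection by information criterion
#'
#' Fits [ols_var()] for each candidate order on each supplied trial, pools
#' the Gaussian log-likelihood proxy `log det(residual_cov)` and applies an
#' AIC or BIC penalty. A helper, not applied automatically.
#'
#' @param trials A list of channels x samples matrices (or a single matrix).
#' @param p_range Candidate orders, default `1:10`.
#' @param criterion `"aic"` or `"bic"`.
#' @return A list with `p` (selected order) and `score` per candidate.
#' @export
select_var_order <- function(trials, p_range = 1:10, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (is.matrix(trials)) trials <- list(trials)
  n <- nrow(trials[[1]])
  scores <- vapply(p_range, function(p) {
    tot <- 0
    n_obs <- 0
    for (tr in trials) {
      fit <- ols_var(tr, p)
      m <- ncol(tr) - p
      tot <- tot + m * determinant(fit$residual_cov, logarithm = TRUE)$modulus
      n_obs <- n_obs + m
    }
    k <- n^2 * p
    pen <- if (criterion == "aic") 2 * k else k * log(n_obs)
    as.numeric(tot + pen)
  }, numeric(1))
  list(p = p_range[which.min(scores)],
       score = stats::setNames(scores, paste0("p", p_range)))
}

#' Companion-matrix stability check
#'
#' A coefficient set is stable iff the spectral radius of its companion
#' matrix is below 1.
#'
#' @param A Either an `n x n x p` array of lag matrices, a single `n x n`
#'   matrix (`p = 1`), or a `tv_mvaar` (checked at time `t`).
#' @param t Time index when `A` is a model.
#' @return `TRUE` if stable.
#' @export
stability_check <- function(A, t = NULL) {
  if (inherits(A, "tv_mvaar")) A <- mvar_coef(A, t %||% dim(A$coeffs)[3])
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1))
  spectral_radius_companion(A) < 1
}

spectral_radius_companion <- function(A) {
  n <- dim(A)[1]
  p <- dim(A)[3]
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- A[, , k]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}
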