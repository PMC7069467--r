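mk_epochs <- function(dat, labels, cond, window = c(-200, 1000), rate = 500) {
  eeg_epochs(dat, window, rate, cond, labels)
}

test_that("condition averaging is the arithmetic trial mean", {
  labels <- c("Fz", "Cz")
  one <- array(rnorm(1 * 2 * 600), dim = c(1, 2, 600))
  ep1 <- mk_epochs(one, labels, "deviant")
  expect_equal(average_erp(ep1, "deviant")$data,
               matrix(one[1, , ], 2, dimnames = list(labels, NULL)))
  # x and -x average to zero
  x <- array(rnorm(2 * 600), dim = c(1, 2, 600))
  both <- array(0, dim = c(2, 2, 600)); both[1, , ] <- x[1, , ]; both[2, , ] <- -x[1, , ]
  expect_equal(max(abs(average_erp(mk_epochs(both, labels, rep("deviant", 2)),
                                   "deviant")$data)), 0)
  expect_error(average_erp(ep1, "standard"), "no trials")
})

test_that("averaging N noisy template copies shrinks RMSE about 1/sqrt(N)", {
  set.seed(8)
  tmpl <- sin(seq(0, 4 * pi, length.out = 600))
  noise_one <- array(0, dim = c(100, 1, 600))
  for (i in 1:100) noise_one[i, 1, ] <- tmpl + rnorm(600)
  avg <- average_erp(mk_epochs(noise_one, "Fz", rep("deviant", 100)), "deviant")
  rmse_avg <- sqrt(mean((avg$data[1, ] - tmpl)^2))
  rmse_one <- sqrt(mean((noise_one[1, 1, ] - tmpl)^2))
  expect_lt(rmse_avg / rmse_one, 1 / sqrt(100) * 1.5)
  expect_gt(rmse_avg / rmse_one, 1 / sqrt(100) / 1.5)
})

test_that("mass-univariate t-tests handle identity, planted and degenerate cases", {
  set.seed(9)
  n_sub <- 6
  arr <- array(rnorm(n_sub * 2 * 600), dim = c(n_sub, 2, 600))
  attr(arr, "rate") <- 500; attr(arr, "window_ms") <- c(-200, 1000)
  attr(arr, "channel_labels") <- c("Fz", "Cz")
  # a == b paired: t = 0, p = 1 everywhere (zero variance warning)
  expect_warning(res0 <- mass_univariate_ttest(arr, arr, paired = TRUE),
                 "zero variance")
  expect_true(all(res0$t == 0))
  expect_true(all(res0$p == 1))
  expect_false(any(res0$fdr_mask))
  # constant nonzero paired difference with tiny jitter: p < 1e-6
  b <- arr
  b[, , ] <- arr[, , ] - 2 + rnorm(length(arr), 0, 1e-4)
  resc <- mass_univariate_ttest(arr, b, paired = TRUE)
  expect_true(all(resc$p < 1e-6))
  # unpaired identical triples: t = 0, p = 1
  a3 <- array(rep(c(1, 2, 3), 600), dim = c(3, 1, 600))
  attr(a3, "rate") <- 500; attr(a3, "window_ms") <- c(0, 1200)
  r3 <- mass_univariate_ttest(a3, a3, paired = FALSE)
  expect_true(all(r3$t == 0))
  expect_true(all(r3$p == 1))
  # test window restricts the time axis
  expect_true(all(res0$times_ms >= 0 & res0$times_ms <= 1000))
})

test_that("BH mask matches the brute-force step-up oracle", {
  expect_false(any(fdr_correct(rep(1, 20))))
  p <- c(0.001, 0.01, 0.02, 0.03, 0.5)
  expect_equal(fdr_correct(p, 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(fdr_correct(0.04, 0.05))           # m = 1 reduces to raw threshold
  set.seed(10)
  for (i in 1:25) {
    m <- sample(1:1000, 1)
    pv <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_equal(fdr_correct(pv, q), bh_oracle(pv, q))
  }
  # shape preserved for matrices
  pm <- matrix(runif(20), 4, 5)
  expect_equal(dim(fdr_correct(pm)), c(4, 5))
  expect_error(fdr_correct(c(0.5, 1.2)), "p-values")
})

test_that("component amplitudes are window means over component electrodes", {
  comps <- erp_components()
  z <- structure(list(data = matrix(0, 1, 600, dimnames = list("Fz", NULL)),
                      rate = 500, window_ms = c(-200, 1000), condition = "deviant",
                      n_trials_averaged = 1, channel_labels = "Fz"),
                 class = "erp_waveform")
  expect_equal(measure_component(z, comps$N1), 0)
  z$data[1, ] <- -5
  expect_equal(measure_component(z, comps$N1), -5)
  # Gaussian bump peaking 3 uV at 300 ms, width SD 50/2 ms: compare window
  # mean against numeric quadrature of the analytic template
  t_ms <- -200 + (0:599) * 2
  bump <- function(t) 3 * exp(-0.5 * ((t - 300) / 25)^2)
  z$data[1, ] <- bump(t_ms)
  expected <- integrate(bump, 250, 350)$value / 100
  # sampled window mean vs continuous quadrature: endpoint weighting differs
  expect_equal(measure_component(z, comps$P3a), expected, tolerance = 0.03)
  expect_error(measure_component(z, comps$LPP), "montage")
})

test_that("planted effects concentrate the FDR mask in their window", {
  set.seed(11)
  n_sub <- 10
  a <- array(rnorm(n_sub * 1 * 600), dim = c(n_sub, 1, 600))
  b <- a + rnorm(length(a), 0, 0.1)
  t_ms <- -200 + (0:599) * 2
  eff <- t_ms >= 300 & t_ms <= 400
  for (i in seq_len(n_sub)) a[i, 1, eff] <- a[i, 1, eff] + 1.5
  attr(a, "rate") <- attr(b, "rate") <- 500
  attr(a, "window_ms") <- attr(b, "window_ms") <- c(-200, 1000)
  attr(a, "channel_labels") <- attr(b, "channel_labels") <- "Fz"
  res <- mass_univariate_ttest(a, b, paired = TRUE)
  inside <- res$times_ms >= 300 & res$times_ms <= 400
  dens_in <- mean(res$fdr_mask[, inside])
  dens_out <- mean(res$fdr_mask[, !inside])
  expect_gt(dens_in, 0.5)
  expect_gt(dens_in, 5 * max(dens_out, 1e-6))
})
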