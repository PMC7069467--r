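test_that("the transfer function solves the spectral coefficient matrix", {
  # all-zero coefficients: H = I at every (f, t)
  m0 <- mk_const_model(matrix(0, 3, 3))
  H0 <- transfer_function(m0, c(1, 10, 20))
  for (f in 1:3) expect_equal(H0$values[1, f, , ], diag(3) + 0i)
  # 2-node VAR(1) worked example at f -> 0: H = [[2, 0], [2, 2]]
  A <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2)
  m <- mk_const_model(A)
  H <- transfer_function(m, 1e-9)
  expect_equal(Re(H$values[1, 1, , ]), matrix(c(2, 2, 0, 2), 2, 2),
               tolerance = 1e-6)
  # brute-force complex inversion oracle on a random frequency
  f <- 7.3
  z <- exp(-1i * 2 * pi * f / 500)
  Ho <- solve(diag(2) - A * z)
  Hf <- transfer_function(m, f)
  expect_equal(Hf$values[1, 1, , ], Ho, tolerance = 1e-12)
  # diagonal coefficients give a diagonal transfer function
  md <- mk_const_model(diag(c(0.5, -0.3)))
  Hd <- transfer_function(md, c(3, 9))$values
  expect_equal(Hd[1, 1, 1, 2], 0 + 0i)
  expect_equal(Hd[1, 2, 2, 1], 0 + 0i)
  expect_error(transfer_function(m, 400), "rate/2")
})

test_that("sink-row normalization produces rows summing to one", {
  A <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2)
  g <- normalize_adtf(transfer_function(mk_const_model(A), 1e-9))
  # H rows (2, 0) and (2, 2) normalize to (1, 0) and (0.5, 0.5)
  expect_equal(g$values[1, 1, 1, ], c(1, 0), tolerance = 1e-6)
  expect_equal(g$values[1, 1, 2, ], c(0.5, 0.5), tolerance = 1e-6)
  # any H: every row sums to 1
  set.seed(20)
  Ar <- matrix(rnorm(16, 0, 0.15), 4); diag(Ar) <- 0.5
  gr <- normalize_adtf(transfer_function(mk_const_model(Ar), 1:30))
  sums <- apply(gr$values, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("band integration preserves normalization and structural zeros", {
  set.seed(21)
  Ar <- matrix(rnorm(16, 0, 0.15), 4); diag(Ar) <- 0.5
  H <- transfer_function(mk_const_model(Ar), 1:30)
  th <- integrate_band(H, c(1, 30))
  # rows sum to 1: compare against a brute-force ratio-of-sums oracle
  g2 <- Mod(H$values)^2
  oracle <- apply(g2[1, , , ], c(2, 3), sum)
  oracle <- oracle / rowSums(oracle)
  expect_equal(th[, , 1], oracle, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(th[, , 1]) - 1)), 1e-9)
  # frequency-constant gamma^2 integrates to itself
  g <- normalize_adtf(transfer_function(mk_const_model(matrix(0, 2, 2)), c(5, 10, 15)))
  thc <- integrate_band(g, c(1, 30))
  expect_equal(thc[, , 1], g$values[1, 1, , ])
  # undriven direction of the unidirectional example stays exactly zero
  A <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2)
  thu <- integrate_band(transfer_function(mk_const_model(A), 1:30), c(1, 30))
  expect_equal(thu[1, 2, 1], 0)          # no flow 2 -> 1
  expect_gt(thu[2, 1, 1], 0)             # planted flow 1 -> 2
  expect_error(integrate_band(H, c(100, 200)), "band")
})

test_that("the compiled band-integrated path matches the reference path", {
  set.seed(22)
  y <- var_sim(matrix(c(0.6, 0.3, -0.2, 0.5), 2, 2), 800)
  model <- fit_kalman_mvaar(y, kalman_config(p = 2, uc = 1e-2))
  net <- adtf_network(model, freqs_hz = 1:30, time_step_ms = NULL)
  idx <- c(5, 400, 800)
  H <- transfer_function(model, 1:30, time_idx = idx)
  ref <- integrate_band(H, c(1, 30))
  expect_equal(net$w[, , idx], ref, tolerance = 1e-10)
  expect_lt(max(abs(apply(net$w, c(1, 3), sum) - 1)), 1e-6)
})

test_that("trial averaging is linear and reduces estimation noise", {
  w <- matrix(c(0, 0.4, 0.6, 0), 2, 2)
  n1 <- mk_network(w); n2 <- mk_network(w + 0.1); n3 <- mk_network(w - 0.1)
  expect_equal(average_trials(list(n1))$w, n1$w)
  avg <- average_trials(list(n2, n3))
  expect_equal(avg$w[, , 1], w, tolerance = 1e-12)
  expect_equal(avg$n_trials_averaged, 2L)
  # 64 noisy copies: RMSE to truth shrinks about 1/sqrt(64)
  set.seed(23)
  noisy <- lapply(1:64, function(i) mk_network(w + matrix(rnorm(4, 0, 0.05), 2)))
  avg64 <- average_trials(noisy)
  rmse1 <- sqrt(mean((noisy[[1]]$w[, , 1] - w)^2))
  rmse64 <- sqrt(mean((avg64$w[, , 1] - w)^2))
  expect_lt(rmse64 / rmse1, 1 / 8 * 2.2)
  # mismatched shapes refused
  bad <- mk_network(matrix(0, 3, 3))
  expect_error(average_trials(list(n1, bad)), "mismatched")
})

test_that("planted directional coupling dominates the reverse direction", {
  set.seed(24)
  A <- matrix(c(0.5, 0.45, 0, 0, 0.5, 0, 0, 0, 0.5), 3, 3)  # 1 -> 2 only
  nets <- lapply(1:50, function(i) {
    y <- var_sim(A, 400)
    model <- fit_kalman_mvaar(y, kalman_config(p = 1, uc = 1e-3))
    adtf_network(model, freqs_hz = seq(2, 30, 2), time_step_ms = 100)
  })
  avg <- average_trials(nets)
  w_late <- avg$w[, , dim(avg$w)[3]]
  expect_gt(w_late[2, 1], 5 * w_late[1, 2])
})

test_that("time-averaged adaptive networks approach the static DTF", {
  set.seed(25)
  A <- matrix(c(0.6, 0.2, 0, 0, 0.5, 0.3, 0.1, 0, 0.4), 3, 3, byrow = TRUE)
  y <- var_sim(A, 8000)
  fit <- fit_kalman_mvaar(y, kalman_config(p = 1, uc = 1e-4))
  net <- adtf_network(fit, freqs_hz = 1:30, time_step_ms = NULL)
  w_avg <- apply(net$w[, , 6001:8000], c(1, 2), mean)
  w_ols <- adtf_network(ols_var(y, 1), freqs_hz = 1:30, time_step_ms = NULL)$w[, , 1]
  expect_lt(max(abs(w_avg - w_ols)), 0.05)
})

test_that("network snapshots, window means and edge export are consistent", {
  w1 <- matrix(c(0, 0.2, 0.8, 0), 2, 2)
  w2 <- matrix(c(0, 0.6, 0.4, 0), 2, 2)
  net <- mk_network(w1, times_ms = c(0, 100), labels = c("F3", "P3"))
  net$w <- array(c(w1, w2), dim = c(2, 2, 2))
  expect_equal(network_at(net, 10), matrix(w1, 2, 2,
               dimnames = list(c("F3", "P3"), c("F3", "P3"))))
  expect_equal(unname(network_window_mean(net, c(0, 100))), (w1 + w2) / 2)
  ed <- network_edges(net, 100)
  expect_equal(ed$weight[ed$source == "F3" & ed$sink == "P3"], w2[2, 1])
})
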