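test_that("zero-lag FIR band-pass preserves in-band and rejects out-of-band tones", {
  rate <- 500
  t <- seq(0, 80 - 1 / rate, by = 1 / rate)
  x10 <- sin(2 * pi * 10 * t)
  x45 <- sin(2 * pi * 45 * t)
  rec <- mk_recording(rbind(x10, x45, 0 * t), rate = rate,
                      labels = c("in", "out", "zero"))
  f <- bandpass_fir(rec, 0.1, 30)
  core <- seq(20 * rate, 60 * rate)   # trim filter edges
  amp_in <- max(abs(f$data["in", core]))
  expect_gt(amp_in, 0.95)
  expect_lt(amp_in, 1.05)
  amp_out <- max(abs(f$data["out", core]))
  expect_lt(20 * log10(amp_out / 1), -40)
  expect_equal(max(abs(f$data["zero", ])), 0)
  # zero-lag: in-band tone not phase shifted
  expect_gt(cor(f$data["in", core], x10[core]), 0.999)
  expect_error(bandpass_fir(rec, 0.1, 300), "band")
})

test_that("mastoid re-referencing subtracts the instantaneous reference mean", {
  dat <- rbind(TP9 = c(1, 0), TP10 = c(3, 0), Cz = c(10, 5))
  rec <- mk_recording(dat, labels = rownames(dat))
  rr <- rereference(rec)
  expect_equal(unname(rr$data["Cz", 1]), 10 - 2)   # 10 - mean(1, 3)
  expect_equal(unname(rr$data["Cz", 2]), 5)        # zero reference: unchanged
  # common-mode offset is rejected
  rec2 <- mk_recording(dat + 7, labels = rownames(dat))
  expect_equal(rereference(rec2)$data["Cz", ], rereference(rec)$data["Cz", ])
  expect_error(rereference(mk_recording(matrix(0, 2, 4))), "montage")
})

test_that("epoching uses a half-open sample grid with onset at index 100", {
  rate <- 500
  dat <- matrix(rnorm(2 * 4000), 2)
  ev <- data.frame(sample = c(1, seq(500, 3000, by = 280)),
                   label = "standard")
  rec <- mk_recording(dat, rate = rate, events = ev)
  expect_warning(ep <- epoch(rec, c(-200, 1000)), "dropped 1")
  expect_equal(dim(ep$data)[1], nrow(ev) - 1)       # boundary event dropped
  expect_equal(dim(ep$data)[3], 600)
  t_ms <- epoch_times_ms(ep)
  expect_equal(t_ms[101], 0)                        # onset at 0-based index 100
  expect_equal(t_ms[1], -200)
  expect_equal(t_ms[600], 1000 - 2)                 # half-open [−200, 1000)
  # trials copy the right samples
  expect_equal(ep$data[1, 1, 101], dat[1, 500])
})

test_that("baseline correction removes the pre-stimulus mean exactly", {
  dat <- array(0, dim = c(2, 1, 600))
  dat[1, 1, ] <- 5                                   # constant trial -> zero
  dat[2, 1, 1:100] <- c(rep(1, 33), rep(2, 34), rep(3, 33))
  dat[2, 1, 101:600] <- 10
  ep <- eeg_epochs(dat, c(-200, 1000), 500, rep("standard", 2), "Cz")
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$data[1, 1, ])), 0)
  expect_equal(bc$data[2, 1, 300], 10 - 2)          # baseline mean {1,2,3} = 2
  # idempotent on corrected data
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data)
  # every trial/channel baseline mean vanishes on random data
  set.seed(1)
  ep3 <- eeg_epochs(array(rnorm(5 * 3 * 600, 0, 50), dim = c(5, 3, 600)),
                    c(-200, 1000), 500, rep("standard", 5), c("a", "b", "c"))
  bc3 <- baseline_correct(ep3)
  bl <- apply(bc3$data[, , 1:100], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9 * 50)
  expect_error(baseline_correct(ep, c(-400, -300)), "baseline")
})

test_that("amplitude rejection removes only extreme trials", {
  set.seed(2)
  base <- array(rnorm(21 * 2 * 100), dim = c(21, 2, 100))
  base[21, , ] <- base[21, , ] * 100                 # one gross outlier
  ep <- eeg_epochs(base, c(-200, 0), 500, rep("standard", 21), c("a", "b"))
  res <- reject_amplitude(ep, k = 3)
  expect_equal(which(res$log$rejected), 21L)
  expect_equal(dim(res$epochs$data)[1], 20)
  # identical trials: zero SD, ties kept
  same <- eeg_epochs(array(1, dim = c(5, 2, 100)), c(-200, 0), 500,
                     rep("standard", 5), c("a", "b"))
  expect_equal(sum(reject_amplitude(same, 3)$log$rejected), 0L)
  # k = Inf disables rejection
  expect_equal(sum(reject_amplitude(ep, Inf)$log$rejected), 0L)
  # stationary Gaussian trials: < 5% rejected
  set.seed(3)
  g <- eeg_epochs(array(rnorm(200 * 3 * 100), dim = c(200, 3, 100)),
                  c(-200, 0), 500, rep("standard", 200), c("a", "b", "c"))
  expect_lt(mean(reject_amplitude(g, 3)$log$rejected), 0.05)
})

test_that("channel selection reduces and reorders the montage", {
  labels <- c(default_montage27(), "TP9", "TP10", "EXT1")
  ep <- eeg_epochs(array(rnorm(2 * 30 * 50), dim = c(2, 30, 50)),
                   c(0, 100), 500, rep("standard", 2), labels)
  sub <- select_channels(ep, default_montage27())
  expect_equal(dim(sub$data)[2], 27)
  expect_equal(sub$channel_labels, default_montage27())
  # identity subset
  expect_equal(select_channels(ep, labels)$data, ep$data)
  # reorder honoured
  rev2 <- select_channels(ep, c("O2", "Fp1"))
  expect_equal(rev2$data[1, 1, ], ep$data[1, match("O2", labels), ])
  expect_error(select_channels(ep, c("Fz", "Fz")), "duplicate")
  expect_error(select_channels(ep, "NoSuch"), "montage")
})

test_that("re-referencing and epoching commute", {
  set.seed(4)
  dat <- matrix(rnorm(5 * 2000), 5)
  labels <- c("TP9", "TP10", "a", "b", "c")
  ev <- data.frame(sample = c(400, 900, 1300), label = "standard")
  rec <- mk_recording(dat, labels = labels, events = ev)
  a <- epoch(rereference(rec), c(-200, 1000))
  b <- epoch(rec, c(-200, 1000))
  ref <- apply(b$data[, 1:2, , drop = FALSE], c(1, 3), mean)
  b$data <- b$data - aperm(array(ref, dim = c(3, 600, 5)), c(1, 3, 2))
  expect_equal(a$data, b$data, tolerance = 1e-12)
})
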