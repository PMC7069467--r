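test_that("oddball blocks have the right composition and no adjacent deviants", {
  blk <- generate_block(seed = 32)
  expect_length(blk$sequence, 110)
  expect_equal(sum(blk$sequence == "standard"), 86)
  expect_equal(sum(blk$sequence == "happy"), 12)
  expect_equal(sum(blk$sequence == "sad"), 12)
  dev <- blk$sequence != "standard"
  expect_false(any(dev[-1] & dev[-length(dev)]))
  # determinism under a seed
  expect_identical(generate_block(seed = 32)$sequence, blk$sequence)
  # all-standard and degenerate cases
  expect_true(all(generate_block(n_happy = 0, n_sad = 0, seed = 1)$sequence == "standard"))
  expect_error(generate_block(n_standard = 2, n_happy = 2, n_sad = 2), "adjacency")
  # adjacency constraint holds across many draws
  for (s in 1:20) {
    d <- generate_block(n_standard = 10, n_happy = 5, n_sad = 5, seed = s)$sequence != "standard"
    expect_false(any(d[-1] & d[-length(d)]))
  }
})

test_that("ERP templates are analytic bumps confined to their window", {
  t_ms <- seq(-200, 998, by = 2)
  tc <- erp_template(t_ms, c(250, 350), 4)
  expect_equal(tc[t_ms <= 250], rep(0, sum(t_ms <= 250)))
  expect_equal(tc[t_ms >= 350], rep(0, sum(t_ms >= 350)))
  expect_equal(max(tc), 4, tolerance = 1e-3)   # midpoint attains the peak
  expect_equal(which.max(tc), which.min(abs(t_ms - 300)))
})

test_that("noiseless simulation reduces to the deterministic template sum", {
  scn <- simulation_scenario(n_subjects_per_group = 1, n_trials_deviant = 2,
                             n_trials_standard = 2, amplitude_jitter_sd = 0,
                             seed = 5)
  sim <- simulate_subject_epochs(scn, "MCS", subject_seed = 1, noise_sd = 0)
  ep <- sim$epochs
  t_ms <- epoch_times_ms(ep)
  wts <- component_scalp_weights(scn$channel_labels)
  comps <- erp_components()
  expected_fz <- scn$erp_peaks_uv[["n1_deviant"]] * wts$N1[["Fz"]] *
    erp_template(t_ms, comps$N1$window_ms, 1) +
    scn$erp_peaks_uv[["p3a_deviant_mcs"]] * wts$P3a[["Fz"]] *
    erp_template(t_ms, comps$P3a$window_ms, 1)
  fz <- match("Fz", ep$channel_labels)
  expect_equal(ep$data[1, fz, ], expected_fz, tolerance = 1e-9)
  # standards carry only the standard N1
  expected_std <- scn$erp_peaks_uv[["n1_standard"]] * wts$N1[["Fz"]] *
    erp_template(t_ms, comps$N1$window_ms, 1)
  expect_equal(ep$data[3, fz, ], expected_std, tolerance = 1e-9)
})

test_that("grand-average deviant response recovers the configured P3a", {
  scn <- simulation_scenario(n_trials_deviant = 100, n_trials_standard = 0,
                             amplitude_jitter_sd = 0, seed = 6)
  sim <- simulate_subject_epochs(scn, "MCS", subject_seed = 33)
  erp <- average_erp(sim$epochs, "deviant")
  measured <- measure_component(erp, erp_components()$P3a)
  t_ms <- epoch_times_ms(sim$epochs)
  win <- t_ms >= 250 & t_ms <= 350
  expected <- mean(scn$erp_peaks_uv[["p3a_deviant_mcs"]] *
                     erp_template(t_ms, c(250, 350), 1)[win])
  expect_lt(abs(measured - expected) / abs(expected), 0.1)
})

test_that("coupling-only trials stay zero mean and carry the planted schedule", {
  scn <- simulation_scenario(n_trials_deviant = 40, n_trials_standard = 0,
                             erp_peaks_uv = c(n1_standard = 0, n1_deviant = 0,
                                              p3a_deviant_mcs = 0, lpp = 0),
                             seed = 7)
  sim <- simulate_subject_epochs(scn, "MCS", subject_seed = 2)
  expect_lt(max(abs(apply(sim$epochs$data, 2, mean))), 1.5)
  expect_equal(sim$truth$coupling$source, "F3")
  expect_equal(sim$truth$coupling$on_ms, c(300, 1000))
  # UWS-like subjects have the coupling switched off by default
  sim_u <- simulate_subject_epochs(scn, "UWS", subject_seed = 2)
  expect_equal(sim_u$truth$coupling$effective_strength, 0)
})

test_that("synthetic cohorts respect the CRS-R schema and planted correlations", {
  co <- generate_cohort(n_per_cell = 10, seed = 34)
  expect_s3_class(co, "doc_cohort")
  expect_equal(nrow(co), 40)
  subs <- as.matrix(co[c("crs_a", "crs_v", "crs_m", "crs_verbal",
                         "crs_comm", "crs_arousal")])
  expect_equal(unname(rowSums(subs)), co$crs_total)
  expect_true(all(subs <= matrix(c(4, 5, 6, 3, 2, 3), 40, 6, byrow = TRUE)))
  expect_true(all(co$crs_total <= 23))
  # correlation planted within the traumatic group only
  tr <- cohort_rows(co, traumatic_group = "traumatic")
  nt <- cohort_rows(co, traumatic_group = "nontraumatic")
  r_tr <- cor(co$strength[tr], co$crs_total[tr])
  expect_gt(r_tr, 0.2)
  # rho = 0.99 at n = 50: sample r above 0.9
  co99 <- generate_cohort(n_per_cell = 25, rho_traumatic = 0.99, seed = 35)
  tr99 <- cohort_rows(co99, traumatic_group = "traumatic")
  expect_gt(cor(co99$strength[tr99], co99$crs_total[tr99]), 0.9)
  # rho = 0: sample r within its null 95% interval
  co0 <- generate_cohort(n_per_cell = 25, rho_traumatic = 0, seed = 36)
  tr0 <- cohort_rows(co0, traumatic_group = "traumatic")
  r0 <- cor(co0$strength[tr0], co0$crs_total[tr0])
  expect_lt(abs(atanh(r0)), 1.96 / sqrt(50 - 3))
  expect_error(generate_cohort(2), "n_per_cell")
  expect_error(generate_cohort(5, rho_traumatic = 1), "correlations")
})

test_that("fixture datasets materialize and reload through the plain format", {
  dir <- tempfile()
  write_fixture_dataset(dir, seed = 37)
  co <- parse_cohort_table(file.path(dir, "cohort.tsv"))
  expect_gt(nrow(co), 0)
  ep <- read_epochs_plain(file.path(dir, "epochs_MCS"))
  expect_s3_class(ep, "eeg_epochs")
  expect_equal(dim(ep$data)[2], 27)
})
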