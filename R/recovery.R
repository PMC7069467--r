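# End-to-end recovery studies on the synthetic scenario: planted-edge
# retention at snapshot latencies, ERP component specificity, and
# score-network association recovery. These drive the package's
# self-validation (test suite and acceptance script).

#' Analytic stationary network of a scenario subject
#'
#' Band-integrated ADTF of the scenario's VAR(1) with the planted coupling
#' held on at a given gain — the stationary, estimation-noise-free limit of
#' the subject's connectivity. Used by the association recovery study, where
#' each cohort subject's latent network strength sets the gain.
#'
#' @param scn A [simulation_scenario()].
#' @param gain Coupling gain (latent network strength).
#' @param freqs_hz,band_hz ADTF grid and band.
#' @return A `tv_network` with a single time slice.
#' @export
stationary_subject_network <- function(scn, gain, freqs_hz = 1:30,
                                       band_hz = c(1, 30)) {
  n <- length(scn$channel_labels)
  A <- scenario_A(scn, gain)
  model <- structure(list(coeffs = array(A, dim = c(n, n, 1)), p = 1L, n = n,
                          rate = scn$rate, uc = 0, obs_noise = scn$noise_sd^2,
                          residual_cov = diag(scn$noise_sd^2, n),
                          channel_labels = scn$channel_labels, config = NULL),
                     class = "tv_mvaar")
  adtf_network(model, freqs_hz = freqs_hz, band_hz = band_hz,
               time_step_ms = NULL, t0_ms = 0)
}

#' Association recovery study on a synthetic cohort
#'
#' For every cohort subject, computes the graph properties of the
#' stationary analytic network scaled by the subject's latent strength and
#' correlates them with the CRS-R totals within each aetiology group.
#'
#' @param cohort A cohort from [generate_cohort()] (needs a `strength` column).
#' @param scn A [simulation_scenario()].
#' @return Named list (`traumatic`, `nontraumatic`) of
#'   [pearson_association()] tables.
#' @export
association_study <- function(cohort, scn = simulation_scenario()) {
  if (is.null(cohort$strength)) stop_docnet("parameter", "cohort lacks a strength column")
  props <- lapply(cohort$strength, function(s) {
    subject_properties(stationary_subject_network(scn, s), window_ms = c(0, 0))
  })
  ptab <- properties_table(props, subject_id = cohort$patient_id)
  out <- list()
  for (tg in c("traumatic", "nontraumatic")) {
    idx <- cohort_rows(cohort, traumatic_group = tg)
    out[[tg]] <- pearson_association(ptab[idx, ], cohort$crs_total[idx])
  }
  attr(out, "properties") <- ptab
  attr(out, "scores") <- cohort$crs_total
  out
}

# Does the 95% percentile-bootstrap interval of cor(x, y) cover rho?
bootstrap_ci_covers <- function(x, y, rho, B = 1000, seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) return(NA)
  rs <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx])
  }, numeric(1)))
  ci <- stats::quantile(rs, c(0.025, 0.975), na.rm = TRUE)
  rho >= ci[[1]] && rho <= ci[[2]]
}

#' One end-to-end recovery replicate
#'
#' Simulates the full two-group study (MCS-like vs UWS-like subjects),
#' runs the complete analysis chain — per-trial Kalman MVAR, trial-averaged
#' ADTF networks, between-group snapshot difference networks, within-group
#' deviant-vs-standard mass-univariate ERP contrasts — plus the cohort
#' association study, and scores the planted effects.
#'
#' @param scn A [simulation_scenario()].
#' @param kalman_cfg Kalman settings for the network fits (default: order 1
#'   matched to the scenario background, uc = 1e-2, RTS smoothing).
#' @param seed Replicate seed.
#' @param snapshots_ms Snapshot latencies tested.
#' @param freqs_hz,time_step_ms ADTF evaluation grid for the study (2 Hz and
#'   100 ms by default: the integrand is smooth for the low-order background
#'   and the planted dynamics evolve over hundreds of ms).
#' @return One-row data frame of outcome indicators: planted-edge retention
#'   at each snapshot (with direction MCS > UWS), its absence at 100 ms,
#'   N1/P3a significance fractions per group, and association results per
#'   aetiology group.
#' @export
recovery_replicate <- function(scn = simulation_scenario(),
                               kalman_cfg = kalman_config(p = 1, uc = 1e-2,
                                                          smooth = TRUE),
                               seed = 1L,
                               snapshots_ms = c(100, 200, 300, 600, 1000),
                               freqs_hz = seq(2, 30, by = 2),
                               time_step_ms = 100) {
  groups <- list(MCS = list(), UWS = list())
  erps <- list(MCS = list(dev = list(), std = list()),
               UWS = list(dev = list(), std = list()))
  for (dx in c("MCS", "UWS")) {
    for (i in seq_len(scn$n_subjects_per_group)) {
      sim <- simulate_subject_epochs(scn, dx, strength = 1,
                                     subject_seed = derive_seed(seed, "subj", dx, i))
      ep <- sim$epochs
      groups[[dx]][[i]] <- subject_network(ep, "deviant", kalman_cfg,
                                           freqs_hz = freqs_hz,
                                           band_hz = range(freqs_hz),
                                           time_step_ms = time_step_ms)
      erps[[dx]]$dev[[i]] <- average_erp(ep, "deviant")
      erps[[dx]]$std[[i]] <- average_erp(ep, "standard")
    }
  }

  snaps <- snapshot_series(groups$MCS, groups$UWS, times_ms = snapshots_ms)
  src <- scn$coupling$source
  snk <- scn$coupling$sink
  edge_at <- function(tm, dir = "A>B") {
    edge_retained(snaps[[paste0("t", tm)]], src, snk, direction = dir)
  }

  comps <- erp_components()
  frac <- list()
  for (dx in c("MCS", "UWS")) {
    res <- mass_univariate_ttest(erps[[dx]]$dev, erps[[dx]]$std, paired = TRUE)
    frac[[dx]] <- vapply(comps[c("N1", "P3a")],
                         function(cp) component_significance(res, cp), numeric(1))
  }

  cohort <- generate_cohort(n_per_cell = scn$n_subjects_per_group,
                            seed = derive_seed(seed, "cohort"))
  assoc <- association_study(cohort, scn)
  r_tr <- assoc$traumatic$r[assoc$traumatic$property == "C"]
  r_nt <- assoc$nontraumatic$r[assoc$nontraumatic$property == "C"]
  idx_tr <- cohort_rows(cohort, traumatic_group = "traumatic")
  covers <- bootstrap_ci_covers(attr(assoc, "properties")$C[idx_tr],
                                cohort$crs_total[idx_tr], rho = 0.5,
                                seed = derive_seed(seed, "boot"))

  data.frame(
    seed = seed,
    edge_300 = edge_at(300), edge_600 = edge_at(600), edge_1000 = edge_at(1000),
    edge_100_absent = !edge_retained(snaps$t100, src, snk),
    n1_mcs = frac$MCS[["N1"]], n1_uws = frac$UWS[["N1"]],
    p3a_mcs = frac$MCS[["P3a"]], p3a_uws = frac$UWS[["P3a"]],
    assoc_r_traumatic = r_tr,
    assoc_covers = covers,
    assoc_r_nontraumatic = r_nt,
    assoc_null_ok = abs(r_nt) < 0.4
  )
}

#' Replicated end-to-end recovery study
#'
#' Runs [recovery_replicate()] across seeds and summarizes the recovery
#' rates. A component "shows" in a contrast when at least `show_threshold`
#' of its window samples are FDR-significant at its electrode (guards
#' against isolated false positives).
#'
#' @param n_replicates Number of replicates (default 20).
#' @param seed Master seed; replicate seeds are derived sub-streams.
#' @param scn,kalman_cfg Passed to [recovery_replicate()].
#' @param show_threshold Significance-fraction threshold (default 0.1).
#' @return A list: `replicates` (per-replicate outcomes) and `rates`
#'   (fractions over replicates for the edge, ERP and association checks).
#' @export
recovery_study <- function(n_replicates = 20, seed = 1L,
                           scn = simulation_scenario(),
                           kalman_cfg = kalman_config(p = 1, uc = 1e-2,
                                                      smooth = TRUE),
                           show_threshold = 0.1) {
  reps <- do.call(rbind, lapply(seq_len(n_replicates), function(k) {
    recovery_replicate(scn, kalman_cfg, seed = derive_seed(seed, "replicate", k))
  }))
  shows <- function(x) x >= show_threshold
  rates <- list(
    edge_recovery = mean(reps$edge_300 & reps$edge_600 & reps$edge_1000 &
                           reps$edge_100_absent),
    edge_300 = mean(reps$edge_300), edge_600 = mean(reps$edge_600),
    edge_1000 = mean(reps$edge_1000), edge_100_absent = mean(reps$edge_100_absent),
    n1_both_groups = mean(shows(reps$n1_mcs) & shows(reps$n1_uws)),
    p3a_specificity = mean(shows(reps$p3a_mcs) & !shows(reps$p3a_uws)),
    assoc_covers = mean(reps$assoc_covers),
    assoc_null_ok = mean(reps$assoc_null_ok),
    mean_r_traumatic = mean(reps$assoc_r_traumatic),
    mean_r_nontraumatic = mean(reps$assoc_r_nontraumatic)
  )
  list(replicates = reps, rates = rates)
}
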