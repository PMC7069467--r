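# Synthetic-data generation: oddball stimulus blocks, ERP-bearing
# time-varying VAR epochs for simulated MCS/UWS x traumatic/nontraumatic
# subjects, and cohort tables with planted score-network associations.
#
# All randomness flows from one scenario seed via named sub-streams (per
# subject, per trial block), so fixtures are bit-reproducible.

#' Generate an oddball stimulus block
#'
#' A randomly permuted sequence of standards and happy/sad deviants with the
#' constraint that no two deviants occupy adjacent positions (the weakest
#' operationalization of "the same sound is never presented in quick
#' succession"). Deviants are placed by sampling distinct gaps between
#' standards.
#'
#' @param n_standard,n_happy,n_sad Stimulus counts; defaults 86/12/12 give
#'   the canonical 110-stimulus block.
#' @param seed Optional seed for reproducibility.
#' @param block_index Block number carried in the result.
#' @return A `stim_block`: `sequence` (character), `counts`, `block_index`.
#' @export
generate_block <- function(n_standard = 86, n_happy = 12, n_sad = 12,
                           seed = NULL, block_index = 1L) {
  if (n_standard < 0 || n_happy < 0 || n_sad < 0) {
    stop_docnet("parameter", "stimulus counts must be >= 0")
  }
  n_dev <- n_happy + n_sad
  if (n_dev > n_standard + 1) {
    stop_docnet("parameter",
                "cannot place %d deviants among %d standards without adjacency",
                n_dev, n_standard)
  }
  seq_out <- with_seed(seed, {
    gaps <- sort(sample.int(n_standard + 1, n_dev))          # 1-based gap ids
    deviants <- sample(c(rep("happy", n_happy), rep("sad", n_sad)))
    out <- character(0)
    di <- 1L
    for (g in seq_len(n_standard + 1)) {
      if (di <= n_dev && gaps[di] == g) {
        out <- c(out, deviants[di])
        di <- di + 1L
      }
      if (g <= n_standard) out <- c(out, "standard")
    }
    out
  })
  structure(list(sequence = seq_out,
                 counts = c(n_standard = n_standard, n_happy = n_happy,
                            n_sad = n_sad),
                 block_index = block_index),
            class = "stim_block")
}

#' Fixed scalp weight vectors for the ERP template components
#'
#' @param channel_labels Montage labels (default the 27-channel analysis set).
#' @return Named list of per-component weight vectors aligned to the montage.
#' @export
component_scalp_weights <- function(channel_labels = default_montage27()) {
  base <- list(
    N1 = c(Fz = 1, F3 = 0.8, F4 = 0.8, FC1 = 0.7, FC2 = 0.7, Cz = 0.6,
           F7 = 0.5, F8 = 0.5, Fp1 = 0.4, Fp2 = 0.4),
    P3a = c(Fz = 1, FC1 = 0.8, FC2 = 0.8, F3 = 0.7, F4 = 0.7, Cz = 0.7),
    LPP = c(Pz = 1, CP1 = 0.8, CP2 = 0.8, P3 = 0.7, P4 = 0.7, CP5 = 0.5,
            CP6 = 0.5, Cz = 0.4)
  )
  lapply(base, function(wts) {
    v <- stats::setNames(numeric(length(channel_labels)), channel_labels)
    common <- intersect(names(wts), channel_labels)
    v[common] <- wts[common]
    v
  })
}

#' ERP template time course
#'
#' Gaussian-windowed half-sine bump: zero outside `window_ms`, a half-sine
#' over the window multiplied by a Gaussian envelope centred on the window
#' midpoint (SD = width/4), scaled so the midpoint value equals `peak_uv`.
#'
#' @param times_ms Sample times in ms.
#' @param window_ms Component window.
#' @param peak_uv Peak amplitude in microvolts (signed).
#' @return Numeric vector over `times_ms`.
#' @export
erp_template <- function(times_ms, window_ms, peak_uv) {
  t0 <- window_ms[1]; t1 <- window_ms[2]
  mid <- (t0 + t1) / 2
  sdv <- (t1 - t0) / 4
  inside <- times_ms > t0 & times_ms < t1
  out <- numeric(length(times_ms))
  out[inside] <- peak_uv * sin(pi * (times_ms[inside] - t0) / (t1 - t0)) *
    exp(-0.5 * ((times_ms[inside] - mid) / sdv)^2)
  out
}

#' Simulation scenario for synthetic subjects
#'
#' Defines the study conditions the generator emulates: a stable diagonal
#' VAR(1) background on the 27-channel montage at 500 Hz, a planted
#' frontal-to-parietal directed coupling (F3 -> P3) switched on between 300
#' and 1000 ms in deviant (emotion) trials of MCS-like subjects, and
#' condition/group-gated ERP templates (N1 in both groups, larger for
#' deviants; P3a on deviants only in the MCS-like group; no LPP in either
#' patient group).
#'
#' @param n_subjects_per_group Subjects per simulated group (default 8).
#' @param n_trials_deviant,n_trials_standard Trials per subject (default 60 each).
#' @param channel_labels Montage (default [default_montage27()]).
#' @param rate,window_ms Sampling rate and epoch window.
#' @param base_ar Diagonal VAR(1) background coefficient (default 0.7).
#' @param base_cross_sd SD of the weak random cross-coupling background
#'   (default 0.03; drawn once from the scenario seed, fixed across subjects,
#'   rescaled if needed to keep the system stable). Gives every channel pair
#'   a nonzero connectivity floor, as volume-conducted cortical background
#'   does in real recordings.
#' @param noise_sd Innovation SD in microvolts (default 4).
#' @param coupling List: `source`, `sink`, `strength`, `on_ms`.
#' @param group_coupling_scale Named multipliers of the coupling strength per
#'   simulated diagnosis (default MCS = 1, UWS = 0).
#' @param erp_peaks_uv Named peaks: `n1_standard`, `n1_deviant`,
#'   `p3a_deviant_mcs`, `lpp` (microvolts).
#' @param amplitude_jitter_sd Per-subject multiplicative SD of template
#'   amplitudes (default 0.15).
#' @param seed Master seed for all sub-streams.
#' @return A `sim_scenario` list; the configured system (coupling on, at the
#'   largest group scale) is verified stable.
#' @export
simulation_scenario <- function(n_subjects_per_group = 8,
                                n_trials_deviant = 60,
                                n_trials_standard = 60,
                                channel_labels = default_montage27(),
                                rate = 500, window_ms = c(-200, 1000),
                                base_ar = 0.7, base_cross_sd = 0.03,
                                noise_sd = 3,
                                coupling = list(source = "F3", sink = "P3",
                                                strength = 0.35,
                                                on_ms = c(300, 1000)),
                                group_coupling_scale = c(MCS = 1, UWS = 0),
                                erp_peaks_uv = c(n1_standard = -2,
                                                 n1_deviant = -6,
                                                 p3a_deviant_mcs = 6,
                                                 lpp = 0),
                                amplitude_jitter_sd = 0.15,
                                seed = 1L) {
  n <- length(channel_labels)
  cross <- with_seed(derive_seed(seed, "base-cross"), {
    M <- matrix(stats::rnorm(n * n, 0, base_cross_sd), n)
    diag(M) <- 0
    M
  })
  base_A <- diag(rep(base_ar, n)) + cross
  # keep the background comfortably stable (radius <= 0.85), leaving margin
  # for the planted coupling at any realistic strength
  rad <- max(Mod(eigen(base_A, only.values = TRUE)$values))
  if (rad > 0.85) {
    cross <- cross * (0.85 - base_ar) / (rad - base_ar)
    base_A <- diag(rep(base_ar, n)) + cross
  }
  scn <- structure(list(
    n_subjects_per_group = n_subjects_per_group,
    n_trials_deviant = n_trials_deviant,
    n_trials_standard = n_trials_standard,
    channel_labels = channel_labels, rate = rate, window_ms = window_ms,
    base_ar = base_ar, base_cross_sd = base_cross_sd, base_A = base_A,
    noise_sd = noise_sd, coupling = coupling,
    group_coupling_scale = group_coupling_scale,
    erp_peaks_uv = erp_peaks_uv,
    amplitude_jitter_sd = amplitude_jitter_sd, seed = seed
  ), class = "sim_scenario")
  # stability including coupling at its largest configured scale
  A_on <- scenario_A(scn, max(scn$group_coupling_scale) * 1.8)
  if (spectral_radius_companion(array(A_on, dim = c(n, n, 1))) >= 1) {
    stop_docnet("parameter", "configured VAR system is unstable with coupling on")
  }
  scn
}

# Coefficient matrix of the scenario's VAR(1), with the planted coupling
# scaled by `gain` (0 = off).
scenario_A <- function(scn, gain) {
  n <- length(scn$channel_labels)
  A <- scn$base_A
  if (gain != 0) {
    si <- match(scn$coupling$source, scn$channel_labels)
    ki <- match(scn$coupling$sink, scn$channel_labels)
    if (is.na(si) || is.na(ki)) stop_docnet("parameter", "coupling channels not in montage")
    A[ki, si] <- A[ki, si] + gain * scn$coupling$strength
  }
  A
}

#' Simulate one subject's epochs
#'
#' Each trial is an innovation-driven sample path of the scenario's
#' time-varying VAR(1) (coupling switched on during its window in deviant
#' trials, scaled by the group multiplier and the subject's latent network
#' strength), plus condition/group-gated ERP templates. A 200-sample burn-in
#' precedes each epoch so trials start near stationarity.
#'
#' @param scn A [simulation_scenario()].
#' @param diagnosis `"MCS"` or `"UWS"` (the simulated group).
#' @param strength Latent network-strength multiplier of the coupling
#'   (default 1; drawn per subject by [generate_cohort()]).
#' @param subject_seed Seed for this subject's sub-stream.
#' @param noise_sd Override of the scenario innovation SD (0 gives the
#'   deterministic template-only limit).
#' @return A list: `epochs` (`eeg_epochs`), and `truth` (coupling schedule
#'   and per-subject template gains) for recovery tests.
#' @export
simulate_subject_epochs <- function(scn, diagnosis = c("MCS", "UWS"),
                                    strength = 1, subject_seed = 1L,
                                    noise_sd = scn$noise_sd) {
  diagnosis <- match.arg(diagnosis)
  n <- length(scn$channel_labels)
  rate <- scn$rate
  n_samp <- ms_to_samples(scn$window_ms[2] - scn$window_ms[1], rate)
  times <- scn$window_ms[1] + (seq_len(n_samp) - 1) * 1000 / rate
  gain <- unname(scn$group_coupling_scale[diagnosis]) * strength
  A_off <- scenario_A(scn, 0)
  A_on <- scenario_A(scn, gain)
  if (spectral_radius_companion(array(A_on, dim = c(n, n, 1))) >= 1) {
    stop_docnet("parameter", "subject system unstable (coupling gain %.3f)", gain)
  }
  on_idx <- times >= scn$coupling$on_ms[1] & times <= scn$coupling$on_ms[2]

  burn <- 200L
  sim_trials <- function(n_trials, schedule_on) {
    if (n_trials == 0L) return(array(0, dim = c(0, n, n_samp)))
    out <- array(0, dim = c(n_trials, n, n_samp))
    state <- matrix(0, n, n_trials)
    for (s in seq_len(burn)) {
      state <- A_off %*% state + matrix(stats::rnorm(n * n_trials, 0, noise_sd), n)
    }
    for (s in seq_len(n_samp)) {
      A <- if (schedule_on && on_idx[s]) A_on else A_off
      state <- A %*% state + matrix(stats::rnorm(n * n_trials, 0, noise_sd), n)
      out[, , s] <- t(state)
    }
    out
  }

  res <- with_seed(subject_seed, {
    dev <- sim_trials(scn$n_trials_deviant, schedule_on = TRUE)
    std <- sim_trials(scn$n_trials_standard, schedule_on = FALSE)
    jit <- 1 + stats::rnorm(3, 0, scn$amplitude_jitter_sd)   # N1, P3a, LPP gains
    list(dev = dev, std = std, jit = jit)
  })

  wts <- component_scalp_weights(scn$channel_labels)
  comps <- erp_components()
  add_template <- function(trials, comp_name, peak) {
    if (peak == 0 || dim(trials)[1] == 0) return(trials)
    tc <- erp_template(times, comps[[comp_name]]$window_ms, peak)
    bump <- outer(wts[[comp_name]], tc)     # channels x samples
    trials + aperm(array(bump, dim = c(n, n_samp, dim(trials)[1])), c(3, 1, 2))
  }
  pk <- scn$erp_peaks_uv
  gains <- stats::setNames(res$jit, c("N1", "P3a", "LPP"))
  std <- add_template(res$std, "N1", pk[["n1_standard"]] * gains[["N1"]])
  dev <- add_template(res$dev, "N1", pk[["n1_deviant"]] * gains[["N1"]])
  if (diagnosis == "MCS") {
    dev <- add_template(dev, "P3a", pk[["p3a_deviant_mcs"]] * gains[["P3a"]])
  }
  if (pk[["lpp"]] != 0) {
    dev <- add_template(dev, "LPP", pk[["lpp"]] * gains[["LPP"]])
  }

  n_dev <- dim(dev)[1]; n_std <- dim(std)[1]
  dat <- array(0, dim = c(n_dev + n_std, n, n_samp))
  if (n_dev) dat[seq_len(n_dev), , ] <- dev
  if (n_std) dat[n_dev + seq_len(n_std), , ] <- std
  stim <- c(rep(c("happy", "sad"), length.out = n_dev), rep("standard", n_std))
  ep <- eeg_epochs(dat, window_ms = scn$window_ms, rate = rate,
                   condition = c(rep("deviant", n_dev), rep("standard", n_std)),
                   channel_labels = scn$channel_labels, stimulus = stim)
  truth <- list(
    coupling = list(source = scn$coupling$source, sink = scn$coupling$sink,
                    on_ms = scn$coupling$on_ms,
                    effective_strength = gain * scn$coupling$strength),
    template_gains = gains, diagnosis = diagnosis, strength = strength
  )
  list(epochs = ep, truth = truth)
}

CRS_SUB_CAPS <- c(4L, 5L, 6L, 3L, 2L, 3L)

# Greedy decomposition of a total into the six capped sub-scores.
decompose_crs_total <- function(total) {
  total <- max(0L, min(23L, as.integer(total)))
  subs <- integer(6)
  rem <- total
  for (i in seq_along(CRS_SUB_CAPS)) {
    subs[i] <- min(CRS_SUB_CAPS[i], rem)
    rem <- rem - subs[i]
  }
  subs
}

#' Generate a synthetic cohort with planted score-network associations
#'
#' Builds a cohort table over the four cells MCS/UWS x traumatic/nontraumatic.
#' CRS-R totals are drawn around diagnosis-specific means and decomposed into
#' valid sub-scores (greedy, respecting the per-subscale maxima 4,5,6,3,2,3).
#' Each subject carries a latent network-strength scalar constructed so that,
#' within each aetiology group, the correlation between strength and CRS-R
#' total equals the configured value (defaults: 0.5 in the traumatic group,
#' 0 in the nontraumatic group). The strength scales the subject's planted
#' coupling in [simulate_subject_epochs()].
#'
#' @param n_per_cell Subjects per diagnosis-by-aetiology cell (>= 3).
#' @param rho_traumatic,rho_nontraumatic Planted correlations, in (-1, 1).
#' @param seed Seed.
#' @return A `doc_cohort` data frame with an extra `strength` column and the
#'   planted parameters in `attr(, "planted")`.
#' @export
generate_cohort <- function(n_per_cell = 8, rho_traumatic = 0.5,
                            rho_nontraumatic = 0, seed = 1L) {
  if (n_per_cell < 3) stop_docnet("parameter", "n_per_cell must be >= 3")
  if (abs(rho_traumatic) >= 1 || abs(rho_nontraumatic) >= 1) {
    stop_docnet("parameter", "planted correlations must lie in (-1, 1)")
  }
  rows <- with_seed(seed, {
    out <- list()
    idx <- 1L
    for (tg in c("traumatic", "nontraumatic")) {
      rho <- if (tg == "traumatic") rho_traumatic else rho_nontraumatic
      diag_cell <- rep(c("MCS", "UWS"), each = n_per_cell)
      n_g <- length(diag_cell)
      mu <- ifelse(diag_cell == "MCS", 9, 5)
      totals <- pmin(23L, pmax(1L, as.integer(round(mu + stats::rnorm(n_g, 0, 2.5)))))
      # plant the correlation against the realized (rounded, clipped) totals
      # exactly in-sample: the noise component is residualized against the
      # standardized totals and rescaled, so cor(strength, totals) equals the
      # configured rho by construction (the group-level invariant), not just
      # in expectation
      u <- as.numeric(scale(totals))
      if (any(!is.finite(u))) u <- rep(0, n_g)
      eps <- stats::rnorm(n_g)
      if (stats::sd(u) > 0) eps <- stats::residuals(stats::lm(eps ~ u))
      eps <- as.numeric(scale(eps))
      if (any(!is.finite(eps))) eps <- rep(0, n_g)
      strength <- 1 + 0.25 * (rho * u + sqrt(1 - rho^2) * eps)
      strength <- pmin(1.8, pmax(0.05, strength))
      etiology <- if (tg == "traumatic") rep("trauma", n_g) else {
        sample(c("hemorrhage", "anoxia"), n_g, replace = TRUE, prob = c(0.7, 0.3))
      }
      for (i in seq_len(n_g)) {
        subs <- decompose_crs_total(totals[i])
        out[[idx]] <- data.frame(
          patient_id = sprintf("S%02d", idx),
          diagnosis = diag_cell[i],
          sex = sample(c("M", "F"), 1, prob = c(0.62, 0.38)),
          age = sample(26:75, 1),
          etiology = etiology[i],
          lesion = "synthetic",
          months_since_injury = round(stats::runif(1, 0.5, 12), 1),
          crs_a = subs[1], crs_v = subs[2], crs_m = subs[3],
          crs_verbal = subs[4], crs_comm = subs[5], crs_arousal = subs[6],
          crs_total = sum(subs),
          strength = strength[i],
          stringsAsFactors = FALSE
        )
        idx <- idx + 1L
      }
    }
    out
  })
  df <- do.call(rbind, rows)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(df[setdiff(names(df), "strength")], tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cohort <- parse_cohort_table(tmp)     # run full schema validation
  cohort$strength <- df$strength
  attr(cohort, "planted") <- list(rho_traumatic = rho_traumatic,
                                  rho_nontraumatic = rho_nontraumatic,
                                  n_per_cell = n_per_cell, seed = seed)
  class(cohort) <- c("synthetic_cohort", class(cohort))
  cohort
}

#' Materialize a small default synthetic dataset on disk
#'
#' Writes a cohort TSV and, for the first subject of each simulated group,
#' plain-format epoch files — a compact fixture set for pipeline smoke tests.
#'
#' @param dir Output directory (created if needed).
#' @param scn A [simulation_scenario()] (a reduced one by default).
#' @param seed Seed.
#' @return `dir`, invisibly.
#' @export
write_fixture_dataset <- function(dir, scn = NULL, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scn <- scn %||% simulation_scenario(n_subjects_per_group = 2,
                                      n_trials_deviant = 4,
                                      n_trials_standard = 4, seed = seed)
  cohort <- generate_cohort(n_per_cell = 3, seed = derive_seed(seed, "cohort"))
  write_cohort_table(cohort, file.path(dir, "cohort.tsv"))
  for (dx in c("MCS", "UWS")) {
    sim <- simulate_subject_epochs(scn, dx,
                                   subject_seed = derive_seed(seed, "fixture", dx))
    write_epochs_plain(sim$epochs, file.path(dir, paste0("epochs_", dx)))
  }
  invisible(dir)
}
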