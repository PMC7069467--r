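# Configuration-driven orchestration: cohort -> (simulate/preprocess) ->
# ERP statistics -> time-varying MVAR -> ADTF networks -> difference
# networks and graph properties -> CRS-R association, with a JSON manifest
# and resumable intermediates.

#' Default pipeline configuration
#'
#' Nested list of all stage parameters with their defaults. Values supplied
#' in `...` (or via a YAML file, see [read_pipeline_config()]) override
#' defaults by name.
#'
#' @param ... Named overrides of top-level sections (each a list merged into
#'   the defaults), e.g. `network = list(alpha = 0.01)`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    paths = list(input_dir = NULL, output_dir = "docnet_run"),
    simulate = list(enabled = TRUE, n_per_cell = 3, n_trials_deviant = 6,
                    n_trials_standard = 6),
    preprocessing = list(band_hz = c(0.1, 30), reference = c("TP9", "TP10"),
                         window_ms = c(-200, 1000), baseline_ms = c(-200, 0),
                         reject_k = 3, montage = default_montage27()),
    kalman = list(p = 1, uc = 1e-2, smooth = TRUE, noise_mode = "scalar"),
    adtf = list(freqs_hz = 1:30, band_hz = c(1, 30), time_step_ms = 20),
    network = list(snapshots_ms = c(100, 200, 300, 600, 1000), alpha = 0.05,
                   directed_handling = "symmetrize",
                   property_window_ms = c(0, 1000)),
    stats = list(q = 0.05, erp_window_ms = c(0, 1000))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_pipeline_config(structure(cfg, class = "pipeline_config"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] sections.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_pipeline_config <- function(cfg) {
  with(cfg, {
    stopifnot(length(preprocessing$band_hz) == 2,
              preprocessing$band_hz[1] < preprocessing$band_hz[2],
              network$alpha >= 0, network$alpha <= 1,
              stats$q > 0, stats$q <= 1,
              kalman$p >= 1, kalman$uc >= 0)
  })
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Trial-averaged ADTF network of one subject
#'
#' Fits the time-varying MVAR to every selected trial independently, turns
#' each into a band-integrated ADTF network and averages trial by trial.
#'
#' @param ep An `eeg_epochs` (typically already channel-subset and baseline
#'   corrected).
#' @param condition Trials to use (default `"deviant"`, the emotion trials).
#' @param kalman_cfg A [kalman_config()].
#' @param freqs_hz,band_hz,time_step_ms Passed to [adtf_network()].
#' @return A `tv_network` averaged over the selected trials.
#' @export
subject_network <- function(ep, condition = "deviant",
                            kalman_cfg = kalman_config(),
                            freqs_hz = 1:30, band_hz = c(1, 30),
                            time_step_ms = 20) {
  sel <- subset_trials(ep, condition)
  nets <- lapply(seq_len(dim(sel$data)[1]), function(i) {
    trial <- matrix(sel$data[i, , ], nrow = dim(sel$data)[2])
    rownames(trial) <- sel$channel_labels
    model <- fit_kalman_mvaar(trial, kalman_cfg, rate = sel$rate)
    adtf_network(model, freqs_hz = freqs_hz, band_hz = band_hz,
                 time_step_ms = time_step_ms, t0_ms = sel$window_ms[1])
  })
  average_trials(nets)
}

#' Run the full analysis pipeline
#'
#' Executes cohort -> simulate/preprocess -> ERP statistics -> connectivity
#' (Kalman MVAR + ADTF) -> difference networks and graph properties ->
#' CRS-R association, writing each stage's outputs plus a JSON run manifest
#' (stages, seed, configuration hash) under `cfg$paths$output_dir`. Stages
#' whose outputs already exist are loaded, not recomputed, unless
#' `force = TRUE`.
#'
#' In simulation mode a synthetic cohort is generated and epochs are
#' simulated for every cohort subject (diagnosis and latent strength taken
#' from the cohort row); otherwise plain-format epoch files named
#' `epochs_<patient_id>` are read from `cfg$paths$input_dir` together with
#' `cohort.tsv`.
#'
#' @param cfg A [pipeline_config()].
#' @param force Recompute all stages even if intermediates exist.
#' @return A `ResultBundle` list: cohort, per-subject ERP amplitude summary,
#'   mass-univariate contrasts, difference-network snapshots, per-subject
#'   properties, associations per aetiology group, and the manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), force = FALSE) {
  out_dir <- cfg$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "docnet",
                   version = as.character(utils::packageVersion("docnet")),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   stages = list())
  stage_done <- function(name, cached, counters = NULL) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, status = if (cached) "cached" else "computed",
           counters = counters)
  }
  cache <- function(name, builder) {
    path <- file.path(out_dir, paste0(name, ".rds"))
    if (!force && file.exists(path)) {
      stage_done(name, cached = TRUE)
      return(readRDS(path))
    }
    val <- builder()
    saveRDS(val, path)
    stage_done(name, cached = FALSE)
    val
  }

  # 1: cohort ----
  cohort <- cache("cohort", function() {
    ch <- if (isTRUE(cfg$simulate$enabled)) {
      generate_cohort(n_per_cell = cfg$simulate$n_per_cell,
                      seed = derive_seed(cfg$seed, "cohort"))
    } else {
      parse_cohort_table(file.path(cfg$paths$input_dir, "cohort.tsv"))
    }
    write_cohort_table(ch, file.path(out_dir, "cohort.tsv"))
    ch
  })
  if (is.null(cohort$strength)) cohort$strength <- 1

  # 2: epochs (simulate or load + preprocess) ----
  epochs <- cache("epochs", function() {
    if (isTRUE(cfg$simulate$enabled)) {
      scn <- simulation_scenario(
        n_trials_deviant = cfg$simulate$n_trials_deviant,
        n_trials_standard = cfg$simulate$n_trials_standard,
        channel_labels = cfg$preprocessing$montage,
        window_ms = cfg$preprocessing$window_ms,
        seed = derive_seed(cfg$seed, "scenario")
      )
      lapply(seq_len(nrow(cohort)), function(i) {
        simulate_subject_epochs(
          scn, as.character(cohort$diagnosis[i]),
          strength = cohort$strength[i],
          subject_seed = derive_seed(cfg$seed, "subject", cohort$patient_id[i])
        )$epochs
      })
    } else {
      lapply(cohort$patient_id, function(id) {
        read_epochs_plain(file.path(cfg$paths$input_dir, paste0("epochs_", id)))
      })
    }
  })

  # 3: preprocess epochs (baseline, rejection, montage subset) ----
  prep <- cache("preprocess", function() {
    lapply(epochs, function(ep) {
      ep <- baseline_correct(ep, cfg$preprocessing$baseline_ms)
      rej <- reject_amplitude(ep, k = cfg$preprocessing$reject_k)
      ep <- rej$epochs
      if (!identical(ep$channel_labels, cfg$preprocessing$montage) &&
          all(cfg$preprocessing$montage %in% ep$channel_labels)) {
        ep <- select_channels(ep, cfg$preprocessing$montage)
      }
      list(epochs = ep, n_rejected = sum(rej$log$rejected))
    })
  })
  prep_eps <- lapply(prep, `[[`, "epochs")

  # 4: ERP statistics ----
  erp_res <- cache("erp", function() {
    erps_dev <- lapply(prep_eps, average_erp, condition = "deviant")
    erps_std <- lapply(prep_eps, average_erp, condition = "standard")
    comps <- erp_components()
    amp <- do.call(rbind, lapply(seq_along(erps_dev), function(i) {
      data.frame(
        patient_id = cohort$patient_id[i],
        condition = rep(c("deviant", "standard"), each = length(comps)),
        component = rep(names(comps), 2),
        amplitude_uv = c(
          vapply(comps, function(cp) measure_component(erps_dev[[i]], cp), numeric(1)),
          vapply(comps, function(cp) measure_component(erps_std[[i]], cp), numeric(1))
        ), stringsAsFactors = FALSE)
    }))
    jsonlite::write_json(amp, file.path(out_dir, "component_amplitudes.json"),
                         dataframe = "rows", digits = NA)
    contrasts <- list()
    for (dx in levels(cohort$diagnosis)) {
      idx <- cohort_rows(cohort, diagnosis = dx)
      if (length(idx) < 2) next
      res <- mass_univariate_ttest(erps_dev[idx], erps_std[idx], paired = TRUE,
                                   window_ms = cfg$stats$erp_window_ms,
                                   q = cfg$stats$q)
      write_mass_univariate_tsv(res, file.path(out_dir,
                                               paste0("erp_contrast_", dx, ".tsv")))
      contrasts[[dx]] <- res
    }
    list(amplitudes = amp, contrasts = contrasts)
  })

  # 5: connectivity (Kalman MVAR + trial-averaged ADTF) ----
  networks <- cache("connectivity", function() {
    kcfg <- kalman_config(p = cfg$kalman$p, uc = cfg$kalman$uc,
                          smooth = cfg$kalman$smooth,
                          noise_mode = cfg$kalman$noise_mode)
    lapply(prep_eps, subject_network, condition = "deviant",
           kalman_cfg = kcfg, freqs_hz = cfg$adtf$freqs_hz,
           band_hz = cfg$adtf$band_hz, time_step_ms = cfg$adtf$time_step_ms)
  })

  # 6: difference networks + graph properties ----
  net_res <- cache("network", function() {
    idx_m <- cohort_rows(cohort, diagnosis = "MCS")
    idx_u <- cohort_rows(cohort, diagnosis = "UWS")
    snaps <- if (length(idx_m) >= 2 && length(idx_u) >= 2) {
      snapshot_series(networks[idx_m], networks[idx_u],
                      times_ms = cfg$network$snapshots_ms,
                      alpha = cfg$network$alpha)
    } else list()
    for (nm in names(snaps)) {
      write_diff_network_tsv(snaps[[nm]],
                             file.path(out_dir, paste0("diff_network_", nm, ".tsv")))
    }
    props <- lapply(networks, subject_properties,
                    window_ms = cfg$network$property_window_ms,
                    directed_handling = cfg$network$directed_handling)
    ptab <- properties_table(props, subject_id = cohort$patient_id)
    utils::write.table(ptab, file.path(out_dir, "network_properties.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(snapshots = snaps, properties = ptab)
  })

  # 7: association with CRS-R ----
  assoc <- cache("associate", function() {
    out <- list()
    for (tg in levels(cohort$traumatic_group)) {
      idx <- cohort_rows(cohort, traumatic_group = tg)
      if (length(idx) >= 3) {
        out[[tg]] <- pearson_association(net_res$properties[idx, ],
                                         cohort$crs_total[idx])
      }
    }
    df <- do.call(rbind, lapply(names(out), function(tg) {
      cbind(group = tg, out[[tg]])
    }))
    if (!is.null(df)) {
      utils::write.table(df, file.path(out_dir, "associations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    out
  })

  manifest$n_subjects <- nrow(cohort)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(cohort = cohort, erp = erp_res, networks = networks,
                 network_stats = net_res, associations = assoc,
                 manifest = manifest))
}
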