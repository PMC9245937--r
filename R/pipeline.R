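# End-to-end orchestration: simulate -> quantify -> analyze, with config
# validation, stage logging and a run manifest.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every tunable parameter at
#' its documented default.  `pixel_size` is deliberately absent: at the
#' pipeline level it must always be given explicitly (never defaulted
#' silently), either in the config file or via this function's argument.
#'
#' @param pixel_size µm per pixel (required for any imaging stage).
#' @param seed integer seed for the stochastic stages.
#' @return nested configuration list.
#' @export
default_config <- function(pixel_size = NULL, seed = 1L) {
  list(
    seed = seed,
    pixel_size = pixel_size,
    simulate_images = list(n_cases = 3, neurons_per_case = 10,
                           coverage_mean = 0.30, coverage_sd = 0.02,
                           soma_area_mean = 450, soma_area_sd = 60,
                           noise_sd = 0.03, scale_range = c(0.6, 1.4)),
    quantify = list(band_halfwidth_um = 0.5,
                    normalize = list(low_pct = 1, high_pct = 99,
                                     puncta_high_pct = 99.9),
                    segmentation = seg_params(),
                    puncta = punctum_params(),
                    qc = qc_params()),
    simulate_cohort = list(enabled = TRUE),
    analyze = list(markers = c("iba1", "cd68", "tmem119"),
                   outcome = "neuron_density",
                   covariates = c("age_death", "sex", "pm_interval")))
}

validate_config <- function(config) {
  problems <- character(0)
  if (is.null(config$pixel_size))
    problems <- c(problems, "pixel_size: required, never defaulted")
  else if (!is.numeric(config$pixel_size) || config$pixel_size <= 0)
    problems <- c(problems, "pixel_size: must be a positive number")
  if (is.null(config$seed) || !is.numeric(config$seed))
    problems <- c(problems, "seed: required integer")
  sim <- config$simulate_images
  for (k in c("n_cases", "neurons_per_case"))
    if (!is.null(sim[[k]]) && sim[[k]] < 1)
      problems <- c(problems, paste0("simulate_images.", k, ": must be >= 1"))
  if (length(problems))
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(config)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Run the full pipeline from a configuration
#'
#' Executes, in order: synthetic image simulation, per-image
#' quantification (normalize, segment, detect, coverage, QC), per-case
#' aggregation, cohort simulation, and cohort statistics.  Writes CSV
#' tables, a plain-text report and a JSON run manifest under `out_dir`.
#' Outputs are bit-reproducible for a fixed config and seed.
#'
#' @param config a configuration list (see [default_config()]), or a path
#'   to a YAML file with the same structure.  Values given override the
#'   defaults; `pixel_size` must be provided.
#' @param out_dir output directory (created if needed).
#' @return the run manifest, invisibly: `config_hash`, `seed`,
#'   `tool_version`, `output_paths`, `timestamps`, per-stage row counts.
#' @export
run_pipeline <- function(config, out_dir = "synapcover_run") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  full <- merge_config(default_config(), config)
  validate_config(full)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_msg <- function(...) message("[synapcover] ", sprintf(...))

  # resolved config is echoed; its file hash identifies the run
  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(full, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  sim <- full$simulate_images
  log_msg("simulate: %d cases x %d neurons", sim$n_cases,
          sim$neurons_per_case)
  renders <- simulate_case_images(
    n_cases = sim$n_cases, neurons_per_case = sim$neurons_per_case,
    coverage_mean = sim$coverage_mean, coverage_sd = sim$coverage_sd,
    soma_area_mean = sim$soma_area_mean, soma_area_sd = sim$soma_area_sd,
    pixel_size = full$pixel_size, noise_sd = sim$noise_sd,
    scale_range = sim$scale_range, seed = full$seed)
  truth <- do.call(rbind, lapply(renders, function(r)
    data.frame(case_id = r$image$case_id, image_id = r$image$image_id,
               soma_area_um2 = r$truth$soma_area_um2,
               n_membrane_puncta = r$truth$n_membrane_puncta,
               planted_coverage = r$truth$planted_coverage,
               intensity_scale = r$truth$intensity_scale,
               degenerate_kind = r$truth$degenerate_kind)))
  truth_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)

  qp <- full$quantify
  log_msg("quantify: %d images", length(renders))
  per_neuron <- do.call(rbind, lapply(renders, function(r)
    process_image(r$image, band_halfwidth_um = qp$band_halfwidth_um,
                  seg = qp$segmentation, det = qp$puncta, qc = qp$qc,
                  low_pct = qp$normalize$low_pct,
                  high_pct = qp$normalize$high_pct,
                  puncta_high_pct = qp$normalize$puncta_high_pct)))
  neuron_path <- file.path(out_dir, "per_neuron.csv")
  utils::write.csv(per_neuron, neuron_path, row.names = FALSE)

  qc_rep <- summarize_qc(per_neuron)
  qc_path <- file.path(out_dir, "qc_report.csv")
  utils::write.csv(
    data.frame(n_photographed = qc_rep$n_photographed,
               n_deleted = qc_rep$n_deleted,
               n_retained = qc_rep$n_retained,
               percent_deleted = qc_rep$percent_deleted,
               t(qc_rep$deleted_by_reason)),
    qc_path, row.names = FALSE)

  per_case <- aggregate_case(per_neuron)
  case_path <- file.path(out_dir, "per_case.csv")
  utils::write.csv(per_case, case_path, row.names = FALSE)
  log_msg("quantify: %d/%d neurons passed QC over %d cases",
          qc_rep$n_retained, qc_rep$n_photographed, nrow(per_case))

  outputs <- c(cfg_path, truth_path, neuron_path, qc_path, case_path)
  stats_rows <- 0L
  if (isTRUE(full$simulate_cohort$enabled)) {
    cohort <- simulate_cohort(cohort_config(), seed = full$seed + 1L)
    cohort_path <- file.path(out_dir, "cohort.csv")
    write_cohort_csv(cohort, cohort_path)
    an <- full$analyze
    strat <- stratified_correlations(
      cohort[cohort$group == "MS", , drop = FALSE],
      markers = an$markers, outcome = an$outcome)
    pooled <- do.call(rbind, lapply(an$markers, function(m) {
      ms <- cohort[cohort$group == "MS", ]
      spearman(ms[[m]], ms[[an$outcome]], an$outcome, m, stratum = "MS_all")
    }))
    adj <- do.call(rbind, lapply(an$markers, function(m)
      fit_adjusted_model(cohort[cohort$group == "MS", ], an$outcome, m,
                         c(an$covariates, "fibrinogen"),
                         stratum = "MS_all")))
    stats_tab <- rbind(pooled, strat, adj)
    stats_path <- file.path(out_dir, "cohort_stats.csv")
    utils::write.csv(stats_tab, stats_path, row.names = FALSE)
    outputs <- c(outputs, cohort_path, stats_path)
    stats_rows <- nrow(stats_tab)
    log_msg("analyze: %d statistics", stats_rows)
  }

  report_path <- file.path(out_dir, "report.txt")
  writeLines(c(
    sprintf("synapcover run %s", cfg_hash),
    sprintf("photographed %d, deleted %d (%d%%), retained %d",
            qc_rep$n_photographed, qc_rep$n_deleted,
            round(qc_rep$percent_deleted), qc_rep$n_retained),
    sprintf("cases aggregated: %d", nrow(per_case)),
    sprintf("mean coverage over cases: %.4f puncta/um^2",
            mean(per_case$mean_coverage)),
    sprintf("mean neuron size over cases: %.1f um^2",
            mean(per_case$mean_neuron_size))), report_path)
  outputs <- c(outputs, report_path)

  manifest <- list(
    config_hash = cfg_hash, seed = full$seed,
    tool_version = as.character(utils::packageVersion("synapcover")),
    output_paths = outputs,
    rows = list(per_neuron = nrow(per_neuron), per_case = nrow(per_case),
                cohort_stats = stats_rows),
    timestamps = list(start = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
                      end = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
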