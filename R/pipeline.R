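# End-to-end reproducible pipeline: simulate -> QC -> classify -> mix.
# Every run is fixed by a single seed recorded in the output manifests.

#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults equal to the
#' experimental constants: compositions of the two stimulation datasets,
#' the pairing protocol, QC thresholds, the two-criterion classifier and
#' the mixing simulation.
#'
#' @param seed Integer master seed; sub-seeds for each stage are derived
#'   from it.
#' @param protocol A [protocol_params()] object.
#' @param control_composition,bicuculline_composition Outcome
#'   compositions (see [control_composition()]).
#' @param sweep_noise_cv Sweep-to-sweep noise CV of the generator.
#' @param qc A [qc_thresholds()] object.
#' @param threshold_pct,alpha,variant Classifier settings
#'   (see [classify_plasticity()]).
#' @param scs_n,strength_mean_pa,strength_sd_pa Unitary-database model
#'   (see [simulate_scs_database()]).
#' @param stop_threshold_pa,n_scr,s_grid,replace Mixing settings
#'   (see [run_mixing()] and [sweep_segregation()]).
#'
#' @return A named list (class `"pipeline_config"`).
#' @export
pipeline_config <- function(seed = 1L,
                            protocol = protocol_params(),
                            control_composition = plastmix::control_composition(),
                            bicuculline_composition = plastmix::bicuculline_composition(),
                            sweep_noise_cv = 0.10,
                            qc = qc_thresholds(),
                            threshold_pct = 15,
                            alpha = 0.05,
                            variant = "student",
                            scs_n = 43L,
                            strength_mean_pa = 19.4,
                            strength_sd_pa = 6,
                            stop_threshold_pa = 350,
                            n_scr = 26L,
                            s_grid = seq(0, 1, by = 0.1),
                            replace = TRUE) {
  cfg <- list(
    seed = check_count(seed, "seed", lower = 0L),
    protocol = protocol,
    control_composition = control_composition,
    bicuculline_composition = bicuculline_composition,
    sweep_noise_cv = check_number(sweep_noise_cv, "sweep_noise_cv", lower = 0),
    qc = qc,
    threshold_pct = threshold_pct,
    alpha = alpha,
    variant = variant,
    scs_n = check_count(scs_n, "scs_n"),
    strength_mean_pa = strength_mean_pa,
    strength_sd_pa = strength_sd_pa,
    stop_threshold_pa = stop_threshold_pa,
    n_scr = check_count(n_scr, "n_scr"),
    s_grid = s_grid,
    replace = isTRUE(replace)
  )
  structure(cfg, class = "pipeline_config")
}

stage_seeds <- function(seed, n = 6L) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate the pipeline's input datasets
#'
#' Generates the control and disinhibited sweep datasets and the
#' unitary-connection database; optionally writes them as CSV plus a JSON
#' manifest recording the seed and configuration hash.
#'
#' @param config A [pipeline_config()] object.
#' @param output_dir Directory for CSV/manifest output, or `NULL` to skip
#'   writing.
#'
#' @return A list with tibbles `control`, `bicuculline`, `scs_db`.
#' @export
run_simulate <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  control <- simulate_ecs_dataset(
    config$control_composition, protocol = config$protocol,
    condition = "control", sweep_noise_cv = config$sweep_noise_cv,
    threshold_pct = config$threshold_pct, seed = seeds[1]
  )
  bicuculline <- simulate_ecs_dataset(
    config$bicuculline_composition, protocol = config$protocol,
    condition = "bicuculline", sweep_noise_cv = config$sweep_noise_cv,
    threshold_pct = config$threshold_pct, seed = seeds[2]
  )
  scs_db <- simulate_scs_database(
    n = config$scs_n, strength_mean_pa = config$strength_mean_pa,
    strength_sd_pa = config$strength_sd_pa,
    threshold_pct = config$threshold_pct, seed = seeds[3]
  )
  out <- list(control = control, bicuculline = bicuculline, scs_db = scs_db)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_recordings(control, file.path(output_dir, "control.csv"))
    write_recordings(bicuculline, file.path(output_dir, "bicuculline.csv"))
    write_connections(scs_db, file.path(output_dir, "scs_database.csv"))
    write_manifest(config, file.path(output_dir, "manifest.json"),
                   stage = "simulate",
                   files = c("control.csv", "bicuculline.csv",
                             "scs_database.csv"))
  }
  out
}

#' QC and classify a sweep dataset
#'
#' Applies [qc_dataset()] and classifies only the cells that pass; failed
#' cells are retained in the output with their failure codes and `NA`
#' statistics, so that input counts always equal retained plus excluded.
#'
#' @param data Sweep tibble for one or more cells.
#' @param config A [pipeline_config()] object.
#'
#' @return Tibble with one row per input cell: classification columns of
#'   [classify_dataset()] plus `qc_passed` and `qc_failures`.
#' @export
run_analyze <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  qc <- qc_dataset(data, thresholds = config$qc)
  keep <- qc$cell_id[qc$passed]
  results <- classify_dataset(
    data[data$cell_id %in% keep, , drop = FALSE],
    threshold_pct = config$threshold_pct, alpha = config$alpha,
    variant = config$variant
  )
  meta <- data |>
    dplyr::distinct(.data$cell_id, .data$condition, .data$clamp_mode,
                    .data$unit)
  out <- qc |>
    select("cell_id", qc_passed = "passed", qc_failures = "failures") |>
    left_join(meta, by = "cell_id") |>
    left_join(select(results, -"condition", -"clamp_mode", -"unit"),
              by = "cell_id")
  stopifnot(nrow(out) == length(unique(data$cell_id)))
  out
}

#' Run the mixing simulation against observed percent changes
#'
#' Thin orchestration over [sweep_segregation()] using the configured
#' grid, repeat count and stopping threshold.
#'
#' @param db Connection database tibble.
#' @param reference_deltas Observed per-cell percent changes.
#' @param config A [pipeline_config()] object.
#' @param seed Seed for this stage (defaults to a sub-seed of
#'   `config$seed`).
#'
#' @return A [sweep_segregation()] table.
#' @export
run_mix <- function(db, reference_deltas, config = pipeline_config(),
                    seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- seed %||% stage_seeds(config$seed)[4]
  sweep_segregation(
    db, reference_deltas, s_grid = config$s_grid, n_scr = config$n_scr,
    stop_threshold_pa = config$stop_threshold_pa, replace = config$replace,
    alpha = config$alpha, seed = seed
  )
}

condition_summary <- function(results, data) {
  deltas <- results$delta_n_pct[results$qc_passed]
  binned <- classify_dataset(
    data[data$cell_id %in% results$cell_id[results$qc_passed], ,
         drop = FALSE],
    use_bins = TRUE
  )
  list(
    n = nrow(results),
    n_excluded = sum(!results$qc_passed),
    outcome_counts = as.list(table(factor(results$label,
                                          levels = outcome_levels()))),
    delta_mean_pct = mean(deltas),
    delta_sd_pct = sd(deltas),
    delta_mean_pct_binned = mean(binned$delta_n_pct),
    delta_sd_pct_binned = sd(binned$delta_n_pct)
  )
}

#' Run the full analysis pipeline
#'
#' Simulates both stimulation datasets and the unitary database, applies
#' QC and classification, compares the two conditions (normality, means,
#' variances), compares the unitary percent-change distribution against
#' both compound datasets (KS), and sweeps the segregation parameter of
#' the mixing simulation against the disinhibited dataset. All results
#' are returned as one report list and, if `output_dir` is given, written
#' as CSV tables plus a JSON report.
#'
#' @inheritParams run_simulate
#' @return A report list (invisibly if written to disk): elements
#'   `datasets`, `per_cell`, `comparisons`, `ks_vs_scs`, `mixing`,
#'   `provenance`.
#' @export
#' @examples
#' \donttest{
#' report <- run_pipeline(pipeline_config(seed = 1))
#' report$datasets$bicuculline$outcome_counts
#' }
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- run_simulate(config, output_dir = output_dir)

  res_control <- run_analyze(sim$control, config)
  res_bicu <- run_analyze(sim$bicuculline, config)
  per_cell <- bind_rows(res_control, res_bicu)

  d_control <- res_control$delta_n_pct[res_control$qc_passed]
  d_bicu <- res_bicu$delta_n_pct[res_bicu$qc_passed]
  d_scs <- db_deltas(sim$scs_db)

  comparisons <- list(
    shapiro_control = shapiro_wilk(d_control),
    shapiro_bicuculline = shapiro_wilk(d_bicu),
    t_control_vs_bicuculline = {
      tt <- t.test(d_control, d_bicu, var.equal = TRUE)
      test_result("t_two_sample", tt$statistic, tt$p.value,
                  length(d_control), length(d_bicu))
    },
    f_control_vs_bicuculline = f_test_variance(d_control, d_bicu)
  )
  ks_vs_scs <- list(
    control = ks_two_sample(d_scs, d_control),
    bicuculline = ks_two_sample(d_scs, d_bicu)
  )
  mixing <- run_mix(sim$scs_db, d_bicu, config)

  report <- list(
    datasets = list(
      control = condition_summary(res_control, sim$control),
      bicuculline = condition_summary(res_bicu, sim$bicuculline),
      scs_db = list(n = nrow(sim$scs_db),
                    outcome_counts = as.list(table(factor(sim$scs_db$outcome,
                                                          levels = outcome_levels()))),
                    delta_mean_pct = mean(d_scs),
                    delta_sd_pct = sd(d_scs))
    ),
    per_cell = per_cell,
    comparisons = comparisons,
    ks_vs_scs = ks_vs_scs,
    mixing = as_tibble(mixing),
    provenance = provenance(config)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(per_cell, file.path(output_dir, "per_cell_results.csv"))
    readr::write_csv(as_tibble(mixing),
                     file.path(output_dir, "segregation_sweep.csv"))
    json <- report
    json$per_cell <- NULL
    json$mixing <- NULL
    jsonlite::write_json(json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Percent changes of a connection database
#'
#' @param db Connection database tibble.
#' @return Numeric vector of per-connection percent changes.
#' @export
db_deltas <- function(db) {
  check_db(db)
  delta_n(db$strength_pre_pa, db$strength_post_pa)
}

provenance <- function(config) {
  list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("plastmix")),
    r_version = R.version.string
  )
}

write_manifest <- function(config, path, stage, files) {
  manifest <- c(list(stage = stage, files = as.list(files)),
                provenance(config))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
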