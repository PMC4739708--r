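# Recording-quality exclusions: access resistance, membrane potential and
# baseline stability.

#' Quality-control thresholds
#'
#' The exclusion rules applied to every recording before analysis:
#' access resistance above 40 MOhm or above 20% of the cell's input
#' resistance, access-resistance drift above 20% of the first reading,
#' membrane potential more positive than -60 mV, and a significant linear
#' trend (p < 0.05) in the baseline amplitude time series.
#'
#' @param max_ra_mohm Absolute access-resistance ceiling (MOhm).
#' @param max_ra_fraction_of_ri Access resistance ceiling as a fraction of
#'   input resistance.
#' @param max_ra_drift Maximum tolerated relative change of access
#'   resistance over the recording, referenced to the first reading.
#' @param max_vm_mv Membrane potentials more positive than this are
#'   rejected (mV).
#' @param baseline_trend_alpha Significance level of the baseline linear
#'   trend test.
#'
#' @return A named list of thresholds (class `"qc_thresholds"`).
#' @export
qc_thresholds <- function(max_ra_mohm = 40,
                          max_ra_fraction_of_ri = 0.20,
                          max_ra_drift = 0.20,
                          max_vm_mv = -60,
                          baseline_trend_alpha = 0.05) {
  check_number(max_ra_mohm, "max_ra_mohm", lower = 0, strict_lower = TRUE)
  check_number(max_ra_fraction_of_ri, "max_ra_fraction_of_ri", lower = 0,
               strict_lower = TRUE)
  check_number(max_ra_drift, "max_ra_drift", lower = 0, strict_lower = TRUE)
  check_number(max_vm_mv, "max_vm_mv")
  check_number(baseline_trend_alpha, "baseline_trend_alpha", lower = 0,
               upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  structure(list(max_ra_mohm = max_ra_mohm,
                 max_ra_fraction_of_ri = max_ra_fraction_of_ri,
                 max_ra_drift = max_ra_drift,
                 max_vm_mv = max_vm_mv,
                 baseline_trend_alpha = baseline_trend_alpha),
            class = "qc_thresholds")
}

#' Baseline stability by linear trend
#'
#' Ordinary least-squares fit of amplitude on time over the baseline
#' sweeps; a two-tailed slope test at `alpha` decides stability. A
#' constant series is stable by definition (slope 0, p = 1); an exact
#' nonzero linear trend has p = 0.
#'
#' @param sweeps Data frame with columns `time_s` and `amplitude`
#'   (rows with missing amplitude are dropped).
#' @param alpha Significance level.
#'
#' @return A one-row tibble with `slope` (amplitude units per second),
#'   `p_value` and `stable`.
#' @export
#' @examples
#' baseline_stability(tibble::tibble(time_s = 1:20, amplitude = rnorm(20, 100)))
baseline_stability <- function(sweeps, alpha = 0.05) {
  check_columns(sweeps, c("time_s", "amplitude"), "sweeps")
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  sweeps <- sweeps[is.finite(sweeps$amplitude), ]
  if (nrow(sweeps) < 3L) {
    stop_data("Baseline stability needs at least 3 sweeps with amplitudes.")
  }
  fit <- lm(amplitude ~ time_s, data = sweeps)
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(cf["time_s", "Estimate"])
  p <- unname(cf["time_s", "Pr(>|t|)"])
  if (!is.finite(p)) {
    # zero residual variance: exact line (p = 0) or exact constant (p = 1)
    scale <- max(abs(sweeps$amplitude), 1e-12)
    p <- if (abs(slope) * diff(range(sweeps$time_s)) < 1e-10 * scale) 1 else 0
    if (p == 1) slope <- 0
  }
  tibble(slope = slope, p_value = p, stable = p >= alpha)
}

#' Quality-control report for one recording
#'
#' Applies the five exclusion rules of [qc_thresholds()] to a single
#' cell's sweep table. Access-resistance drift is computed as
#' `|Ra_last - Ra_first| / Ra_first`; the absolute and relative ceilings
#' are checked against the maximum reading.
#'
#' @param rec Sweep tibble of one cell ([simulate_recording()] schema);
#'   must carry `ra_mohm`, `vm_mv` and `input_r_mohm`.
#' @param thresholds A [qc_thresholds()] object.
#'
#' @return One-row tibble: `cell_id`, `passed`, `failures`
#'   (semicolon-separated codes among `ra_absolute`, `ra_relative`,
#'   `ra_drift`, `vm`, `baseline_trend`; empty when passed), `ra_max_mohm`,
#'   `ra_drift_frac`, `trend_slope`, `trend_p`.
#' @export
qc_experiment <- function(rec, thresholds = qc_thresholds()) {
  check_columns(rec, c("cell_id", "epoch", "time_s", "amplitude",
                       "ra_mohm", "vm_mv", "input_r_mohm"), "rec")
  if (!inherits(thresholds, "qc_thresholds")) {
    stop_param("`thresholds` must be created by qc_thresholds().")
  }
  cell <- unique(rec$cell_id)
  if (length(cell) != 1L) {
    stop_data("`rec` must contain exactly one cell; see qc_dataset().")
  }
  ra <- rec$ra_mohm[is.finite(rec$ra_mohm)]
  if (length(ra) < 2L) {
    stop_data(sprintf("Cell %s: need at least 2 access-resistance readings.",
                      cell))
  }
  vm <- rec$vm_mv[is.finite(rec$vm_mv)]
  ri <- rec$input_r_mohm[is.finite(rec$input_r_mohm)]
  if (length(vm) == 0L) {
    stop_data(sprintf("Cell %s: membrane potential missing.", cell))
  }
  if (length(ri) == 0L) {
    stop_data(sprintf("Cell %s: input resistance missing.", cell))
  }

  ra_drift <- abs(ra[length(ra)] - ra[1]) / ra[1]
  pre <- rec[rec$epoch == "pre", c("time_s", "amplitude")]
  trend <- baseline_stability(pre, alpha = thresholds$baseline_trend_alpha)

  failures <- c(
    if (max(ra) > thresholds$max_ra_mohm) "ra_absolute",
    if (max(ra) > thresholds$max_ra_fraction_of_ri * ri[1]) "ra_relative",
    if (ra_drift > thresholds$max_ra_drift) "ra_drift",
    if (vm[1] > thresholds$max_vm_mv) "vm",
    if (!trend$stable) "baseline_trend"
  )
  tibble(
    cell_id = cell,
    passed = length(failures) == 0L,
    failures = paste(failures, collapse = ";"),
    ra_max_mohm = max(ra),
    ra_drift_frac = ra_drift,
    trend_slope = trend$slope,
    trend_p = trend$p_value
  )
}

#' Quality control over a multi-cell dataset
#'
#' @param data Sweep tibble of one or more cells.
#' @inheritParams qc_experiment
#' @return Tibble with one [qc_experiment()] row per cell.
#' @export
qc_dataset <- function(data, thresholds = qc_thresholds()) {
  check_columns(data, "cell_id", "data")
  if (nrow(data) == 0L) stop_data("`data` has no sweeps.")
  data |>
    dplyr::group_split(.data$cell_id) |>
    purrr::map(qc_experiment, thresholds = thresholds) |>
    bind_rows()
}
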