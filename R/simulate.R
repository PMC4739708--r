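# Synthetic sweep-series and connection-database generators.
#
# The generators emulate the structure of a standard pairing experiment:
# a baseline test epoch, a pairing epoch during which no responses are
# measured, and a post-pairing test epoch. Pairing is represented only as
# a partition of the time axis; no biophysics is simulated.

#' Pairing-protocol parameters
#'
#' Describes the stimulation protocol: a pre-pairing test epoch (default
#' 120 stimuli at 0.2 Hz), a pairing epoch (default 60 pairings at 0.1 Hz,
#' postsynaptic burst onset leading the stimulation pulse by 10 ms, 6-9
#' action potentials per burst) and a post-pairing test epoch (default 120
#' stimuli at 0.2 Hz, i.e. at least 10 minutes of post-test).
#'
#' @param n_pre_sweeps Number of baseline test stimuli.
#' @param pre_rate_hz Test stimulation rate (Hz) for both test epochs.
#' @param n_pairings Number of pairing repetitions.
#' @param pairing_rate_hz Pairing repetition rate (Hz).
#' @param post_lead_ms Lead of the postsynaptic burst onset over the
#'   stimulation pulse, in milliseconds.
#' @param n_ap_range Length-2 integer range of action potentials per burst.
#' @param n_post_sweeps Number of post-pairing test stimuli.
#' @param clamp_mode `"V-clamp"` (responses in pA) or `"I-clamp"` (mV).
#'
#' @return A named list of validated protocol constants (class
#'   `"protocol_params"`).
#' @export
#' @examples
#' protocol_params()
protocol_params <- function(n_pre_sweeps = 120L,
                            pre_rate_hz = 0.2,
                            n_pairings = 60L,
                            pairing_rate_hz = 0.1,
                            post_lead_ms = 10,
                            n_ap_range = c(6L, 9L),
                            n_post_sweeps = 120L,
                            clamp_mode = c("V-clamp", "I-clamp")) {
  clamp_mode <- match.arg(clamp_mode)
  p <- list(
    n_pre_sweeps = check_count(n_pre_sweeps, "n_pre_sweeps"),
    pre_rate_hz = check_number(pre_rate_hz, "pre_rate_hz", lower = 0,
                               strict_lower = TRUE),
    n_pairings = check_count(n_pairings, "n_pairings"),
    pairing_rate_hz = check_number(pairing_rate_hz, "pairing_rate_hz",
                                   lower = 0, strict_lower = TRUE),
    post_lead_ms = check_number(post_lead_ms, "post_lead_ms", lower = 0),
    n_ap_range = n_ap_range,
    n_post_sweeps = check_count(n_post_sweeps, "n_post_sweeps"),
    clamp_mode = clamp_mode
  )
  if (length(n_ap_range) != 2L || any(n_ap_range < 1L) ||
      n_ap_range[2] < n_ap_range[1]) {
    stop_param("`n_ap_range` must be an increasing pair of positive counts.")
  }
  structure(p, class = "protocol_params")
}

default_baseline_mean <- function(clamp_mode) {
  # target response sizes: ~350-400 pA under V-clamp, ~3-5 mV under I-clamp
  switch(clamp_mode, "V-clamp" = 375, "I-clamp" = 4)
}

clamp_unit <- function(clamp_mode) {
  switch(clamp_mode, "V-clamp" = "pA", "I-clamp" = "mV")
}

#' Simulate one recording (sweep time series)
#'
#' Generates the sweep table of a single cell: per-stimulus peak response
#' amplitudes around a baseline mean with multiplicative Gaussian noise,
#' an optional linear drift, a step change of `true_delta_pct` percent in
#' the post-pairing epoch, and a linearly drifting access-resistance
#' series. Pairing-epoch rows carry the event times but no amplitude
#' (responses are not tested during pairing).
#'
#' @param protocol A [protocol_params()] object.
#' @param baseline_mean Baseline response mean; defaults to 375 pA
#'   (V-clamp) or 4 mV (I-clamp).
#' @param sweep_noise_cv Coefficient of variation of sweep-to-sweep noise.
#' @param true_delta_pct Ground-truth percent change applied to the
#'   post-pairing epoch.
#' @param drift_slope Linear drift in amplitude units per test sweep
#'   (non-zero values create baseline-unstable cells).
#' @param ra_initial_mohm Initial access resistance (MOhm).
#' @param ra_drift_pct Percent change of access resistance from first to
#'   last sweep.
#' @param vm_mv Resting membrane potential (mV).
#' @param input_r_mohm Input resistance (MOhm).
#' @param cell_id,condition Identifier columns carried into the output.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble with one row per sweep/pairing event and columns
#'   `cell_id`, `condition`, `clamp_mode`, `epoch` (pre/pairing/post),
#'   `sweep`, `time_s`, `amplitude`, `unit`, `ra_mohm`, `vm_mv`,
#'   `input_r_mohm`, `true_delta_pct`.
#' @export
#' @examples
#' rec <- simulate_recording(seed = 1)
#' dplyr::count(rec, epoch)
simulate_recording <- function(protocol = protocol_params(),
                               baseline_mean = NULL,
                               sweep_noise_cv = 0.10,
                               true_delta_pct = 0,
                               drift_slope = 0,
                               ra_initial_mohm = 12,
                               ra_drift_pct = 0,
                               vm_mv = -70,
                               input_r_mohm = 150,
                               cell_id = "cell_01",
                               condition = "control",
                               seed = NULL) {
  if (!inherits(protocol, "protocol_params")) {
    stop_param("`protocol` must be created by protocol_params().")
  }
  baseline_mean <- baseline_mean %||% default_baseline_mean(protocol$clamp_mode)
  check_number(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE)
  check_number(sweep_noise_cv, "sweep_noise_cv", lower = 0)
  check_number(true_delta_pct, "true_delta_pct")
  check_number(ra_initial_mohm, "ra_initial_mohm", lower = 0,
               strict_lower = TRUE)

  with_optional_seed(seed, {
    pre_dt <- 1 / protocol$pre_rate_hz
    pair_dt <- 1 / protocol$pairing_rate_hz
    t_pre <- (seq_len(protocol$n_pre_sweeps) - 1L) * pre_dt
    t_pair <- max(t_pre) + pre_dt +
      (seq_len(protocol$n_pairings) - 1L) * pair_dt
    t_post <- max(t_pair) + pair_dt +
      (seq_len(protocol$n_post_sweeps) - 1L) * pre_dt

    n_meas <- protocol$n_pre_sweeps + protocol$n_post_sweeps
    noise <- rnorm(n_meas, mean = 0, sd = sweep_noise_cv)
    level <- c(rep(baseline_mean, protocol$n_pre_sweeps),
               rep(baseline_mean * (1 + true_delta_pct / 100),
                   protocol$n_post_sweeps))
    amp_meas <- level * (1 + noise) + drift_slope * (seq_len(n_meas) - 1L)

    epoch <- c(rep("pre", protocol$n_pre_sweeps),
               rep("pairing", protocol$n_pairings),
               rep("post", protocol$n_post_sweeps))
    time_s <- c(t_pre, t_pair, t_post)
    amplitude <- rep(NA_real_, length(time_s))
    amplitude[epoch != "pairing"] <- amp_meas

    n_total <- length(time_s)
    ra <- seq(ra_initial_mohm,
              ra_initial_mohm * (1 + ra_drift_pct / 100),
              length.out = n_total)

    tibble(
      cell_id = cell_id,
      condition = condition,
      clamp_mode = protocol$clamp_mode,
      epoch = factor(epoch, levels = c("pre", "pairing", "post")),
      sweep = seq_len(n_total),
      time_s = time_s,
      amplitude = amplitude,
      unit = clamp_unit(protocol$clamp_mode),
      ra_mohm = ra,
      vm_mv = vm_mv,
      input_r_mohm = input_r_mohm,
      true_delta_pct = true_delta_pct
    )
  })
}

# Truncated normal draw by rejection; bounds may be open (strict) or closed.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        strict = FALSE) {
  inside <- function(x) {
    if (strict) x > lower & x < upper else x >= lower & x <= upper
  }
  if (sd == 0) {
    if (!inside(mean)) {
      stop_param(sprintf(
        "Degenerate delta model: mean %g with sd 0 lies outside (%g, %g).",
        mean, lower, upper))
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (i in seq_len(1000L)) {
    cand <- rnorm(n * 4L, mean, sd)
    out <- c(out, cand[inside(cand)])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop_param("Truncated-normal rejection sampling failed; check the delta model.")
}

# class-conditional truncation bounds at the +/-15% classification boundary
delta_bounds <- function(outcome, threshold_pct = 15) {
  switch(outcome,
    LTP = list(lower = threshold_pct, upper = Inf, strict = TRUE),
    LTD = list(lower = -Inf, upper = -threshold_pct, strict = TRUE),
    NC = list(lower = -threshold_pct, upper = threshold_pct, strict = FALSE),
    stop_param(sprintf("Unknown outcome class '%s'.", outcome))
  )
}

#' Outcome compositions of the two stimulation datasets
#'
#' `bicuculline_composition()` returns the outcome composition of the
#' disinhibited (2 uM bicuculline) extracellular-stimulation dataset:
#' 7 LTP cells (+39.9 +/- 14.7%), 9 LTD cells (-38.5 +/- 20.4%) and
#' 10 NC cells (-3.0 +/- 7.6%). `control_composition()` returns the
#' intact-inhibition composition: 1 LTP, 3 LTD, 24 NC of 28, with
#' well-separated effect sizes (+/-30%) for the plastic cells and 0 for NC.
#'
#' @return A tibble with columns `outcome`, `n`, `mean_delta_pct`,
#'   `sd_delta_pct`, usable as the `composition` argument of
#'   [simulate_ecs_dataset()].
#' @export
bicuculline_composition <- function() {
  tibble(
    outcome = c("LTP", "LTD", "NC"),
    n = c(7L, 9L, 10L),
    mean_delta_pct = c(39.9, -38.5, -3.0),
    sd_delta_pct = c(14.7, 20.4, 7.6)
  )
}

#' @rdname bicuculline_composition
#' @export
control_composition <- function() {
  tibble(
    outcome = c("LTP", "LTD", "NC"),
    n = c(1L, 3L, 24L),
    mean_delta_pct = c(30, -30, 0),
    sd_delta_pct = c(0, 0, 0)
  )
}

#' Simulate an extracellular-stimulation dataset
#'
#' Generates one recording per cell with ground-truth percent changes
#' drawn from per-outcome group distributions. Draws are truncated at the
#' +/-15% classification boundary so that generated ground truth respects
#' the class definition (LTP strictly above +15, LTD strictly below -15,
#' NC within the closed band), making round-trip classification counts
#' exact for well-behaved noise.
#'
#' @param composition Tibble with columns `outcome`, `n`,
#'   `mean_delta_pct`, `sd_delta_pct` (see [bicuculline_composition()]).
#' @param protocol A [protocol_params()] object.
#' @param condition Condition label stored on every cell.
#' @param cell_prefix Prefix for generated cell ids.
#' @param threshold_pct Class boundary used for truncation (percent).
#' @param seed Optional integer seed.
#' @inheritParams simulate_recording
#' @inheritDotParams simulate_recording ra_initial_mohm ra_drift_pct vm_mv
#'   input_r_mohm drift_slope
#'
#' @return A tibble of sweeps for all cells (rows of
#'   [simulate_recording()] outputs bound together).
#' @export
#' @examples
#' ds <- simulate_ecs_dataset(control_composition(), seed = 1)
#' length(unique(ds$cell_id))
simulate_ecs_dataset <- function(composition,
                                 protocol = protocol_params(),
                                 condition = "control",
                                 baseline_mean = NULL,
                                 sweep_noise_cv = 0.10,
                                 cell_prefix = condition,
                                 threshold_pct = 15,
                                 seed = NULL,
                                 ...) {
  check_columns(composition,
                c("outcome", "n", "mean_delta_pct", "sd_delta_pct"),
                "composition")
  if (nrow(composition) == 0L || sum(composition$n) == 0L) {
    stop_param("`composition` must request at least one cell.")
  }
  if (any(composition$n < 0) || any(composition$sd_delta_pct < 0)) {
    stop_param("`composition` counts and SDs must be non-negative.")
  }
  if (!all(composition$outcome %in% outcome_levels())) {
    stop_param("`composition$outcome` must be LTP, LTD or NC.")
  }

  composition <- composition[, c("outcome", "n", "mean_delta_pct",
                                 "sd_delta_pct")]
  with_optional_seed(seed, {
    rows <- purrr::pmap(composition, function(outcome, n, mean_delta_pct,
                                              sd_delta_pct) {
      if (n == 0L) return(NULL)
      b <- delta_bounds(outcome, threshold_pct)
      tibble(
        outcome = outcome,
        true_delta_pct = rtrunc_norm(n, mean_delta_pct, sd_delta_pct,
                                     b$lower, b$upper, b$strict)
      )
    })
    truth <- bind_rows(rows)
    truth$cell_id <- sprintf("%s_%02d", cell_prefix, seq_len(nrow(truth)))
    recs <- purrr::map2(truth$cell_id, truth$true_delta_pct, function(id, d) {
      simulate_recording(protocol = protocol, baseline_mean = baseline_mean,
                         sweep_noise_cv = sweep_noise_cv,
                         true_delta_pct = d, cell_id = id,
                         condition = condition, ...)
    })
    bind_rows(recs)
  })
}

#' Empirical outcome frequencies of the unitary-connection dataset
#'
#' Class frequencies of pairing outcomes observed across unitary
#' (single-cell stimulation) connections: 7/43 LTP, 18/43 LTD, 18/43 NC.
#'
#' @return Named probability vector over LTP/LTD/NC.
#' @export
scs_outcome_probs <- function() {
  c(LTP = 7 / 43, LTD = 18 / 43, NC = 18 / 43)
}

#' Per-outcome effect-size models for the synthetic unitary database
#'
#' The per-connection percent changes of the unitary dataset are not
#' published; as a synthetic stand-in the generator reuses the printed
#' compound-stimulation group statistics under disinhibition
#' (+39.9 +/- 14.7 for LTP, -38.5 +/- 20.4 for LTD, -3.0 +/- 7.6 for NC),
#' truncated at the class boundary.
#'
#' @return Tibble with columns `outcome`, `mean_delta_pct`, `sd_delta_pct`.
#' @export
scs_delta_models <- function() {
  tibble(
    outcome = c("LTP", "LTD", "NC"),
    mean_delta_pct = c(39.9, -38.5, -3.0),
    sd_delta_pct = c(14.7, 20.4, 7.6)
  )
}

#' Simulate a unitary-connection (SCS) database
#'
#' Generates `n` unitary connections: pre-pairing strengths from a
#' truncated-positive normal model (default mean 19.4 pA, so that a
#' typical compound response of 350 pA is reached after about 18
#' connections), outcome labels drawn multinomially, and post-pairing
#' strengths obtained by applying an outcome-conditional percent change.
#'
#' @param n Number of connections (default 43).
#' @param outcome_probs Named probability triple over LTP/LTD/NC.
#' @param strength_mean_pa,strength_sd_pa Normal model of the pre-pairing
#'   unitary strength (pA), truncated at 0.
#' @param delta_models Tibble with per-outcome `mean_delta_pct` and
#'   `sd_delta_pct` (see [scs_delta_models()]).
#' @param threshold_pct Class boundary used to truncate per-outcome
#'   percent changes.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `conn_id`, `strength_pre_pa`,
#'   `strength_post_pa`, `outcome`, `delta_n_pct`.
#' @export
#' @examples
#' db <- simulate_scs_database(seed = 1)
#' dplyr::count(db, outcome)
simulate_scs_database <- function(n = 43L,
                                  outcome_probs = scs_outcome_probs(),
                                  strength_mean_pa = 19.4,
                                  strength_sd_pa = 6,
                                  delta_models = scs_delta_models(),
                                  threshold_pct = 15,
                                  seed = NULL) {
  n <- check_count(n, "n")
  outcome_probs <- check_outcome_probs(outcome_probs)
  check_number(strength_mean_pa, "strength_mean_pa", lower = 0,
               strict_lower = TRUE)
  check_number(strength_sd_pa, "strength_sd_pa", lower = 0)
  check_columns(delta_models, c("outcome", "mean_delta_pct", "sd_delta_pct"),
                "delta_models")

  with_optional_seed(seed, {
    outcome <- sample(outcome_levels(), n, replace = TRUE,
                      prob = outcome_probs)
    strength_pre <- rtrunc_norm(n, strength_mean_pa, strength_sd_pa,
                                lower = 0, strict = TRUE)
    delta <- vapply(outcome, function(o) {
      m <- delta_models[delta_models$outcome == o, ]
      if (nrow(m) != 1L) {
        stop_param(sprintf("`delta_models` must have one row for '%s'.", o))
      }
      b <- delta_bounds(o, threshold_pct)
      rtrunc_norm(1L, m$mean_delta_pct, m$sd_delta_pct,
                  b$lower, b$upper, b$strict)
    }, numeric(1))
    tibble(
      conn_id = sprintf("conn_%02d", seq_len(n)),
      strength_pre_pa = strength_pre,
      strength_post_pa = strength_pre * (1 + delta / 100),
      outcome = outcome,
      delta_n_pct = delta
    )
  })
}

# CSV input/output ------------------------------------------------------------

recording_csv_cols <- c("cell_id", "condition", "clamp_mode", "epoch",
                        "time_s", "amplitude", "unit", "ra_mohm")

#' Read and write sweep datasets and connection databases
#'
#' Flat CSV formats: sweep datasets carry one row per sweep
#' (`cell_id, condition, clamp_mode, epoch, time_s, amplitude, unit,
#' ra_mohm, vm_mv, input_r_mohm`), connection databases one row per
#' unitary connection (`conn_id, strength_pre_pa, strength_post_pa,
#' outcome, delta_n_pct`).
#'
#' @param data Tibble to write.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name plastmix_io
NULL

#' @rdname plastmix_io
#' @export
write_recordings <- function(data, path) {
  check_columns(data, recording_csv_cols, "data")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname plastmix_io
#' @export
read_recordings <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(data, recording_csv_cols, basename(path))
  data$epoch <- factor(data$epoch, levels = c("pre", "pairing", "post"))
  data
}

connection_csv_cols <- c("conn_id", "strength_pre_pa", "strength_post_pa",
                         "outcome", "delta_n_pct")

#' @rdname plastmix_io
#' @export
write_connections <- function(data, path) {
  check_columns(data, connection_csv_cols, "data")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname plastmix_io
#' @export
read_connections <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(data, connection_csv_cols, basename(path))
  data
}
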