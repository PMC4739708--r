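# Two-criterion plasticity classification: a significant pre/post change
# (two-tailed t-test, p < 0.05) whose magnitude exceeds 15%.

#' Normalized percent change in response strength
#'
#' `100 * (post - pre) / pre`, the normalized strength change applied to
#' single experiments and to simulated compound responses alike.
#'
#' @param pre_mean,post_mean Mean response strengths (same units);
#'   `pre_mean` must be positive. Vectorized.
#' @return Percent change (numeric).
#' @export
#' @examples
#' delta_n(100, 159.4)
delta_n <- function(pre_mean, post_mean) {
  if (!is.numeric(pre_mean) || !is.numeric(post_mean)) {
    stop_param("`pre_mean` and `post_mean` must be numeric.")
  }
  if (any(!is.finite(pre_mean)) || any(pre_mean <= 0)) {
    stop_param("`pre_mean` must be positive and finite.")
  }
  100 * (post_mean - pre_mean) / pre_mean
}

#' Classify the plasticity outcome of one experiment
#'
#' Labels an experiment LTP if the post-pairing amplitudes show a
#' statistically significant increase (two-sample two-tailed t-test,
#' `p < alpha`) whose magnitude exceeds `threshold_pct` percent of the
#' baseline mean, LTD for a significant decrease beyond the threshold,
#' and NC otherwise. Significance alone is not sufficient: a significant
#' +10% change is NC. The threshold is strict (exactly +15.0% is NC).
#'
#' @param pre,post Numeric amplitude vectors (missing values dropped;
#'   at least 2 values each).
#' @param threshold_pct Magnitude threshold (percent) for a plastic label.
#' @param alpha Significance level of the t-test.
#' @param variant `"student"` for the classical pooled-variance t-test
#'   (default) or `"welch"`.
#'
#' @return One-row tibble: `delta_n_pct`, `p_value`, `label`, `pre_mean`,
#'   `post_mean`, `n_pre`, `n_post`.
#' @export
#' @examples
#' classify_plasticity(rnorm(120, 100, 10), rnorm(120, 140, 10))
classify_plasticity <- function(pre, post, threshold_pct = 15, alpha = 0.05,
                                variant = c("student", "welch")) {
  variant <- match.arg(variant)
  check_number(threshold_pct, "threshold_pct", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  pre <- pre[is.finite(pre)]
  post <- post[is.finite(post)]
  if (length(pre) < 2L || length(post) < 2L) {
    stop_data("Need at least 2 finite amplitudes in each epoch.")
  }

  pre_mean <- mean(pre)
  post_mean <- mean(post)
  if (sd(pre) == 0 && sd(post) == 0) {
    # degenerate: no within-epoch variability to test against
    p <- if (isTRUE(all.equal(pre_mean, post_mean))) 1 else 0
  } else {
    p <- t.test(post, pre, var.equal = (variant == "student"))$p.value
  }
  dn <- delta_n(pre_mean, post_mean)
  label <- if (p < alpha && dn > threshold_pct) {
    "LTP"
  } else if (p < alpha && dn < -threshold_pct) {
    "LTD"
  } else {
    "NC"
  }
  tibble(delta_n_pct = dn, p_value = p, label = label,
         pre_mean = pre_mean, post_mean = post_mean,
         n_pre = length(pre), n_post = length(post))
}

#' Classify every cell of a sweep dataset
#'
#' Splits a sweep table by cell, compares pre- against post-epoch
#' amplitudes with [classify_plasticity()], and optionally also reports a
#' binned variant of the percent change (computed from minute-average
#' bins rather than raw sweeps).
#'
#' @param data Sweep tibble ([simulate_recording()] schema) for one or
#'   more cells; each cell must carry a single amplitude unit.
#' @param use_bins If `TRUE`, run the t-test and percent change on
#'   per-bin means instead of raw sweeps.
#' @param bin_s Bin width in seconds for the binned variant.
#' @inheritParams classify_plasticity
#'
#' @return Tibble with one row per cell: `cell_id`, `condition`,
#'   `clamp_mode`, `unit`, `n_pre`, `n_post`, `pre_mean`, `post_mean`,
#'   `delta_n_pct`, `p_value`, `label`.
#' @export
#' @examples
#' ds <- simulate_ecs_dataset(control_composition(), seed = 1)
#' dplyr::count(classify_dataset(ds), label)
classify_dataset <- function(data, threshold_pct = 15, alpha = 0.05,
                             variant = c("student", "welch"),
                             use_bins = FALSE, bin_s = 60) {
  variant <- match.arg(variant)
  check_columns(data, c("cell_id", "condition", "clamp_mode", "epoch",
                        "time_s", "amplitude", "unit"), "data")
  if (nrow(data) == 0L) stop_data("`data` has no sweeps.")
  data |>
    dplyr::group_split(.data$cell_id) |>
    purrr::map(function(rec) {
      if (length(unique(rec$unit)) != 1L) {
        stop_data(sprintf("Cell %s mixes amplitude units.", rec$cell_id[1]))
      }
      if (use_bins) {
        binned <- rec |>
          filter(is.finite(.data$amplitude)) |>
          mutate(bin = floor(.data$time_s / bin_s)) |>
          group_by(.data$epoch, .data$bin) |>
          summarise(amplitude = mean(.data$amplitude), .groups = "drop")
        pre <- binned$amplitude[binned$epoch == "pre"]
        post <- binned$amplitude[binned$epoch == "post"]
      } else {
        pre <- rec$amplitude[rec$epoch == "pre"]
        post <- rec$amplitude[rec$epoch == "post"]
      }
      res <- classify_plasticity(pre, post, threshold_pct = threshold_pct,
                                 alpha = alpha, variant = variant)
      bind_cols(
        tibble(cell_id = rec$cell_id[1], condition = rec$condition[1],
               clamp_mode = rec$clamp_mode[1], unit = rec$unit[1]),
        res[, c("n_pre", "n_post", "pre_mean", "post_mean",
                "delta_n_pct", "p_value", "label")]
      )
    }) |>
    bind_rows()
}

#' Binned, baseline-normalized time plot
#'
#' Minute-average time course of the response, normalized to the
#' pre-pairing mean of each cell (so the baseline normalized mean is 1 by
#' construction). Cells are pooled within bins; bars are SEM over the
#' pooled sweeps.
#'
#' @param data Sweep tibble for one or more cells.
#' @param bin_s Bin width in seconds (default 60).
#'
#' @return Tibble with `bin_start_s`, `epoch`, `n_sweeps`, `mean_norm`,
#'   `sem_norm`.
#' @export
#' @examples
#' bin_timeplot(simulate_recording(seed = 1))
bin_timeplot <- function(data, bin_s = 60) {
  check_columns(data, c("cell_id", "epoch", "time_s", "amplitude"), "data")
  check_number(bin_s, "bin_s", lower = 0, strict_lower = TRUE)
  if (nrow(data) == 0L) stop_data("`data` has no sweeps.")

  data |>
    filter(is.finite(.data$amplitude)) |>
    group_by(.data$cell_id) |>
    mutate(norm = .data$amplitude /
             mean(.data$amplitude[.data$epoch == "pre"])) |>
    ungroup() |>
    mutate(bin_start_s = floor(.data$time_s / bin_s) * bin_s) |>
    group_by(.data$bin_start_s) |>
    summarise(
      epoch = .data$epoch[1],
      n_sweeps = dplyr::n(),
      mean_norm = mean(.data$norm),
      sem_norm = if (dplyr::n() > 1L) sd(.data$norm) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    ) |>
    arrange(.data$bin_start_s)
}
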