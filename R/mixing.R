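# Simulated compound responses (SCRs): sequential sampling of unitary
# connections to a strength threshold, with a segregation parameter S
# biasing later draws toward the plasticity class of the first draw.

check_db <- function(db) {
  check_columns(db, c("conn_id", "strength_pre_pa", "strength_post_pa",
                      "outcome"), "db")
  if (nrow(db) == 0L) stop_data("Connection database is empty.")
  if (any(!is.finite(db$strength_pre_pa)) || any(db$strength_pre_pa <= 0)) {
    stop_data("All `strength_pre_pa` values must be positive.")
  }
  if (!all(db$outcome %in% outcome_levels())) {
    stop_data("`db$outcome` must be LTP, LTD or NC.")
  }
  invisible(db)
}

empirical_outcome_probs <- function(db) {
  tab <- table(factor(db$outcome, levels = outcome_levels()))
  check_outcome_probs(as.numeric(tab) / nrow(db))
}

#' Segregation-biased outcome draw
#'
#' After the first connection of a compound response is drawn, each
#' subsequent connection's plasticity class is the first draw's class
#' with probability `s`, and otherwise an independent draw from
#' `outcome_probs`. The probability of matching the first class is
#' therefore `s + (1 - s) * p(first)`: linear in `s`, equal to the
#' marginal probability at `s = 0` and to 1 at `s = 1`.
#'
#' @param first_outcome Class of the first draw (`"LTP"`, `"LTD"`, `"NC"`).
#' @param s Segregation parameter in `[0, 1]`.
#' @param outcome_probs Named marginal probabilities over LTP/LTD/NC.
#' @param n Number of draws (vectorized; consumes the current RNG stream).
#'
#' @return Character vector of `n` outcome classes.
#' @export
#' @examples
#' set.seed(1)
#' table(draw_outcome("LTP", s = 0.5, n = 1000))
draw_outcome <- function(first_outcome, s, outcome_probs = scs_outcome_probs(),
                         n = 1L) {
  if (!is.character(first_outcome) || length(first_outcome) != 1L ||
      !first_outcome %in% outcome_levels()) {
    stop_param("`first_outcome` must be one of LTP, LTD, NC.")
  }
  check_number(s, "s", lower = 0, upper = 1)
  outcome_probs <- check_outcome_probs(outcome_probs)
  n <- check_count(n, "n")
  base <- sample(outcome_levels(), n, replace = TRUE, prob = outcome_probs)
  if (s == 0) return(base)
  ifelse(runif(n) < s, first_outcome, base)
}

# Core sampler, returning a bare list (run_mixing builds tibbles in bulk).
scr_draw <- function(db, s, stop_threshold_pa, outcome_probs, replace,
                     class_idx) {
  first <- sample(outcome_levels(), 1L, prob = outcome_probs)
  used <- integer(0)
  outcomes <- character(0)
  total_pre <- 0
  total_post <- 0
  last_strength <- NA_real_
  repeat {
    o <- if (length(used) == 0L) {
      first
    } else {
      draw_outcome(first, s, outcome_probs, n = 1L)
    }
    pool <- class_idx[[o]]
    if (!replace) pool <- setdiff(pool, used)
    if (length(pool) == 0L) {
      stop_data(sprintf(
        "Outcome class '%s' exhausted before reaching %g pA (without-replacement sampling).",
        o, stop_threshold_pa), class = "plastmix_error_exhausted")
    }
    i <- pool[sample.int(length(pool), 1L)]
    used <- c(used, i)
    outcomes <- c(outcomes, o)
    last_strength <- db$strength_pre_pa[i]
    total_pre <- total_pre + last_strength
    total_post <- total_post + db$strength_post_pa[i]
    if (total_pre >= stop_threshold_pa) break
  }
  list(
    member_ids = db$conn_id[used],
    n_inputs = length(used),
    scr_pre_pa = total_pre,
    scr_post_pa = total_post,
    last_strength_pa = last_strength,
    delta_n_pct = delta_n(total_pre, total_post),
    first_outcome = first,
    homogeneous = all(outcomes == first)
  )
}

#' Build one simulated compound response
#'
#' Sequentially samples unitary connections from `db` until their
#' combined pre-pairing strength reaches `stop_threshold_pa` (default
#' 350 pA, the typical size of a compound extracellularly evoked
#' response). The first connection's class is drawn from
#' `outcome_probs`; subsequent classes via [draw_outcome()] with
#' segregation `s`; the member within a class is uniform. Sampling is
#' with replacement by default (a small class cannot otherwise sum to the
#' threshold at `s = 1`).
#'
#' @param db Connection database tibble (`conn_id`, `strength_pre_pa`,
#'   `strength_post_pa`, `outcome`).
#' @param s Segregation parameter in `[0, 1]`.
#' @param stop_threshold_pa Stopping threshold for the summed
#'   pre-pairing strength (pA).
#' @param outcome_probs Marginal class probabilities; default
#'   (`NULL`) uses the empirical class frequencies of `db`.
#' @param replace Sample members with replacement within an SCR. With
#'   `replace = FALSE` an exhausted class raises an error naming it.
#'
#' @return One-row tibble: `n_inputs`, `scr_pre_pa`, `scr_post_pa`,
#'   `last_strength_pa`, `delta_n_pct`, `first_outcome`, `homogeneous`,
#'   plus a `member_ids` list-column. Consumes the current RNG stream.
#' @export
#' @examples
#' db <- simulate_scs_database(seed = 1)
#' set.seed(2)
#' build_scr(db, s = 1)
build_scr <- function(db, s = 0, stop_threshold_pa = 350,
                      outcome_probs = NULL, replace = TRUE) {
  check_db(db)
  check_number(s, "s", lower = 0, upper = 1)
  check_number(stop_threshold_pa, "stop_threshold_pa", lower = 0,
               strict_lower = TRUE)
  outcome_probs <- if (is.null(outcome_probs)) {
    empirical_outcome_probs(db)
  } else {
    check_outcome_probs(outcome_probs)
  }
  class_idx <- split(seq_len(nrow(db)),
                     factor(db$outcome, levels = outcome_levels()))
  empty <- names(outcome_probs)[outcome_probs > 0 &
                                  lengths(class_idx[names(outcome_probs)]) == 0]
  if (length(empty) > 0L) {
    stop_data(sprintf("Outcome class(es) %s have sampling probability > 0 but no entries.",
                      paste(empty, collapse = ", ")))
  }
  x <- scr_draw(db, s, stop_threshold_pa, outcome_probs, replace, class_idx)
  tibble(n_inputs = x$n_inputs, scr_pre_pa = x$scr_pre_pa,
         scr_post_pa = x$scr_post_pa, last_strength_pa = x$last_strength_pa,
         delta_n_pct = x$delta_n_pct, first_outcome = x$first_outcome,
         homogeneous = x$homogeneous, member_ids = list(x$member_ids))
}

#' Run the input-mixing simulation at one segregation value
#'
#' Draws `n_scr` independent simulated compound responses (default 26,
#' matching the size of the observed compound-stimulation dataset) from
#' one seeded RNG stream.
#'
#' @inheritParams build_scr
#' @param n_scr Number of SCRs.
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `"mixing_run"` with one row per SCR
#'   (`scr_id`, `s`, plus the [build_scr()] columns). Summaries via
#'   [glance()].
#' @export
#' @examples
#' db <- simulate_scs_database(seed = 1)
#' run <- run_mixing(db, s = 0, n_scr = 26, seed = 2)
#' glance(run)
run_mixing <- function(db, s = 0, n_scr = 26L, stop_threshold_pa = 350,
                       outcome_probs = NULL, replace = TRUE, seed = NULL) {
  check_db(db)
  check_number(s, "s", lower = 0, upper = 1)
  n_scr <- check_count(n_scr, "n_scr")
  check_number(stop_threshold_pa, "stop_threshold_pa", lower = 0,
               strict_lower = TRUE)
  probs <- if (is.null(outcome_probs)) {
    empirical_outcome_probs(db)
  } else {
    check_outcome_probs(outcome_probs)
  }
  class_idx <- split(seq_len(nrow(db)),
                     factor(db$outcome, levels = outcome_levels()))
  empty <- names(probs)[probs > 0 & lengths(class_idx[names(probs)]) == 0]
  if (length(empty) > 0L) {
    stop_data(sprintf("Outcome class(es) %s have sampling probability > 0 but no entries.",
                      paste(empty, collapse = ", ")))
  }

  draws <- with_optional_seed(seed, {
    purrr::map(seq_len(n_scr), function(i) {
      scr_draw(db, s, stop_threshold_pa, probs, replace, class_idx)
    })
  })
  out <- tibble(
    scr_id = seq_len(n_scr),
    s = s,
    n_inputs = purrr::map_int(draws, "n_inputs"),
    scr_pre_pa = purrr::map_dbl(draws, "scr_pre_pa"),
    scr_post_pa = purrr::map_dbl(draws, "scr_post_pa"),
    last_strength_pa = purrr::map_dbl(draws, "last_strength_pa"),
    delta_n_pct = purrr::map_dbl(draws, "delta_n_pct"),
    first_outcome = purrr::map_chr(draws, "first_outcome"),
    homogeneous = purrr::map_lgl(draws, "homogeneous"),
    member_ids = purrr::map(draws, "member_ids")
  )
  structure(out,
            class = c("mixing_run", class(out)),
            params = list(s = s, n_scr = n_scr,
                          stop_threshold_pa = stop_threshold_pa,
                          outcome_probs = probs, replace = replace,
                          seed = seed))
}

#' Sweep the segregation parameter against a reference distribution
#'
#' Runs the mixing simulation at every value of `s_grid` and compares the
#' variance of the simulated percent changes against the variance of an
#' observed reference (e.g. the per-cell percent changes of the
#' disinhibited compound-stimulation dataset) with the two-sided variance
#' F-test.
#'
#' @inheritParams run_mixing
#' @param reference_deltas Numeric vector of observed percent changes
#'   (length >= 2, non-degenerate).
#' @param s_grid Segregation values (default 0 to 1 in 0.1 increments).
#' @param alpha Significance level for flagging a lower variance.
#'
#' @return A tibble of class `"segregation_sweep"`: one row per `s` with
#'   `n_scr`, `mean_delta_pct`, `var_delta`, `f_statistic`, `p_value` and
#'   `variance_lower` (simulated variance significantly below the
#'   reference). The reference variance is stored as attribute
#'   `reference_variance`.
#' @export
#' @examples
#' db <- simulate_scs_database(seed = 1)
#' ref <- rnorm(26, 0, 35)
#' sweep_segregation(db, ref, s_grid = c(0, 1), n_scr = 50, seed = 3)
sweep_segregation <- function(db, reference_deltas,
                              s_grid = seq(0, 1, by = 0.1),
                              n_scr = 26L, stop_threshold_pa = 350,
                              outcome_probs = NULL, replace = TRUE,
                              alpha = 0.05, seed = NULL) {
  if (!is.numeric(reference_deltas) || length(reference_deltas) < 2L) {
    stop_param("`reference_deltas` must hold at least 2 values.")
  }
  if (var(reference_deltas) == 0) {
    stop_param("`reference_deltas` has zero variance.")
  }
  if (!is.numeric(s_grid) || length(s_grid) == 0L ||
      any(s_grid < 0 | s_grid > 1)) {
    stop_param("`s_grid` must contain values in [0, 1].")
  }
  ref_var <- var(reference_deltas)

  rows <- with_optional_seed(seed, {
    purrr::map(s_grid, function(s) {
      run <- run_mixing(db, s = s, n_scr = n_scr,
                        stop_threshold_pa = stop_threshold_pa,
                        outcome_probs = outcome_probs, replace = replace)
      ft <- f_test_variance(run$delta_n_pct, reference_deltas)
      tibble(s = s, n_scr = n_scr,
             mean_delta_pct = mean(run$delta_n_pct),
             var_delta = var(run$delta_n_pct),
             f_statistic = ft$statistic, p_value = ft$p_value,
             variance_lower = ft$p_value < alpha & var(run$delta_n_pct) < ref_var)
    })
  })
  out <- bind_rows(rows)
  structure(out, class = c("segregation_sweep", class(out)),
            reference_variance = ref_var,
            n_reference = length(reference_deltas))
}

#' Closed-form large-segregation variance limit
#'
#' At `s = 1` every compound response is drawn from a single plasticity
#' class, so with many inputs per response its percent change
#' concentrates near the strength-weighted mean change of that class.
#' The variance of the percent changes then approaches the between-class
#' variance of those class means under the first-draw probabilities:
#' `sum(p * d^2) - (sum(p * d))^2` with
#' `d_c = 100 * (sum(post_c) - sum(pre_c)) / sum(pre_c)`.
#'
#' @inheritParams build_scr
#' @return The limiting variance (percent squared).
#' @export
segregation_variance_limit <- function(db, outcome_probs = NULL) {
  check_db(db)
  probs <- if (is.null(outcome_probs)) {
    empirical_outcome_probs(db)
  } else {
    check_outcome_probs(outcome_probs)
  }
  d <- vapply(outcome_levels(), function(o) {
    sub <- db[db$outcome == o, ]
    if (nrow(sub) == 0L) return(NA_real_)
    delta_n(sum(sub$strength_pre_pa), sum(sub$strength_post_pa))
  }, numeric(1))
  keep <- probs > 0
  if (any(is.na(d[keep]))) {
    stop_data("A class with positive probability has no entries.")
  }
  sum(probs[keep] * d[keep]^2) - sum(probs[keep] * d[keep])^2
}

# broom-style accessors --------------------------------------------------------

#' @rdname run_mixing
#' @param x A `mixing_run` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mixing_run <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mixing_run")
  attr(out, "params") <- NULL
  out
}

#' @rdname run_mixing
#' @exportS3Method generics::glance
glance.mixing_run <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    s = p$s,
    n_scr = nrow(x),
    mean_delta_pct = mean(x$delta_n_pct),
    var_delta = var(x$delta_n_pct),
    sd_delta = sd(x$delta_n_pct),
    n_inputs_mean = mean(x$n_inputs),
    n_inputs_sd = sd(x$n_inputs),
    prop_homogeneous = mean(x$homogeneous)
  )
}
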