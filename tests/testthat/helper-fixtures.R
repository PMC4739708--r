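# Fixtures are generated in code; no files are read.

# short protocol for cheap sweep-level tests
short_protocol <- function(n = 20L) {
  protocol_params(n_pre_sweeps = n, n_pairings = 5L, n_post_sweeps = n)
}

# database of identical-strength connections with fixed per-class deltas
uniform_db <- function(strength_pa = 20, n_per_class = c(LTP = 5L, LTD = 5L,
                                                         NC = 5L),
                       class_delta = c(LTP = 50, LTD = -50, NC = 0)) {
  rows <- purrr::imap(as.list(n_per_class), function(k, o) {
    tibble::tibble(
      outcome = rep(o, k),
      strength_pre_pa = strength_pa,
      strength_post_pa = strength_pa * (1 + class_delta[[o]] / 100)
    )
  })
  db <- dplyr::bind_rows(rows)
  db$conn_id <- sprintf("u%02d", seq_len(nrow(db)))
  db$delta_n_pct <- delta_n(db$strength_pre_pa, db$strength_post_pa)
  db[, c("conn_id", "strength_pre_pa", "strength_post_pa", "outcome",
         "delta_n_pct")]
}

# independent closed-form OLS slope test (oracle for baseline_stability)
ols_slope_test <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  rss <- sum((y - intercept - slope * t)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, t = tstat, p = 2 * pt(-abs(tstat), df = n - 2))
}

# independent pooled-variance two-sample t-test (oracle for the classifier)
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
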