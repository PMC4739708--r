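test_that("protocol timing and epoch counts follow the stimulation constants", {
  rec <- simulate_recording(seed = 1)
  counts <- table(rec$epoch)
  expect_equal(unname(counts[c("pre", "pairing", "post")]),
               c(120L, 60L, 120L), ignore_attr = TRUE)

  t_pre <- rec$time_s[rec$epoch == "pre"]
  t_pair <- rec$time_s[rec$epoch == "pairing"]
  expect_equal(diff(range(t_pre)), 595)     # 120 sweeps at 0.2 Hz
  expect_equal(diff(range(t_pair)), 590)    # 60 pairings at 0.1 Hz
  expect_true(all(diff(rec$time_s) > 0))
  expect_true(max(t_pre) < min(t_pair))
  expect_true(max(t_pair) < min(rec$time_s[rec$epoch == "post"]))
  expect_true(all(is.na(rec$amplitude[rec$epoch == "pairing"])))
})

test_that("generated amplitudes respect the null and effect-size contracts", {
  # null generator: epoch means within 3 noise SEs of each other
  rec0 <- simulate_recording(true_delta_pct = 0, seed = 11)
  se <- 0.10 * 375 * sqrt(2 / 120)
  d <- mean(rec0$amplitude[rec0$epoch == "post"], na.rm = TRUE) -
    mean(rec0$amplitude[rec0$epoch == "pre"], na.rm = TRUE)
  expect_lt(abs(d), 3 * se)

  # potentiation example: +59.4% on a 100 pA baseline
  rec <- simulate_recording(baseline_mean = 100, true_delta_pct = 59.4,
                            seed = 12)
  post_mean <- mean(rec$amplitude[rec$epoch == "post"], na.rm = TRUE)
  sem <- 0.10 * 159.4 / sqrt(120)
  expect_lt(abs(post_mean - 159.4), 3 * sem)
})

test_that("generators are deterministic given a seed and leave RNG state alone", {
  a <- simulate_recording(seed = 5)
  set.seed(99)
  b <- simulate_recording(seed = 5)
  expect_identical(a, b)

  d1 <- simulate_ecs_dataset(bicuculline_composition(), seed = 7)
  d2 <- simulate_ecs_dataset(bicuculline_composition(), seed = 7)
  expect_identical(d1, d2)

  db1 <- simulate_scs_database(seed = 3)
  db2 <- simulate_scs_database(seed = 3)
  expect_identical(db1, db2)
})

test_that("dataset composition is count-exact with class-boundary truncation", {
  ds <- simulate_ecs_dataset(bicuculline_composition(), seed = 2)
  truth <- dplyr::distinct(ds, cell_id, true_delta_pct)
  expect_equal(nrow(truth), 26L)
  expect_equal(sum(truth$true_delta_pct > 15), 7L)
  expect_equal(sum(truth$true_delta_pct < -15), 9L)
  expect_equal(sum(abs(truth$true_delta_pct) <= 15), 10L)

  nc_only <- simulate_ecs_dataset(
    tibble::tibble(outcome = "NC", n = 5L, mean_delta_pct = 0,
                   sd_delta_pct = 0),
    seed = 2
  )
  expect_equal(unique(nc_only$true_delta_pct), 0)
  expect_equal(length(unique(nc_only$cell_id)), 5L)
})

test_that("clamp mode fixes the amplitude unit and baseline scale", {
  v <- simulate_recording(protocol_params(clamp_mode = "V-clamp"), seed = 1)
  i <- simulate_recording(protocol_params(clamp_mode = "I-clamp"), seed = 1)
  expect_equal(unique(v$unit), "pA")
  expect_equal(unique(i$unit), "mV")
  expect_gt(mean(v$amplitude, na.rm = TRUE), 300)
  expect_lt(mean(i$amplitude, na.rm = TRUE), 10)
})

test_that("unitary database honours outcome probabilities and strength model", {
  all_ltp <- simulate_scs_database(n = 20, outcome_probs = c(LTP = 1, LTD = 0,
                                                             NC = 0),
                                   seed = 4)
  expect_true(all(all_ltp$outcome == "LTP"))
  expect_true(all(all_ltp$delta_n_pct > 15))

  big <- simulate_scs_database(n = 10000, strength_mean_pa = 19.4,
                               strength_sd_pa = 5, seed = 5)
  expect_lt(abs(mean(big$strength_pre_pa) - 19.4), 3 * 5 / sqrt(10000))
  expect_true(all(big$strength_pre_pa > 0))

  # per-class truncation of ground-truth deltas
  expect_true(all(big$delta_n_pct[big$outcome == "LTP"] > 15))
  expect_true(all(big$delta_n_pct[big$outcome == "LTD"] < -15))
  expect_true(all(abs(big$delta_n_pct[big$outcome == "NC"]) <= 15))
  # delta column consistent with strengths
  expect_equal(big$delta_n_pct,
               delta_n(big$strength_pre_pa, big$strength_post_pa))
})

test_that("invalid generator parameters raise parameter errors", {
  expect_error(protocol_params(n_pre_sweeps = 0), class = "plastmix_error_parameter")
  expect_error(simulate_recording(baseline_mean = -5),
               class = "plastmix_error_parameter")
  expect_error(simulate_ecs_dataset(tibble::tibble()), class = "plastmix_error_data")
  expect_error(
    simulate_scs_database(outcome_probs = c(LTP = 0.5, LTD = 0.2, NC = 0.2)),
    class = "plastmix_error_parameter"
  )
  # degenerate delta model outside its class band
  expect_error(
    simulate_ecs_dataset(tibble::tibble(outcome = "LTP", n = 1L,
                                        mean_delta_pct = 5, sd_delta_pct = 0)),
    class = "plastmix_error_parameter"
  )
})

test_that("recordings and connection tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  ds <- simulate_ecs_dataset(control_composition(), seed = 1)
  f <- file.path(dir, "ds.csv")
  write_recordings(ds, f)
  back <- read_recordings(f)
  expect_equal(back$amplitude, ds$amplitude)
  expect_equal(as.character(back$epoch), as.character(ds$epoch))

  db <- simulate_scs_database(seed = 1)
  g <- file.path(dir, "db.csv")
  write_connections(db, g)
  expect_equal(read_connections(g), db, ignore_attr = TRUE)
})
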