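test_that("delta_n matches hand-computed percent changes", {
  expect_equal(delta_n(100, 159.4), 59.4)
  expect_equal(delta_n(100, 62.4), -37.6)
  expect_equal(delta_n(c(50, 375), c(50, 375)), c(0, 0))
  expect_error(delta_n(0, 10), class = "plastmix_error_parameter")
  expect_error(delta_n(-5, 10), class = "plastmix_error_parameter")
})

test_that("both classification criteria are required for a plastic label", {
  set.seed(51)
  pre <- rnorm(120, 100, 0.1)
  post <- rnorm(120, 130, 0.1)
  res <- classify_plasticity(pre, post)
  expect_equal(res$label, "LTP")
  expect_equal(res$delta_n_pct, 30, tolerance = 0.01)

  # significant but below the 15% magnitude threshold -> NC
  set.seed(52)
  pre <- rnorm(200, 100, 5)
  post <- rnorm(200, 110, 5)
  res <- classify_plasticity(pre, post)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$label, "NC")

  # large but non-significant change at n = 3 -> NC; p matches pooled oracle
  set.seed(53)
  repeat {
    pre <- rnorm(3, 100, 60)
    post <- rnorm(3, 130, 60)
    if (mean(pre) > 0 &&
        delta_n(mean(pre), mean(post)) > 15 &&
        pooled_t_test(post, pre) > 0.05) break
  }
  res <- classify_plasticity(pre, post)
  expect_equal(res$label, "NC")
  expect_equal(res$p_value, pooled_t_test(post, pre), tolerance = 1e-12)

  # exactly +15.0% is NC (threshold is strict)
  res <- classify_plasticity(rep(c(99.9, 100.1), 30), rep(c(114.9, 115.1), 30))
  expect_equal(res$delta_n_pct, 15)
  expect_equal(res$label, "NC")
})

test_that("classification is invariant to amplitude scaling", {
  for (seed in 1:5) {
    set.seed(seed)
    pre <- rnorm(60, 100, 12)
    post <- rnorm(60, 100 + sample(c(-40, -10, 0, 25), 1), 12)
    a <- classify_plasticity(pre, post)
    b <- classify_plasticity(pre * 7.3, post * 7.3)
    expect_equal(a$delta_n_pct, b$delta_n_pct, tolerance = 1e-10)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
    expect_equal(a$label, b$label)
  }
})

test_that("swapping epochs inverts the normalized change and the label", {
  for (seed in 1:5) {
    set.seed(seed + 10)
    pre <- rnorm(120, 100, 5)
    post <- rnorm(120, sample(c(60, 150), 1), 5)
    fwd <- classify_plasticity(pre, post)
    rev <- classify_plasticity(post, pre)
    expect_equal((1 + fwd$delta_n_pct / 100) * (1 + rev$delta_n_pct / 100), 1,
                 tolerance = 1e-10)
    if (fwd$label == "LTP") expect_equal(rev$label, "LTD")
    if (fwd$label == "LTD" && rev$delta_n_pct > 15) {
      expect_equal(rev$label, "LTP")
    }
  }
})

test_that("degenerate zero-variance input yields NC with p = 1", {
  res <- classify_plasticity(rep(100, 5), rep(100, 5))
  expect_equal(res$p_value, 1)
  expect_equal(res$label, "NC")
})

test_that("the joint criterion is conservative on null data", {
  ds <- simulate_ecs_dataset(
    tibble::tibble(outcome = "NC", n = 1000L, mean_delta_pct = 0,
                   sd_delta_pct = 0),
    protocol = protocol_params(),
    seed = 54
  )
  res <- classify_dataset(ds)
  rate <- mean(res$label != "NC")
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("classify_dataset keeps per-cell metadata and refuses mixed units", {
  ds <- simulate_ecs_dataset(control_composition(), seed = 55)
  res <- classify_dataset(ds)
  expect_equal(nrow(res), 28L)
  expect_setequal(res$cell_id, unique(ds$cell_id))
  expect_true(all(res$n_pre == 120 & res$n_post == 120))

  bad <- ds
  bad$unit[1] <- "mV"
  expect_error(classify_dataset(bad), class = "plastmix_error_data")
})

test_that("binned classification variant is exposed and close to raw", {
  ds <- simulate_ecs_dataset(control_composition(), seed = 56)
  raw <- classify_dataset(ds)
  binned <- classify_dataset(ds, use_bins = TRUE)
  expect_equal(binned$delta_n_pct, raw$delta_n_pct, tolerance = 0.05)
})

test_that("minute binning normalizes to the baseline mean", {
  rec <- simulate_recording(seed = 61)
  tp <- bin_timeplot(rec, bin_s = 60)
  pre_bins <- tp[tp$epoch == "pre", ]
  expect_equal(nrow(pre_bins), 10L)            # 120 sweeps at 0.2 Hz
  expect_true(all(pre_bins$n_sweeps == 12L))
  expect_equal(mean(rep(pre_bins$mean_norm, pre_bins$n_sweeps)), 1,
               tolerance = 1e-10)

  const <- rec
  const$amplitude[!is.na(const$amplitude)] <- 375
  tpc <- bin_timeplot(const)
  expect_true(all(abs(tpc$mean_norm - 1) < 1e-12))
  expect_true(all(tpc$sem_norm == 0))

  plus50 <- simulate_recording(true_delta_pct = 50, seed = 62)
  tp50 <- bin_timeplot(plus50)
  post_bins <- tp50[tp50$epoch == "post", ]
  expect_equal(mean(post_bins$mean_norm), 1.5, tolerance = 0.05)

  expect_error(bin_timeplot(rec, bin_s = 0), class = "plastmix_error_parameter")
})
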