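test_that("segregation-biased outcome draws obey the linear mixing law", {
  probs <- scs_outcome_probs()

  set.seed(71)
  s0 <- draw_outcome("LTP", s = 0, n = 30000)
  emp <- table(factor(s0, levels = outcome_levels())) / 30000
  for (o in outcome_levels()) {
    se <- sqrt(probs[[o]] * (1 - probs[[o]]) / 30000)
    expect_lt(abs(emp[[o]] - probs[[o]]), 3 * se)
  }

  set.seed(72)
  expect_true(all(draw_outcome("LTD", s = 1, n = 5000) == "LTD"))

  # P(LTP | first = LTP, S = 0.5) = 0.5 + 0.5 * 7/43
  set.seed(73)
  s5 <- draw_outcome("LTP", s = 0.5, n = 30000)
  p_exp <- 0.5 + 0.5 * probs[["LTP"]]
  se <- sqrt(p_exp * (1 - p_exp) / 30000)
  expect_lt(abs(mean(s5 == "LTP") - p_exp), 3 * se)
})

test_that("the stopping rule is reached minimally", {
  # identical 350 pA connections: threshold met on the first draw
  db350 <- uniform_db(strength_pa = 350)
  set.seed(74)
  one <- build_scr(db350)
  expect_equal(one$n_inputs, 1L)
  expect_equal(one$scr_pre_pa, 350)

  # identical 20 pA connections: ceiling(350/20) = 18 draws, 360 pA
  db20 <- uniform_db(strength_pa = 20)
  set.seed(75)
  run <- run_mixing(db20, s = 0, n_scr = 50)
  expect_true(all(run$n_inputs == 18L))
  expect_true(all(run$scr_pre_pa == 360))

  # property: every SCR exceeds the threshold and is minimal
  db <- simulate_scs_database(seed = 76)
  for (s in c(0, 0.5, 1)) {
    run <- run_mixing(db, s = s, n_scr = 500, seed = 77 + round(10 * s))
    expect_true(all(run$scr_pre_pa >= 350))
    expect_true(all(run$scr_pre_pa - run$last_strength_pa < 350))
    expect_equal(run$delta_n_pct,
                 delta_n(run$scr_pre_pa, run$scr_post_pa))
  }
})

test_that("complete segregation produces only homogeneous compound responses", {
  db <- simulate_scs_database(seed = 78)
  run <- run_mixing(db, s = 1, n_scr = 2000, seed = 79)
  expect_true(all(run$homogeneous))

  # members all carry the first draw's class
  first <- run$first_outcome[1]
  ids <- run$member_ids[[1]]
  expect_true(all(db$outcome[match(ids, db$conn_id)] == first))
})

test_that("without-replacement sampling errors when a class is exhausted", {
  db <- uniform_db(strength_pa = 20,
                   n_per_class = c(LTP = 3L, LTD = 10L, NC = 10L))
  set.seed(80)
  expect_error(
    run_mixing(db, s = 1, n_scr = 200, replace = FALSE,
               outcome_probs = c(LTP = 1, LTD = 0, NC = 0)),
    class = "plastmix_error_exhausted"
  )
})

test_that("an all-NC database with unchanged strengths gives zero variance", {
  db <- uniform_db(strength_pa = 20,
                   n_per_class = c(LTP = 0L, LTD = 0L, NC = 10L))
  run <- run_mixing(db, s = 0.5, n_scr = 26, seed = 81)
  expect_true(all(run$delta_n_pct == 0))
  expect_equal(glance(run)$var_delta, 0)
})

test_that("mixing runs are deterministic given a seed", {
  db <- simulate_scs_database(seed = 82)
  a <- run_mixing(db, s = 0.3, n_scr = 40, seed = 83)
  b <- run_mixing(db, s = 0.3, n_scr = 40, seed = 83)
  expect_identical(tidy(a), tidy(b))
})

test_that("segregation broadens the outcome distribution", {
  db <- simulate_scs_database(seed = 84)
  v0 <- glance(run_mixing(db, s = 0, n_scr = 500, seed = 85))$var_delta
  v1 <- glance(run_mixing(db, s = 1, n_scr = 500, seed = 86))$var_delta
  expect_gt(v1, v0)
})

test_that("the closed-form variance limit matches a hand-computed case", {
  db <- uniform_db(strength_pa = 20,
                   n_per_class = c(LTP = 4L, LTD = 6L, NC = 10L),
                   class_delta = c(LTP = 50, LTD = -50, NC = 0))
  probs <- c(LTP = 0.2, LTD = 0.3, NC = 0.5)
  # sum(p d^2) - (sum(p d))^2 = 1250 - 25 = 1225
  expect_equal(segregation_variance_limit(db, probs), 1225)
  # empirical default probs come from class counts
  expect_equal(segregation_variance_limit(db),
               0.2 * 2500 + 0.3 * 2500 - (0.2 * 50 - 0.3 * 50)^2)
})

test_that("sweep_segregation compares variances against the reference", {
  db <- simulate_scs_database(seed = 87)
  run <- run_mixing(db, s = 0.3, n_scr = 100, seed = 88)

  # self-comparison: F = 1 and two-sided p = 1
  self <- f_test_variance(run$delta_n_pct, run$delta_n_pct)
  expect_equal(self$statistic, 1)
  expect_equal(self$p_value, 1)

  ref <- withr::with_seed(89, rnorm(26, 0, 35))
  sw <- sweep_segregation(db, ref, s_grid = c(0, 1), n_scr = 200, seed = 90)
  expect_equal(nrow(sw), 2L)
  expect_true(all(c("s", "var_delta", "f_statistic", "p_value",
                    "variance_lower") %in% names(sw)))
  expect_gt(sw$var_delta[sw$s == 1], sw$var_delta[sw$s == 0])
  # random mixing is much narrower than a 35%-SD reference
  expect_true(sw$variance_lower[sw$s == 0])
  expect_equal(attr(sw, "reference_variance"), var(ref))
})
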