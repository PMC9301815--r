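test_that("simulated trials are reproducible and structurally valid", {
  p <- base_params()
  a <- simulate_trial(p, n_per_arm = 300, seed = 5)
  b <- simulate_trial(p, n_per_arm = 300, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 600)
  expect_setequal(unique(a$arm), c("txa", "no_txa"))
  expect_true(all(a$icu_days <= a$total_los + 1e-12))
  expect_true(all(is.na(a$death_day) | (a$death_day >= 1 & a$death_day <= 28)))
  # unit counts are zero exactly when the transfusion indicator is off
  for (nm in c("blood", "ffp", "platelets")) {
    expect_true(all(a[[paste0("units_", nm)]][a[[paste0("transf_", nm)]] == 0] == 0))
  }
})

test_that("simulator moments match the generating parameters", {
  p <- base_params()
  rec <- simulate_trial(p, n_per_arm = 20000, seed = 31)
  ctl <- rec[rec$arm == "no_txa", ]
  risk <- p$risk28$deaths / p$risk28$n
  se_bin <- sqrt(risk * (1 - risk) / nrow(ctl))
  expect_lt(abs(mean(!is.na(ctl$death_day)) - risk), 3 * se_bin)
  # front-loaded daily curve: more deaths in week 1 than week 4
  dd <- ctl$death_day[!is.na(ctl$death_day)]
  expect_gt(sum(dd <= 7), sum(dd > 21))
  # unconditional transfusion-unit mean = probability x conditional mean
  tr <- p$resource_use$no_txa$transfusions$blood
  expected <- (tr$k / tr$n) * tr$mean_units
  expect_equal(mean(ctl$units_blood), expected, tolerance = 0.05)
  expect_equal(mean(ctl$total_los), 5.80, tolerance = 0.02)
})

test_that("trial records round-trip through CSV with seed metadata", {
  rec <- simulate_trial(base_params(), n_per_arm = 50, seed = 9)
  tmp <- tempfile(fileext = ".csv")
  write_trial_csv(rec, tmp)
  expect_true(startsWith(readLines(tmp, n = 1), "# seed:"))
  back <- read_trial_csv(tmp)
  expect_equal(attr(back, "seed"), 9L)
  expect_equal(back$death_day, rec$death_day)
  expect_equal(back$total_los, rec$total_los, tolerance = 1e-9)
})

test_that("estimators recover the generating parameters as n grows", {
  p <- base_params()
  risk_true <- p$risk28$deaths / p$risk28$n
  err <- vapply(c(1000, 10000), function(n) {
    est <- estimate_parameters(simulate_trial(p, n_per_arm = n, seed = 77))
    abs(est$risk28$deaths / est$risk28$n - risk_true) +
      abs(est$rr_mortality$value - p$rr_mortality$value) +
      abs(est$resource_use$no_txa$total_los$mean - 5.80)
  }, numeric(1))
  expect_lt(err[2], err[1]) # bias + noise shrink with sample size
  est <- estimate_parameters(simulate_trial(p, n_per_arm = 10000, seed = 77))
  expect_equal(est$risk28$deaths / est$risk28$n, risk_true, tolerance = 0.1)
  expect_equal(est$resource_use$txa$transfusions$blood$mean_units, 2.8,
               tolerance = 0.05)
  expect_true(est$rr_mortality$lo < est$rr_mortality$value &
                est$rr_mortality$value < est$rr_mortality$hi)
})

test_that("an arm without deaths flags the risk ratio as undefined", {
  p <- base_params()
  p$risk28 <- list(deaths = 0L, n = 100L)
  rec <- simulate_trial(p, n_per_arm = 30, seed = 1)
  expect_warning(est <- estimate_parameters(rec), "undefined")
  expect_true(is.na(est$rr_mortality$value))
  rec_one_arm <- rec[rec$arm == "txa", ]
  expect_error(estimate_parameters(rec_one_arm), "both")
})

test_that("estimate -> patch -> model pipeline reproduces the base-case economics", {
  p <- base_params()
  est <- estimate_parameters(simulate_trial(p, n_per_arm = 60000, seed = 13))
  fitted <- patch_parameters(p, est)
  res <- run_model(fitted, fixture_life_table())
  ref <- base_case_result()
  # entry costs are tightly identified even in one simulated trial
  expect_equal(res$txa$cost, ref$txa$cost, tolerance = 0.01)
  # the RR estimate carries binomial noise, which the incrementals amplify;
  # check agreement within its propagated Monte Carlo band
  rr_se <- (log(est$rr_mortality$hi) - log(est$rr_mortality$lo)) / (2 * qnorm(0.975))
  dq_per_rr <- abs(ref$delta_qaly / (p$rr_mortality$value - 1))
  expect_lt(abs(res$delta_qaly - ref$delta_qaly),
            3 * rr_se * 1.03 * dq_per_rr)
})
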