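test_that("probability/rate conversions satisfy closed forms and round-trips", {
  expect_equal(prob_to_rate(0, 1), 0)
  expect_equal(prob_to_rate(0.05, 1), -log(0.95))
  expect_equal(prob_to_rate(0.05, 1), 0.051293, tolerance = 1e-5)
  expect_equal(rate_to_prob(prob_to_rate(0.3, 1), 1), 0.3, tolerance = 1e-12)
  for (p in c(0.001, 0.1, 0.5, 0.93)) {
    expect_equal(rate_to_prob(prob_to_rate(p, 2.5), 2.5), p, tolerance = 1e-12)
  }
  expect_error(prob_to_rate(1), "infinite")
})

test_that("SMR adjustment acts on the hazard scale", {
  expect_equal(apply_smr(0.4, 1), 0.4)
  expect_equal(apply_smr(0, 7), 0)
  expect_equal(apply_smr(0.01, 5.21), 1 - 0.99^5.21)
  expect_equal(apply_smr(0.01, 5.21), 0.051015, tolerance = 1e-5)
  # stays a probability even where naive multiplication would not
  expect_lt(apply_smr(0.5, 5.21), 1)
  expect_error(apply_smr(0.5, -1))
})

test_that("annual/daily conversion compounds exactly", {
  expect_equal(annual_to_daily(0), 0)
  expect_equal(annual_to_daily(0.05), 1 - 0.95^(1 / 365))
  expect_equal(annual_to_daily(0.05), 1.4052e-4, tolerance = 1e-4)
  for (q in c(0.01, 0.2, 0.8)) {
    expect_equal(1 - (1 - annual_to_daily(q))^365, q, tolerance = 1e-10)
  }
})

test_that("trial curve honours the survival-product identity and day shares", {
  tc <- make_trial_curve(0.092, rep(1, 28))
  expect_equal(tc$fractions, rep(0.092 / 28, 28))
  expect_equal(1 - prod(1 - tc$p_daily), 0.092, tolerance = 1e-12)

  w <- 0.9^(0:27)
  tc2 <- make_trial_curve(0.092, w)
  expect_equal(1 - prod(1 - tc2$p_daily), 0.092, tolerance = 1e-12)
  # rescaling the same shape preserves day-share proportions
  tc3 <- make_trial_curve(0.084, w)
  expect_equal(tc3$fractions / sum(tc3$fractions),
               tc2$fractions / sum(tc2$fractions), tolerance = 1e-12)

  expect_equal(make_trial_curve(0, w)$p_daily, rep(0, 28))
  expect_error(make_trial_curve(0.1, c(-1, rep(1, 27))), "non-negative")
})

test_that("schedule reproduces the 28-day cumulative risks per arm", {
  p <- base_params()
  lt <- fixture_life_table()
  risk <- p$risk28$deaths / p$risk28$n
  cum28 <- function(sched) 1 - prod(1 - sched$p_death[1:28])

  s_ctl <- build_schedule(p, lt, "no_txa")
  expect_equal(cum28(s_ctl), risk, tolerance = 1e-12)

  s_txa <- build_schedule(p, lt, "txa")
  expect_equal(cum28(s_txa), 1.03 * risk, tolerance = 1e-12)

  # arms differ only within the trial window
  expect_equal(s_txa$p_death[-(1:28)], s_ctl$p_death[-(1:28)])
  expect_false(isTRUE(all.equal(s_txa$p_death[1:28], s_ctl$p_death[1:28])))

  # null treatment effect gives identical schedules
  p1 <- p; p1$rr_mortality$value <- 1
  expect_equal(build_schedule(p1, lt, "txa"), build_schedule(p1, lt, "no_txa"))

  # an effect pushing cumulative risk to 1 is rejected
  p2 <- p; p2$rr_mortality$value <- 11; p2$rr_mortality$hi <- 11
  expect_error(build_schedule(p2, lt, "txa"), "reaches 1")
})

test_that("cycle structure partitions the horizon", {
  s <- build_schedule(base_params(), fixture_life_table(), "no_txa")
  expect_equal(s$length[1:365], rep(1, 365))
  expect_true(all(s$length[-(1:365)] == 365))
  expect_equal(s$start, cumsum(c(0, s$length[-nrow(s)])))
  expect_equal(s$age, base_params()$start_age + s$start / 365)
})

test_that("with SMR 1 and no trial deaths the schedule tracks the life table", {
  p <- base_params()
  p$start_age <- 58 # integer start so whole years align with table rows
  p$smr_y1$value <- 1; p$smr_y1$lo <- 1
  p$smr_y2plus$value <- 1; p$smr_y2plus$lo <- 1
  lt <- fixture_life_table()
  curve <- make_trial_curve(0, rep(1, 28))
  s <- build_schedule(p, lt, "no_txa", curve)
  surv <- cumprod(1 - s$p_death)
  q <- lt$q_annual[match(58:97, lt$age)]
  # year 1 only accrues 337 days of general-population hazard (the trial
  # window carries its own curve, here zero), so the boundary is approximate
  expect_equal(surv[365], 1 - q[1], tolerance = 1e-3)
  # later annual transitions match the raw life table exactly
  annual_idx <- 365 + seq_len(nrow(s) - 365)
  expect_equal(s$p_death[annual_idx][1:39], q[2:40], tolerance = 1e-12)
})

test_that("raising either SMR weakly lowers life expectancy", {
  p <- base_params()
  lt <- fixture_life_table()
  le <- function(p) {
    s <- build_schedule(p, lt, "no_txa")
    sum(run_trace(s, no_utility, NULL, 0, 0)$cycles$ly)
  }
  base <- le(p)
  p1 <- p; p1$smr_y1$value <- p1$smr_y1$value * 2; p1$smr_y1$hi <- 20
  p2 <- p; p2$smr_y2plus$value <- p2$smr_y2plus$value * 2; p2$smr_y2plus$hi <- 20
  expect_lt(le(p1), base)
  expect_lt(le(p2), base)
})

test_that("life tables validate their structure", {
  expect_error(as_life_table(data.frame(age = c(50, 52), q_annual = c(0.1, 0.2))),
               "contiguous")
  expect_error(as_life_table(data.frame(age = 50:51, q_annual = c(0.1, 1.2))),
               "\\[0, 1\\]")
  lt <- gompertz_makeham_life_table(ages = 40:100)
  expect_s3_class(lt, "txace_life_table")
  expect_equal(lt$q_annual[lt$age == 100], 1)
  expect_true(all(diff(lt$q_annual) >= 0))
  # fixture was generated by the same law at default parameters
  fx <- fixture_life_table()
  gm <- gompertz_makeham_life_table()
  expect_equal(fx$q_annual, gm$q_annual, tolerance = 1e-7)
})
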