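test_that("log-normal fits treat the point as the log-scale median", {
  d <- lognormal_from_ci(1.03, 0.92, 1.16)
  expect_equal(d$pars$meanlog, log(1.03))
  expect_equal(d$pars$meanlog, 0.029559, tolerance = 1e-5)
  expect_equal(d$pars$sdlog, (log(1.16) - log(0.92)) / (2 * qnorm(0.975)))
  expect_equal(d$pars$sdlog, 0.059134, tolerance = 1e-4)
  expect_equal(d$median, 1.03)

  d2 <- lognormal_from_ci(5.21, 4.25, 6.38)
  expect_equal(d2$pars$sdlog, (log(6.38) - log(4.25)) / (2 * qnorm(0.975)))
  expect_equal(d2$pars$sdlog, 0.1036, tolerance = 1e-3)

  d3 <- lognormal_from_ci(2, 2, 2)
  expect_equal(unique(rdist(d3, 5)), 2)
  expect_error(lognormal_from_ci(1, -0.5, 2), "positive")
})

test_that("beta-from-counts uses exact event counts", {
  d <- beta_from_counts(548, 5981)
  expect_equal(d$pars$shape1, 548)
  expect_equal(d$pars$shape2, 5433)
  expect_equal(d$mean, 548 / 5981)
  expect_equal(d$mean, 0.09162, tolerance = 1e-4)
  expect_equal(beta_from_counts(4781, 5953)$mean, 0.8031, tolerance = 1e-4)
  # degenerate counts collapse to a point mass
  expect_equal(unique(rdist(beta_from_counts(0, 10), 5)), 0)
  expect_error(beta_from_counts(5, 0), "positive")
})

test_that("beta-from-CI matches the stated method of moments", {
  d <- beta_from_ci(0.735, 0.70, 0.77)
  expect_equal(d$pars$shape1, 448.2, tolerance = 1e-3)
  expect_equal(d$pars$shape2, 161.6, tolerance = 1e-3)
  # analytic mean reproduces the source mean exactly
  expect_equal(d$pars$shape1 / (d$pars$shape1 + d$pars$shape2), 0.735,
               tolerance = 1e-12)
  expect_equal(unique(rdist(beta_from_ci(0.5, 0.5, 0.5), 3)), 0.5)
  # a CI far wider than a (0,1)-supported mean of 0.01 can carry
  expect_error(beta_from_ci(0.01, 0.0001, 0.5), "infeasible")
})

test_that("gamma-from-mean-SE matches closed-form shape and scale", {
  d <- gamma_from_mean_se(5.83, 1.46)
  expect_equal(d$pars$shape, (5.83 / 1.46)^2)
  expect_equal(d$pars$shape, 15.945, tolerance = 1e-4)
  expect_equal(d$pars$scale, 1.46^2 / 5.83)
  expect_equal(d$pars$scale, 0.36563, tolerance = 1e-4)

  d2 <- gamma_from_mean_se(4350, 2175)
  expect_equal(d2$pars$shape, 4)
  expect_equal(d2$pars$scale, 1087.5)
  # moment identity: shape x scale is the mean
  expect_equal(d2$pars$shape * d2$pars$scale, 4350, tolerance = 1e-12)
  expect_equal(unique(rdist(gamma_from_mean_se(3, 0), 4)), 3)
})

test_that("every fitted base-case distribution reproduces its source point", {
  dists <- fit_psa_distributions(base_params())
  expect_equal(dists$rr_mortality$median, 1.03, tolerance = 1e-6)
  expect_equal(dists$smr_y1$median, 5.21, tolerance = 1e-6)
  expect_equal(dists$smr_y2plus$median, 1.74, tolerance = 1e-6)
  expect_equal(dists$risk28$mean, 548 / 5981, tolerance = 1e-6)
  expect_equal(dists$utility_survivor$mean, 0.735, tolerance = 1e-6)
  expect_equal(dists$resource_use$txa$total_los$mean, 5.83, tolerance = 1e-6)
  expect_equal(dists$postdischarge$year1$mean, 4350, tolerance = 1e-6)
  expect_equal(dists$postdischarge$year1$pars$shape, 4, tolerance = 1e-6)
  for (nm in names(dists$resource_use$no_txa$procedures)) {
    d <- dists$resource_use$no_txa$procedures[[nm]]
    k <- base_params()$resource_use$no_txa$procedures[[nm]]$k
    n <- base_params()$resource_use$no_txa$procedures[[nm]]$n
    expect_equal(d$mean, k / n, tolerance = 1e-12)
  }
})

test_that("sampled draws match their analytic distributions", {
  set.seed(99)
  d <- lognormal_from_ci(1.03, 0.92, 1.16)
  x <- rdist(d, 10000)
  analytic_mean <- exp(d$pars$meanlog + d$pars$sdlog^2 / 2)
  analytic_se <- sqrt((exp(d$pars$sdlog^2) - 1)) * analytic_mean / sqrt(10000)
  expect_lt(abs(mean(x) - analytic_mean), 3 * analytic_se)

  g <- gamma_from_mean_se(5.83, 1.46)
  y <- rdist(g, 10000)
  expect_lt(abs(mean(y) - 5.83), 4 * 1.46 / sqrt(10000))
  expect_equal(sd(y), 1.46, tolerance = 0.1)
})
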