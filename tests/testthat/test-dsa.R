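test_that("set_param replaces existing leaves and rejects unknown paths", {
  p <- base_params()
  p2 <- set_param(p, "postdischarge_costs.year4plus_fraction", 1)
  expect_equal(p2$postdischarge_costs$year4plus_fraction, 1)
  expect_equal(p$postdischarge_costs$year4plus_fraction, 1 / 3) # copy semantics
  expect_error(set_param(p, "no.such.key", 5), "unknown parameter path")
})

test_that("the shipped scenario set covers the published one-way analyses", {
  sc <- default_scenarios()
  expect_setequal(names(sc),
                  c("base_case", "monitoring_full_year4",
                    "monitoring_none_beyond_year3", "discount_0", "discount_6",
                    "utility_0.5", "monitoring_year1_reduced", "rr_0.92",
                    "rr_1.16", "txa_admin_zero"))
  # every override path exists in the parameter set
  p <- base_params()
  for (s in sc) {
    expect_s3_class(apply_scenario(p, s), "txace_params")
  }
})

test_that("a null treatment effect with identical resource use yields exactly zero incrementals", {
  p <- base_params()
  p$rr_mortality$value <- 1
  p$resource_use$no_txa <- p$resource_use$txa
  zero_admin <- lapply(p$txa_admin_components, function(x) 0)
  p$txa_admin_components <- zero_admin
  res <- run_model(p, fixture_life_table())
  expect_identical(res$delta_ly, 0)
  expect_identical(res$delta_qaly, 0)
  expect_identical(res$delta_cost, 0)
})

test_that("scenario directions are economically coherent", {
  dsa <- run_dsa(base_params(), fixture_life_table())
  row <- function(nm) dsa[dsa$scenario == nm, ]
  base <- row("base_case")

  # undiscounted effects exceed discounted; 6% discounting shrinks them
  expect_gt(abs(row("discount_0")$delta_ly), abs(base$delta_ly))
  expect_lt(abs(row("discount_6")$delta_ly), abs(base$delta_ly))
  # monitoring-cost scenarios leave the health effects untouched
  expect_equal(row("monitoring_full_year4")$delta_qaly, base$delta_qaly)
  expect_equal(row("txa_admin_zero")$delta_qaly, base$delta_qaly)
  # lower utility shrinks the QALY increment but not the LY increment
  expect_equal(row("utility_0.5")$delta_ly, base$delta_ly)
  expect_lt(abs(row("utility_0.5")$delta_qaly), abs(base$delta_qaly))
  # excluding year-1 inpatient-type monitoring reduces the cost increment
  expect_lt(abs(row("monitoring_year1_reduced")$delta_cost), abs(base$delta_cost))
  # free TXA makes the TXA arm cheaper still
  expect_lt(row("txa_admin_zero")$delta_cost, base$delta_cost)
  # a protective RR flips the plane quadrant to TXA-favouring
  expect_equal(row("rr_0.92")$quadrant, "NE")
  expect_gt(row("rr_0.92")$inmb, 0)
  expect_equal(row("rr_1.16")$quadrant, "SW")
  expect_lt(row("rr_1.16")$inmb, base$inmb)
})

test_that("the meta-analysis parameterisation swaps risk and effect", {
  mp <- meta_analysis_params(base_params())
  expect_equal(mp$risk28$deaths / mp$risk28$n, 71 / 850)
  expect_equal(mp$rr_mortality$value, 0.60)
  expect_equal(c(mp$rr_mortality$lo, mp$rr_mortality$hi), c(0.42, 0.87))
  res <- run_model(mp, fixture_life_table())
  # TXA now saves lives at modest extra cost: NE quadrant, positive INMB
  expect_gt(res$delta_qaly, 0)
  expect_equal(res$icer_qaly$quadrant, "NE")
  expect_gt(res$inmb, 0)
})

test_that("base-case report groups costs both ways consistently", {
  rep <- report_base_case(base_params(), fixture_life_table())
  tab <- rep$table
  expect_equal(tab$arm, c("no_txa", "txa"))
  expect_equal(tab$total_cost,
               tab$txa_cost + tab$hospital_combined + tab$monitoring,
               tolerance = 1e-9)
  expect_equal(tab$hospital_combined,
               tab$inpatient + tab$procedures + tab$transfusions)
  expect_equal(tab$txa_cost, c(0, 30.02))
})

test_that("run manifests record config hash, seed and outputs", {
  tmp <- file.path(tempdir(), "manifest.json")
  m <- write_run_manifest(base_params(), seed = 42, command = "test",
                          outputs = c("a.csv", "b.csv"), path = tmp)
  expect_true(file.exists(tmp))
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$seed, 42)
  expect_equal(back$outputs, c("a.csv", "b.csv"))
  expect_match(back$config_md5, "^[0-9a-f]{32}$")
  # same parameters hash identically
  m2 <- write_run_manifest(base_params(), 42, "test", "a.csv",
                           file.path(tempdir(), "m2.json"))
  expect_equal(m$config_md5, m2$config_md5)
})
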