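#' Set a parameter by dotted path
#'
#' Helper for scenario definitions: `set_param(p, "postdischarge_costs.year1",
#' 1980)` returns a copy of `p` with that leaf replaced. The path must
#' already exist.
#'
#' @param params A `txace_params` object.
#' @param path Dotted key path.
#' @param value Replacement value.
#' @return The modified parameter set.
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (is.null(node[[k]])) stop("unknown parameter path: ", path)
    node <- node[[k]]
  }
  params[[keys]] <- value
  params
}

#' Apply a scenario's overrides to a parameter set
#' @param params A `txace_params` object.
#' @param scenario A scenario: list with `name` and `overrides` (named list
#'   of dotted paths to values).
#' @return The modified parameter set.
#' @export
apply_scenario <- function(params, scenario) {
  for (path in names(scenario$overrides)) {
    params <- set_param(params, path, scenario$overrides[[path]])
  }
  params
}

#' The shipped deterministic one-way sensitivity scenarios
#'
#' One scenario per structural or parameter assumption probed in the
#' deterministic sensitivity analysis:
#' \itemize{
#'   \item `base_case` - no overrides;
#'   \item `monitoring_full_year4` - year 4+ monitoring at the full year-3
#'     amount (fraction 1) instead of one-third;
#'   \item `monitoring_none_beyond_year3` - no monitoring costs after year 3;
#'   \item `discount_0` / `discount_6` - 0\% / 6\% annual discounting,
#'     applied jointly to costs and QALYs;
#'   \item `utility_0.5` - survivor utility lowered to 0.5;
#'   \item `monitoring_year1_reduced` - year-1 monitoring with
#'     inpatient-type spend excluded; the year-1 annual amount is set to the
#'     year-2 level (1980 GBP), a documented choice since no separate
#'     outpatient-only year-1 estimate is available;
#'   \item `rr_0.92` / `rr_1.16` - mortality risk ratio at its 95\% CI
#'     bounds;
#'   \item `txa_admin_zero` - TXA drug and administration free of charge.
#' }
#'
#' @param params A `txace_params` object (supplies the CI bounds).
#' @return Named list of scenarios.
#' @export
default_scenarios <- function(params = default_parameters()) {
  rr <- params$rr_mortality
  zero_admin <- as.list(stats::setNames(
    rep(0, length(params$txa_admin_components)),
    paste0("txa_admin_components.", names(params$txa_admin_components))))
  list(
    base_case = list(name = "base_case", overrides = list()),
    monitoring_full_year4 = list(
      name = "monitoring_full_year4",
      overrides = list("postdischarge_costs.year4plus_fraction" = 1)),
    monitoring_none_beyond_year3 = list(
      name = "monitoring_none_beyond_year3",
      overrides = list("postdischarge_costs.year4plus_fraction" = 0)),
    discount_0 = list(
      name = "discount_0",
      overrides = list("discount_rate_costs" = 0, "discount_rate_qalys" = 0)),
    discount_6 = list(
      name = "discount_6",
      overrides = list("discount_rate_costs" = 0.06, "discount_rate_qalys" = 0.06)),
    utility_0.5 = list(
      name = "utility_0.5",
      overrides = list("utility_survivor.value" = 0.5,
                       "utility_survivor.lo" = 0.5,
                       "utility_survivor.hi" = 0.5)),
    monitoring_year1_reduced = list(
      name = "monitoring_year1_reduced",
      overrides = list("postdischarge_costs.year1" = 1980)),
    rr_0.92 = list(
      name = "rr_0.92",
      overrides = list("rr_mortality.value" = rr$lo, "rr_mortality.hi" = rr$lo)),
    rr_1.16 = list(
      name = "rr_1.16",
      overrides = list("rr_mortality.value" = rr$hi, "rr_mortality.lo" = rr$hi)),
    txa_admin_zero = list(name = "txa_admin_zero", overrides = zero_admin)
  )
}

#' Parameter overrides for the pre-trial meta-analysis scenario
#'
#' Re-parameterises the model with the pooled evidence available before the
#' large trial: control-arm 28-day mortality risk 0.084 (71/850) and an
#' all-cause mortality risk ratio of 0.60 (95\% CI 0.42 to 0.87).
#'
#' @param params A `txace_params` object.
#' @return The re-parameterised `txace_params`.
#' @export
meta_analysis_params <- function(params = default_parameters()) {
  params$risk28 <- list(deaths = 71L, n = 850L)
  params$rr_mortality <- list(value = 0.60, lo = 0.42, hi = 0.87)
  assert_valid(params)
}

#' Run the deterministic one-way sensitivity analysis
#'
#' Runs one deterministic model evaluation per scenario and tabulates the
#' incremental results.
#'
#' @param params A `txace_params` object.
#' @param life_table A `txace_life_table`.
#' @param scenarios Named list of scenarios (default [default_scenarios()]).
#' @return A data frame with one row per scenario: `scenario`, `delta_cost`,
#'   `delta_ly`, `delta_qaly`, `icer_ly`, `icer_qaly`, `inmb`, `quadrant`.
#' @export
run_dsa <- function(params, life_table = default_life_table(),
                    scenarios = default_scenarios(params)) {
  rows <- lapply(scenarios, function(sc) {
    res <- run_model(apply_scenario(params, sc), life_table)
    data.frame(
      scenario = sc$name,
      delta_cost = res$delta_cost, delta_ly = res$delta_ly,
      delta_qaly = res$delta_qaly,
      icer_ly = res$icer_ly$value, icer_qaly = res$icer_qaly$value,
      inmb = res$inmb, quadrant = res$icer_qaly$quadrant,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
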