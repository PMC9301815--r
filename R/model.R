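#' Run the deterministic cohort model for one arm
#'
#' Builds the mortality schedule, cost schedule and cohort trace for one
#' treatment arm under a given parameter set.
#'
#' @param params A `txace_params` object.
#' @param life_table A `txace_life_table`.
#' @param arm `"txa"` or `"no_txa"`.
#' @param curve Optional control-arm `txace_trial_curve` override.
#' @return A `txace_trace`.
#' @export
run_arm <- function(params, life_table, arm = c("no_txa", "txa"), curve = NULL) {
  arm <- match.arg(arm)
  sched <- build_schedule(params, life_table, arm, curve)
  costs <- build_cost_schedule(params, arm, sched)
  run_trace(
    sched,
    utilities = list(base = params$utility_survivor$value,
                     decrements = params$utility_decrements),
    cost_schedule = costs,
    discount_costs = params$discount_rate_costs,
    discount_qalys = params$discount_rate_qalys,
    half_cycle = params$half_cycle_correction
  )
}

#' Run the deterministic cost-effectiveness model
#'
#' Runs both arms over the lifetime horizon and returns the incremental
#' cost-effectiveness result (TXA minus no-TXA).
#'
#' @param params A `txace_params` object.
#' @param life_table A `txace_life_table`; defaults to the vendored fixture.
#' @param curve Optional control-arm `txace_trial_curve` override (used by
#'   the probabilistic analysis to pass sampled risks).
#' @return A `txace_ce_result`.
#' @export
#' @examples
#' \donttest{
#' res <- run_model(default_parameters())
#' res$icer_qaly$value
#' }
run_model <- function(params, life_table = default_life_table(), curve = NULL) {
  tr_txa <- run_arm(params, life_table, "txa", curve)
  tr_ctl <- run_arm(params, life_table, "no_txa", curve)
  ce_result(lifetime_outputs(tr_txa), lifetime_outputs(tr_ctl),
            wtp = params$wtp_threshold)
}
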