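#' Fit all PSA distributions for a parameter set
#'
#' Assigns a sampling distribution to every uncertain parameter, mirroring
#' the source summaries: log-normal for the two SMRs and the mortality risk
#' ratio; beta from exact counts for the 28-day risk and every procedure /
#' transfusion probability; beta by method of moments for the survivor
#' utility; gamma for lengths of stay, ICU days, transfusion units and the
#' post-discharge annual costs (with SE = `psa$cost_se_fraction` times the
#' mean). Unit costs, discount rates, utility decrements and the TXA
#' administration cost carry no distribution and are held fixed.
#'
#' @param params A `txace_params` object.
#' @return Nested list of `txace_dist` objects, shaped like the sampled
#'   parts of the parameter set.
#' @export
fit_psa_distributions <- function(params) {
  p <- params
  frac <- p$psa$cost_se_fraction
  ru_dists <- function(ru) {
    list(
      total_los = gamma_from_mean_se(ru$total_los$mean, ru$total_los$se),
      icu_days = gamma_from_mean_se(ru$icu_days$mean, ru$icu_days$se),
      procedures = lapply(ru$procedures, function(x) beta_from_counts(x$k, x$n)),
      transfusions = lapply(ru$transfusions, function(x) {
        list(prob = beta_from_counts(x$k, x$n),
             mean_units = gamma_from_mean_se(x$mean_units, x$se_units))
      })
    )
  }
  list(
    smr_y1 = lognormal_from_ci(p$smr_y1$value, p$smr_y1$lo, p$smr_y1$hi),
    smr_y2plus = lognormal_from_ci(p$smr_y2plus$value, p$smr_y2plus$lo, p$smr_y2plus$hi),
    rr_mortality = lognormal_from_ci(p$rr_mortality$value, p$rr_mortality$lo, p$rr_mortality$hi),
    risk28 = beta_from_counts(p$risk28$deaths, p$risk28$n),
    utility_survivor = beta_from_ci(p$utility_survivor$value,
                                    p$utility_survivor$lo, p$utility_survivor$hi),
    resource_use = list(txa = ru_dists(p$resource_use$txa),
                        no_txa = ru_dists(p$resource_use$no_txa)),
    postdischarge = list(
      year1 = gamma_from_mean_se(p$postdischarge_costs$year1, frac * p$postdischarge_costs$year1),
      year2 = gamma_from_mean_se(p$postdischarge_costs$year2, frac * p$postdischarge_costs$year2),
      year3 = gamma_from_mean_se(p$postdischarge_costs$year3, frac * p$postdischarge_costs$year3)
    )
  )
}

# seed for draw i under master seed s, kept within the 32-bit integer range
.draw_seed <- function(seed, draw_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(draw_index) * 16807) %% 2147483647)
}

#' Sample one joint parameter draw
#'
#' Draws every uncertain parameter once from its fitted distribution and
#' returns the perturbed parameter set. All parameters are sampled
#' independently (across parameters and across arms); the draw is fully
#' reproducible given `(seed, draw_index)` via a per-draw substream, so
#' results do not depend on execution order. Draws that violate a model
#' precondition (ICU days exceeding the total length of stay, or a TXA-arm
#' 28-day risk reaching 1) are rejected and redrawn; the number of
#' rejections is recorded in the `rejections` attribute.
#'
#' @param params A `txace_params` object.
#' @param seed Master seed (integer).
#' @param draw_index Draw number (1-based).
#' @param dists Fitted distributions from [fit_psa_distributions()]
#'   (refitted if omitted).
#' @param collapse If TRUE, return the point-estimate parameter set (all
#'   distributions collapsed to their source points); used to check that the
#'   PSA machinery reproduces the deterministic result exactly.
#' @return A `txace_params` object with sampled values; the sampled
#'   control-arm 28-day risk is stored in `risk28$draw`.
#' @export
sample_parameter_set <- function(params, seed, draw_index,
                                 dists = fit_psa_distributions(params),
                                 collapse = FALSE) {
  p <- params
  if (collapse) {
    p$risk28$draw <- p$risk28$deaths / p$risk28$n
    return(p)
  }
  set.seed(.draw_seed(seed, draw_index))
  rejections <- 0L
  p$smr_y1$value <- rdist(dists$smr_y1)
  p$smr_y2plus$value <- rdist(dists$smr_y2plus)
  rr <- rdist(dists$rr_mortality)
  risk <- rdist(dists$risk28)
  while (rr * risk >= 1) {
    rejections <- rejections + 1L
    if (rejections > 1000L) stop("could not draw a feasible RR x risk pair")
    rr <- rdist(dists$rr_mortality)
    risk <- rdist(dists$risk28)
  }
  p$rr_mortality$value <- rr
  p$risk28$draw <- risk
  p$utility_survivor$value <- rdist(dists$utility_survivor)
  for (arm in c("txa", "no_txa")) {
    d <- dists$resource_use[[arm]]
    los <- rdist(d$total_los)
    icu <- rdist(d$icu_days)
    while (icu > los) {
      rejections <- rejections + 1L
      if (rejections > 1000L) stop("could not draw ICU days <= length of stay")
      icu <- rdist(d$icu_days)
    }
    p$resource_use[[arm]]$total_los$mean <- los
    p$resource_use[[arm]]$icu_days$mean <- icu
    for (nm in names(d$procedures)) {
      p$resource_use[[arm]]$procedures[[nm]]$k <-
        rdist(d$procedures[[nm]]) * p$resource_use[[arm]]$procedures[[nm]]$n
    }
    for (nm in names(d$transfusions)) {
      p$resource_use[[arm]]$transfusions[[nm]]$k <-
        rdist(d$transfusions[[nm]]$prob) * p$resource_use[[arm]]$transfusions[[nm]]$n
      p$resource_use[[arm]]$transfusions[[nm]]$mean_units <-
        rdist(d$transfusions[[nm]]$mean_units)
    }
  }
  p$postdischarge_costs$year1 <- rdist(dists$postdischarge$year1)
  p$postdischarge_costs$year2 <- rdist(dists$postdischarge$year2)
  p$postdischarge_costs$year3 <- rdist(dists$postdischarge$year3)
  attr(p, "rejections") <- rejections
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs `n_draws` Monte Carlo simulations: each draw samples the joint
#' parameter set, rebuilds both arms' schedules and costs, runs the cohort
#' model and records the incremental cost, life years and QALYs (TXA minus
#' no-TXA).
#'
#' @param params A `txace_params` object.
#' @param life_table A `txace_life_table`.
#' @param n_draws Number of Monte Carlo draws (default from `params$psa$n`).
#' @param seed Master seed (default from `params$psa$seed`).
#' @return An object of class `txace_psa`: list with `draws` (data frame:
#'   `draw`, sampled `rr`, `risk28`, `utility`, and `delta_cost`,
#'   `delta_ly`, `delta_qaly`), `mean_result` (mean probabilistic
#'   incrementals with ICERs and INMB), `wtp`, `n_rejections`.
#' @export
run_psa <- function(params, life_table = default_life_table(),
                    n_draws = params$psa$n, seed = params$psa$seed) {
  stopifnot(n_draws >= 1)
  dists <- fit_psa_distributions(params)
  cols <- c("rr", "risk28", "utility", "delta_cost", "delta_ly", "delta_qaly")
  out <- matrix(NA_real_, nrow = n_draws, ncol = length(cols),
                dimnames = list(NULL, cols))
  n_rej <- 0L
  for (i in seq_len(n_draws)) {
    pi <- sample_parameter_set(params, seed, i, dists)
    n_rej <- n_rej + attr(pi, "rejections")
    res <- run_model(pi, life_table)
    out[i, ] <- c(pi$rr_mortality$value, pi$risk28$draw,
                  pi$utility_survivor$value,
                  res$delta_cost, res$delta_ly, res$delta_qaly)
  }
  draws <- data.frame(draw = seq_len(n_draws), out)
  mean_result <- list(
    delta_cost = mean(draws$delta_cost),
    delta_ly = mean(draws$delta_ly),
    delta_qaly = mean(draws$delta_qaly)
  )
  mean_result$icer_ly <- icer(mean_result$delta_cost, mean_result$delta_ly)
  mean_result$icer_qaly <- icer(mean_result$delta_cost, mean_result$delta_qaly)
  mean_result$inmb <- inmb(mean_result$delta_cost, mean_result$delta_qaly,
                           params$wtp_threshold)
  structure(list(draws = draws, mean_result = mean_result,
                 wtp = params$wtp_threshold, n_rejections = n_rej,
                 seed = seed),
            class = "txace_psa")
}

#' Summarise a PSA: CEAC and quadrant shares
#'
#' @param psa A `txace_psa` object.
#' @param thresholds Willingness-to-pay grid for the CEAC.
#' @return List with `ceac` (data frame), `quadrants` (named proportions)
#'   and `p_ce` closure giving P(TXA cost-effective) at any threshold.
#' @export
summarise_psa <- function(psa, thresholds = seq(0, 50000, by = 500)) {
  d <- psa$draws
  cc <- ceac(d$delta_cost, d$delta_qaly, thresholds)
  qs <- quadrant_shares(d$delta_cost, d$delta_qaly)
  p_ce <- function(wtp) {
    b <- wtp * d$delta_qaly - d$delta_cost
    (sum(b > 0) + 0.5 * sum(b == 0)) / nrow(d)
  }
  list(ceac = cc, quadrants = qs, p_ce = p_ce)
}

#' @export
print.txace_psa <- function(x, ...) {
  s <- summarise_psa(x, thresholds = c(20000, 30000))
  cat(sprintf("PSA with %d draws (seed %s)\n", nrow(x$draws), x$seed))
  cat(sprintf("  mean incrementals: cost %.2f, LY %.4f, QALY %.4f\n",
              x$mean_result$delta_cost, x$mean_result$delta_ly,
              x$mean_result$delta_qaly))
  cat(sprintf("  P(TXA cost-effective): %.1f%% at 20000, %.1f%% at 30000\n",
              100 * s$p_ce(20000), 100 * s$p_ce(30000)))
  q <- round(100 * s$quadrants)
  cat(sprintf("  quadrants: NE %d%%, SE %d%%, NW %d%%, SW %d%%\n",
              q["NE"], q["SE"], q["NW"], q["SW"]))
  invisible(x)
}
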