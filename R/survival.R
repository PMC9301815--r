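#' Convert a probability over a period to a constant hazard rate
#'
#' @param p Probability of the event within the period, in [0, 1).
#' @param t Period length (any time unit); the returned rate is per that unit.
#' @return The hazard rate -log(1 - p) / t.
#' @export
prob_to_rate <- function(p, t = 1) {
  stopifnot(t > 0)
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1): a probability of 1 implies an infinite rate")
  -log(1 - p) / t
}

#' Convert a constant hazard rate to a probability over a period
#' @param r Hazard rate (per time unit), >= 0.
#' @param t Period length.
#' @return 1 - exp(-r * t).
#' @export
rate_to_prob <- function(r, t = 1) {
  stopifnot(t > 0)
  if (any(r < 0)) stop("rate must be non-negative")
  1 - exp(-r * t)
}

#' Apply a standardised mortality ratio to an annual death probability
#'
#' The SMR multiplies the hazard, not the probability: the adjusted
#' probability is 1 - (1 - q)^smr (constant hazard within the year). This
#' keeps results in [0, 1) even for large SMRs at old ages, where direct
#' probability multiplication would exceed 1.
#'
#' @param q_annual Annual probability of death, in [0, 1).
#' @param smr Hazard multiplier, > 0.
#' @return Adjusted annual probability of death.
#' @export
#' @examples
#' apply_smr(0.01, 5.21)
apply_smr <- function(q_annual, smr) {
  if (any(q_annual < 0 | q_annual >= 1)) stop("q_annual must lie in [0, 1)")
  if (any(smr <= 0)) stop("smr must be positive")
  1 - (1 - q_annual)^smr
}

#' Convert an annual death probability to a daily probability
#'
#' Constant hazard within the year: compounding 365 daily cycles recovers
#' the annual probability. A model year is 365 days; leap years are ignored.
#'
#' @param q_annual Annual probability of death, in [0, 1).
#' @return Daily probability 1 - (1 - q)^(1/365).
#' @export
annual_to_daily <- function(q_annual) {
  if (any(q_annual < 0 | q_annual >= 1)) stop("q_annual must lie in [0, 1)")
  1 - (1 - q_annual)^(1 / 365)
}

#' Build the 28-day trial-period daily death curve
#'
#' Distributes a cumulative 28-day mortality risk over days 1-28 in
#' proportion to a vector of non-negative weights. The unconditional death
#' fraction on day d is `cumulative_risk * w_d / sum(w)`; conditional
#' per-day probabilities are derived so the survival product identity
#' `1 - prod(1 - p_d) == cumulative_risk` holds exactly. Rescaling the
#' cumulative risk (as in treatment-effect application or probabilistic
#' sampling) preserves the day-share proportions.
#'
#' @param cumulative_risk 28-day cumulative probability of death, in [0, 1).
#' @param weights 28 non-negative day weights with a positive sum.
#' @return An object of class `txace_trial_curve`: list with `p_daily`
#'   (28 conditional daily probabilities), `fractions` (unconditional daily
#'   death fractions) and `cumulative_risk`.
#' @export
#' @examples
#' tc <- make_trial_curve(0.092, rep(1, 28))
#' 1 - prod(1 - tc$p_daily) # 0.092
make_trial_curve <- function(cumulative_risk, weights) {
  if (length(weights) != 28L) stop("weights must have length 28")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must have a positive sum")
  if (cumulative_risk < 0 || cumulative_risk >= 1) {
    stop("cumulative_risk must lie in [0, 1)")
  }
  fractions <- cumulative_risk * weights / sum(weights)
  # conditional probability of dying on day d given alive at start of day d
  surv_before <- 1 - c(0, cumsum(fractions)[-28L])
  p_daily <- ifelse(surv_before > 0, fractions / surv_before, 0)
  structure(list(p_daily = p_daily, fractions = fractions,
                 cumulative_risk = cumulative_risk),
            class = "txace_trial_curve")
}

#' Day weights for the trial curve specified in a parameter set
#'
#' `"geometric"` gives a front-loaded curve with the share of deaths on day
#' d proportional to ratio^(d-1); `"uniform"` spreads deaths evenly.
#'
#' @param params A `txace_params` object.
#' @return Numeric vector of 28 weights.
#' @export
trial_curve_weights <- function(params) {
  tc <- params$trial_curve
  switch(tc$shape,
         geometric = tc$ratio^(0:27),
         uniform = rep(1, 28),
         stop("unknown trial curve shape: ", tc$shape))
}

#' Build the per-arm lifetime mortality schedule
#'
#' Constructs the cycle-by-cycle death probabilities of the cohort model:
#' \itemize{
#'   \item days 1-28 (daily cycles): the trial-period curve; for the TXA arm
#'     the cumulative 28-day risk is multiplied by the all-cause mortality
#'     risk ratio with the daily shape preserved;
#'   \item days 29-365 (daily cycles): general-population annual mortality at
#'     the attained age, SMR-adjusted on the hazard scale with the year-1
#'     SMR, converted to daily probabilities;
#'   \item years 2+ (annual 365-day cycles): SMR-adjusted annual mortality
#'     with the year-2+ SMR, until the attained age reaches the horizon age.
#' }
#' The treatment effect acts only within days 1-28. Attained age advances
#' with model time from `start_age`; age lookup uses `floor(attained_age)`.
#'
#' @param params A `txace_params` object.
#' @param life_table A `txace_life_table` covering
#'   `[floor(start_age), horizon_age]`.
#' @param arm `"txa"` or `"no_txa"`.
#' @param curve Optional `txace_trial_curve` for the control arm; defaults to
#'   the curve implied by `params` (28-day risk from the stored counts and
#'   the configured shape).
#' @return A data frame of class `txace_schedule` with columns `start`
#'   (days since model entry), `length` (days), `p_death` (probability of
#'   death within the cycle) and `age` (attained age in years at cycle
#'   start).
#' @export
build_schedule <- function(params, life_table, arm = c("no_txa", "txa"),
                           curve = NULL) {
  arm <- match.arg(arm)
  start_age <- params$start_age
  horizon_age <- params$horizon_age
  if (min(life_table$age) > floor(start_age) || max(life_table$age) < horizon_age) {
    stop("life table must cover [floor(start_age), horizon_age]")
  }
  if (is.null(curve)) {
    # a probabilistic draw of the control-arm risk overrides the count ratio
    risk0 <- if (is.null(params$risk28$draw)) {
      params$risk28$deaths / params$risk28$n
    } else {
      params$risk28$draw
    }
    curve <- make_trial_curve(risk0, trial_curve_weights(params))
  }
  if (arm == "txa") {
    rr <- params$rr_mortality$value
    risk <- curve$cumulative_risk * rr
    if (risk >= 1) {
      stop("RR x 28-day cumulative risk reaches 1; schedule undefined")
    }
    # rr == 1 keeps the curve bit-identical so a null effect is exactly null
    if (rr != 1) curve <- make_trial_curve(risk, curve$fractions)
  }
  qv <- .q_lookup(life_table)

  # year 1: 365 daily cycles (28 trial days + 337 SMR-adjusted days)
  start_y1 <- 0:364
  age_y1 <- start_age + start_y1 / 365
  p_y1 <- numeric(365)
  p_y1[1:28] <- curve$p_daily
  idx <- 29:365
  q_tail <- qv[floor(age_y1[idx]) + 1L]
  p_y1[idx] <- annual_to_daily(apply_smr(q_tail, params$smr_y1$value))

  # years 2+: annual cycles until attained age reaches the horizon
  n_annual <- max(0L, ceiling(horizon_age - (start_age + 1)))
  if (n_annual > 0) {
    start_ann <- 365 * seq_len(n_annual)
    age_ann <- start_age + start_ann / 365
    q_ann <- qv[pmin(floor(age_ann), horizon_age) + 1L]
    p_ann <- ifelse(q_ann >= 1, 1, apply_smr(q_ann, params$smr_y2plus$value))
  } else {
    start_ann <- age_ann <- p_ann <- numeric(0)
  }

  sched <- data.frame(
    start = c(start_y1, start_ann),
    length = c(rep(1, 365), rep(365, n_annual)),
    p_death = c(p_y1, p_ann),
    age = c(age_y1, age_ann)
  )
  class(sched) <- c("txace_schedule", "data.frame")
  sched
}
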