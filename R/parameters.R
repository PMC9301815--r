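#' Default model parameters
#'
#' Returns the complete base-case parameterisation of the lifetime
#' cost-effectiveness model of tranexamic acid (TXA) versus no-TXA for acute
#' gastrointestinal bleeding (AGIB): trial-period mortality, long-term excess
#' mortality (standardised mortality ratios), utilities, resource use, unit
#' costs and run settings. All currency values are GBP (2021 price year);
#' no inflation machinery is provided.
#'
#' Uncertain parameters are stored as `list(value, lo, hi)` (point estimate
#' with a 95\% CI) or as exact event counts `list(k, n)`, so that
#' probabilistic sensitivity analysis can fit distributions from the source
#' summaries rather than from pre-computed proportions.
#'
#' @return An object of class `txace_params`: a named list, see
#'   `vignette("txa-cost-effectiveness")` for the full schema.
#' @export
#' @examples
#' p <- default_parameters()
#' p$rr_mortality$value
default_parameters <- function() {
  p <- list(
    start_age = 58.1,
    horizon_age = 100,
    smr_y1 = list(value = 5.21, lo = 4.25, hi = 6.38),
    smr_y2plus = list(value = 1.74, lo = 1.42, hi = 2.13),
    rr_mortality = list(value = 1.03, lo = 0.92, hi = 1.16),
    risk28 = list(deaths = 548L, n = 5981L),
    utility_survivor = list(value = 0.735, lo = 0.70, hi = 0.77),
    # utility decrement applied by attained age band (subtracted from base)
    utility_decrements = list(under65 = 0, age65_74 = 0.02, age75plus = 0.07),
    discount_rate_costs = 0.035,
    discount_rate_qalys = 0.035,
    wtp_threshold = 20000,
    # within-28-day daily death distribution: share of deaths on day d is
    # proportional to ratio^(d-1) ("geometric"), or flat ("uniform")
    trial_curve = list(shape = "geometric", ratio = 0.9),
    half_cycle_correction = TRUE,
    resource_use = list(
      txa = list(
        total_los = list(mean = 5.83, se = 1.46),
        icu_days = list(mean = 0.4, se = 0.46),
        procedures = list(
          endoscopy_diagnostic  = list(k = 4781L, n = 5953L),
          endoscopy_therapeutic = list(k = 2542L, n = 5953L),
          surgery               = list(k = 146L,  n = 5953L),
          radiology_diagnostic  = list(k = 1704L, n = 5953L),
          radiology_therapeutic = list(k = 74L,   n = 5953L)
        ),
        transfusions = list(
          blood     = list(k = 3984L, n = 5951L, mean_units = 2.80, se_units = 0.61),
          ffp       = list(k = 910L,  n = 5951L, mean_units = 0.90, se_units = 0.61),
          platelets = list(k = 219L,  n = 5951L, mean_units = 0.20, se_units = 0.23)
        )
      ),
      no_txa = list(
        total_los = list(mean = 5.80, se = 1.47),
        icu_days = list(mean = 0.4, se = 0.51),
        procedures = list(
          endoscopy_diagnostic  = list(k = 4729L, n = 5978L),
          endoscopy_therapeutic = list(k = 2658L, n = 5978L),
          surgery               = list(k = 158L,  n = 5978L),
          radiology_diagnostic  = list(k = 1744L, n = 5978L),
          radiology_therapeutic = list(k = 89L,   n = 5978L)
        ),
        transfusions = list(
          blood     = list(k = 4018L, n = 5978L, mean_units = 2.90, se_units = 0.69),
          ffp       = list(k = 993L,  n = 5978L, mean_units = 1.0,  se_units = 0.66),
          platelets = list(k = 255L,  n = 5978L, mean_units = 0.20, se_units = 0.26)
        )
      )
    ),
    unit_costs = list(
      bed_day_nonicu = 338, bed_day_icu = 1594,
      endoscopy_diagnostic = 665, endoscopy_therapeutic = 777,
      surgery = 1377, radiology_diagnostic = 4986, radiology_therapeutic = 4986,
      blood_unit = 132, ffp_unit = 31, platelets_unit = 192
    ),
    txa_admin_components = list(
      drug = 12, needle = 0.05, syringe = 0.07,
      infusion_bag = 0.59, isotonic_solution = 2.96, nurse_time = 14.35
    ),
    postdischarge_costs = list(
      year1 = 4350, year2 = 1980, year3 = 1938,
      # year 4 onwards is this fraction of the year-3 amount
      year4plus_fraction = 1 / 3
    ),
    psa = list(n = 10000L, cost_se_fraction = 0.5, seed = 1L)
  )
  class(p) <- "txace_params"
  p
}

#' @export
print.txace_params <- function(x, ...) {
  risk <- x$risk28$deaths / x$risk28$n
  cat("Cost-effectiveness model parameters (TXA vs no-TXA in AGIB)\n")
  cat(sprintf("  start age %.1f y, horizon age %d\n", x$start_age, x$horizon_age))
  cat(sprintf("  28-day mortality risk %.3f (%d/%d); RR %.2f (%.2f-%.2f)\n",
              risk, x$risk28$deaths, x$risk28$n,
              x$rr_mortality$value, x$rr_mortality$lo, x$rr_mortality$hi))
  cat(sprintf("  SMR year 1: %.2f; year 2+: %.2f\n",
              x$smr_y1$value, x$smr_y2plus$value))
  cat(sprintf("  utility %.3f; discounting %.1f%%/%.1f%% (costs/QALYs)\n",
              x$utility_survivor$value, 100 * x$discount_rate_costs,
              100 * x$discount_rate_qalys))
  invisible(x)
}

# recursively check that every leaf name in `template` exists in `x`
.missing_keys <- function(x, template, prefix = "") {
  out <- character()
  for (nm in names(template)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.null(x[[nm]])) {
      out <- c(out, path)
    } else if (is.list(template[[nm]])) {
      out <- c(out, .missing_keys(x[[nm]], template[[nm]], path))
    }
  }
  out
}

#' Load a model configuration file
#'
#' Reads a YAML configuration mirroring the structure of
#' [default_parameters()] and returns a validated parameter set. By default
#' every key must be present; with `use_defaults = TRUE` missing keys fall
#' back to the shipped base-case values, so a config need only state
#' overrides.
#'
#' @param path Path to a YAML file.
#' @param use_defaults Fall back to the shipped base case for missing keys?
#' @return A validated `txace_params` object.
#' @export
load_config <- function(path, use_defaults = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("config parse failure in '", path, "': ", conditionMessage(e))
  })
  defaults <- unclass(default_parameters())
  if (use_defaults) {
    p <- utils::modifyList(defaults, raw)
  } else {
    miss <- .missing_keys(raw, defaults)
    if (length(miss) > 0) {
      stop("config is missing required keys (use use_defaults = TRUE to fill ",
           "from the base case): ", paste(miss, collapse = ", "))
    }
    p <- utils::modifyList(defaults, raw) # keeps integer storage where possible
  }
  class(p) <- "txace_params"
  assert_valid(p)
  p
}

#' Write a parameter set to a YAML configuration file
#'
#' The written file round-trips: `load_config(write_config(p, f))` compares
#' equal to `p`.
#'
#' @param params A `txace_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path, precision = 15L)
  invisible(path)
}

#' Export a validated parameter set as JSON (provenance log)
#'
#' @param params A `txace_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
params_to_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.check_ci <- function(p, name, out, positive = FALSE) {
  x <- p[[name]]
  if (!(x$lo <= x$value && x$value <= x$hi)) {
    out <- c(out, sprintf("%s: CI (%g, %g) does not bracket point %g",
                          name, x$lo, x$hi, x$value))
  }
  if (positive && x$lo <= 0) {
    out <- c(out, sprintf("%s: lower CI bound must be positive", name))
  }
  out
}

.check_counts <- function(k, n, label, out) {
  if (k < 0 || n <= 0 || k != round(k) || n != round(n)) {
    out <- c(out, sprintf("%s: counts must be non-negative integers (n > 0)", label))
  } else if (k > n) {
    out <- c(out, sprintf("%s: numerator %d exceeds denominator %d", label, k, n))
  }
  out
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameterisation and returns a
#' character vector of violations (empty when valid). This is a reporting
#' operation; it never throws.
#'
#' @param params A `txace_params` object (or plain list with the same shape).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
#' @examples
#' validate_parameters(default_parameters())
validate_parameters <- function(params) {
  p <- params
  v <- character()
  v <- .check_ci(p, "smr_y1", v, positive = TRUE)
  v <- .check_ci(p, "smr_y2plus", v, positive = TRUE)
  v <- .check_ci(p, "rr_mortality", v, positive = TRUE)
  v <- .check_ci(p, "utility_survivor", v)
  u <- p$utility_survivor$value
  if (!(u > 0 && u <= 1)) {
    v <- c(v, sprintf("utility_survivor: value %g outside (0, 1]", u))
  }
  v <- .check_counts(p$risk28$deaths, p$risk28$n, "risk28", v)
  risk <- p$risk28$deaths / p$risk28$n
  if (risk >= 1) v <- c(v, "risk28: derived risk must be < 1")
  for (r in c("discount_rate_costs", "discount_rate_qalys")) {
    if (p[[r]] < 0 || p[[r]] > 0.10) {
      v <- c(v, sprintf("%s: %g outside [0, 0.10]", r, p[[r]]))
    }
  }
  for (d in names(p$utility_decrements)) {
    dd <- p$utility_decrements[[d]]
    if (dd < 0 || dd > u) {
      v <- c(v, sprintf("utility_decrements.%s: %g leaves utility outside [0,1]", d, dd))
    }
  }
  if (p$start_age < 0 || p$start_age >= p$horizon_age) {
    v <- c(v, "start_age must lie in [0, horizon_age)")
  }
  if (!p$trial_curve$shape %in% c("geometric", "uniform")) {
    v <- c(v, sprintf("trial_curve.shape: unknown shape '%s'", p$trial_curve$shape))
  }
  for (arm in c("txa", "no_txa")) {
    ru <- p$resource_use[[arm]]
    for (q in c("total_los", "icu_days")) {
      if (ru[[q]]$mean < 0) v <- c(v, sprintf("%s.%s: mean < 0", arm, q))
      if (ru[[q]]$se < 0) v <- c(v, sprintf("%s.%s: SE < 0", arm, q))
    }
    if (ru$icu_days$mean > ru$total_los$mean) {
      v <- c(v, sprintf("%s: mean ICU days exceed mean total length of stay", arm))
    }
    for (pr in names(ru$procedures)) {
      v <- .check_counts(ru$procedures[[pr]]$k, ru$procedures[[pr]]$n,
                         paste0(arm, ".procedures.", pr), v)
    }
    for (tr in names(ru$transfusions)) {
      t <- ru$transfusions[[tr]]
      v <- .check_counts(t$k, t$n, paste0(arm, ".transfusions.", tr), v)
      if (t$mean_units < 0) v <- c(v, sprintf("%s.transfusions.%s: mean units < 0", arm, tr))
      if (t$se_units < 0) v <- c(v, sprintf("%s.transfusions.%s: SE < 0", arm, tr))
    }
  }
  for (uc in names(p$unit_costs)) {
    if (p$unit_costs[[uc]] < 0) v <- c(v, sprintf("unit_costs.%s < 0", uc))
  }
  for (cc in names(p$txa_admin_components)) {
    if (p$txa_admin_components[[cc]] < 0) {
      v <- c(v, sprintf("txa_admin_components.%s < 0", cc))
    }
  }
  pd <- p$postdischarge_costs
  if (any(unlist(pd[c("year1", "year2", "year3")]) < 0)) {
    v <- c(v, "postdischarge_costs: annual amounts must be >= 0")
  }
  if (pd$year4plus_fraction < 0) {
    v <- c(v, "postdischarge_costs.year4plus_fraction < 0")
  }
  if (p$psa$n < 1) v <- c(v, "psa.n must be >= 1")
  if (p$psa$cost_se_fraction < 0) v <- c(v, "psa.cost_se_fraction < 0")
  if (p$wtp_threshold < 0) v <- c(v, "wtp_threshold < 0")
  v
}

#' Stop on an invalid parameter set
#' @param params A `txace_params` object.
#' @return `params`, invisibly, when valid.
#' @export
assert_valid <- function(params) {
  v <- validate_parameters(params)
  if (length(v) > 0) {
    stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  }
  invisible(params)
}
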