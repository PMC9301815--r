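#' Simulate patient-level two-arm trial data
#'
#' Generates one record per randomised patient with the statistical
#' structure the cohort model assumes: 28-day deaths follow the configured
#' daily death curve (cumulative risk from the stored counts for the
#' control arm, multiplied by the mortality risk ratio for the TXA arm,
#' shape preserved); total and ICU lengths of stay are gamma distributed
#' with the per-arm means and spreads (ICU days truncated at the total
#' stay by resampling); procedure and transfusion indicators are Bernoulli
#' at the stored count proportions; transfusion unit counts are Poisson
#' among recipients with the stored conditional means (zero otherwise), so
#' the unconditional mean is probability x conditional mean.
#'
#' @param truth A `txace_params` object supplying the generating values.
#' @param n_per_arm Patients per arm, >= 1.
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return A data frame with one row per patient: `id`, `arm` (`"txa"` /
#'   `"no_txa"`), `death_day` (1-28, NA if alive at day 28), `total_los`,
#'   `icu_days`, five `proc_*` indicators, three `transf_*` indicators and
#'   three `units_*` counts. The seed is recorded in the `seed` attribute.
#' @export
#' @examples
#' trial <- simulate_trial(default_parameters(), n_per_arm = 100, seed = 1)
#' table(trial$arm, is.na(trial$death_day))
simulate_trial <- function(truth, n_per_arm, seed) {
  stopifnot(n_per_arm >= 1)
  set.seed(as.integer(seed))
  weights <- trial_curve_weights(truth)
  risk_ctl <- truth$risk28$deaths / truth$risk28$n
  arms <- c("txa", "no_txa")
  recs <- lapply(arms, function(arm) {
    risk <- if (arm == "txa") risk_ctl * truth$rr_mortality$value else risk_ctl
    curve <- make_trial_curve(risk, weights)
    # death day: categorical over days 1..28 plus survival
    probs <- c(curve$fractions, 1 - risk)
    day <- sample.int(29L, n_per_arm, replace = TRUE, prob = probs)
    death_day <- ifelse(day == 29L, NA_integer_, day)
    ru <- truth$resource_use[[arm]]
    los_d <- gamma_from_mean_se(ru$total_los$mean, ru$total_los$se)
    icu_d <- gamma_from_mean_se(ru$icu_days$mean, ru$icu_days$se)
    total_los <- rdist(los_d, n_per_arm)
    icu <- rdist(icu_d, n_per_arm)
    bad <- which(icu > total_los)
    while (length(bad) > 0) {
      icu[bad] <- rdist(icu_d, length(bad))
      bad <- bad[icu[bad] > total_los[bad]]
    }
    df <- data.frame(arm = arm, death_day = death_day,
                     total_los = total_los, icu_days = icu,
                     stringsAsFactors = FALSE)
    for (nm in names(ru$procedures)) {
      pr <- ru$procedures[[nm]]
      df[[paste0("proc_", nm)]] <- stats::rbinom(n_per_arm, 1L, pr$k / pr$n)
    }
    for (nm in names(ru$transfusions)) {
      tr <- ru$transfusions[[nm]]
      ind <- stats::rbinom(n_per_arm, 1L, tr$k / tr$n)
      units <- integer(n_per_arm)
      units[ind == 1L] <- stats::rpois(sum(ind), tr$mean_units)
      df[[paste0("transf_", nm)]] <- ind
      df[[paste0("units_", nm)]] <- units
    }
    df
  })
  out <- do.call(rbind, recs)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write / read patient-level trial records
#'
#' The CSV carries the generating seed in a `# seed:` metadata comment line
#' before the header; [read_trial_csv()] restores it as an attribute.
#'
#' @param records Data frame from [simulate_trial()].
#' @param path Output path.
#' @return `path` ([write_trial_csv()]) or the records data frame
#'   ([read_trial_csv()]).
#' @export
write_trial_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(records, "seed")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  first <- readLines(path, n = 1)
  has_meta <- startsWith(first, "# seed:")
  rec <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (has_meta) attr(rec, "seed") <- as.integer(sub("# seed:\\s*", "", first))
  rec
}

.mean_se <- function(x) {
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

#' Estimate model parameters from patient-level trial records
#'
#' Recovers the trial-derived slots of the parameter set from simulated (or
#' similarly structured) records: the control-arm 28-day mortality risk with
#' its event counts, the mortality risk ratio with a log-scale 95\% CI,
#' per-arm length-of-stay and ICU means with standard errors, procedure and
#' transfusion event counts, and mean transfusion units among recipients
#' (the stored convention). The result can be patched into a parameter set
#' with [patch_parameters()].
#'
#' @param records Data frame from [simulate_trial()] / [read_trial_csv()].
#' @return List with `risk28`, `rr_mortality` (point and CI; NA with a
#'   warning if either arm has zero deaths), and `resource_use` per arm.
#' @export
estimate_parameters <- function(records) {
  if (!all(c("txa", "no_txa") %in% records$arm)) {
    stop("records must contain both trial arms")
  }
  by_arm <- split(records, records$arm)
  deaths <- vapply(by_arm, function(d) sum(!is.na(d$death_day)), integer(1))
  n <- vapply(by_arm, nrow, integer(1))
  risk <- deaths / n
  if (deaths[["no_txa"]] == 0 || deaths[["txa"]] == 0) {
    warning("zero deaths in an arm: risk ratio undefined")
    rr <- list(value = NA_real_, lo = NA_real_, hi = NA_real_)
  } else {
    est <- risk[["txa"]] / risk[["no_txa"]]
    # log-scale SE of a risk ratio from two binomial proportions
    se_log <- sqrt(1 / deaths[["txa"]] - 1 / n[["txa"]] +
                   1 / deaths[["no_txa"]] - 1 / n[["no_txa"]])
    z <- stats::qnorm(0.975)
    rr <- list(value = unname(est), lo = unname(est * exp(-z * se_log)),
               hi = unname(est * exp(z * se_log)))
  }
  ru <- lapply(by_arm, function(d) {
    proc_cols <- grep("^proc_", names(d), value = TRUE)
    transf_cols <- grep("^transf_", names(d), value = TRUE)
    procedures <- lapply(proc_cols, function(cl) {
      list(k = sum(d[[cl]]), n = nrow(d))
    })
    names(procedures) <- sub("^proc_", "", proc_cols)
    transfusions <- lapply(transf_cols, function(cl) {
      nm <- sub("^transf_", "", cl)
      got <- d[[cl]] == 1L
      units <- d[[paste0("units_", nm)]][got]
      list(k = sum(got), n = nrow(d),
           mean_units = if (length(units)) mean(units) else 0,
           se_units = if (length(units) > 1) stats::sd(units) / sqrt(length(units)) else 0)
    })
    names(transfusions) <- sub("^transf_", "", transf_cols)
    list(total_los = .mean_se(d$total_los), icu_days = .mean_se(d$icu_days),
         procedures = procedures, transfusions = transfusions)
  })
  list(
    risk28 = list(deaths = unname(deaths[["no_txa"]]), n = unname(n[["no_txa"]])),
    rr_mortality = rr,
    resource_use = list(txa = ru[["txa"]], no_txa = ru[["no_txa"]])
  )
}

#' Patch estimated parameters into a parameter set
#'
#' Overwrites the trial-derived slots of `params` with the estimates from
#' [estimate_parameters()], leaving all literature-derived and cost inputs
#' unchanged. Closes the loop from patient-level records back to a runnable
#' model parameterisation.
#'
#' @param params A `txace_params` object.
#' @param estimates Output of [estimate_parameters()].
#' @return The updated `txace_params`.
#' @export
patch_parameters <- function(params, estimates) {
  params$risk28 <- estimates$risk28
  if (!is.na(estimates$rr_mortality$value)) {
    params$rr_mortality <- estimates$rr_mortality
  }
  for (arm in c("txa", "no_txa")) {
    est <- estimates$resource_use[[arm]]
    params$resource_use[[arm]]$total_los <- est$total_los
    params$resource_use[[arm]]$icu_days <- est$icu_days
    for (nm in names(est$procedures)) {
      params$resource_use[[arm]]$procedures[[nm]]$k <- est$procedures[[nm]]$k
      params$resource_use[[arm]]$procedures[[nm]]$n <- est$procedures[[nm]]$n
    }
    for (nm in names(est$transfusions)) {
      params$resource_use[[arm]]$transfusions[[nm]] <- est$transfusions[[nm]]
    }
  }
  params
}
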