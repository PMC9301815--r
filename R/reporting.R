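#' Base-case report with cost breakdown
#'
#' Runs the deterministic model and tabulates per-arm totals with the cost
#' breakdown in two groupings: the model's own four components (TXA
#' administration, inpatient stay, procedures, transfusions, lifetime
#' monitoring) and a publication-style grouping (TXA cost; hospital stay,
#' procedures and transfusions combined; monitoring).
#'
#' @param params A `txace_params` object.
#' @param life_table A `txace_life_table`.
#' @return List with `table` (per-arm data frame), `result` (the
#'   `txace_ce_result`).
#' @export
report_base_case <- function(params, life_table = default_life_table()) {
  res <- run_model(params, life_table)
  comp <- lapply(c(no_txa = "no_txa", txa = "txa"), function(arm) {
    sched <- build_schedule(params, life_table, arm)
    build_cost_schedule(params, arm, sched)
  })
  per_arm <- function(arm, totals) {
    cm <- comp[[arm]]$components
    monitoring <- totals$cost - comp[[arm]]$entry_cost
    data.frame(
      arm = arm,
      total_cost = totals$cost,
      txa_cost = cm[["txa_admin"]],
      inpatient = cm[["inpatient"]],
      procedures = cm[["procedures"]],
      transfusions = cm[["transfusions"]],
      hospital_combined = cm[["inpatient"]] + cm[["procedures"]] + cm[["transfusions"]],
      monitoring = monitoring,
      ly = totals$ly, qaly = totals$qaly,
      stringsAsFactors = FALSE
    )
  }
  tab <- rbind(per_arm("no_txa", res$no_txa), per_arm("txa", res$txa))
  rownames(tab) <- NULL
  list(table = tab, result = res)
}

#' Write a run manifest for provenance
#'
#' Records the configuration hash (MD5 of the serialised parameter set),
#' seed, package version, timestamp, invoking command and the list of
#' output files, as JSON next to the outputs. Re-running with the same
#' configuration and seed reproduces all stochastic outputs bit-for-bit.
#'
#' @param params A `txace_params` object.
#' @param seed Seed used for any stochastic output (NA for deterministic).
#' @param command Character description of the command run.
#' @param outputs Character vector of output file paths.
#' @param path Manifest output path.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(params, seed, command, outputs, path) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(params, tmp)
  manifest <- list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("txace")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export PSA draws and summaries to CSV
#'
#' Writes the per-draw scatter (`*_draws.csv`: draw, sampled values,
#' incremental cost/LY/QALY) and the CEAC (`*_ceac.csv`: threshold,
#' P(TXA), P(no-TXA)).
#'
#' @param psa A `txace_psa` object.
#' @param prefix Path prefix for the two files.
#' @param thresholds CEAC willingness-to-pay grid.
#' @return Character vector of the files written, invisibly.
#' @export
write_psa_csv <- function(psa, prefix, thresholds = seq(0, 50000, by = 500)) {
  s <- summarise_psa(psa, thresholds)
  draws_path <- paste0(prefix, "_draws.csv")
  ceac_path <- paste0(prefix, "_ceac.csv")
  utils::write.csv(psa$draws, draws_path, row.names = FALSE)
  cc <- s$ceac
  names(cc) <- c("wtp", "p_txa", "p_no_txa")
  utils::write.csv(cc, ceac_path, row.names = FALSE)
  invisible(c(draws_path, ceac_path))
}
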