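#!/usr/bin/env Rscript
# Thin command-line front end over the txace package.
#
# Usage:
#   Rscript scripts/txace.R <command> [--config FILE] [--life-table FILE]
#                           [--seed INT] [--n-draws INT] [--out-dir DIR]
# Commands:
#   base-case      deterministic per-arm totals, incrementals, ICERs, INMB
#   dsa            one-way deterministic sensitivity analysis table
#   psa            probabilistic sensitivity analysis (draws + CEAC CSVs)
#   scenario-meta  pre-trial meta-analysis scenario (deterministic + PSA)
#   simulate-trial synthetic patient-level trial records CSV
#   estimate       re-estimate parameters from a records CSV (--records FILE)
suppressPackageStartupMessages(library(txace))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: txace.R <command> [options]; see header")
command <- args[[1]]

opt <- list(config = NULL, `life-table` = NULL, seed = 1L, `n-draws` = NULL,
            `out-dir` = "txace_out", records = NULL, `n-per-arm` = 6000L)
rest <- args[-1]
i <- 1
while (i <= length(rest)) {
  key <- sub("^--", "", rest[[i]])
  if (!key %in% names(opt)) stop("unknown option: ", rest[[i]])
  opt[[key]] <- rest[[i + 1]]
  i <- i + 2
}
opt$seed <- as.integer(opt$seed)
opt$`n-per-arm` <- as.integer(opt$`n-per-arm`)

params <- if (is.null(opt$config)) default_parameters() else
  load_config(opt$config, use_defaults = TRUE)
lt <- if (is.null(opt$`life-table`)) default_life_table() else
  read_life_table(opt$`life-table`)
n_draws <- if (is.null(opt$`n-draws`)) params$psa$n else as.integer(opt$`n-draws`)
out_dir <- opt$`out-dir`
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
outfile <- function(name) file.path(out_dir, name)

fmt_gbp <- function(x) formatC(round(x), format = "d", big.mark = " ")

finish <- function(outputs, seed = NA) {
  manifest_path <- outfile(paste0(command, "_manifest.json"))
  write_run_manifest(params, seed, paste(c("txace.R", args), collapse = " "),
                     outputs, manifest_path)
  cat("outputs:\n", paste(" ", c(outputs, manifest_path), collapse = "\n"), "\n")
}

if (command == "base-case") {
  rep <- report_base_case(params, lt)
  print(rep$result)
  tab <- rep$table
  for (col in c("total_cost", "txa_cost", "hospital_combined", "monitoring")) {
    cat(sprintf("  %-18s no-TXA %10s   TXA %10s\n", col,
                fmt_gbp(tab[[col]][1]), fmt_gbp(tab[[col]][2])))
  }
  path <- outfile("base_case.csv")
  write.csv(tab, path, row.names = FALSE)
  finish(path)
} else if (command == "dsa") {
  dsa <- run_dsa(params, lt)
  print(cbind(dsa["scenario"], round(dsa[2:7], 2), dsa["quadrant"]))
  path <- outfile("dsa.csv")
  write.csv(dsa, path, row.names = FALSE)
  finish(path)
} else if (command == "psa") {
  psa <- run_psa(params, lt, n_draws = n_draws, seed = opt$seed)
  print(psa)
  paths <- write_psa_csv(psa, outfile("psa"))
  finish(paths, seed = opt$seed)
} else if (command == "scenario-meta") {
  mp <- meta_analysis_params(params)
  res <- run_model(mp, lt)
  print(res)
  psa <- run_psa(mp, lt, n_draws = n_draws, seed = opt$seed)
  s <- summarise_psa(psa, thresholds = params$wtp_threshold)
  cat(sprintf("  P(TXA cost-effective at %s): %.1f%%\n",
              fmt_gbp(params$wtp_threshold), 100 * s$p_ce(params$wtp_threshold)))
  paths <- write_psa_csv(psa, outfile("scenario_meta"))
  finish(paths, seed = opt$seed)
} else if (command == "simulate-trial") {
  rec <- simulate_trial(params, n_per_arm = opt$`n-per-arm`, seed = opt$seed)
  path <- outfile("trial_records.csv")
  write_trial_csv(rec, path)
  cat(sprintf("simulated %d records (%d per arm)\n", nrow(rec), opt$`n-per-arm`))
  finish(path, seed = opt$seed)
} else if (command == "estimate") {
  if (is.null(opt$records)) stop("estimate requires --records FILE")
  est <- estimate_parameters(read_trial_csv(opt$records))
  cat(sprintf("28-day risk %.4f (%d/%d); RR %.3f (%.3f-%.3f)\n",
              est$risk28$deaths / est$risk28$n, est$risk28$deaths, est$risk28$n,
              est$rr_mortality$value, est$rr_mortality$lo, est$rr_mortality$hi))
  path <- outfile("estimates.json")
  jsonlite::write_json(est, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  finish(path)
} else {
  stop("unknown command: ", command)
}
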