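#!/usr/bin/env Rscript
# Thin command-line front end over the sleepcrit package.
#
#   Rscript scripts/sleepcrit.R analyze  --config cfg.yaml --input rec.edf [--input ...] --out dir/
#   Rscript scripts/sleepcrit.R simulate --config sim.yaml --out dir/
#   Rscript scripts/sleepcrit.R model    --config model.yaml --out dir/
#   Rscript scripts/sleepcrit.R dfa      --input durations.tsv --out dir/
#
# Exit codes: 0 success, 1 configuration error, 2 data error.

suppressMessages(library(sleepcrit))

fail <- function(code, msg) { message(msg); quit(status = code) }

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) fail(1, "usage: sleepcrit.R <analyze|simulate|model|dfa> ...")
cmd <- args[1]; args <- args[-1]

opts <- list(input = character(0))
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (key == "input") opts$input <- c(opts$input, args[i + 1])
  else opts[[key]] <- args[i + 1]
  i <- i + 2
}
if (is.null(opts$out)) fail(1, "--out is required")

cfg_or_die <- function() {
  if (is.null(opts$config)) return(analysis_config())
  tryCatch(read_analysis_config(opts$config),
           error = function(e) fail(1, conditionMessage(e)))
}

if (cmd == "analyze") {
  if (length(opts$input) == 0) fail(1, "--input is required")
  cfg <- cfg_or_die()
  tryCatch(run_analysis(as.list(opts$input), cfg, out_dir = opts$out),
           error = function(e) fail(2, conditionMessage(e)))
} else if (cmd == "simulate") {
  sim <- if (is.null(opts$config)) list() else yaml::read_yaml(opts$config)
  N <- if (is.null(sim$N)) 500L else sim$N
  w <- if (is.null(sim$w)) 5 else sim$w
  seed <- if (is.null(sim$seed)) 1L else sim$seed
  bs <- generate_duration_sequence(N = N, w = w, seed = seed)
  spec <- eeg_synth_spec(snr_db = if (is.null(sim$snr_db)) 10 else sim$snr_db,
                         seed = seed + 1L)
  write_simulation(bs, spec, opts$out)
} else if (cmd == "model") {
  m <- if (is.null(opts$config)) list() else yaml::read_yaml(opts$config)
  cfg <- do.call(burst_model_config, m)
  out <- run_model(cfg)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_burst_table(out$fine, file.path(opts$out, "model_fine.tsv"))
  write_burst_table(out$coarse, file.path(opts$out, "model_coarse.tsv"))
} else if (cmd == "dfa") {
  if (length(opts$input) == 0) fail(1, "--input is required")
  tab <- tryCatch(read.table(opts$input, header = TRUE, sep = "\t"),
                  error = function(e) fail(2, conditionMessage(e)))
  col <- intersect(c("duration_s", "d", "value"), names(tab))
  if (length(col) == 0) fail(2, "no duration column found")
  res <- dfa(tab[[col[1]]])
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_dfa(res, file.path(opts$out, "dfa.tsv"))
  jsonlite::write_json(list(alpha_d = res$alpha_d,
                            alpha_d_se = res$alpha_d_se,
                            fit_range = res$fit_range),
                       file.path(opts$out, "dfa.json"), auto_unbox = TRUE,
                       digits = 10)
} else {
  fail(1, paste("unknown command:", cmd))
}
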