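#!/usr/bin/env Rscript

# Thin shell entry point over the package pipeline:
#   Rscript scripts/run_pipeline.R --config run.yaml [--seed 1] [--out dir]
# Exit codes: 0 success, 2 config error, 3 data validation error,
# 4 inference error.

suppressMessages(library(coralheat))

args <- commandArgs(trailingOnly = TRUE)
if ("--version" %in% args) {
  cat(as.character(utils::packageVersion("coralheat")), "\n")
  quit(status = 0)
}
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
cfg_path <- get_arg("--config")
if (is.null(cfg_path) || !file.exists(cfg_path)) {
  message("usage: Rscript scripts/run_pipeline.R --config <run.yaml> [--seed n] [--out dir]")
  quit(status = 2)
}

status <- 0
tryCatch({
  cfg <- read_run_config(cfg_path)
  seed <- get_arg("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- get_arg("--out")
  if (!is.null(out)) cfg$output_dir <- out
  res <- run_full_analysis(cfg)
  cat(sprintf("run complete: %d colonies scored, outputs in %s\n",
              res$summary$n_colonies_scored, res$output_dir))
}, coralheat_config_error = function(e) {
  message("config error: ", conditionMessage(e)); status <<- 2
}, coralheat_validation_error = function(e) {
  message("validation error: ", conditionMessage(e)); status <<- 3
}, coralheat_schema_error = function(e) {
  message("schema error: ", conditionMessage(e)); status <<- 3
}, error = function(e) {
  message("error: ", conditionMessage(e)); status <<- 4
})
quit(status = status)
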