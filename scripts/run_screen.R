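#!/usr/bin/env Rscript
# Thin command-line wrapper over the package pipeline.
#
#   Rscript scripts/run_screen.R --config run.yaml [--out-dir DIR]
#
# The YAML schema mirrors run_config()/sim_config()/rank_params()/
# read_layout(); see ?read_run_config.

suppressPackageStartupMessages(library(prscreen))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
config_path <- get_arg("--config")
if (is.null(config_path)) {
  stop("usage: Rscript scripts/run_screen.R --config run.yaml [--out-dir DIR]")
}
status <- tryCatch({
  run_pipeline(read_run_config(config_path, out_dir = get_arg("--out-dir")))
  0L
}, error = function(e) {
  message("pipeline failed: ", conditionMessage(e))
  1L
})
quit(status = status)
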