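#!/usr/bin/env Rscript
# Thin shell entry point over malefert::run_pipeline(). Usage:
#   Rscript scripts/pipeline.R --config config.yml [--out-dir DIR] [--seed N]
# The YAML keys mirror malefert::pipeline_config(); --out-dir and --seed
# override the config file.

suppressPackageStartupMessages({
  library(optparse)
  library(malefert)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character",
              help = "YAML pipeline configuration"),
  make_option("--out-dir", type = "character", default = NULL,
              dest = "out_dir", help = "override output directory"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override seed"))))

if (is.null(opts$config)) stop("--config is required", call. = FALSE)
config <- read_pipeline_config(opts$config)
if (!is.null(opts$out_dir)) config$out_dir <- opts$out_dir
if (!is.null(opts$seed)) config$seed <- opts$seed

manifest <- run_pipeline(config)
cat("pipeline complete:", file.path(config$out_dir, "manifest.json"), "\n")
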