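#!/usr/bin/env Rscript
# Thin command-line wrapper over msatpop::run_all(). Either analyse real
# input tables or generate-and-analyse a synthetic dataset.
#
#   Rscript scripts/run_pipeline.R --isolates isolates.csv --panel panel.csv \
#       --outdir run1 --seed 1
#   Rscript scripts/run_pipeline.R --simulate --outdir run2 --seed 1 \
#       --skip-structure

suppressPackageStartupMessages({
  library(optparse)
  library(msatpop)
})

parser <- OptionParser(option_list = list(
  make_option("--isolates", type = "character", default = NULL,
              help = "isolate genotype table (CSV/TSV)"),
  make_option("--panel", type = "character", default = NULL,
              help = "commercial reference panel (CSV/TSV)"),
  make_option("--simulate", action = "store_true", default = FALSE,
              help = "generate a synthetic dataset instead of reading inputs"),
  make_option("--outdir", type = "character", default = "msatpop_run",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed [default %default]"),
  make_option("--permutations", type = "integer", default = 199L,
              help = "permutations for F_ST / R2 tests [default %default]"),
  make_option("--k-range", type = "character", default = "1:6", dest = "k_range",
              help = "K values for DIC selection, e.g. 1:8 [default %default]"),
  make_option("--iterations", type = "integer", default = 20000L,
              help = "MCMC sweeps per chain [default %default]"),
  make_option("--burn-in", type = "integer", default = 5000L, dest = "burn_in",
              help = "MCMC burn-in [default %default]"),
  make_option("--skip-structure", action = "store_true", default = FALSE,
              dest = "skip_structure", help = "skip the admixture MCMC stage")
))
opt <- parse_args(parser)

kr <- eval(parse(text = opt$k_range))
cfg <- run_config(
  isolates_path = opt$isolates, panel_path = opt$panel,
  simulate = if (opt$simulate) sim_config(seed = opt$seed) else NULL,
  n_permutations = opt$permutations,
  run_structure = !opt$skip_structure, k_range = kr,
  iterations = opt$iterations, burn_in = opt$burn_in,
  seed = opt$seed, outdir = opt$outdir)

t0 <- Sys.time()
res <- run_all(cfg)
cat(sprintf("pipeline finished in %.1f s: %d isolates, %d MLGs -> %s\n",
            as.numeric(Sys.time() - t0, units = "secs"),
            res$n_isolates, res$n_mlgs, cfg$outdir))
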