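#!/usr/bin/env Rscript

# Calibrates the clonality-index cutoff from a user-supplied external
# mutation catalog (for example a TCGA liver-cancer MAF exported as TSV
# with columns chrom, pos, ref, alt, sample). This requires restricted
# external data and network access to obtain it, so it is a standalone
# utility, not part of the test suite.
#
# Usage:
#   Rscript scripts/calibrate_external_catalog.R \
#       --catalog tcga_lihc_mutations.tsv [--n-tumors 200] [--seed 1] \
#       [--reference-cutoff 36.59]
#
# The script samples the requested number of tumors from the catalog,
# builds per-tumor mutation sets and the occurrence catalog, runs the
# 100-repeat subsampling calibration and prints the median cutoff
# (optionally next to a published reference value for comparison).

suppressPackageStartupMessages({
  library(recurrevol)
  library(dplyr)
})

args <- commandArgs(trailingOnly = TRUE)
opt <- list(catalog = NULL, n_tumors = 200L, seed = 1L,
            reference_cutoff = NA_real_)
i <- 1L
while (i <= length(args)) {
  key <- args[i]
  val <- args[i + 1]; i <- i + 2L
  switch(key,
         "--catalog" = { opt$catalog <- val },
         "--n-tumors" = { opt$n_tumors <- as.integer(val) },
         "--seed" = { opt$seed <- as.integer(val) },
         "--reference-cutoff" = { opt$reference_cutoff <- as.numeric(val) },
         stop("unknown argument: ", key))
}
if (is.null(opt$catalog)) stop("--catalog is required")

raw <- readr::read_tsv(opt$catalog, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", ref = "c",
                                               alt = "c", sample = "c",
                                               .default = readr::col_guess()))
norm <- normalize_variant(raw$chrom, raw$pos, raw$ref, raw$alt)
raw$key <- norm$key

tumors <- unique(raw$sample)
set.seed(opt$seed)
if (length(tumors) > opt$n_tumors) {
  tumors <- sample(tumors, opt$n_tumors)
}
sets <- lapply(tumors, function(t) unique(raw$key[raw$sample == t]))
catalog <- cohort_catalog(table(raw$key), n_tumors = length(tumors))

cal <- calibrate_ci_cutoff(sets, catalog, repeats = 100, seed = opt$seed)
cat(sprintf("tumors: %d; mutations: %d\n", length(sets), catalog$n_total))
cat(sprintf("median calibrated cutoff: %.2f (accuracy %.4f)\n",
            cal$cutoff, cal$accuracy))
if (!is.na(opt$reference_cutoff)) {
  cat(sprintf("reference cutoff: %.2f (difference %+.2f)\n",
              opt$reference_cutoff, cal$cutoff - opt$reference_cutoff))
}
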