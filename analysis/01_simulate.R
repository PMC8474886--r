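#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study inputs.
#
# Generates the default two-dataset compendium (8 planted sources, 4 shared
# across datasets, spike-and-slab gene weights, group-shifted mixing,
# Gaussian noise), its gene-set collection (per-source signal blocks plus
# random sets), and the drug / immune response tables. Everything is
# written as plain text under results/data/ and re-read by later stages.

suppressPackageStartupMessages(library(metica))

dir.create("results/cache", showWarnings = FALSE, recursive = TRUE)

manifest <- read_manifest(system.file("extdata",
                                      "compendium_manifest.json",
                                      package = "metica"))
s <- summarize_manifest(manifest)
message(sprintf(paste0("real compendium bookkeeping: %d samples over %d ",
                       "datasets, %d metabolic gene sets, %d cell-line ",
                       "samples"),
                s$total_samples, length(manifest$datasets),
                s$total_gene_sets, s$total_cell_line_samples))

config <- synthetic_config()
study <- simulate_study(config)
paths <- write_study(study, "results/data")
message("wrote ", length(paths), " input files under results/data/")
for (d in names(study$datasets)) {
  message(sprintf("  %s: %d genes x %d samples", d,
                  nrow(study$datasets[[d]]$values),
                  ncol(study$datasets[[d]]$values)))
}
message(sprintf("  %d gene sets (%d planted signal blocks), %d drugs, %d immune types",
                length(study$gene_sets$sets),
                length(unique(stats::na.omit(
                  attr(study$gene_sets, "set_blocks")$source))),
                ncol(study$drug), ncol(study$immune)))

saveRDS(study, "results/cache/study.rds")
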