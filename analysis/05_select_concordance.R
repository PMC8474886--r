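#!/usr/bin/env Rscript
# Stage 5 — nominate metabolic components and call cross-dataset
# concordance.
#
# Selection applies the two per-cluster top-3 rules (max single-set |z|
# and |mean z|) against the planted gene-set blocks relevant to each
# dataset. Concordance between the two datasets' selected components uses
# the |weight| > 3 top-gene overlap (10,000-draw permutation null) plus
# Spearman correlation of the overlapping weights, with the
# |rho| > 0.5 & both p < 0.05 rule.

suppressPackageStartupMessages(library(metica))

study <- readRDS("results/cache/study.rds")
fits <- readRDS("results/cache/fits.rds")
enr <- readRDS("results/cache/enrichment.rds")
blocks <- attr(study$gene_sets, "set_blocks")

mtcs <- list()
for (d in names(fits)) {
  rel <- blocks[!is.na(blocks$source) &
                  blocks$dataset %in% c("shared", d), ]
  asg <- stats::setNames(rel$source, rel$set)
  sel <- select_mtcs(enr[[d]], asg[names(asg) %in% rownames(enr[[d]]$z)])
  mtcs[[d]] <- sel
  message(sprintf("%s: %d mTCs selected over %d gene-set clusters", d,
                  length(sel$mtc_ids),
                  length(unique(sel$provenance$cluster))))
  utils::write.table(sel$provenance, sprintf("results/mtc_%s.tsv", d),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

pairs <- call_concordance(fits[["D1"]]$components, fits[["D2"]]$components,
                          mtcs_a = mtcs[["D1"]]$mtc_ids,
                          mtcs_b = mtcs[["D2"]]$mtc_ids,
                          n_perm = 10000, seed = 3)
utils::write.table(pairs, "results/concordance_pairs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
s <- concordance_summary(pairs)
message(sprintf("concordant pairs: %d of %d", sum(pairs$concordant),
                nrow(pairs)))
for (i in seq_len(nrow(s$per_dataset))) {
  r <- s$per_dataset[i, ]
  message(sprintf("  %s: %d/%d mTCs concordant with the other dataset (%.0f%%)",
                  r$dataset, r$n_concordant, r$n_mtcs,
                  100 * r$fraction_concordant))
}
saveRDS(list(mtcs = mtcs, pairs = pairs), "results/cache/selection.rds")
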