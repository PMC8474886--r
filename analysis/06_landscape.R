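#!/usr/bin/env Rscript
# Stage 6 — the metabolic landscape: subtypes, explained variance, and
# association screens.
#
# Samples are clustered on the correlation distance of their mTC activity
# profiles with ward.D2 linkage; the dendrogram is cut at the first height
# in the sweep where the smallest cluster reaches the minimum size.
# Explained variance attributes each component's share of a sample's
# squared activity and is averaged per sample group. Activities of the
# cell-line dataset are screened against the drug IC50 and immune-fraction
# tables with Spearman correlation (|rho| > 0.2 flags).

suppressPackageStartupMessages(library(metica))

study <- readRDS("results/cache/study.rds")
fits <- readRDS("results/cache/fits.rds")
sel <- readRDS("results/cache/selection.rds")

## subtypes on the dedicated subtype-structure study
scf <- subtype_structure_config()
sst <- generate_compendium(scf)
sfit <- decompose(sst$datasets[[1]], n_components = 12, n_runs = 25,
                  seed = 21)
keep <- sfit$components$stability >= 0.9
stp <- subtype_samples(sfit$mixing$activities[, keep, drop = FALSE],
                       min_cluster_size = 20, sweep = c(0, 400, 0.2))
ari <- mclust::adjustedRandIndex(stp$assignment,
                                 sst$truth$group_labels[["D1"]])
message(sprintf("subtype study: %d subtypes at height %.1f, ARI vs planted groups = %.3f",
                stp$n_subtypes, stp$cut_height, ari))
utils::write.table(
  data.frame(sample = names(stp$assignment), subtype = stp$assignment),
  "results/subtypes.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
med <- subtype_medians(sfit$mixing$activities[, keep, drop = FALSE], stp)
utils::write.table(
  data.frame(subtype = rownames(med), med, check.names = FALSE),
  "results/subtype_median_activity.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

## explained variance per sample group on the default compendium
for (d in names(fits)) {
  ev <- explained_variance(fits[[d]]$mixing,
                           groups = study$truth$group_labels[[d]])
  message(sprintf("%s: %d/%d components exceed 10%% mean explained variance in some group",
                  d, sum(ev$flagged), length(ev$flagged)))
  utils::write.table(
    data.frame(group = rownames(ev$per_group), ev$per_group,
               check.names = FALSE),
    sprintf("results/ev_groups_%s.tsv", d),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

## association screens on the cell-line dataset (D2)
act <- fits[["D2"]]$mixing
drug <- associate(act, study$drug, threshold = 0.2)
immune <- associate(act, study$immune, threshold = 0.2)
message(sprintf("drug screen: %d/%d (component, drug) pairs flagged at |rho| > 0.2",
                sum(drug$flagged), nrow(drug)))
message(sprintf("immune screen: %d/%d pairs flagged", sum(immune$flagged),
                nrow(immune)))
utils::write.table(drug, "results/associations_drug.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(immune, "results/associations_immune.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("landscape stage complete; see results/ for all tables")
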