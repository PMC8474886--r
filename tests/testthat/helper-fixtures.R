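# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Default two-dataset compendium with gene sets and response tables.
default_study <- function() {
  fixture("default_study", function() simulate_study(synthetic_config()))
}

# Consensus decompositions of the default compendium (K = 12, R = 25).
default_fits <- function() {
  fixture("default_fits", function() {
    st <- default_study()
    fits <- lapply(seq_along(st$datasets), function(d) {
      decompose(st$datasets[[d]], n_components = 12, n_runs = 25,
                stability_threshold = 0.5, seed = 100 + d)
    })
    names(fits) <- names(st$datasets)
    fits
  })
}

# Credibility-screened view of a decomposition: components reproduced in at
# least `thr` of the runs.
screen_fit <- function(fit, thr = 0.9) {
  keep <- fit$components$stability >= thr
  fit$components$weights <- fit$components$weights[, keep, drop = FALSE]
  fit$components$stability <- fit$components$stability[keep]
  fit$mixing$activities <- fit$mixing$activities[, keep, drop = FALSE]
  fit
}

screened_fits <- function() {
  fixture("screened_fits", function() lapply(default_fits(), screen_fit))
}

# Best |Pearson| match of every planted source to the fitted components.
match_sources <- function(truth_sources, components) {
  cc <- abs(stats::cor(truth_sources, components$weights))
  data.frame(source = rownames(cc),
             component = colnames(cc)[apply(cc, 1, which.max)],
             cor = apply(cc, 1, max),
             stringsAsFactors = FALSE)
}

# Planted-block study for gene-set clustering plus enrichment of its
# decomposition (seeded by the study's own master seed: the enrichment
# matrix is part of the fixture, the clustering seed is what varies).
blocks_enrichment <- function() {
  fixture("blocks_enrichment", function() {
    cf <- planted_blocks_config()
    st <- generate_compendium(cf)
    gsc <- generate_gene_sets(cf, st$truth)
    fit <- decompose(st$datasets[[1]], n_components = 12, n_runs = 15,
                     seed = cf$seed)
    blocks <- attr(gsc, "set_blocks")
    e <- enrich_all(fit$components, gsc)
    list(enrichment = e, gene_sets = gsc, truth = st$truth, fit = fit,
         block_labels = stats::setNames(blocks$source,
                                        blocks$set)[rownames(e$z)])
  })
}

read_matrix_tsv_test <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[-1])
  rownames(m) <- as.character(tab[[1]])
  m
}

# Subtype-structure study with its screened decomposition.
subtype_fit <- function() {
  fixture("subtype_fit", function() {
    cf <- subtype_structure_config()
    st <- generate_compendium(cf)
    fit <- screen_fit(decompose(st$datasets[[1]], n_components = 12,
                                n_runs = 25, seed = 21))
    list(fit = fit, truth = st$truth)
  })
}
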