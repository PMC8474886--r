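#' Configuration for the synthetic compendium generator
#'
#' Defines a multi-dataset expression compendium with planted ground truth:
#' additive gene-weight sources shared (or not) across datasets, sample
#' groups with shifted source activity, gene sets enriched in planted
#' sources, and drug / immune columns monotonically tied to source activity.
#' The generator is the oracle for every downstream stage: decomposition
#' should recover the sources, enrichment should light up the planted sets,
#' set clustering should recover the planted blocks, and the association
#' screens should flag the planted drug and immune targets.
#'
#' Source gene weights are spike-and-slab: a heavy-tailed top-gene block
#' (normal, sd 4) on a fraction `top_gene_fraction` of genes and near-zero
#' weights (normal, sd 0.5) elsewhere, then standardized per source so that
#' top genes mostly exceed |weight| 3 — the working definition of a
#' component's "top genes". Mixing entries are standard normal plus a
#' `group_activity_shift` added, for each sample group, to that group's
#' designated source.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_dataset Integer vector; one dataset per entry.
#' @param n_sources Number of planted sources per dataset.
#' @param n_shared_sources How many leading sources are identical (same gene
#'   weights) in every dataset.
#' @param n_metabolic_sources How many leading sources carry gene-set signal
#'   ("metabolic" sources); at most `n_sources`.
#' @param top_gene_fraction Fraction of genes in each source's top block.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param n_gene_sets Total number of gene sets to generate.
#' @param genes_per_set Genes per set.
#' @param set_signal_fraction Fraction of each signal set's members drawn
#'   from its source's top-gene block.
#' @param sets_per_block Number of redundant signal sets planted per
#'   metabolic source realization.
#' @param n_sample_groups Number of sample groups per dataset.
#' @param group_activity_shift Activity shift applied to each group's
#'   designated source.
#' @param source_power_range Variances of the first and last source's base
#'   mixing entries; intermediate sources interpolate linearly. A graded
#'   power spectrum mirrors the decaying scree of real expression data and
#'   keeps the planted sources identifiable as distinct principal
#'   directions.
#' @param n_drugs Number of drug (IC50) columns.
#' @param n_immune_types Number of immune-fraction columns.
#' @param seed Master seed; every dataset and table derives its own stream
#'   from it, so adding a dataset does not perturb earlier ones.
#' @return A validated list of class `metica_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_samples_per_dataset = c(300, 250),
                             n_sources = 8,
                             n_shared_sources = 4,
                             n_metabolic_sources = n_sources,
                             top_gene_fraction = 0.02,
                             noise_sd = 0.5,
                             n_gene_sets = 40,
                             genes_per_set = 25,
                             set_signal_fraction = 0.8,
                             sets_per_block = 3,
                             n_sample_groups = 4,
                             group_activity_shift = 3,
                             source_power_range = c(4, 1),
                             n_drugs = 10,
                             n_immune_types = 6,
                             seed = 7) {
  assert_positive_int(n_genes, "n_genes")
  assert_positive_int(n_samples_per_dataset, "n_samples_per_dataset")
  assert_positive_int(n_sources, "n_sources")
  assert_positive_int(n_shared_sources, "n_shared_sources",
                      allow_zero = TRUE)
  assert_positive_int(n_metabolic_sources, "n_metabolic_sources",
                      allow_zero = TRUE)
  assert_positive_int(n_gene_sets, "n_gene_sets", allow_zero = TRUE)
  assert_positive_int(genes_per_set, "genes_per_set")
  assert_positive_int(sets_per_block, "sets_per_block")
  assert_positive_int(n_sample_groups, "n_sample_groups")
  assert_positive_int(n_drugs, "n_drugs", allow_zero = TRUE)
  assert_positive_int(n_immune_types, "n_immune_types", allow_zero = TRUE)
  if (n_shared_sources > n_sources) {
    stop("n_shared_sources must not exceed n_sources")
  }
  if (n_metabolic_sources > n_sources) {
    stop("n_metabolic_sources must not exceed n_sources")
  }
  if (top_gene_fraction <= 0 || top_gene_fraction >= 1) {
    stop("top_gene_fraction must lie in (0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (set_signal_fraction <= 0 || set_signal_fraction > 1) {
    stop("set_signal_fraction must lie in (0, 1]")
  }
  if (genes_per_set > n_genes) stop("genes_per_set exceeds n_genes")
  block_len <- round(top_gene_fraction * n_genes)
  if (block_len < 2) stop("top_gene_fraction yields fewer than 2 top genes")
  if (block_len * n_sources > n_genes) {
    stop("top-gene blocks of all sources exceed the gene universe")
  }
  if (round(set_signal_fraction * genes_per_set) > block_len) {
    stop("signal genes per set exceed the top-gene block size")
  }
  if (length(source_power_range) != 2 || any(source_power_range <= 0)) {
    stop("source_power_range must be two positive variances")
  }
  structure(mget(names(formals()), environment()),
            class = "metica_config")
}

#' Preset study conditions for stage-specific validation
#'
#' Two named variants of [synthetic_config()] accompany the default
#' two-dataset compendium:
#'
#' * `planted_blocks_config()` — a single-dataset study with 8 sources of
#'   which 5 are metabolic; the gene-set collection consists of 5 blocks
#'   of 30 near-identical sets, one block per metabolic source (every set
#'   drawn entirely from its source's top genes). It emulates the
#'   redundancy between curated catalogues that gene-set consensus
#'   clustering is meant to collapse, with the planted block structure as
#'   ground truth.
#' * `subtype_structure_config()` — a single-dataset study in which the
#'   group shifts dominate the base source activity
#'   (`source_power_range = c(0.125, 0.03125)`), emulating a cohort whose
#'   metabolic activity structure is driven by strong sample subtypes; the
#'   planted groups are the ground truth for subtype recovery.
#'
#' @return A [synthetic_config()].
#' @export
planted_blocks_config <- function() {
  synthetic_config(n_samples_per_dataset = 250, n_sources = 8,
                   n_shared_sources = 4, n_metabolic_sources = 5,
                   n_gene_sets = 150, sets_per_block = 30,
                   set_signal_fraction = 1, genes_per_set = 95,
                   top_gene_fraction = 0.10, seed = 7)
}

#' @rdname planted_blocks_config
#' @export
subtype_structure_config <- function() {
  synthetic_config(n_samples_per_dataset = 300,
                   source_power_range = c(0.125, 0.03125), seed = 7)
}

#' Generate a synthetic multi-dataset expression compendium
#'
#' Draws the planted sources, mixing matrices, group labels and noise under
#' the streams derived from `config$seed` and returns the datasets together
#' with the full ground truth. With `noise_sd = 0` each dataset equals
#' `true_sources %*% t(true_mixing)` exactly.
#'
#' @param config A [synthetic_config()].
#' @return List with `datasets` (list of [expression_matrix()] objects) and
#'   `truth` (class `metica_truth`): per-dataset `true_sources`
#'   (genes x sources, standardized) and `true_mixing`
#'   (samples x sources), `shared_source_ids`, `metabolic_source_ids`,
#'   per-dataset `group_labels` and `source_top_genes`, and the
#'   `drug_target_map` / `immune_target_map` used by
#'   [generate_response_tables()].
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "metica_config"))
  cf <- config
  gene_ids <- sprintf("g%04d", seq_len(cf$n_genes))
  source_ids <- sprintf("S%d", seq_len(cf$n_sources))
  block_len <- round(cf$top_gene_fraction * cf$n_genes)
  spike_sd <- 0.5
  slab_sd <- 4

  draw_source <- function(block_idx) {
    w <- stats::rnorm(cf$n_genes, 0, spike_sd)
    w[block_idx] <- stats::rnorm(length(block_idx), 0, slab_sd)
    w
  }

  # Master stream: shared blocks and shared source weights only, so that the
  # shared part of the compendium is invariant to the number of datasets.
  shared <- with_seed(cf$seed, {
    blocks <- matrix(sample.int(cf$n_genes, block_len * cf$n_shared_sources),
                     nrow = block_len)
    weights <- apply(blocks, 2, draw_source)
    list(blocks = blocks, weights = weights)
  })
  shared_gene_pool <- setdiff(seq_len(cf$n_genes), as.vector(shared$blocks))

  datasets <- vector("list", length(cf$n_samples_per_dataset))
  true_sources <- true_mixing <- group_labels <- top_genes <- datasets
  for (d in seq_along(cf$n_samples_per_dataset)) {
    n_s <- cf$n_samples_per_dataset[d]
    label <- sprintf("D%d", d)
    out <- with_seed(derive_seed(cf$seed, paste0("dataset_", d)), {
      n_unique <- cf$n_sources - cf$n_shared_sources
      s_mat <- matrix(0, cf$n_genes, cf$n_sources)
      blocks <- vector("list", cf$n_sources)
      if (cf$n_shared_sources > 0) {
        s_mat[, seq_len(cf$n_shared_sources)] <- shared$weights
        for (j in seq_len(cf$n_shared_sources)) {
          blocks[[j]] <- shared$blocks[, j]
        }
      }
      if (n_unique > 0) {
        ub <- matrix(sample(shared_gene_pool, block_len * n_unique),
                     nrow = block_len)
        for (j in seq_len(n_unique)) {
          jj <- cf$n_shared_sources + j
          blocks[[jj]] <- ub[, j]
          s_mat[, jj] <- draw_source(ub[, j])
        }
      }
      s_mat <- standardize_cols(s_mat)
      groups <- sample(rep_len(seq_len(cf$n_sample_groups), n_s))
      source_sd <- sqrt(seq(cf$source_power_range[1],
                            cf$source_power_range[2],
                            length.out = cf$n_sources))
      mix <- matrix(stats::rnorm(n_s * cf$n_sources), n_s, cf$n_sources)
      mix <- sweep(mix, 2, source_sd, "*")
      for (g in seq_len(cf$n_sample_groups)) {
        src <- ((g - 1) %% cf$n_sources) + 1
        mix[groups == g, src] <- mix[groups == g, src] +
          cf$group_activity_shift
      }
      x <- s_mat %*% t(mix)
      if (cf$noise_sd > 0) {
        x <- x + matrix(stats::rnorm(length(x), 0, cf$noise_sd),
                        nrow = nrow(x))
      }
      list(s = s_mat, mix = mix, groups = groups, x = x, blocks = blocks)
    })
    sample_ids <- sprintf("%s_s%03d", label, seq_len(n_s))
    dimnames(out$x) <- list(gene_ids, sample_ids)
    dimnames(out$s) <- list(gene_ids, source_ids)
    dimnames(out$mix) <- list(sample_ids, source_ids)
    datasets[[d]] <- expression_matrix(out$x, label)
    true_sources[[d]] <- out$s
    true_mixing[[d]] <- out$mix
    group_labels[[d]] <- stats::setNames(sprintf("G%d", out$groups),
                                         sample_ids)
    top_genes[[d]] <- stats::setNames(
      lapply(out$blocks, function(b) gene_ids[b]), source_ids)
    names(datasets)[d] <- names(true_sources)[d] <- label
    names(true_mixing)[d] <- names(group_labels)[d] <- label
    names(top_genes)[d] <- label
  }

  metabolic_ids <- source_ids[seq_len(cf$n_metabolic_sources)]
  drug_map <- immune_map <- NULL
  if (cf$n_drugs > 0) {
    n_targeted <- if (cf$n_metabolic_sources > 0) {
      ceiling(0.8 * cf$n_drugs)
    } else 0L
    idx <- seq_len(cf$n_drugs)
    drug_map <- data.frame(
      drug = sprintf("drug_%02d", idx),
      source = ifelse(idx <= n_targeted & cf$n_metabolic_sources > 0,
                      metabolic_ids[((idx - 1) %% max(cf$n_metabolic_sources,
                                                      1)) + 1], NA),
      sign = ifelse(idx %% 2 == 0, -1, 1),
      stringsAsFactors = FALSE)
    drug_map$sign[is.na(drug_map$source)] <- NA
  }
  if (cf$n_immune_types > 0 && cf$n_metabolic_sources > 0) {
    idx <- seq_len(cf$n_immune_types)
    immune_map <- data.frame(
      immune_type = sprintf("immune_%02d", idx),
      source = metabolic_ids[((idx - 1) %% cf$n_metabolic_sources) + 1],
      sign = ifelse(idx %% 2 == 0, -1, 1),
      stringsAsFactors = FALSE)
  }

  truth <- structure(list(
    true_sources = true_sources,
    true_mixing = true_mixing,
    shared_source_ids = source_ids[seq_len(cf$n_shared_sources)],
    metabolic_source_ids = metabolic_ids,
    group_labels = group_labels,
    source_top_genes = top_genes,
    drug_target_map = drug_map,
    immune_target_map = immune_map
  ), class = "metica_truth")
  list(datasets = datasets, truth = truth)
}

#' Generate gene sets with planted enrichment blocks
#'
#' For each metabolic source realization (shared sources once, dataset-
#' specific sources once per dataset) a block of `sets_per_block` redundant
#' sets is built, each drawing `set_signal_fraction` of its members from
#' that source's top-gene block and the remainder uniformly from the other
#' genes. Signal members are drawn from the majority-sign side of the top
#' block (padded from the other side only if it is too small): gene sets
#' describe co-regulated genes, which move in a common direction within a
#' component, and the Welch enrichment statistic detects exactly such
#' one-directional weight shifts. Any remaining budget up to `n_gene_sets` is filled with fully
#' random sets. The planted block of every set is recorded in the
#' `"set_blocks"` attribute (a data frame with columns `set`, `source`,
#' `dataset`; `NA` source for random sets).
#'
#' @param config The [synthetic_config()] used for the compendium.
#' @param truth The `metica_truth` from the same [generate_compendium()]
#'   call.
#' @return A [gene_set_collection()] with the `"set_blocks"` attribute.
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "metica_config"),
            inherits(truth, "metica_truth"))
  cf <- config
  gene_ids <- rownames(truth$true_sources[[1]])
  n_signal <- round(cf$set_signal_fraction * cf$genes_per_set)

  # One realization per shared metabolic source, one per dataset for
  # dataset-specific metabolic sources.
  signal_pool <- function(sid, d) {
    top <- truth$source_top_genes[[d]][[sid]]
    w <- truth$true_sources[[d]][top, sid]
    side <- if (sum(w > 0) >= sum(w < 0)) top[w > 0] else top[w < 0]
    if (length(side) < n_signal) {
      pad <- setdiff(top[order(-abs(w))], side)
      side <- c(side, pad[seq_len(n_signal - length(side))])
    }
    side
  }
  blocks <- list()
  for (sid in truth$metabolic_source_ids) {
    if (sid %in% truth$shared_source_ids) {
      blocks[[length(blocks) + 1]] <- list(
        source = sid, dataset = "shared",
        top = signal_pool(sid, names(truth$source_top_genes)[1]))
    } else {
      for (d in names(truth$source_top_genes)) {
        blocks[[length(blocks) + 1]] <- list(
          source = sid, dataset = d, top = signal_pool(sid, d))
      }
    }
  }
  n_block_sets <- length(blocks) * cf$sets_per_block
  if (n_block_sets > cf$n_gene_sets) {
    stop(sprintf(paste0("n_gene_sets (%d) is smaller than the %d planted ",
                        "signal sets; increase n_gene_sets or reduce ",
                        "sets_per_block"), cf$n_gene_sets, n_block_sets))
  }
  n_random <- cf$n_gene_sets - n_block_sets

  sets <- with_seed(derive_seed(cf$seed, "genesets"), {
    out <- list()
    for (b in blocks) {
      rest <- setdiff(gene_ids, b$top)
      for (j in seq_len(cf$sets_per_block)) {
        nm <- sprintf("SET_%s_%s_%d", b$source, b$dataset, j)
        out[[nm]] <- c(sample(b$top, n_signal),
                       sample(rest, cf$genes_per_set - n_signal))
      }
    }
    for (j in seq_len(n_random)) {
      out[[sprintf("SET_RAND_%02d", j)]] <- sample(gene_ids,
                                                   cf$genes_per_set)
    }
    out
  })

  gsc <- gene_set_collection(sets, collection_label = "synthetic")
  meta <- data.frame(
    set = names(sets),
    source = c(unlist(lapply(blocks, function(b) {
      rep(b$source, cf$sets_per_block)
    })), rep(NA_character_, n_random)),
    dataset = c(unlist(lapply(blocks, function(b) {
      rep(b$dataset, cf$sets_per_block)
    })), rep(NA_character_, n_random)),
    stringsAsFactors = FALSE)
  attr(gsc, "set_blocks") <- meta
  gsc
}

#' Generate drug-response and immune-fraction tables
#'
#' Emulates a cell-line drug screen and an immune-deconvolution output over
#' the samples of the last dataset (the cell-line analogue of the
#' compendium). Each targeted drug's IC50 column is its target source's true
#' activity times the planted sign plus Gaussian noise (`noise_sd`);
#' untargeted drugs are pure noise. Immune fractions are an affine monotone
#' transform of the target source's activity plus noise, clipped at zero.
#'
#' @param config The [synthetic_config()] used for the compendium.
#' @param truth Matching `metica_truth`.
#' @return List with `drug` and `immune` numeric matrices (samples in rows),
#'   either of which may be `NULL` when the config requests none.
#' @export
generate_response_tables <- function(config, truth) {
  stopifnot(inherits(config, "metica_config"),
            inherits(truth, "metica_truth"))
  cf <- config
  act <- truth$true_mixing[[length(truth$true_mixing)]]
  n <- nrow(act)
  with_seed(derive_seed(cf$seed, "response"), {
    drug <- immune <- NULL
    if (!is.null(truth$drug_target_map)) {
      dm <- truth$drug_target_map
      drug <- sapply(seq_len(nrow(dm)), function(i) {
        if (is.na(dm$source[i])) {
          stats::rnorm(n)
        } else {
          dm$sign[i] * act[, dm$source[i]] + stats::rnorm(n, 0, cf$noise_sd)
        }
      })
      dimnames(drug) <- list(rownames(act), dm$drug)
    }
    if (!is.null(truth$immune_target_map)) {
      im <- truth$immune_target_map
      immune <- sapply(seq_len(nrow(im)), function(i) {
        raw <- 0.25 + 0.06 * im$sign[i] * act[, im$source[i]] +
          stats::rnorm(n, 0, 0.06 * cf$noise_sd)
        pmax(raw, 0)
      })
      dimnames(immune) <- list(rownames(act), im$immune_type)
    }
    list(drug = drug, immune = immune)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_compendium()],
#' [generate_gene_sets()] and [generate_response_tables()] in one call.
#'
#' @param config A [synthetic_config()].
#' @return List with `datasets`, `truth`, `gene_sets`, `drug`, `immune`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  comp <- generate_compendium(config)
  gsc <- generate_gene_sets(config, comp$truth)
  resp <- generate_response_tables(config, comp$truth)
  list(datasets = comp$datasets, truth = comp$truth, gene_sets = gsc,
       drug = resp$drug, immune = resp$immune)
}

#' Write a synthetic study to disk
#'
#' Expression matrices and response tables as TSV, gene sets as GMT, and
#' the ground truth as a JSON sidecar.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (d in names(study$datasets)) {
    p <- file.path(dir, sprintf("expression_%s.tsv", d))
    write_expression(study$datasets[[d]], p)
    paths[sprintf("expression_%s", d)] <- p
  }
  paths["gene_sets"] <- write_gmt(study$gene_sets,
                                  file.path(dir, "gene_sets.gmt"))
  if (!is.null(study$drug)) {
    paths["drug"] <- write_matrix_tsv(study$drug,
                                      file.path(dir, "drug_ic50.tsv"),
                                      "sample_id")
  }
  if (!is.null(study$immune)) {
    paths["immune"] <- write_matrix_tsv(study$immune,
                                        file.path(dir,
                                                  "immune_fractions.tsv"),
                                        "sample_id")
  }
  tr <- study$truth
  sidecar <- list(
    shared_source_ids = tr$shared_source_ids,
    metabolic_source_ids = tr$metabolic_source_ids,
    group_labels = tr$group_labels,
    source_top_genes = tr$source_top_genes,
    drug_target_map = tr$drug_target_map,
    immune_target_map = tr$immune_target_map)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(sidecar, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
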