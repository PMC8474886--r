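#' Pipeline configuration
#'
#' Bundles every stage parameter with defaults matching the published
#' analysis conventions (2000 clustering resamplings, 10,000 overlap
#' permutations, |weight| > 3 top genes, |rho| > 0.5 concordance at
#' p < 0.05, |rho| > 0.2 drug screen, minimum subtype size 50, CDF-area
#' delta 0.01, height sweep 0.0-8.0 by 0.2, maxK 150). The `"desk"`
#' profile overrides the compute-heavy settings to sizes suited to the
#' bundled synthetic compendium.
#'
#' @param profile `"desk"` (default) or `"full"` (publication-scale settings).
#' @param synthetic A [synthetic_config()] describing the input compendium.
#' @param seed Master seed; each stage derives its own stream.
#' @param ... Named overrides of individual parameters.
#' @return List of class `metica_pipeline_config`.
#' @export
pipeline_config <- function(profile = c("desk", "full"),
                            synthetic = synthetic_config(), seed = 7, ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    synthetic = synthetic,
    seed = seed,
    n_components = 12,
    n_runs = 25,
    stability_threshold = 0.5,
    selection_stability = 0.9,
    cluster_maxK = 150,
    cluster_reps = 2000,
    p_item = 0.8,
    p_feature = 0.8,
    delta_threshold = 0.01,
    n_top_rule = 3,
    top_gene_threshold = 3,
    rho_threshold = 0.5,
    concordance_p = 0.05,
    n_perm = 10000,
    min_cluster_size = 50,
    sweep = c(0, 8, 0.2),
    drug_threshold = 0.2,
    immune_threshold = 0.2,
    ev_flag_threshold = 0.10)
  if (profile == "desk") {
    cfg$cluster_maxK <- 15
    cfg$cluster_reps <- 100
    cfg$n_perm <- 2000
    cfg$min_cluster_size <- 20
    cfg$sweep <- c(0, 400, 0.2)
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "metica_pipeline_config")
}

#' Run the full pipeline on a synthetic compendium
#'
#' Executes the stages in order — simulate inputs, decompose each dataset,
#' enrich components against the gene sets, consensus-cluster the gene
#' sets, select metabolic components, call cross-dataset concordance,
#' subtype samples, attribute explained variance, and screen activities
#' against the drug and immune tables — writing each stage's outputs as
#' TSV under `out_dir` and a JSON run manifest (config snapshot, per-stage
#' seeds, input and output checksums) last. A stage failure aborts with
#' the stage name; outputs of completed stages are left intact.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "metica_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("decompose", "enrich", "cluster_genesets", "select_mtc",
              "concordance", "subtype", "explained_variance", "associate")
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  t0 <- Sys.time()

  # Inputs (the synthetic compendium stands in for the real collections).
  study <- simulate_study(config$synthetic)
  input_paths <- write_study(study, file.path(out_dir, "inputs"))
  message("inputs: ", length(study$datasets), " dataset(s), ",
          length(study$gene_sets$sets), " gene sets")

  fits <- run_stage("decompose", {
    lapply(study$datasets, function(ds) {
      fit <- decompose(ds, n_components = config$n_components,
                       n_runs = config$n_runs,
                       stability_threshold = config$stability_threshold,
                       seed = derive_seed(config$seed,
                                          paste0("decompose_",
                                                 ds$dataset_label)))
      # Credibility screen: only components reproduced in at least
      # `selection_stability` of the runs enter the landscape stages.
      keep <- fit$components$stability >= config$selection_stability
      if (sum(keep) >= 2 && any(!keep)) {
        fit$components$weights <-
          fit$components$weights[, keep, drop = FALSE]
        fit$components$stability <- fit$components$stability[keep]
        fit$mixing$activities <-
          fit$mixing$activities[, keep, drop = FALSE]
        fit$mixing$component_ids <- colnames(fit$mixing$activities)
      }
      fit
    })
  })
  for (d in names(fits)) {
    write_matrix_tsv(fits[[d]]$components$weights,
                     file.path(out_dir, sprintf("weights_%s.tsv", d)),
                     "gene_id")
    write_matrix_tsv(fits[[d]]$mixing$activities,
                     file.path(out_dir, sprintf("activities_%s.tsv", d)),
                     "sample_id")
    utils::write.table(
      data.frame(component = names(fits[[d]]$components$stability),
                 stability = fits[[d]]$components$stability),
      file.path(out_dir, sprintf("stability_%s.tsv", d)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("decompose: ",
          paste(vapply(fits, function(f) ncol(f$components$weights),
                       integer(1)), collapse = "/"),
          " consensus components per dataset")

  enr <- run_stage("enrich", {
    lapply(fits, function(f) enrich_all(f$components, study$gene_sets))
  })
  for (d in names(enr)) {
    write_matrix_tsv(enr[[d]]$z,
                     file.path(out_dir, sprintf("enrichment_%s.tsv", d)),
                     "set_id")
  }

  cc <- run_stage("cluster_genesets", {
    lapply(names(enr), function(d) {
      consensus_cluster(enr[[d]],
                        maxK = config$cluster_maxK,
                        reps = config$cluster_reps,
                        p_item = config$p_item,
                        p_feature = config$p_feature,
                        delta_threshold = config$delta_threshold,
                        seed = derive_seed(config$seed,
                                           paste0("cluster_", d)))
    })
  })
  names(cc) <- names(enr)
  for (d in names(cc)) {
    utils::write.table(
      data.frame(set = names(cc[[d]]$assignment),
                 cluster = cc[[d]]$assignment),
      file.path(out_dir, sprintf("geneset_clusters_%s.tsv", d)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("cluster_genesets: chosen k = ",
          paste(vapply(cc, `[[`, integer(1), "chosen_k"), collapse = "/"))

  mtcs <- run_stage("select_mtc", {
    lapply(names(enr), function(d) {
      select_mtcs(enr[[d]], cc[[d]]$assignment, n_top = config$n_top_rule)
    })
  })
  names(mtcs) <- names(enr)
  for (d in names(mtcs)) {
    utils::write.table(mtcs[[d]]$provenance,
                       file.path(out_dir, sprintf("mtc_%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("select_mtc: ",
          paste(vapply(mtcs, function(m) length(m$mtc_ids), integer(1)),
                collapse = "/"), " mTCs per dataset")

  conc <- run_stage("concordance", {
    ds <- names(fits)
    pairs <- list()
    for (i in seq_along(ds)) {
      for (j in seq_along(ds)) {
        if (j <= i) next
        pairs[[paste(ds[i], ds[j], sep = "_")]] <- call_concordance(
          fits[[i]]$components, fits[[j]]$components,
          mtcs_a = mtcs[[i]]$mtc_ids, mtcs_b = mtcs[[j]]$mtc_ids,
          top_threshold = config$top_gene_threshold,
          rho_threshold = config$rho_threshold,
          p_threshold = config$concordance_p,
          n_perm = config$n_perm,
          seed = derive_seed(config$seed, "concordance"))
      }
    }
    pairs
  })
  conc_tab <- do.call(rbind, conc)
  utils::write.table(conc_tab, file.path(out_dir, "concordance_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("concordance: ", sum(conc_tab$concordant), "/",
          nrow(conc_tab), " pairs concordant")

  subtypes <- run_stage("subtype", {
    lapply(names(fits), function(d) {
      act <- fits[[d]]$mixing$activities[, mtcs[[d]]$mtc_ids, drop = FALSE]
      subtype_samples(act, min_cluster_size = config$min_cluster_size,
                      sweep = config$sweep)
    })
  })
  names(subtypes) <- names(fits)
  for (d in names(subtypes)) {
    utils::write.table(
      data.frame(sample = names(subtypes[[d]]$assignment),
                 subtype = subtypes[[d]]$assignment),
      file.path(out_dir, sprintf("subtypes_%s.tsv", d)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(
      subtype_medians(fits[[d]]$mixing$activities[,
        mtcs[[d]]$mtc_ids, drop = FALSE], subtypes[[d]]$assignment),
      file.path(out_dir, sprintf("subtype_medians_%s.tsv", d)), "subtype")
  }
  message("subtype: ",
          paste(vapply(subtypes, `[[`, integer(1), "n_subtypes"),
                collapse = "/"), " subtypes per dataset")

  evs <- run_stage("explained_variance", {
    lapply(names(fits), function(d) {
      explained_variance(fits[[d]]$mixing,
                         groups = study$truth$group_labels[[d]],
                         flag_threshold = config$ev_flag_threshold)
    })
  })
  names(evs) <- names(fits)
  for (d in names(evs)) {
    write_matrix_tsv(evs[[d]]$per_group,
                     file.path(out_dir, sprintf("ev_groups_%s.tsv", d)),
                     "group")
  }

  assoc <- run_stage("associate", {
    cell_line <- names(fits)[length(fits)]
    act <- fits[[cell_line]]$mixing
    out <- list()
    if (!is.null(study$drug)) {
      out$drug <- associate(act, study$drug,
                            threshold = config$drug_threshold)
    }
    if (!is.null(study$immune)) {
      out$immune <- associate(act, study$immune,
                              threshold = config$immune_threshold)
    }
    out
  })
  for (nm in names(assoc)) {
    utils::write.table(assoc[[nm]],
                       file.path(out_dir,
                                 sprintf("associations_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message("associate (", nm, "): ", sum(assoc[[nm]]$flagged),
            " flagged associations")
  }

  outputs <- setdiff(list.files(out_dir, recursive = TRUE,
                                full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
  manifest <- list(
    config = config_snapshot(config),
    stages = stages,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) derive_seed(config$seed, s)), stages),
    input_checksums = as.list(tools::md5sum(unname(input_paths))),
    output_checksums = as.list(tools::md5sum(sort(outputs))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Plain-list snapshot of a pipeline config for the manifest.
config_snapshot <- function(config) {
  cfg <- unclass(config)
  cfg$synthetic <- unclass(cfg$synthetic)
  cfg
}

#' Read and write pipeline configurations as YAML
#'
#' Serializes a [pipeline_config()] (including its embedded
#' [synthetic_config()]) so a run is fully described by one text file.
#'
#' @param config A `metica_pipeline_config`.
#' @param path Path to a YAML file.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a validated
#'   `metica_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "metica_pipeline_config"))
  yaml::write_yaml(config_snapshot(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, raw$synthetic)
  raw$synthetic <- NULL
  profile <- raw$profile %||% "desk"
  raw$profile <- NULL
  do.call(pipeline_config,
          c(list(profile = profile, synthetic = syn), raw))
}
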