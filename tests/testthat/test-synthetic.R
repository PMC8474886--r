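test_that("config validation rejects impossible requests", {
  expect_error(synthetic_config(n_shared_sources = 9, n_sources = 8),
               "n_shared_sources")
  expect_error(synthetic_config(n_genes = 0), "n_genes")
  expect_error(synthetic_config(n_samples_per_dataset = c(100, 0)),
               "n_samples_per_dataset")
  expect_error(synthetic_config(genes_per_set = 5000), "genes_per_set")
  expect_error(synthetic_config(top_gene_fraction = 1.2),
               "top_gene_fraction")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("noiseless generation reconstructs exactly and has source rank", {
  cf <- synthetic_config(n_genes = 400, n_samples_per_dataset = 60,
                         n_sources = 2, n_shared_sources = 0,
                         n_metabolic_sources = 2, noise_sd = 0,
                         n_sample_groups = 2, n_gene_sets = 6,
                         sets_per_block = 3, genes_per_set = 8, seed = 3)
  out <- generate_compendium(cf)
  x <- out$datasets[[1]]$values
  recon <- out$truth$true_sources[[1]] %*% t(out$truth$true_mixing[[1]])
  expect_equal(unname(x), unname(recon), tolerance = 1e-12)
  expect_equal(qr(x)$rank, 2)
})

test_that("identical config and seed reproduce byte-identical output", {
  cf <- synthetic_config()
  a <- simulate_study(cf)
  b <- simulate_study(cf)
  expect_identical(a$datasets[["D1"]]$values, b$datasets[["D1"]]$values)
  expect_identical(a$datasets[["D2"]]$values, b$datasets[["D2"]]$values)
  expect_identical(a$gene_sets$sets, b$gene_sets$sets)
  expect_identical(a$drug, b$drug)
  expect_identical(a$immune, b$immune)
  cf2 <- synthetic_config(seed = 8)
  c2 <- simulate_study(cf2)
  expect_false(identical(a$datasets[["D1"]]$values,
                         c2$datasets[["D1"]]$values))
})

test_that("shared sources are identical across datasets, unique ones not", {
  st <- default_study()
  tr <- st$truth
  for (sid in tr$shared_source_ids) {
    expect_identical(tr$true_sources[["D1"]][, sid],
                     tr$true_sources[["D2"]][, sid])
  }
  unique_ids <- setdiff(colnames(tr$true_sources[["D1"]]),
                        tr$shared_source_ids)
  for (sid in unique_ids) {
    expect_lt(abs(stats::cor(tr$true_sources[["D1"]][, sid],
                             tr$true_sources[["D2"]][, sid])), 0.3)
  }
})

test_that("planted sources align with leading singular directions", {
  st <- default_study()
  for (d in c("D1", "D2")) {
    x <- st$datasets[[d]]$values
    xc <- sweep(x, 2, colMeans(x))
    u <- svd(xc)$u[, 1:12]
    best <- apply(abs(stats::cor(st$truth$true_sources[[d]], u)), 1, max)
    expect_true(all(best >= 0.8))
  }
})

test_that("top-gene blocks behave as heavy-tailed standardized weights", {
  st <- default_study()
  w <- st$truth$true_sources[["D1"]]
  expect_equal(unname(colMeans(w)), rep(0, ncol(w)), tolerance = 1e-9)
  expect_equal(unname(apply(w, 2, stats::sd)), rep(1, ncol(w)),
               tolerance = 1e-9)
  fracs <- sapply(colnames(w), function(sid) {
    tg <- st$truth$source_top_genes[["D1"]][[sid]]
    expect_lt(mean(abs(w[setdiff(rownames(w), tg), sid]) > 3), 0.01)
    mean(abs(w[tg, sid]) > 3)
  })
  expect_gt(mean(fracs), 0.5)   # top-block genes mostly exceed |weight| 3
  expect_true(all(fracs > 0.4))
})

test_that("signal gene sets come from their source's top genes", {
  cf <- synthetic_config(set_signal_fraction = 1)
  out <- generate_compendium(cf)
  gsc <- generate_gene_sets(cf, out$truth)
  blocks <- attr(gsc, "set_blocks")
  signal <- blocks[!is.na(blocks$source), ]
  for (i in sample(nrow(signal), 10)) {
    d <- if (signal$dataset[i] == "shared") "D1" else signal$dataset[i]
    top <- out$truth$source_top_genes[[d]][[signal$source[i]]]
    expect_true(all(gsc$sets[[signal$set[i]]] %in% top))
  }
})

test_that("random sets show null enrichment against true sources", {
  cf <- synthetic_config(n_gene_sets = 200, n_metabolic_sources = 0,
                         n_drugs = 0, n_immune_types = 0)
  out <- generate_compendium(cf)
  gsc <- generate_gene_sets(cf, out$truth)
  e <- enrich_all(out$truth$true_sources[["D1"]], gsc)
  zbar <- mean(e$z)
  se <- stats::sd(e$z) / sqrt(length(e$z))
  expect_lt(abs(zbar), 3 * stats::sd(e$z[, 1]) / sqrt(nrow(e$z)))
  expect_lt(abs(zbar), 0.5)  # sanity on the magnitude itself
  # within-block enrichment profiles correlate more than between blocks
  st <- default_study()
  e2 <- enrich_all(st$truth$true_sources[["D1"]], st$gene_sets)
  blocks <- attr(st$gene_sets, "set_blocks")
  b1 <- blocks$set[which(blocks$source == "S1")]
  b2 <- blocks$set[which(blocks$source == "S2")]
  cors <- stats::cor(t(e2$z[c(b1, b2), ]))
  within <- mean(cors[seq_along(b1), seq_along(b1)][upper.tri(diag(3))])
  between <- mean(cors[seq_along(b1), length(b1) + seq_along(b2)])
  expect_gt(within, between)
})

test_that("response tables encode monotone planted associations", {
  cf0 <- synthetic_config(noise_sd = 0)
  out0 <- generate_compendium(cf0)
  resp0 <- generate_response_tables(cf0, out0$truth)
  act <- out0$truth$true_mixing[[length(out0$truth$true_mixing)]]
  dm <- out0$truth$drug_target_map
  targeted <- which(!is.na(dm$source))
  for (i in targeted) {
    rho <- stats::cor(resp0$drug[, dm$drug[i]], act[, dm$source[i]],
                      method = "spearman")
    expect_equal(rho, dm$sign[i], tolerance = 1e-12)
  }
  # untargeted columns are null: |rho| < 0.2 with high probability (n = 250)
  st <- default_study()
  dm2 <- st$truth$drug_target_map
  act2 <- st$truth$true_mixing[[length(st$truth$true_mixing)]]
  null_rhos <- sapply(dm2$drug[is.na(dm2$source)], function(dr) {
    max(abs(stats::cor(st$drug[, dr], act2, method = "spearman")))
  })
  expect_true(all(null_rhos < 0.3))
  expect_true(all(st$immune >= 0))
})

test_that("written study round-trips through the readers", {
  st <- default_study()
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  x <- read_expression(paths[["expression_D1"]], "D1")
  expect_equal(x$values, st$datasets[["D1"]]$values, tolerance = 1e-12)
  g <- read_gmt(paths[["gene_sets"]])
  expect_identical(g$sets, st$gene_sets$sets)
})
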