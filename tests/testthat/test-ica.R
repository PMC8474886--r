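test_that("noiseless two-source mixtures are recovered near-exactly", {
  cf <- synthetic_config(n_genes = 500, n_samples_per_dataset = 80,
                         n_sources = 2, n_shared_sources = 0,
                         n_metabolic_sources = 2, noise_sd = 0,
                         n_sample_groups = 2, n_gene_sets = 6,
                         sets_per_block = 3, genes_per_set = 10, seed = 5)
  out <- generate_compendium(cf)
  fit <- decompose(out$datasets[[1]], n_components = 2, n_runs = 10,
                   seed = 2)
  cc <- abs(stats::cor(out$truth$true_sources[[1]],
                       fit$components$weights))
  expect_true(all(apply(cc, 1, max) >= 0.99))
})

test_that("weight columns are standardized with a positive-max sign", {
  fit <- default_fits()[["D1"]]
  w <- fit$components$weights
  expect_equal(unname(colMeans(w)), rep(0, ncol(w)), tolerance = 1e-9)
  expect_equal(unname(apply(w, 2, stats::sd)), rep(1, ncol(w)),
               tolerance = 1e-9)
  for (j in seq_len(ncol(w))) {
    expect_gt(w[which.max(abs(w[, j])), j], 0)
  }
  expect_true(all(diff(fit$components$stability) <= 1e-12))
})

test_that("decomposition rejects impossible component counts", {
  st <- default_study()
  expect_error(decompose(st$datasets[["D1"]], n_components = 1), "\\[2,")
  expect_error(decompose(st$datasets[["D1"]], n_components = 12,
                         n_runs = 1), "n_runs")
  cf <- synthetic_config(n_genes = 200, n_samples_per_dataset = 30,
                         n_sources = 2, n_shared_sources = 0,
                         n_metabolic_sources = 2, noise_sd = 0,
                         top_gene_fraction = 0.05, n_sample_groups = 2,
                         n_gene_sets = 6, sets_per_block = 3,
                         genes_per_set = 8, seed = 5)
  rank2 <- generate_compendium(cf)$datasets[[1]]
  expect_error(decompose(rank2, n_components = 10), "rank")
})

test_that("same seed is bit-identical, different seeds agree per component", {
  st <- default_study()
  a <- decompose(st$datasets[["D2"]], 12, 10, seed = 4)
  b <- decompose(st$datasets[["D2"]], 12, 10, seed = 4)
  expect_identical(a$components$weights, b$components$weights)
  expect_identical(a$mixing$activities, b$mixing$activities)
  c2 <- decompose(st$datasets[["D2"]], 12, 10, seed = 9)
  keep_a <- a$components$stability >= 0.9
  cc <- abs(stats::cor(a$components$weights[, keep_a, drop = FALSE],
                       c2$components$weights))
  expect_true(all(apply(cc, 1, max) >= 0.95))
})

test_that("sample order does not affect weights, only mixing rows", {
  st <- default_study()
  x <- st$datasets[["D2"]]
  perm <- sample(ncol(x$values))
  xp <- expression_matrix(x$values[, perm], "D2perm")
  a <- decompose(x, 8, 5, seed = 6)
  b <- decompose(xp, 8, 5, seed = 6)
  # stable components agree up to ordering; mixing rows follow the samples
  keep <- a$components$stability >= 0.9
  cc <- stats::cor(a$components$weights[, keep, drop = FALSE],
                   b$components$weights)
  match_b <- apply(abs(cc), 1, which.max)
  expect_identical(anyDuplicated(match_b), 0L)
  expect_true(all(apply(abs(cc), 1, max) > 0.999))
  am <- stats::cor(a$mixing$activities[, keep, drop = FALSE],
                   b$mixing$activities[colnames(x$values), ])
  expect_true(all(abs(am[cbind(seq_along(match_b), match_b)]) > 0.999))
})

test_that("negating the data negates activities, not absolute weights", {
  st <- default_study()
  x <- st$datasets[["D2"]]
  xn <- expression_matrix(-x$values, "D2neg")
  a <- decompose(x, 8, 5, seed = 6)
  b <- decompose(xn, 8, 5, seed = 6)
  expect_equal(abs(a$components$weights), abs(b$components$weights),
               tolerance = 1e-6, ignore_attr = TRUE)
  flip <- sign(diag(stats::cor(a$components$weights,
                               b$components$weights)))
  expect_equal(sweep(b$mixing$activities, 2, flip, "*"),
               -a$mixing$activities, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("reconstruction residual decreases with component count", {
  st <- default_study()
  x <- st$datasets[["D2"]]$values
  xc <- sweep(x, 2, colMeans(x))
  runs <- lapply(c(2, 4, 8, 12), function(k) {
    fit <- decompose(st$datasets[["D2"]], k, 5, seed = 8)
    w <- fit$components$weights
    a <- fit$mixing$activities
    list(k_eff = ncol(w), res = mean((xc - w %*% t(a))^2))
  })
  k_eff <- vapply(runs, `[[`, numeric(1), "k_eff")
  res_var <- vapply(runs, `[[`, numeric(1), "res")
  grew <- diff(k_eff) > 0
  expect_true(any(grew))
  expect_true(all(diff(res_var)[grew] < 0))
})

test_that("projection recovers exact least-squares activities", {
  set.seed(1)
  w <- metica:::standardize_cols(matrix(rnorm(200 * 3), 200, 3))
  dimnames(w) <- list(paste0("g", 1:200), paste0("TC", 1:3))
  comps <- structure(list(weights = w, stability = rep(1, 3),
                          dataset_label = "toy"),
                     class = "metica_components")
  act <- matrix(rnorm(15), 5, 3,
                dimnames = list(paste0("s", 1:5), colnames(w)))
  x <- expression_matrix(w %*% t(act), "toy")
  rec <- project_activities(comps, x)
  expect_equal(rec$activities, act, tolerance = 1e-8)

  # single sample equal to one component's weights, orthogonalized basis
  qw <- qr.Q(qr(w)) * sqrt(nrow(w) - 1)
  dimnames(qw) <- dimnames(w)
  comps_o <- structure(list(weights = qw, stability = rep(1, 3),
                            dataset_label = "toy"),
                       class = "metica_components")
  x1 <- expression_matrix(qw[, 2, drop = FALSE] %*%
                            matrix(1, 1, 1,
                                   dimnames = list(NULL, "s1")), "toy")
  a1 <- project_activities(comps_o, x1)
  expect_equal(unname(a1$activities[1, ]), c(0, 1, 0), tolerance = 1e-8)
})

test_that("projection enforces the shared-gene floor", {
  fit <- default_fits()[["D1"]]
  st <- default_study()
  x <- st$datasets[["D1"]]
  small <- expression_matrix(
    x$values[seq_len(0.4 * nrow(x$values)), , drop = FALSE], "small")
  expect_error(project_activities(fit$components, small), "50")
  # projected activities track the planted mixing on shared sources
  proj <- project_activities(fit$components, x)
  cc <- abs(stats::cor(st$truth$true_mixing[["D1"]], proj$activities))
  expect_true(all(apply(cc, 1, max) >= 0.9))
})

test_that("suggest_k follows the cumulative variance of the scree", {
  st <- default_study()
  k80 <- suggest_k(st$datasets[["D1"]], 0.8)
  k99 <- suggest_k(st$datasets[["D1"]], 0.99)
  expect_true(k80 >= 2 && k80 <= 8)
  expect_gt(k99, k80)
})
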