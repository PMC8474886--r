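test_that("planted sample groups are recovered as metabolic subtypes", {
  sf <- subtype_fit()
  stp <- subtype_samples(sf$fit$mixing, min_cluster_size = 20,
                         sweep = c(0, 400, 0.2))
  ari <- mclust::adjustedRandIndex(stp$assignment,
                                   sf$truth$group_labels[["D1"]])
  expect_gte(ari, 0.9)
  expect_gte(min(table(stp$assignment)), 20)
})

test_that("minimum cluster size is non-decreasing in cut height", {
  sf <- subtype_fit()
  a <- sf$fit$mixing$activities
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(t(a))),
                      method = "ward.D2")
  sizes <- sapply(seq(0, ceiling(max(hc$height)), by = 0.5), function(h) {
    min(table(stats::cutree(hc, h = h)))
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("subtyping is invariant to sample order and positive scaling", {
  sf <- subtype_fit()
  a <- sf$fit$mixing$activities
  base <- subtype_samples(a, 20, c(0, 400, 0.2))
  perm <- sample(nrow(a))
  permuted <- subtype_samples(a[perm, ], 20, c(0, 400, 0.2))
  expect_identical(base$cut_height, permuted$cut_height)
  tab <- table(base$assignment[rownames(a)[perm]], permuted$assignment)
  expect_true(all(rowSums(tab > 0) == 1))   # label-permutation equal
  scaled <- subtype_samples(3.7 * a, 20, c(0, 400, 0.2))
  expect_identical(unname(scaled$assignment[names(base$assignment)]),
                   unname(base$assignment))
})

test_that("near-identical samples collapse to a single subtype", {
  set.seed(4)
  base <- rnorm(6)
  a <- matrix(rep(base, each = 50), 50, 6) + rnorm(300, sd = 1e-4)
  rownames(a) <- paste0("s", 1:50)
  colnames(a) <- paste0("TC", 1:6)
  stp <- subtype_samples(a, min_cluster_size = 25, sweep = c(0, 50, 0.2))
  expect_identical(stp$n_subtypes, 1L)
})

test_that("subtype preconditions and sweep failure are reported", {
  a <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("TC", 1:4)))
  expect_error(subtype_samples(a, min_cluster_size = 50), "samples")
  sf <- subtype_fit()
  act <- sf$fit$mixing$activities
  expect_error(subtype_samples(act, 20, sweep = c(0, 0.2, 0.2)), "sweep")
})

test_that("subtype medians summarize activity per subtype", {
  a <- rbind(s1 = c(1, 10), s2 = c(3, 30), s3 = c(-1, -10))
  colnames(a) <- c("TC1", "TC2")
  asg <- c(s1 = "MS1", s2 = "MS1", s3 = "MS2")
  med <- subtype_medians(a, asg)
  expect_equal(med["MS1", ], c(TC1 = 2, TC2 = 20))
  expect_equal(med["MS2", ], c(TC1 = -1, TC2 = -10))
})

test_that("explained variance rows are simplex weights", {
  ev <- explained_variance(rbind(s1 = c(3, 4)))
  expect_equal(unname(ev$per_sample[1, ]), c(0.36, 0.64))
  fits <- screened_fits()
  st <- default_study()
  ev2 <- explained_variance(fits[["D1"]]$mixing,
                            groups = st$truth$group_labels[["D1"]])
  expect_equal(unname(rowSums(ev2$per_sample)),
               rep(1, nrow(ev2$per_sample)), tolerance = 1e-9)
  expect_true(all(ev2$per_sample >= 0 & ev2$per_sample <= 1))
  # per-group means over the two-sample toy case
  g <- c(s1 = "a", s2 = "a")
  ev3 <- explained_variance(rbind(s1 = c(1, 0), s2 = c(0, 1)), groups = g)
  expect_equal(unname(ev3$per_group["a", ]), c(0.5, 0.5))
  # scaling a sample's activity row leaves its EV unchanged
  a <- fits[["D1"]]$mixing$activities
  a2 <- a
  a2[1, ] <- 10 * a2[1, ]
  expect_equal(explained_variance(a2)$per_sample[1, ],
               explained_variance(a)$per_sample[1, ], tolerance = 1e-12)
})

test_that("all-zero activity rows are excluded with a warning", {
  a <- rbind(s1 = c(1, 2), s2 = c(0, 0))
  expect_warning(ev <- explained_variance(a), "all-zero")
  expect_identical(rownames(ev$per_sample), "s1")
  expect_identical(ev$excluded, "s2")
})

test_that("group shifts are flagged as high explained-variance components", {
  sf <- subtype_fit()
  truth_groups <- sf$truth$group_labels[["D1"]]
  ev <- explained_variance(sf$fit$mixing, groups = truth_groups)
  expect_true(any(ev$flagged))
  expect_true(all(ev$max_group_ev[ev$flagged] > 0.10))
})

test_that("planted drug targets are flagged and nulls are calibrated", {
  st <- default_study()
  fits <- screened_fits()
  fit <- fits[["D2"]]
  assoc <- associate(fit$mixing, st$drug, threshold = 0.2)
  dm <- st$truth$drug_target_map
  map <- match_sources(st$truth$true_sources[["D2"]], fit$components)
  targeted <- merge(dm[!is.na(dm$source), ],
                    map[map$cor >= 0.9, ], by.x = "source", by.y = "source")
  hit <- merge(targeted, assoc, by.x = c("component", "drug"),
               by.y = c("component", "feature"))
  expect_identical(nrow(hit), sum(!is.na(dm$source)))
  expect_true(all(hit$flagged))
  # sign of the planted association survives the sign conventions
  expect_true(all(abs(hit$rho) > 0.5))
})

test_that("associations are invariant to monotone feature transforms", {
  st <- default_study()
  fits <- screened_fits()
  fit <- fits[["D2"]]
  f1 <- st$drug[, 1, drop = FALSE]
  a1 <- associate(fit$mixing, f1, threshold = 0.2)
  f2 <- exp(f1 / 2)
  a2 <- associate(fit$mixing, f2, threshold = 0.2)
  expect_equal(a1$rho, a2$rho, tolerance = 1e-12)
})

test_that("sparse and constant features yield undefined cells", {
  fits <- screened_fits()
  act <- fits[["D2"]]$mixing$activities
  f <- matrix(NA_real_, nrow(act), 2,
              dimnames = list(rownames(act), c("sparse", "constant")))
  f[1:3, "sparse"] <- rnorm(3)
  f[, "constant"] <- 1
  res <- associate(act, f, threshold = 0.2)
  expect_true(all(is.na(res$rho)))
  expect_true(all(!res$flagged))
  expect_identical(unique(res$n[res$feature == "sparse"]), 3L)
})
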