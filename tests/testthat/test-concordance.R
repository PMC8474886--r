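test_that("top genes use a strict absolute-weight cutoff", {
  w <- matrix(c(3.0, 3.01, -3.5), 3, 1,
              dimnames = list(c("gene1", "gene2", "gene3"), "TC1"))
  expect_setequal(top_genes(w, "TC1"), c("gene2", "gene3"))
  expect_setequal(top_genes(w, "TC1", threshold = 0),
                  c("gene1", "gene2", "gene3"))
})

test_that("standard-normal weights put the expected count above 3", {
  set.seed(2)
  w <- matrix(rnorm(1e4), ncol = 1,
              dimnames = list(paste0("g", 1:1e4), "TC1"))
  n <- length(top_genes(w, "TC1"))
  expected <- 2 * (1 - stats::pnorm(3)) * 1e4
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("permutation overlap p matches the hypergeometric tail", {
  # worked example: universe 20, lists of 5 and 5, overlap 3
  p_exact <- sum(stats::dhyper(3:5, 5, 15, 5))
  expect_equal(p_exact, 0.0726, tolerance = 1e-3)
  p_mc <- overlap_pvalue(5, 5, 3, 20, n_perm = 10000, seed = 1)
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e4))
  expect_equal(overlap_pvalue(5, 5, 3, 20, method = "hypergeometric"),
               p_exact, tolerance = 1e-12)
})

test_that("overlap p-value honors its degenerate contracts", {
  expect_equal(overlap_pvalue(10, 8, 0, 100, n_perm = 200, seed = 1), 1)
  expect_equal(overlap_pvalue(50, 10, 10, 50, n_perm = 200, seed = 1), 1)
  expect_error(overlap_pvalue(10, 8, 9, 100), "exceeds")
  expect_error(overlap_pvalue(80, 80, 10, 100), "impossible")
  expect_error(overlap_pvalue(101, 8, 0, 100), "larger than the universe")
  # symmetry in the two list sizes
  expect_identical(overlap_pvalue(9, 4, 2, 60, n_perm = 500, seed = 3),
                   overlap_pvalue(4, 9, 2, 60, n_perm = 500, seed = 3))
})

test_that("monte-carlo overlap p converges to the exact tail broadly", {
  set.seed(5)
  ok <- 0
  for (i in 1:20) {
    u <- sample(50:500, 1)
    na <- sample(5:(u / 3), 1)
    nb <- sample(5:(u / 3), 1)
    ov <- sample(0:min(na, nb, 8), 1)
    p_exact <- stats::phyper(ov - 1, na, u - na, nb, lower.tail = FALSE)
    p_mc <- overlap_pvalue(na, nb, ov, u, n_perm = 2000, seed = i)
    se <- sqrt(p_exact * (1 - p_exact) / 2000)
    if (abs(p_mc - p_exact) <= 3 * se + 1 / 2001) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("spearman_t reproduces the rank formula and reference p", {
  res <- spearman_t(1:5, c(1, 3, 2, 5, 4))
  expect_equal(res$rho, 1 - 6 * 4 / (5 * 24), tolerance = 1e-12)  # 0.8
  expect_equal(res$rho, 0.8, tolerance = 1e-12)
  expect_equal(res$p, 0.104, tolerance = 1e-3)
  ref <- suppressWarnings(stats::cor.test(1:5, c(1, 3, 2, 5, 4),
                                          method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)

  anti <- spearman_t(1:6, -(1:6))
  expect_equal(anti$rho, -1)
  expect_equal(anti$p, 0)
  expect_true(anti$below_approximation)

  flat <- spearman_t(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(flat$rho, 0.6, tolerance = 1e-12)
  expect_error(spearman_t(rep(1, 5), 1:5), "constant")
  expect_error(spearman_t(1:3, 3:1), "at least 4")
})

test_that("shared planted sources are concordant, unique ones are not", {
  st <- default_study()
  fits <- screened_fits()
  pairs <- call_concordance(fits[["D1"]]$components,
                            fits[["D2"]]$components,
                            n_perm = 2000, seed = 77)
  maps <- lapply(c("D1", "D2"), function(d) {
    match_sources(st$truth$true_sources[[d]],
                  fits[[d]]$components)
  })
  names(maps) <- c("D1", "D2")
  src_a <- with(maps[["D1"]],
                ifelse(cor >= 0.9, source, NA)[match(pairs$mtc_a,
                                                     component)])
  src_b <- with(maps[["D2"]],
                ifelse(cor >= 0.9, source, NA)[match(pairs$mtc_b,
                                                     component)])
  shared_pair <- !is.na(src_a) & !is.na(src_b) & src_a == src_b &
    src_a %in% st$truth$shared_source_ids
  expect_identical(sum(shared_pair), 4L)
  expect_true(all(pairs$concordant[shared_pair]))
  expect_false(any(pairs$concordant[!shared_pair]))
  expect_true(all(pairs$n_overlap <= pmin(pairs$n_top_a, pairs$n_top_b)))
  expect_true(all(pairs$overlap_p > 0 & pairs$overlap_p <= 1))
})

test_that("concordance is symmetric and sign-invariant", {
  fits <- screened_fits()
  a <- fits[["D1"]]$components
  b <- fits[["D2"]]$components
  sub_a <- a; sub_a$weights <- a$weights[, 1:3]
  sub_b <- b; sub_b$weights <- b$weights[, 1:3]
  ab <- call_concordance(sub_a, sub_b, n_perm = 500, seed = 9)
  ba <- call_concordance(sub_b, sub_a, n_perm = 500, seed = 9)
  key_ab <- paste(ab$mtc_a, ab$mtc_b)
  key_ba <- paste(ba$mtc_b, ba$mtc_a)
  ord <- match(key_ab, key_ba)
  expect_identical(ab$concordant, ba$concordant[ord])
  expect_equal(abs(ab$rho), abs(ba$rho[ord]), tolerance = 1e-12)
  expect_identical(ab$overlap_p, ba$overlap_p[ord])
  # sign flip of one side changes neither overlap nor the verdict
  flip <- sub_b
  flip$weights <- -flip$weights
  ab2 <- call_concordance(sub_a, flip, n_perm = 500, seed = 9)
  expect_identical(ab$concordant, ab2$concordant)
  expect_equal(abs(ab$rho), abs(ab2$rho), tolerance = 1e-12)
  expect_identical(ab$n_overlap, ab2$n_overlap)
})

test_that("a component is perfectly concordant with itself", {
  fits <- screened_fits()
  a <- fits[["D1"]]$components
  pairs <- call_concordance(a, a, mtcs_a = "TC1", mtcs_b = "TC1",
                            n_perm = 500, seed = 2)
  expect_equal(pairs$rho, 1)
  expect_identical(pairs$n_overlap, pairs$n_top_a)
  expect_true(pairs$concordant)
})

test_that("summary reports per-dataset fractions and the all-dataset count", {
  pairs <- data.frame(
    mtc_a = c("TC1", "TC2"), mtc_b = c("TC5", "TC6"),
    dataset_a = "D1", dataset_b = "D2",
    n_top_a = 10, n_top_b = 10, n_overlap = c(8, 0),
    overlap_p = c(0.001, 1), rho = c(0.9, NA), rho_p = c(0.001, NA),
    concordant = c(TRUE, FALSE), reason = "",
    stringsAsFactors = FALSE)
  s <- concordance_summary(pairs)
  d1 <- s$per_dataset[s$per_dataset$dataset == "D1", ]
  expect_equal(d1$fraction_concordant, 0.5)
  expect_identical(s$n_concordant_all_datasets, 2L)  # TC1 in D1, TC5 in D2
})
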