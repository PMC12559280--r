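test_that("pairwise divergence averages absolute level differences", {
  a <- calls_fixture(c("m", "m", "u", "i"))
  b <- calls_fixture(c("m", "u", "u", "i"))
  expect_equal(pairwise_divergence(a, b)$D, 0.25)
  expect_equal(pairwise_divergence(a, a)$D, 0)

  # the DMP proxy scores any state switch as a full difference
  c1 <- calls_fixture(c("m", "i", "u"))
  c2 <- calls_fixture(c("u", "m", "u"))
  expect_equal(pairwise_divergence(c1, c2, encoding = "dmp")$D, 2 / 3)
  expect_equal(pairwise_divergence(c1, c2, encoding = "level")$D, 0.5)
})

test_that("posterior filtering controls the divergence denominator", {
  a <- calls_fixture(c("m", "m", "u"), posterior = c(1, 0.95, 1))
  b <- calls_fixture(c("u", "u", "u"), posterior = 1)
  d <- pairwise_divergence(a, b, min_posterior = 0.99)
  expect_identical(d$n, 2L)
  expect_equal(d$D, 0.5)
  low <- calls_fixture(c("m", "m"), posterior = 0.5)
  expect_error(pairwise_divergence(low, calls_fixture(c("u", "u"))),
               "no sites pass")
})

test_that("divergence matches a brute-force site loop on random calls", {
  withr::local_seed(19)
  n <- 200
  a <- calls_fixture(sample(c("u", "i", "m"), n, TRUE),
                     posterior = runif(n, 0.95, 1))
  b <- calls_fixture(sample(c("u", "i", "m"), n, TRUE),
                     posterior = runif(n, 0.95, 1))
  d <- pairwise_divergence(a, b, min_posterior = 0.99)
  lev <- c(u = 0, i = 0.5, m = 1)
  keep <- a$posterior_max >= 0.99 & b$posterior_max >= 0.99
  brute <- mean(abs(lev[a$state[keep]] - lev[b$state[keep]]))
  expect_equal(d$D, brute)
  expect_identical(d$n, sum(keep))
})

test_that("divergence is a pseudometric on the level encoding", {
  withr::local_seed(23)
  lv <- matrix(sample(c(0, 0.5, 1), 500 * 5, TRUE), 500, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  D <- divergence_matrix(lv)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("Cohen's d follows the pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d_c, 0)
  # means 3 and 1 with unit pooled SD give d = 2
  r <- cohens_d(c(2, 3, 4), c(0, 1, 2))
  expect_equal(r$pooled_sd, 1)
  expect_equal(r$d_c, 2)
  expect_identical(r$band, "large")
  # zero pooled SD with unequal means is flagged, not silently divided
  r2 <- cohens_d(c(2, 2, 2, 2), c(0, 0, 0, 0))
  expect_true(r2$degenerate)
  expect_identical(r2$d_c, Inf)
})

test_that("normalised fold change matches the published computation", {
  m <- published_stem_divergences()
  fc <- normalized_fold_change(m[["replicates"]], m[["moderate"]],
                               m[["heavy"]])
  expect_equal(round(fc$fold_change, 2), 2.64)
  expect_equal(normalized_fold_change(0.1, 0.2, 0.2)$fold_change, 1)
  expect_equal(normalized_fold_change(0.1, 0.2, 0.1)$fold_change, 0)
  expect_false(normalized_fold_change(0.2, 0.1, 0.3)$defined)

  # invariant under affine rescaling D -> aD + b of all three means
  fc2 <- normalized_fold_change(3 * m[[1]] + 0.02, 3 * m[[2]] + 0.02,
                                3 * m[[3]] + 0.02)
  expect_equal(fc2$fold_change, fc$fold_change)
})

test_that("UPGMA clustering is order-invariant and validates input", {
  withr::local_seed(41)
  tr <- make_topology(6, 200, branch_times = spaced_branch_times(6),
                      seed = 41)
  sim <- evolve_methylomes(tr, evolution_params(alpha = 1e-3, beta = 1e-3),
                           5e4, seed = 42)
  D <- divergence_matrix(sim$levels, encoding = "dmp")
  cl <- cluster_samples(D)
  perm <- sample(nrow(D))
  cl2 <- cluster_samples(D[perm, perm])
  rf <- phangorn::RF.dist(ape::unroot(cl$phylo), ape::unroot(cl2$phylo))
  expect_equal(rf, 0, ignore_attr = TRUE)

  two <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  expect_identical(length(cluster_samples(two)$hclust$height), 1L)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(cluster_samples(bad), "symmetric")
})

test_that("group comparisons report Wilcoxon W, p and effect size", {
  # fully separated groups of 3 vs 3 reach the maximal W of 9
  dv <- tibble::tibble(
    treatment = c(rep("moderate", 4), rep("heavy", 3), rep("moderate", 3)),
    comparison = c(rep("RR", 4), rep("RS", 6)),
    divergence = c(0.01, 0.012, 0.011, 0.013,
                   0.05, 0.06, 0.055, 0.02, 0.021, 0.022))
  rep_ <- compare_divergence_groups(dv)
  hm <- rep_[rep_$group1 == "heavy_RS" & rep_$group2 == "moderate_RS", ]
  expect_identical(unname(hm$W), 9)
  expect_equal(hm$p_value, 1 / choose(6, 3), tolerance = 1e-9)

  # identical groups: one-sided p near 1, zero effect
  dv2 <- dv
  dv2$divergence[dv2$comparison == "RS"] <- rep(c(0.03, 0.04, 0.05), 2)
  rep2 <- compare_divergence_groups(dv2)
  hm2 <- rep2[rep2$group1 == "heavy_RS" & rep2$group2 == "moderate_RS", ]
  expect_gte(hm2$p_value, 0.5)
  expect_equal(hm2$d_c, 0)
})
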