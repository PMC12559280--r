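test_that("simulated topologies are dated, reproducible and validated", {
  tr <- make_topology(2, 200, branch_times = 150, seed = 1)
  dt <- divergence_times(tr)
  expect_equal(dt$delta_t, 100) # two 50-year lineages

  t1 <- make_topology(10, 200, seed = 99)
  t2 <- make_topology(10, 200, seed = 99)
  expect_identical(ape::write.tree(t1$phy), ape::write.tree(t2$phy))

  expect_error(make_topology(4, 100, branch_times = c(10, 50, 120)),
               "within")

  # three-leaf pedigree with the earliest branch point at germination:
  # divergence through the root spans the full tree age on both sides
  tr3 <- make_topology(3, 200, branch_times = c(0, 150), seed = 5)
  dt3 <- divergence_times(tr3)
  expect_equal(max(dt3$delta_t), 400)
  expect_equal(sort(dt3$delta_t), c(100, 400, 400))
  expect_identical(sum(dt3$root_censored), 2L)
})

test_that("zero rates leave every leaf identical to the ancestor", {
  tr <- make_topology(5, 300, seed = 3)
  sim <- evolve_methylomes(tr, evolution_params(alpha = 0, beta = 0, p0 = 0.4),
                           1000, seed = 4, include_internal = TRUE)
  root_states <- sim$node_states[[length(tr$phy$tip.label) + 1L]]
  for (k in seq_len(ncol(sim$leaf_states))) {
    expect_identical(sim$leaf_states[, k], root_states)
  }
})

test_that("equilibrium divergence matches the two-state closed form", {
  # closed form D(dt) = 2 pi (1 - pi) (1 - gamma^dt) at equilibrium
  n_sites <- 1e5
  for (rates in list(c(0.5, 0.5), c(1e-3, 2e-3))) {
    al <- rates[1]; be <- rates[2]
    tr <- make_topology(2, 400, branch_times = 300, seed = 7)
    sim <- evolve_methylomes(tr, evolution_params(alpha = al, beta = be),
                             n_sites, seed = 8)
    d_obs <- mean(sim$levels[, 1] != sim$levels[, 2])
    pi_ss <- al / (al + be)
    d_exp <- 2 * pi_ss * (1 - pi_ss) * (1 - (1 - al - be)^200)
    se <- sqrt(d_exp * (1 - d_exp) / n_sites)
    expect_lt(abs(d_obs - d_exp), 3 * se)
  }
})

test_that("read-count emission respects states, depth and seed", {
  lv <- matrix(c(1, 0, 0.5), 3, 1, dimnames = list(NULL, "s"))
  m <- emit_wgbs_counts(lv, depth = 20, err_fm = 0, err_fu = 0, seed = 1)[[1]]
  expect_identical(m$count_methylated[1], m$count_total[1]) # state m
  expect_identical(m$count_methylated[2], 0L)               # state u

  # epiheterozygote converges to level 0.5 at high depth
  lv_i <- matrix(0.5, 1, 1, dimnames = list(NULL, "s"))
  mi <- emit_wgbs_counts(lv_i, depth = 1e4, dispersion = 1e4, seed = 2)[[1]]
  expect_lt(abs(mi$count_methylated / mi$count_total - 0.5), 0.02)

  m2 <- emit_wgbs_counts(lv, depth = 20, err_fm = 0, err_fu = 0, seed = 1)[[1]]
  expect_identical(m, m2)
})

test_that("stem design couples divergence to the division rate", {
  # equal division rates: opposite-side divergence identical in
  # expectation across treatments (normalized fold change ~ 1)
  sim_eq <- simulate_stem_design(kappa = c(moderate = 10, heavy = 10),
                                 eps_gain = 2e-6, eps_loss = 2e-6,
                                 n_sites = 5e4, seed = 11)
  dv <- stem_design_divergence(sim_eq)
  means <- tapply(dv$divergence[dv$comparison == "RS"],
                  dv$treatment[dv$comparison == "RS"], mean)
  rr <- mean(dv$divergence[dv$comparison == "RR"])
  fc <- normalized_fold_change(rr, means[["moderate"]], means[["heavy"]])
  expect_lt(abs(fc$fold_change - 1), 0.25)

  # doubled division rate doubles the replicate-normalised divergence
  sim2 <- simulate_stem_design(kappa = c(moderate = 10, heavy = 20),
                               eps_gain = 2e-6, eps_loss = 2e-6,
                               n_sites = 5e4, seed = 12)
  dv2 <- stem_design_divergence(sim2)
  m2 <- tapply(dv2$divergence[dv2$comparison == "RS"],
               dv2$treatment[dv2$comparison == "RS"], mean)
  rr2 <- mean(dv2$divergence[dv2$comparison == "RR"])
  fc2 <- normalized_fold_change(rr2, m2[["moderate"]], m2[["heavy"]])
  expect_lt(abs(fc2$fold_change - 2), 0.3)

  # replicates share nearly the whole lineage: RR divergence is far below
  # opposite-side divergence
  expect_lt(10 * rr2, mean(dv2$divergence[dv2$comparison == "RS"]))
})

test_that("per-year rate scales linearly with the division rate", {
  p1 <- evolution_params(kappa = 10, eps_gain = 5e-7, eps_loss = 5e-7)
  p2 <- evolution_params(kappa = 20, eps_gain = 5e-7, eps_loss = 5e-7)
  expect_lt(abs(p2$alpha / p1$alpha - 2), 0.05 * 2)
  expect_error(evolution_params(alpha = 1e-6, kappa = 10,
                                eps_gain = 1e-7, eps_loss = 1e-7),
               "not both")
})

test_that("simulated annotations carry their class signal", {
  ann <- make_annotation(n_genes = 20, fractions = c(gbM = 0, teM = 0,
                                                     unmethylated = 1),
                         seed = 21)
  bg <- exonic_background(ann$methylome, ann$genes)
  calls <- classify_gbm(ann$methylome, ann$genes, bg)
  expect_identical(sum(calls$gbm), 0L)

  ann2 <- make_annotation(n_genes = 20, fractions = c(gbM = 1, teM = 0,
                                                      unmethylated = 0),
                          seed = 22)
  # an all-gbM cohort needs an external (mixed-cohort-style) background
  ref_bg <- tibble::tibble(context = c("CG", "CHG", "CHH"),
                           methylated = NA, total = NA,
                           proportion = c(0.3, 0.02, 0.02))
  calls2 <- classify_gbm(ann2$methylome, ann2$genes, ref_bg)
  expect_identical(mean(calls2$gbm), 1)

  ann3 <- make_annotation(n_genes = 20, seed = 23)
  ann3b <- make_annotation(n_genes = 20, seed = 23)
  expect_identical(ann3$truth, ann3b$truth)
  expect_identical(ann3$methylome$count_methylated,
                   ann3b$methylome$count_methylated)
})
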