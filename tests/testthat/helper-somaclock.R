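# shared fixture builders (everything generated in code; no stored data)

# random well-formed methylome tibble
random_methylome <- function(n = 50, seed = 1) {
  withr::local_seed(seed)
  total <- rnbinom(n, mu = 20, size = 5) + 1L
  tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(5000L, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    count_methylated = rbinom(n, total, 0.3),
    count_total = total
  ) |>
    dplyr::distinct(chrom, pos, .keep_all = TRUE) |>
    dplyr::arrange(chrom, pos)
}

# per-site calls with controllable states and posteriors
calls_fixture <- function(states, posterior = 1, pos = seq_along(states)) {
  fake_calls(states, posterior_max = posterior, pos = pos)
}

# simulate divergence-vs-time pairs from a tree at given rates, returning
# the pair table ready for fit_neutral_model plus the observed p0
sim_rate_pairs <- function(alpha, beta, n_leaves = 10, age = 200,
                           n_sites = 5e5, seed = 1) {
  tree <- make_topology(n_leaves, age, seed = seed)
  sim <- evolve_methylomes(tree, evolution_params(alpha = alpha, beta = beta),
                           n_sites, seed = seed + 1000L)
  D <- divergence_matrix(sim$levels)
  dt <- divergence_times(tree)
  dt$D <- purrr::map2_dbl(dt$leaf_i, dt$leaf_j, ~D[.x, .y])
  attr(dt, "p0") <- mean(sim$levels)
  dt
}

# branch times on a jittered grid with >= min_gap years of separation
spaced_branch_times <- function(n_leaves, lo = 40, hi = 190, min_gap = 10) {
  k <- n_leaves - 1
  spacing <- (hi - lo) / k
  stopifnot(spacing > min_gap)
  sort(lo + (0:(k - 1)) * spacing + runif(k, 0, spacing - min_gap))
}
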