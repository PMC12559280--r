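test_that("window binning follows the 100-bp grid", {
  m <- tibble::tibble(chrom = "chr1", pos = c(10L, 50L, 120L),
                      strand = "+", context = "CG",
                      count_methylated = c(10L, 0L, 10L),
                      count_total = c(10L, 10L, 10L))
  w <- bin_to_windows(m, 100L, context = "CG")
  expect_identical(w$start, c(1L, 101L))
  expect_identical(w$end, c(100L, 200L))
  expect_identical(w$count_total, c(2L, 1L))
  expect_identical(w$count_methylated, c(1L, 1L)) # majority-read calls

  expect_identical(nrow(bin_to_windows(m[0, ])), 0L)
})

test_that("window counts equal a brute-force per-position tally", {
  m <- random_methylome(n = 200, seed = 7)
  m$state <- sample(c("u", "i", "m"), nrow(m), replace = TRUE)
  w <- bin_to_windows(m, 100L)
  # brute force: loop positions into windows, sum level weights
  lev <- c(u = 0, i = 0.5, m = 1)
  brute <- list()
  for (k in seq_len(nrow(m))) {
    win <- (m$pos[k] - 1L) %/% 100L
    key <- paste(m$chrom[k], win)
    prev <- if (is.null(brute[[key]])) numeric() else brute[[key]]
    brute[[key]] <- c(prev, lev[[m$state[k]]])
  }
  for (k in seq_len(nrow(w))) {
    key <- paste(w$chrom[k], (w$start[k] - 1L) %/% 100L)
    expect_identical(w$count_total[k], length(brute[[key]]))
    expect_identical(w$count_methylated[k],
                     as.integer(floor(sum(brute[[key]]) + 0.5)))
  }
  expect_identical(nrow(w), length(brute))
})

test_that("extreme counts are called with near-certain posteriors", {
  counts <- tibble::tibble(
    pos = seq_len(30) * 10L,
    count_methylated = rep(c(0L, 20L, 10L), 10),
    count_total = 20L)
  calls <- call_states(counts)
  expect_identical(calls$state, rep(c("u", "m", "i"), 10))

  # oracle: exact posterior under the fixed components (0.01, 0.5, 0.95)
  # with equal priors; the EM-estimated components can only sharpen it
  oracle_m <- dbinom(20, 20, 0.95) /
    (dbinom(20, 20, 0.01) + dbinom(20, 20, 0.5) + dbinom(20, 20, 0.95))
  expect_gt(oracle_m, 0.99)
  expect_gte(min(calls$posterior_max[calls$state == "m"]), 0.99)
  expect_gte(min(calls$posterior_max[calls$state == "u"]), 0.99)

  # posterior vectors sum to one
  sums <- calls$posterior_u + calls$posterior_i + calls$posterior_m
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("degenerate all-identical counts do not crash", {
  counts <- tibble::tibble(pos = 1:20, count_methylated = 5L,
                           count_total = 10L)
  calls <- call_states(counts)
  expect_identical(length(unique(calls$state)), 1L)
})

test_that("independent and chain modes agree on extreme units", {
  withr::local_seed(9)
  n <- 500
  truth <- sample(c("u", "i", "m"), n, replace = TRUE)
  p <- c(u = 0.01, i = 0.5, m = 0.99)[truth]
  counts <- tibble::tibble(pos = seq_len(n) * 7L,
                           count_total = 30L,
                           count_methylated = rbinom(n, 30L, p))
  ind <- call_states(counts, mode = "independent")
  ch <- call_states(counts, mode = "chain")
  extreme <- counts$count_methylated == 0 |
    counts$count_methylated == counts$count_total
  expect_identical(ind$state[extreme], ch$state[extreme])
})

test_that("SMP calling filters on posterior and matches brute force", {
  a <- calls_fixture(c("m", "m", "u", "i"), posterior = c(1, 0.95, 1, 1))
  b <- calls_fixture(c("u", "u", "u", "m"), posterior = 1)
  smps <- call_smps(a, b, min_posterior = 0.99)
  expect_identical(smps$pos, c(1L, 4L)) # site 2 fails the filter in a
  expect_identical(attr(smps, "n_eligible"), 3L)

  withr::local_seed(31)
  n <- 300
  a2 <- calls_fixture(sample(c("u", "i", "m"), n, TRUE),
                      posterior = runif(n, 0.9, 1))
  b2 <- calls_fixture(sample(c("u", "i", "m"), n, TRUE),
                      posterior = runif(n, 0.9, 1))
  smps2 <- call_smps(a2, b2, min_posterior = 0.99)
  brute <- which(a2$posterior_max >= 0.99 & b2$posterior_max >= 0.99 &
                   a2$state != b2$state)
  expect_identical(smps2$pos, a2$pos[brute])

  # disjoint universes are an error
  b3 <- calls_fixture(c("u", "m"), pos = c(1000L, 2000L))
  expect_error(call_smps(a, b3), "shared unit universe")
})

test_that("raising the posterior threshold never adds SMPs", {
  withr::local_seed(77)
  n <- 400
  a <- calls_fixture(sample(c("u", "i", "m"), n, TRUE),
                     posterior = runif(n, 0.8, 1))
  b <- calls_fixture(sample(c("u", "i", "m"), n, TRUE),
                     posterior = runif(n, 0.8, 1))
  counts <- vapply(c(0.8, 0.9, 0.95, 0.99, 0.999),
                   function(t) nrow(call_smps(a, b, min_posterior = t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("DMR calling recovers simulated window switches", {
  # 40 windows; a block of 8 switches from u to m between samples
  withr::local_seed(5)
  n <- 40
  truth_a <- rep("u", n); truth_b <- rep("u", n)
  truth_b[15:22] <- "m"
  emit <- function(states) {
    p <- c(u = 0.02, i = 0.5, m = 0.97)[states]
    tibble::tibble(chrom = "chr1",
                   start = (seq_len(n) - 1L) * 100L + 1L,
                   end = (seq_len(n)) * 100L,
                   count_total = 25L,
                   count_methylated = rbinom(n, 25L, p))
  }
  ca <- call_states(emit(truth_a))
  cb <- call_states(emit(truth_b))
  dmrs <- call_dmrs(ca, cb, min_posterior = 0.99)
  expect_true(all(15:22 %in% ((dmrs$start - 1L) %/% 100L + 1L)))
  expect_true(all(dmrs$state_a == "u" & dmrs$state_b == "m"))

  # same state on both sides is never a DMR
  same <- call_dmrs(ca, ca)
  expect_identical(nrow(same), 0L)
})
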