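#' Parameters of the neutral epimutation process
#'
#' Bundles the per-year gain rate \eqn{\alpha} (unmethylated to
#' methylated), per-year loss rate \eqn{\beta} (methylated to
#' unmethylated), the ancestral methylated proportion `p0`, and the
#' heterozygote handling mode. Rates may instead be supplied per cell
#' division (`eps_gain`, `eps_loss`) together with a divisions-per-year
#' factor `kappa`; per-year rates are then derived as
#' \eqn{\alpha = 1 - (1 - \epsilon_g)^\kappa} (and analogously
#' \eqn{\beta}), which couples epimutation accrual to the mitotic rate.
#'
#' @param alpha,beta Per-site per-year gain/loss probabilities in `[0, 1]`.
#'   Must not be supplied together with `kappa`.
#' @param p0 Ancestral methylated proportion in `[0, 1]`, or `NULL` for
#'   the steady state `alpha / (alpha + beta)`.
#' @param mode `"two_state"` (haploid u/m chain, the rate-estimation
#'   model's world) or `"three_state"` (two independent alleles; site
#'   state u/i/m by allele count, capturing somatic epiheterozygotes).
#' @param kappa Optional divisions per year (> 0).
#' @param eps_gain,eps_loss Optional per-division gain/loss probabilities,
#'   required with `kappa`.
#' @return An object of class `evolution_params`.
#' @export
#' @examples
#' evolution_params(alpha = 4.69e-6, beta = 6.50e-6)
#' evolution_params(kappa = 10, eps_gain = 5e-7, eps_loss = 5e-7)
evolution_params <- function(alpha = NULL, beta = NULL, p0 = NULL,
                             mode = c("two_state", "three_state"),
                             kappa = NULL, eps_gain = NULL, eps_loss = NULL) {
  mode <- match.arg(mode)
  if (!is.null(kappa)) {
    if (!is.null(alpha) || !is.null(beta)) {
      abort("supply either per-year (alpha, beta) or per-division rates with kappa, not both")
    }
    stopifnot(kappa > 0, !is.null(eps_gain), !is.null(eps_loss))
    alpha <- 1 - (1 - eps_gain)^kappa
    beta <- 1 - (1 - eps_loss)^kappa
  }
  if (is.null(alpha) || is.null(beta)) abort("alpha and beta are required")
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  if (is.null(p0)) {
    p0 <- if (alpha + beta > 0) alpha / (alpha + beta) else 0
  }
  stopifnot(p0 >= 0, p0 <= 1)
  structure(list(alpha = alpha, beta = beta, p0 = p0, mode = mode,
                 kappa = kappa, eps_gain = eps_gain, eps_loss = eps_loss),
            class = "evolution_params")
}

# Exact end-state sampling of the discrete-time two-state chain over t
# whole years: P(m | start m) = pi + (1 - pi) gamma^t,
# P(m | start u) = pi (1 - gamma^t), gamma = 1 - alpha - beta.
transition_probs <- function(alpha, beta, t) {
  if (alpha + beta == 0) return(c(p_m_given_m = 1, p_m_given_u = 0))
  pi_ss <- alpha / (alpha + beta)
  g <- (1 - alpha - beta)^t
  c(p_m_given_m = pi_ss + (1 - pi_ss) * g, p_m_given_u = pi_ss * (1 - g))
}

evolve_branch <- function(states, alpha, beta, years) {
  p <- transition_probs(alpha, beta, years)
  out <- integer(length(states))
  m <- states == 1L
  out[m] <- rbinom(sum(m), 1L, p[["p_m_given_m"]])
  out[!m] <- rbinom(sum(!m), 1L, p[["p_m_given_u"]])
  out
}

#' Evolve methylomes along a dated lineage tree
#'
#' Each site evolves independently along the branches as a discrete-time
#' (per-year) two-state Markov chain with per-year gain probability
#' \eqn{\alpha} (u to m) and loss probability \eqn{\beta} (m to u).
#' Ancestral states are drawn i.i.d. with `P(m) = p0`. In `three_state`
#' mode two independent alleles are evolved and a site's state is u, i or
#' m according to how many alleles are methylated.
#'
#' @param tree A [lineage_tree()].
#' @param params An [evolution_params()].
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed.
#' @param include_internal Also return states at internal nodes (for
#'   small-scale oracle checks).
#' @return An object of class `state_matrix_sim`: a list with
#'   * `leaf_states`: integer matrix, `n_sites` x leaves — allele count of
#'     methylation (0/1 in two-state mode; 0/1/2 in three-state mode),
#'   * `levels`: the matrix mapped to methylation levels in `[0, 1]`,
#'   * `node_states` (optional), `params`, `tree`.
#' @export
evolve_methylomes <- function(tree, params, n_sites, seed = 1L,
                              include_internal = FALSE) {
  stopifnot(inherits(tree, "lineage_tree"),
            inherits(params, "evolution_params"), n_sites >= 1)
  withr::local_seed(seed)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  n_nodes <- ntip + phy$Nnode
  root <- ntip + 1L
  n_alleles <- if (params$mode == "three_state") 2L else 1L

  # process edges so a parent's states exist before its children's
  states <- vector("list", n_nodes)
  states[[root]] <- matrix(
    rbinom(n_sites * n_alleles, 1L, params$p0), n_sites, n_alleles)
  remaining <- seq_len(nrow(phy$edge))
  while (length(remaining) > 0) {
    ready <- remaining[!vapply(phy$edge[remaining, 1],
                               function(p) is.null(states[[p]]), logical(1))]
    if (length(ready) == 0) abort("disconnected tree")
    for (e in ready) {
      from <- phy$edge[e, 1]; to <- phy$edge[e, 2]
      s <- apply(states[[from]], 2, evolve_branch,
                 alpha = params$alpha, beta = params$beta,
                 years = phy$edge.length[e])
      states[[to]] <- matrix(s, n_sites, n_alleles)
    }
    remaining <- setdiff(remaining, ready)
  }

  leaf_states <- vapply(seq_len(ntip), function(k) rowSums(states[[k]]),
                        numeric(n_sites))
  leaf_states <- matrix(as.integer(leaf_states), n_sites, ntip,
                        dimnames = list(NULL, phy$tip.label))
  out <- list(
    leaf_states = leaf_states,
    levels = leaf_states / n_alleles,
    params = params,
    tree = tree
  )
  if (include_internal) {
    out$node_states <- lapply(states, function(s) as.integer(rowSums(s)))
  }
  class(out) <- "state_matrix_sim"
  out
}

#' @export
print.state_matrix_sim <- function(x, ...) {
  cat(sprintf("<state_matrix_sim> %d sites x %d leaves (%s mode)\n",
              nrow(x$leaf_states), ncol(x$leaf_states), x$params$mode))
  invisible(x)
}

#' Tidy leaf states of a simulated methylome
#'
#' @param x A `state_matrix_sim`.
#' @param ... Unused.
#' @return A long tibble with columns `site`, `sample`, `state`
#'   (u/i/m), `level`.
#' @method tidy state_matrix_sim
#' @export
tidy.state_matrix_sim <- function(x, ...) {
  lv <- x$levels
  tibble::tibble(
    site = rep(seq_len(nrow(lv)), times = ncol(lv)),
    sample = rep(colnames(lv), each = nrow(lv)),
    level = as.vector(lv),
    state = STATES[match(as.vector(lv), c(0, 0.5, 1))]
  )
}

#' Emit bisulfite read counts from true methylation states
#'
#' Per-site read totals follow a negative-binomial distribution with the
#' stated mean depth (dispersion configurable); methylated read counts are
#' binomial with success probability `err_fm` for unmethylated sites,
#' `0.5` for epiheterozygous sites, and `1 - err_fu` for methylated sites.
#'
#' @param sim A `state_matrix_sim` from [evolve_methylomes()], or a
#'   numeric matrix of levels in `{0, 0.5, 1}` (sites x samples).
#' @param depth Mean read depth (> 0); the field's typical whole-genome
#'   bisulfite coverage is ~20x.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param err_fm Probability that a read on an unmethylated cytosine
#'   appears methylated (bisulfite non-conversion).
#' @param err_fu Probability that a read on a methylated cytosine appears
#'   unmethylated.
#' @param seed Integer seed.
#' @param positions Optional integer vector of site positions; defaults to
#'   random distinct positions on one chromosome.
#' @param context Context label for the emitted records.
#' @return A named list of `methylome` tibbles, one per sample.
#' @export
emit_wgbs_counts <- function(sim, depth = 20, dispersion = 5,
                             err_fm = 0.01, err_fu = 0.01, seed = 1L,
                             positions = NULL, context = "CG") {
  levels <- if (inherits(sim, "state_matrix_sim")) sim$levels else sim
  stopifnot(is.matrix(levels), depth > 0)
  withr::local_seed(seed)
  n_sites <- nrow(levels)
  samples <- colnames(levels) %||% paste0("S", seq_len(ncol(levels)))
  if (is.null(positions)) {
    positions <- sort(sample.int(n_sites * 50L, n_sites))
  }
  stopifnot(length(positions) == n_sites)
  p_read <- function(lv) ifelse(lv == 0, err_fm,
                         ifelse(lv == 1, 1 - err_fu, 0.5))
  out <- lapply(seq_along(samples), function(k) {
    total <- as.integer(rnbinom(n_sites, mu = depth, size = dispersion))
    meth <- as.integer(rbinom(n_sites, total, p_read(levels[, k])))
    new_methylome(tibble::tibble(
      chrom = "chr1", pos = positions, strand = "+", context = context,
      count_methylated = meth, count_total = total))
  })
  names(out) <- samples
  out
}
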