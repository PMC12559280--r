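# --- pairwise methylation divergence and effect sizes -------------------

#' Pairwise methylation divergence between two samples
#'
#' For each site \eqn{i} passing the posterior filter in both samples,
#' computes the absolute difference of the methylation encodings,
#' \eqn{D_i = |M(A, i) - M(B, i)|}, and averages over passing sites:
#' \eqn{D = \frac{1}{n}\sum_i D_i}. The default encoding is three-level
#' (`u` = 0, `i` = 0.5, `m` = 1); the `"dmp"` encoding instead scores any
#' state difference as 1 (differentially methylated positions as a proxy
#' for divergence).
#'
#' @param calls_a,calls_b Per-site (or per-window) state calls from
#'   [call_states()] on a shared unit universe.
#' @param min_posterior Minimum `posterior_max` required in both samples
#'   at counted sites (default 0.99).
#' @param encoding `"level"` (0 / 0.5 / 1) or `"dmp"` (state-difference
#'   indicator).
#' @return A one-row tibble with columns `D`, `n` (sites passing filters).
#' @export
#' @examples
#' a <- fake_calls(c("m", "m", "u", "i"))
#' b <- fake_calls(c("m", "u", "u", "i"))
#' pairwise_divergence(a, b) # D = 0.25
pairwise_divergence <- function(calls_a, calls_b, min_posterior = 0.99,
                                encoding = c("level", "dmp")) {
  encoding <- match.arg(encoding)
  key <- unit_key_cols(calls_a)
  a <- tibble::as_tibble(calls_a); b <- tibble::as_tibble(calls_b)
  ka <- do.call(paste, c(a[key], sep = "\r"))
  kb <- do.call(paste, c(b[key], sep = "\r"))
  if (!setequal(ka, kb)) abort("divergence requires a shared site universe")
  b <- b[match(ka, kb), ]
  pass <- a$posterior_max >= min_posterior & b$posterior_max >= min_posterior
  if (!any(pass)) abort("no sites pass the posterior filter in both samples")
  d_i <- if (encoding == "level") {
    abs(state_to_level(a$state[pass]) - state_to_level(b$state[pass]))
  } else {
    as.numeric(a$state[pass] != b$state[pass])
  }
  tibble::tibble(D = mean(d_i), n = sum(pass))
}

#' Build a minimal state-call tibble from state labels
#'
#' Convenience constructor for hand-built fixtures and examples: wraps a
#' character vector of states into the tibble shape [call_states()]
#' produces, with unit positions `1..n` and `posterior_max = 1`.
#'
#' @param states Character vector of `"u"`, `"i"`, `"m"`.
#' @param posterior_max Posterior confidence to attach (recycled).
#' @param pos Unit positions.
#' @return A tibble with columns `pos`, `state`, `posterior_max`.
#' @export
fake_calls <- function(states, posterior_max = 1, pos = seq_along(states)) {
  stopifnot(all(states %in% STATES))
  tibble::tibble(pos = pos, state = states,
                 posterior_max = rep_len(posterior_max, length(states)))
}

#' Divergence matrix from a matrix of methylation levels
#'
#' Computes all pairwise divergences \eqn{D} from a sites-by-samples
#' matrix of methylation levels (0 / 0.5 / 1), as produced by the
#' simulator's truth or by stacking call levels. This is the bulk
#' counterpart of [pairwise_divergence()] used for clustering and rate
#' fitting at scale.
#'
#' @param levels Numeric matrix, sites x samples, values in `[0, 1]`.
#' @param encoding `"level"` or `"dmp"` as in [pairwise_divergence()].
#' @return A symmetric matrix of divergences with zero diagonal.
#' @export
divergence_matrix <- function(levels, encoding = c("level", "dmp")) {
  encoding <- match.arg(encoding)
  stopifnot(is.matrix(levels))
  ns <- ncol(levels)
  D <- matrix(0, ns, ns, dimnames = list(colnames(levels), colnames(levels)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      d <- if (encoding == "level") mean(abs(levels[, i] - levels[, j]))
           else mean(levels[, i] != levels[, j])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Cohen's d effect size between two divergence groups
#'
#' \eqn{d_C = (\bar D_1 - \bar D_2) / s} with the pooled standard
#' deviation \eqn{s = \sqrt{((n_1 - 1) s_1^2 + (n_2 - 1) s_2^2) /
#' (n_1 + n_2 - 2)}}. Interpretation bands: small effect for
#' \eqn{0.2 < d_C < 0.5}, medium for \eqn{d_C > 0.5}, large for
#' \eqn{d_C > 0.8}.
#'
#' @param group1,group2 Numeric vectors of divergences (each of length
#'   >= 2).
#' @return A one-row tibble: `mean1`, `mean2`, `n1`, `n2`, `sd1`, `sd2`,
#'   `pooled_sd`, `d_c`, `band`, `degenerate` (`TRUE` when the pooled SD
#'   is zero with unequal means, leaving `d_c` infinite).
#' @export
#' @examples
#' cohens_d(c(3, 4, 3.5), c(1, 1.5, 0.5))
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) abort("each group needs at least two observations")
  s1 <- sd(group1); s2 <- sd(group2)
  s <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  m1 <- mean(group1); m2 <- mean(group2)
  degenerate <- s == 0 && m1 != m2
  d <- if (s > 0) (m1 - m2) / s else if (m1 == m2) 0 else Inf * sign(m1 - m2)
  ad <- abs(d)
  band <- if (ad > 0.8) "large" else if (ad > 0.5) "medium"
          else if (ad > 0.2) "small" else "negligible"
  tibble::tibble(mean1 = m1, mean2 = m2, n1 = n1, n2 = n2,
                 sd1 = s1, sd2 = s2, pooled_sd = s, d_c = d,
                 band = band, degenerate = degenerate)
}

#' Replicate-normalised fold change of opposite-side divergence
#'
#' Normalises opposite-side stem divergence by subtracting the baseline
#' variation between same-side replicates, then forms the treatment fold
#' change: `(mean_heavy - mean_rr) / (mean_mod - mean_rr)`.
#'
#' @param mean_rr Mean divergence between same-side replicate pairs.
#' @param mean_mod Mean opposite-side divergence, moderate treatment.
#' @param mean_heavy Mean opposite-side divergence, heavy treatment.
#' @return A one-row tibble with columns `fold_change` and `defined`
#'   (`FALSE`, with `fold_change = NA`, when the denominator is not
#'   positive and the ratio is therefore undefined).
#' @export
#' @examples
#' m <- published_stem_divergences()
#' normalized_fold_change(m["replicates"], m["moderate"], m["heavy"]) # 2.64
normalized_fold_change <- function(mean_rr, mean_mod, mean_heavy) {
  denom <- mean_mod - mean_rr
  if (denom <= 0) {
    return(tibble::tibble(fold_change = NA_real_, defined = FALSE))
  }
  tibble::tibble(fold_change = (mean_heavy - mean_rr) / denom,
                 defined = TRUE)
}

#' Cluster samples from a divergence matrix
#'
#' Unsupervised average-linkage (UPGMA) hierarchical clustering of samples
#' from a symmetric divergence matrix. The result can be compared with a
#' reference lineage topology (e.g. by Robinson-Foulds distance through
#' `phangorn::RF.dist` on the `$phylo` component).
#'
#' @param D Symmetric numeric matrix of divergences with zero diagonal and
#'   sample names as dimnames.
#' @return A list of class `divergence_clustering` with `hclust` (the
#'   stats::hclust tree), `phylo` (ape conversion) and `leaf_order`.
#' @export
cluster_samples <- function(D) {
  stopifnot(is.matrix(D))
  if (max(abs(D - t(D))) > 1e-12) abort("divergence matrix must be symmetric")
  if (any(diag(D) != 0)) abort("divergence matrix must have a zero diagonal")
  hc <- hclust(as.dist(D), method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 leaf_order = hc$labels[hc$order]),
            class = "divergence_clustering")
}

#' @export
print.divergence_clustering <- function(x, ...) {
  cat(sprintf("<divergence_clustering> UPGMA over %d samples\n",
              length(x$leaf_order)))
  invisible(x)
}

#' Compare divergence groups of a stem sampling design
#'
#' Runs the planned one-sided comparisons among replicate (RR) and
#' opposite-side (RS) divergence groups: unpaired one-sided Wilcoxon
#' rank-sum tests (alternative: the first group's divergences are
#' greater) together with Cohen's d per comparison.
#'
#' @param divergences A tibble with columns `treatment`, `comparison`
#'   (`"RR"` or `"RS"`) and `divergence`, e.g. from
#'   [stem_design_divergence()].
#' @return A tibble with one row per comparison: `group1`, `group2`, `W`,
#'   `p_value`, `d_c`, `n1`, `n2`.
#' @export
compare_divergence_groups <- function(divergences) {
  assert_columns(divergences, c("treatment", "comparison", "divergence"),
                 "divergence table")
  g <- list(
    RR = divergences$divergence[divergences$comparison == "RR"],
    moderate_RS = divergences$divergence[divergences$comparison == "RS" &
                                           divergences$treatment == "moderate"],
    heavy_RS = divergences$divergence[divergences$comparison == "RS" &
                                        divergences$treatment == "heavy"])
  combos <- list(c("moderate_RS", "RR"), c("heavy_RS", "RR"),
                 c("heavy_RS", "moderate_RS"))
  purrr::map_dfr(combos, function(cm) {
    x <- g[[cm[1]]]; y <- g[[cm[2]]]
    if (length(x) < 2 || length(y) < 2) {
      abort(sprintf("group %s or %s has fewer than 2 observations", cm[1], cm[2]))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
    tibble::tibble(group1 = cm[1], group2 = cm[2],
                   W = unname(wt$statistic), p_value = wt$p.value,
                   d_c = cohens_d(x, y)$d_c,
                   n1 = length(x), n2 = length(y))
  })
}
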