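#' Simulate the cambium stem-sampling design
#'
#' Emulates the stem sampling geometry used to compare treatments with
#' different growth (cell-division) rates: per tree, two neighbouring
#' replicate cambium samples from one side of the stem (`R1`, `R2`) and
#' one sample from the polar opposite side (`S`). `R1` and `R2` share all
#' but a small terminal number of cell divisions; `S` diverges from them
#' at the stem core. Epimutations accrue per cell division, so a treatment
#' with a higher division rate `kappa` accumulates proportionally more
#' divergence per year of growth.
#'
#' @param kappa Named numeric vector of divisions per year, one per
#'   treatment, e.g. `c(moderate = 10, heavy = 20)`. The heavy treatment
#'   must exceed the moderate one.
#' @param eps_gain,eps_loss Per-division gain/loss probabilities.
#' @param n_trees Named integer vector of trees per treatment (defaults to
#'   the study design: 4 moderate, 3 heavy).
#' @param age_years Tree age (lineage duration) in years.
#' @param replicate_divisions Number of terminal divisions separating `R1`
#'   from `R2` (shared-lineage geometry of neighbouring samples).
#' @param n_sites Sites per methylome.
#' @param seed Integer seed.
#' @param emit When `TRUE`, also emit read counts ([emit_wgbs_counts()])
#'   with the given `depth`.
#' @param depth Mean read depth for emission.
#' @return A list with
#'   * `design`: tibble (`sample`, `tree`, `treatment`, `role`),
#'   * `levels`: sites x samples matrix of true methylation levels,
#'   * `methylomes`: named list of `methylome` tibbles (when `emit`),
#'   * `divisions`: tibble of total divisions per lineage.
#' @export
simulate_stem_design <- function(kappa = c(moderate = 10, heavy = 20),
                                 eps_gain = 5e-7, eps_loss = 5e-7,
                                 n_trees = c(moderate = 4, heavy = 3),
                                 age_years = 200,
                                 replicate_divisions = 5,
                                 n_sites = 1e4, seed = 1L,
                                 emit = FALSE, depth = 20) {
  stopifnot(length(kappa) == 2, all(names(kappa) %in% names(n_trees)))
  if (kappa[["heavy"]] < kappa[["moderate"]]) {
    abort("kappa must be at least as large in the heavy as in the moderate treatment")
  }
  withr::local_seed(seed)
  p0 <- if (eps_gain + eps_loss > 0) eps_gain / (eps_gain + eps_loss) else 0

  design <- list(); levels <- list(); div_rows <- list()
  for (tr in names(n_trees)) {
    for (t_i in seq_len(n_trees[[tr]])) {
      tree_id <- sprintf("%s_%d", tr, t_i)
      n_div <- round(kappa[[tr]] * age_years)
      d_rep <- min(replicate_divisions, n_div)
      ancestor <- rbinom(n_sites, 1L, p0) # stem core state
      s_state <- evolve_branch(ancestor, eps_gain, eps_loss, n_div)
      r_common <- evolve_branch(ancestor, eps_gain, eps_loss, n_div - d_rep)
      r1 <- evolve_branch(r_common, eps_gain, eps_loss, d_rep)
      r2 <- evolve_branch(r_common, eps_gain, eps_loss, d_rep)
      for (role in c("R1", "R2", "S")) {
        id <- sprintf("%s_%s", tree_id, role)
        design[[id]] <- tibble::tibble(sample = id, tree = tree_id,
                                       treatment = tr, role = role)
        levels[[id]] <- switch(role, R1 = r1, R2 = r2, S = s_state)
      }
      div_rows[[tree_id]] <- tibble::tibble(tree = tree_id, treatment = tr,
                                            divisions = n_div)
    }
  }
  lv <- do.call(cbind, levels)
  out <- list(design = dplyr::bind_rows(design),
              levels = lv,
              divisions = dplyr::bind_rows(div_rows))
  if (emit) {
    out$methylomes <- emit_wgbs_counts(lv, depth = depth,
                                       seed = child_seed(seed, 1L))
  }
  out
}

#' Treatment-level divergence summary of a simulated stem design
#'
#' Computes the true-state pairwise divergences the design implies: the
#' replicate pair (RR) and the two opposite-side pairs (R1 vs S, R2 vs S)
#' per tree, averaged per comparison group.
#'
#' @param sim Output of [simulate_stem_design()].
#' @return A tibble with one row per pairwise comparison: `tree`,
#'   `treatment`, `comparison` (`"RR"` or `"RS"`), `divergence`.
#' @export
stem_design_divergence <- function(sim) {
  trees <- unique(sim$design$tree)
  purrr::map_dfr(trees, function(tr) {
    tr_rows <- dplyr::filter(sim$design, .data$tree == tr)
    lv <- sim$levels
    id <- function(role) tr_rows$sample[tr_rows$role == role]
    d <- function(a, b) mean(abs(lv[, a] - lv[, b]))
    tibble::tibble(
      tree = tr, treatment = tr_rows$treatment[1],
      comparison = c("RR", "RS", "RS"),
      divergence = c(d(id("R1"), id("R2")),
                     d(id("R1"), id("S")),
                     d(id("R2"), id("S"))))
  })
}
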