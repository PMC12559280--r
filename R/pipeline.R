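# --- end-to-end orchestration -------------------------------------------

default_config <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("somaclock_run_"),
    simulate = list(n_leaves = 6L, age_years = 200L, n_sites = 5000L,
                    alpha = 5e-4, beta = 5e-4, mode = "two_state",
                    depth = 30, err = 0.005),
    min_posterior = 0.99,
    window_size = 100L,
    exclude_root_censored = TRUE
  )
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_config()
  known <- names(base)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(base, config)
  if (is.null(cfg$seed)) abort("a seed is mandatory")
  cfg
}

#' Run the simulation-to-rates pipeline
#'
#' Orchestrates the full analysis on a simulated dataset: topology
#' simulation, methylome evolution and read-count emission, per-site state
#' calling, pairwise divergence and clustering, pedigree divergence times,
#' and neutral-model rate fitting. Every stage's outputs are written under
#' the configured output directory and checksummed into a manifest, so a
#' run can be reproduced bit-identically from its config.
#'
#' @param config A config list or path to a JSON config file. Keys (all
#'   optional except `seed` if reproducibility matters): `seed`,
#'   `out_dir`, `simulate` (`n_leaves`, `age_years`, `n_sites`, `alpha`,
#'   `beta`, `mode`, `depth`, `err`), `min_posterior`, `window_size`,
#'   `exclude_root_censored`. Unknown keys are rejected.
#' @return The run manifest: a list with `config`, `stages` (tibble of
#'   stage, output file, md5 checksum), `fit` (glance of the rate fit) and
#'   `clustering` leaf order.
#' @export
#' @examples
#' \donttest{
#' man <- run_pipeline(list(seed = 7,
#'                          simulate = list(n_sites = 2000L)))
#' man$stages
#' }
run_pipeline <- function(config = list()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), stage))
  }
  run_stage <- function(stage, f) {
    log_stage(stage)
    tryCatch(f(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  files <- character()

  # 1. simulate
  sim_out <- run_stage("simulate", function() {
    sc <- cfg$simulate
    tree <- make_topology(sc$n_leaves, sc$age_years,
                          seed = child_seed(cfg$seed, 1L))
    params <- evolution_params(alpha = sc$alpha, beta = sc$beta,
                               mode = sc$mode)
    sim <- evolve_methylomes(tree, params, sc$n_sites,
                             seed = child_seed(cfg$seed, 2L))
    meths <- emit_wgbs_counts(sim, depth = sc$depth, err_fm = sc$err,
                              err_fu = sc$err,
                              seed = child_seed(cfg$seed, 3L))
    tree_file <- file.path(cfg$out_dir, "tree.nwk")
    write_tree_newick(tree, tree_file)
    files["tree"] <<- tree_file
    list(tree = tree, sim = sim, methylomes = meths)
  })

  # 2. callstates
  calls <- run_stage("callstates", function() {
    out <- purrr::map(sim_out$methylomes, function(m) {
      call_states(m[, c("chrom", "pos", "count_methylated", "count_total")])
    })
    f <- file.path(cfg$out_dir, "state_matrix.tsv")
    write_state_matrix(out, f)
    files["state_matrix"] <<- f
    out
  })

  # 3. divergence (+ clustering)
  div <- run_stage("divergence", function() {
    samples <- names(calls)
    pairs <- utils::combn(samples, 2)
    tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      d <- pairwise_divergence(calls[[a]], calls[[b]],
                               min_posterior = cfg$min_posterior)
      dplyr::mutate(d, sample_a = a, sample_b = b, .before = 1)
    })
    D <- matrix(0, length(samples), length(samples),
                dimnames = list(samples, samples))
    for (k in seq_len(ncol(pairs))) {
      D[pairs[1, k], pairs[2, k]] <- D[pairs[2, k], pairs[1, k]] <- tbl$D[k]
    }
    clus <- cluster_samples(D)
    f <- file.path(cfg$out_dir, "divergence.tsv")
    write_divergence_table(tbl, f)
    files["divergence"] <<- f
    fn <- file.path(cfg$out_dir, "dendrogram.nwk")
    ape::write.tree(clus$phylo, file = fn)
    files["dendrogram"] <<- fn
    list(table = tbl, matrix = D, clustering = clus)
  })

  # 4. pedigree
  pairs_dt <- run_stage("pedigree", function() {
    dt <- divergence_times(sim_out$tree)
    f <- file.path(cfg$out_dir, "pair_times.tsv")
    write_divergence_table(dt, f)
    files["pair_times"] <<- f
    dt
  })

  # 5. rates
  fit <- run_stage("rates", function() {
    merged <- dplyr::inner_join(
      div$table, pairs_dt,
      by = c(sample_a = "leaf_i", sample_b = "leaf_j"))
    p0 <- mean(purrr::map_dbl(calls, ~mean(state_to_level(.x$state))))
    fit <- fit_neutral_model(
      merged, p0 = p0,
      exclude_root_censored = cfg$exclude_root_censored)
    f <- file.path(cfg$out_dir, "fit_report.tsv")
    write_fit_report(fit, f)
    files["fit_report"] <<- f
    fit
  })

  # 6. report / manifest
  manifest <- run_stage("report", function() {
    stages <- tibble::tibble(
      stage = c("simulate", "callstates", "divergence", "divergence",
                "pedigree", "rates")[seq_along(files)],
      file = unname(files),
      md5 = unname(tools::md5sum(unname(files))))
    man <- list(config = cfg, stages = stages,
                fit = glance.neutral_fit(fit),
                clustering = div$clustering$leaf_order)
    jsonlite::write_json(
      list(config = cfg[setdiff(names(cfg), "out_dir")],
           files = as.list(setNames(stages$md5, basename(stages$file)))),
      file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE)
    man
  })
  manifest
}
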