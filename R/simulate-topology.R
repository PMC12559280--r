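#' Simulate a dated branching topology
#'
#' Generates a random rooted, dated topology for an intra-organismal
#' pedigree: all leaves are sampled at `age_years`, and internal branch
#' points sit at the supplied (or randomly drawn) years since germination.
#' The shape is grown forward in time: at each successive branch point a
#' uniformly chosen active lineage splits in two.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param age_years Sampling age of the organism in years (>= 1).
#' @param branch_times Optional vector of `n_leaves - 1` branch-point
#'   years in `[0, age_years]`. When omitted, branch points are drawn
#'   uniformly on `[0.2 * age_years, 0.95 * age_years]`.
#' @param seed Integer seed; the same seed and arguments give an identical
#'   tree.
#' @return A [lineage_tree()] whose root sits at the earliest branch point.
#' @export
#' @examples
#' make_topology(n_leaves = 4, age_years = 200, seed = 7)
make_topology <- function(n_leaves, age_years, branch_times = NULL,
                          seed = 1L) {
  stopifnot(n_leaves >= 2, age_years >= 1)
  withr::local_seed(seed)
  if (is.null(branch_times)) {
    branch_times <- runif(n_leaves - 1, 0.2 * age_years, 0.95 * age_years)
  }
  if (length(branch_times) != n_leaves - 1) {
    abort("need exactly n_leaves - 1 branch times")
  }
  if (any(branch_times < 0 | branch_times > age_years)) {
    abort("branch_times must lie within [0, age_years]")
  }
  branch_times <- sort(branch_times)

  # grow forward in time: the root split starts two lineages; each later
  # branch point splits one uniformly chosen active lineage in two. An
  # active lineage is represented by the node it currently hangs from.
  ntip <- n_leaves
  n_nodes <- 2L * ntip - 1L
  parent <- integer(n_nodes) # 0 for root
  node_time <- numeric(n_nodes)
  root <- ntip + 1L
  node_time[root] <- branch_times[1]
  active <- c(root, root)
  next_internal <- root + 1L
  for (k in seq_along(branch_times)[-1]) {
    idx <- sample.int(length(active), 1L)
    v <- next_internal
    next_internal <- next_internal + 1L
    parent[v] <- active[idx]
    node_time[v] <- branch_times[k]
    active[idx] <- v
    active <- c(active, v)
  }
  # each surviving lineage terminates in a leaf sampled at age_years
  for (leaf_id in seq_len(ntip)) {
    parent[leaf_id] <- active[leaf_id]
    node_time[leaf_id] <- age_years
  }

  edge <- cbind(parent[-root], seq_len(n_nodes)[-root])
  keep <- edge[, 1] > 0
  edge <- edge[keep, , drop = FALSE]
  phy <- structure(list(
    edge = edge,
    edge.length = node_time[edge[, 2]] - node_time[edge[, 1]],
    tip.label = paste0("L", seq_len(ntip)),
    Nnode = ntip - 1L
  ), class = "phylo")
  lineage_tree(phy, root_age = branch_times[1])
}
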