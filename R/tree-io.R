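#' Read a dated lineage tree
#'
#' Reads an intra-organismal lineage tree either from a Newick file with
#' branch lengths in years or from an edge-list TSV with columns `parent`,
#' `child`, `years`. The result is a rooted tree in which every tip sits at
#' the tree's sampling age and every internal node is a dated branch point.
#'
#' @param path Path to a `.nwk`/`.newick`/`.tre` file or an edge-list TSV
#'   (format auto-detected: files whose first non-blank character is `(`
#'   are parsed as Newick).
#' @return A `lineage_tree` object; see [lineage_tree()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:50,B:50):150,C:200);", tf)
#' read_tree(tf)
read_tree <- function(path) {
  if (!file.exists(path)) abort(sprintf("tree file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (grepl("^\\s*\\(", txt)) {
    phy <- ape::read.tree(text = txt)
    if (is.null(phy)) abort("could not parse Newick tree")
    return(lineage_tree(phy))
  }
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(edges, c("parent", "child", "years"), "edge list")
  lineage_tree_from_edges(edges)
}

#' Construct a dated lineage tree
#'
#' Wraps an `ape::phylo` tree whose branch lengths are in years. Validates
#' that the tree is rooted, has unique tip labels, non-negative branch
#' lengths, and that all tips are contemporaneous (sampled at the same
#' age), which is what an intra-organismal pedigree of a standing tree
#' requires.
#'
#' @param phy An `ape::phylo` object with edge lengths in years.
#' @param root_age Years from germination to the earliest branch point (the
#'   tree root). Divergence times never need it; it only anchors node ages
#'   on the germination time axis.
#' @param tol Tolerance (years) for the ultrametricity check.
#' @return An object of class `lineage_tree`: a list with elements `phy`
#'   (the phylo tree), `root_age`, and `age` (germination-to-leaf time in
#'   years).
#' @export
lineage_tree <- function(phy, root_age = 0, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) abort("tree has no branch lengths")
  # canonical edge ordering: ape's traversal-based functions assume it
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (any(phy$edge.length < 0)) abort("negative branch lengths")
  if (anyDuplicated(phy$tip.label)) abort("duplicate leaf labels")
  if (!ape::is.rooted(phy)) abort("tree must be rooted (exactly one root)")
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  if (diff(range(depths)) > tol) {
    abort("all leaves must be sampled at the same age (ultrametric in years)")
  }
  structure(list(phy = phy, root_age = root_age,
                 age = root_age + max(depths)),
            class = "lineage_tree")
}

lineage_tree_from_edges <- function(edges) {
  parents <- as.character(edges$parent)
  children <- as.character(edges$child)
  if (anyDuplicated(children)) abort("node with multiple parents")
  nodes <- union(parents, children)
  roots <- setdiff(parents, children)
  if (length(roots) != 1) {
    abort(sprintf("expected exactly one root, found %d", length(roots)))
  }
  # cycle check: children must all be reachable from the root
  kids <- split(children, factor(parents, levels = nodes))
  seen <- character()
  frontier <- roots
  while (length(frontier) > 0) {
    if (any(frontier %in% seen)) abort("cycle detected in edge list")
    seen <- c(seen, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  if (!setequal(seen, nodes)) abort("cycle detected in edge list")

  tips <- setdiff(children, parents)
  internal <- c(roots, setdiff(unique(parents), roots))
  ntip <- length(tips)
  idx <- c(setNames(seq_len(ntip), tips),
           setNames(ntip + seq_along(internal), internal))
  edge <- cbind(idx[parents], idx[children])
  dimnames(edge) <- NULL
  phy <- structure(list(edge = edge,
                        edge.length = as.numeric(edges$years),
                        tip.label = tips,
                        Nnode = length(internal)),
                   class = "phylo")
  lineage_tree(phy)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %d leaves, age %s years\n",
              length(x$phy$tip.label), format(x$age)))
  cat("  leaves:", paste(head(x$phy$tip.label, 8), collapse = ", "),
      if (length(x$phy$tip.label) > 8) "..." else "", "\n")
  invisible(x)
}

#' @method as_tibble lineage_tree
#' @export
as_tibble.lineage_tree <- function(x, ...) {
  phy <- x$phy
  depth <- ape::node.depth.edgelength(phy)
  labs <- c(phy$tip.label, paste0("node", seq_len(phy$Nnode)))
  tibble::tibble(
    node = seq_along(depth),
    label = labs,
    is_leaf = seq_along(depth) <= length(phy$tip.label),
    age_years = x$root_age + depth # years since germination
  )
}

#' Write a lineage tree to Newick
#'
#' @param tree A `lineage_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}
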