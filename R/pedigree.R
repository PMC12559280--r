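#' Pairwise divergence times on an intra-organismal pedigree
#'
#' For every unordered pair of leaves, traces back the branch ages to the
#' pair's most recent common branch point and reports the time from that
#' branch point to each leaf (`tau_i`, `tau_j`) and their sum, the
#' divergence time `delta_t`. Divergence can only be dated down to the
#' tree's earliest branch point: pairs whose common ancestor is the root
#' are flagged `root_censored` (their `delta_t` is a lower bound).
#'
#' @param tree A [lineage_tree()].
#' @return A tibble with columns `leaf_i`, `leaf_j`, `tau_i`, `tau_j`,
#'   `delta_t`, `root_censored`, one row per unordered leaf pair.
#' @export
#' @examples
#' tr <- make_topology(n_leaves = 3, age_years = 200,
#'                     branch_times = c(60, 150), seed = 1)
#' divergence_times(tr)
divergence_times <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  if (ntip < 2) abort("need at least two leaves")
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(phy) # years from root to node
  mrca <- ape::mrca(phy) # ntip x ntip matrix of MRCA node ids
  pairs <- utils::combn(ntip, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  anc <- mrca[cbind(i, j)]
  tibble::tibble(
    leaf_i = phy$tip.label[i],
    leaf_j = phy$tip.label[j],
    tau_i = depth[i] - depth[anc],
    tau_j = depth[j] - depth[anc],
    delta_t = (depth[i] - depth[anc]) + (depth[j] - depth[anc]),
    root_censored = anc == root
  )
}

#' Read ring-width series
#'
#' Reads a CSV of annual ring widths measured along the four cardinal
#' directions of a stem disk. Expected columns: `direction` (N/E/S/W),
#' `year` (calendar year), `width_mm` (ring width in mm, 1/100 mm
#' precision). Years must be strictly increasing and contiguous within a
#' direction; widths must be non-negative.
#'
#' @param path CSV file path.
#' @return A tibble with columns `direction`, `year`, `width_mm`.
#' @export
read_ring_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("ring series not found: %s", path))
  rings <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(rings, c("direction", "year", "width_mm"), "ring series")
  validate_ring_series(rings)
}

validate_ring_series <- function(rings) {
  if (any(rings$width_mm < 0)) abort("ring widths must be non-negative")
  by_dir <- split(rings$year, rings$direction)
  for (d in names(by_dir)) {
    ys <- by_dir[[d]]
    if (any(diff(ys) != 1)) {
      abort(sprintf("years not strictly increasing and contiguous (direction %s)", d))
    }
  }
  tibble::as_tibble(rings)
}

#' Basal area increment from ring widths
#'
#' Converts annual ring widths to basal area increments,
#' \eqn{bai_t = \pi (r_t^2 - r_{t-1}^2)}, where \eqn{r_t} is the stem
#' radius in year \eqn{t} accumulated from the pith outward. By default
#' each direction's series is converted separately and the series are then
#' averaged per year ("per-series-then-average"); `average_first = TRUE`
#' instead averages the four radii into one series before the conversion.
#'
#' @param rings Ring series tibble as from [read_ring_series()] (widths in
#'   mm).
#' @param average_first Average radii across directions before computing
#'   increments (default `FALSE`).
#' @return A tibble with columns `year`, `direction` (`"mean"` rows give
#'   the per-year average over directions), `radius_cm`, `bai_cm2`. The
#'   attribute `growth_rate_cm2_yr` holds the stem growth rate: the mean
#'   annual basal area increment over all four series.
#' @export
#' @examples
#' rings <- tibble::tibble(direction = "N", year = 2001:2003,
#'                         width_mm = c(20, 15, 10))
#' basal_area_increment(rings)
basal_area_increment <- function(rings, average_first = FALSE) {
  rings <- validate_ring_series(rings)
  per_dir <- rings |>
    dplyr::group_by(.data$direction) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(
      radius_cm = cumsum(.data$width_mm) / 10, # mm -> cm, pith outward
      bai_cm2 = pi * (.data$radius_cm^2 -
                        dplyr::lag(.data$radius_cm, default = 0)^2)
    ) |>
    dplyr::ungroup()

  if (average_first) {
    mean_rows <- per_dir |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(radius_cm = mean(.data$radius_cm), .groups = "drop") |>
      dplyr::mutate(
        bai_cm2 = pi * (.data$radius_cm^2 -
                          dplyr::lag(.data$radius_cm, default = 0)^2),
        direction = "mean")
  } else {
    mean_rows <- per_dir |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(radius_cm = mean(.data$radius_cm),
                       bai_cm2 = mean(.data$bai_cm2), .groups = "drop") |>
      dplyr::mutate(direction = "mean")
  }
  out <- dplyr::bind_rows(
    per_dir[, c("year", "direction", "radius_cm", "bai_cm2")],
    mean_rows[, c("year", "direction", "radius_cm", "bai_cm2")]) |>
    dplyr::arrange(.data$direction != "mean", .data$direction, .data$year)
  attr(out, "growth_rate_cm2_yr") <- mean(per_dir$bai_cm2)
  out
}

#' Stem growth rate
#'
#' The stem growth rate is the average annual basal area increment,
#' considering all ring series of the stem disk.
#'
#' @param rings Ring series tibble (widths in mm).
#' @return Growth rate in cm^2 per year.
#' @export
stem_growth_rate <- function(rings) {
  attr(basal_area_increment(rings), "growth_rate_cm2_yr")
}

#' Correlation between cumulative growth and cumulative cell counts
#'
#' Pearson correlation between a cumulative basal-area series and the
#' cumulative number of xylem cells, on aligned yearly series. Used to
#' check that stem growth acceleration reflects increased cell
#' proliferation rather than cell expansion alone.
#'
#' @param growth Tibble with columns `year` and `cum_bai_cm2` (or any
#'   cumulative growth measure).
#' @param cells Tibble with columns `year` and `cum_cells`.
#' @return A one-row tibble with columns `r`, `n_years`.
#' @export
growth_cellcount_correlation <- function(growth, cells) {
  assert_columns(growth, c("year", "cum_bai_cm2"), "growth series")
  assert_columns(cells, c("year", "cum_cells"), "cell-count series")
  joined <- dplyr::inner_join(growth, cells, by = "year")
  if (nrow(joined) != nrow(growth) || nrow(joined) != nrow(cells)) {
    abort("growth and cell-count series must cover the same years")
  }
  tibble::tibble(r = cor(joined$cum_bai_cm2, joined$cum_cells),
                 n_years = nrow(joined))
}
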