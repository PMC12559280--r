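# --- deterministic TSV writers ------------------------------------------

#' Write a state matrix to TSV
#'
#' Writes per-unit state calls of several samples side by side: unit
#' columns first, then one state column per sample. Deterministic column
#' order and fixed float precision, so identical inputs give
#' byte-identical files.
#'
#' @param calls_by_sample Named list of call tibbles (from
#'   [call_states()]) on a shared unit universe.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_matrix <- function(calls_by_sample, path) {
  stopifnot(length(calls_by_sample) >= 1, !is.null(names(calls_by_sample)))
  key <- unit_key_cols(calls_by_sample[[1]])
  out <- tibble::as_tibble(calls_by_sample[[1]])[key]
  for (nm in names(calls_by_sample)) {
    calls <- tibble::as_tibble(calls_by_sample[[nm]])
    k <- do.call(paste, c(calls[key], sep = "\r"))
    k0 <- do.call(paste, c(out[key], sep = "\r"))
    if (!setequal(k, k0)) abort("samples must share the unit universe")
    out[[nm]] <- calls$state[match(k0, k)]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a state matrix written by [write_state_matrix()]
#'
#' @param path TSV path.
#' @return A tibble with the unit columns and one state column per sample.
#' @export
read_state_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a divergence table to TSV
#'
#' @param pairs Tibble of pairwise divergences (columns kept in input
#'   order; numeric columns written at fixed precision).
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 10).
#' @return `path`, invisibly.
#' @export
write_divergence_table <- function(pairs, path, digits = 10) {
  out <- dplyr::mutate(tibble::as_tibble(pairs), dplyr::across(
    dplyr::where(is.numeric), ~fmt_num(.x, digits)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a divergence table written by [write_divergence_table()]
#'
#' @param path TSV path.
#' @return A tibble with numeric columns restored.
#' @export
read_divergence_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a fit report to TSV
#'
#' Writes a neutral-model fit as a two-section key/value and parameter
#' table (term, estimate, std.error), at fixed precision.
#'
#' @param fit A `neutral_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "neutral_fit"))
  tbl <- tidy.neutral_fit(fit)
  meta <- tibble::tibble(
    term = c("p0", "pi", "rss", "n_pairs", "converged", "se_unreliable"),
    estimate = c(fit$p0, fit$params$pi, fit$rss, fit$n_pairs,
                 as.numeric(fit$converged), as.numeric(fit$se_unreliable)),
    std.error = NA_real_)
  out <- dplyr::mutate(dplyr::bind_rows(tbl, meta), dplyr::across(
    dplyr::where(is.numeric), ~fmt_num(.x, 10)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
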