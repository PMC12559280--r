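#' Read a per-cytosine methylome table
#'
#' Reads a Bismark-style cytosine report (columns: chromosome, 1-based
#' position, strand, context, methylated read count, total read count) or a
#' bedGraph-like methylation table (chromosome, position, strand, context,
#' methylation level, total count; detected from the header). Records are
#' validated and returned sorted by (chrom, pos).
#'
#' Malformed lines are rejected, never silently dropped: the returned
#' tibble carries an attribute `rejected` with the offending line numbers
#' and reasons, and `n_input = nrow(accepted) + nrow(rejected)` always
#' holds.
#'
#' @param path Path to a TSV file. A header is optional for the cytosine
#'   report dialect; the bedGraph-like dialect is recognised by a header
#'   containing a `level` column.
#' @param context Optional filter: keep only records in these contexts
#'   (subset of `"CG"`, `"CHG"`, `"CHH"`).
#' @return A tibble of class `methylome` with columns `chrom`, `pos`,
#'   `strand`, `context`, `count_methylated`, `count_total`, sorted by
#'   (chrom, pos). Attributes: `rejected` (tibble of line, reason),
#'   `n_input`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t10\t+\tCG\t5\t20", "chr1\t45\t-\tCHH\t0\t18"), tf)
#' read_methylome(tf)
read_methylome <- function(path, context = NULL) {
  if (!file.exists(path)) abort(sprintf("methylome file not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom|pos|context", first, ignore.case = TRUE)
  level_dialect <- has_header && grepl("level", first, ignore.case = TRUE)

  raw <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else
      c("chrom", "pos", "strand", "context", "count_methylated", "count_total"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  line0 <- if (has_header) 1L else 0L # offset to physical line numbers

  if (level_dialect) {
    need <- c("chrom", "pos", "strand", "context", "level", "count_total")
    assert_columns(raw, need, "bedGraph-like methylome")
  } else {
    need <- c("chrom", "pos", "strand", "context",
              "count_methylated", "count_total")
    assert_columns(raw, need, "cytosine report")
  }

  pos <- suppressWarnings(as.integer(raw$pos))
  total <- suppressWarnings(as.numeric(raw$count_total))
  if (level_dialect) {
    level <- suppressWarnings(as.numeric(raw$level))
    meth <- round(level * total)
  } else {
    meth <- suppressWarnings(as.numeric(raw$count_methylated))
  }

  reason <- rep(NA_character_, nrow(raw))
  bad <- is.na(pos) | pos < 1L
  reason[bad & is.na(reason)] <- "position not a positive integer"
  b <- !(raw$strand %in% c("+", "-"))
  reason[b & is.na(reason)] <- "strand not + or -"
  b <- !(raw$context %in% CONTEXTS)
  reason[b & is.na(reason)] <- "context not CG/CHG/CHH"
  b <- is.na(meth) | is.na(total) | meth < 0 | total < 0
  reason[b & is.na(reason)] <- "counts not non-negative numbers"
  b <- !is.na(meth) & !is.na(total) & meth > total
  reason[b & is.na(reason)] <- "count_methylated exceeds count_total"

  if (any(!is.na(reason) & reason == "count_methylated exceeds count_total")) {
    lines <- which(reason == "count_methylated exceeds count_total") + line0
    abort(sprintf(
      "methylome validation: count_methylated > count_total at line(s) %s of %s",
      paste(head(lines, 5), collapse = ", "), path))
  }

  keep <- is.na(reason)
  rejected <- tibble::tibble(line = which(!keep) + line0,
                             reason = reason[!keep])
  out <- tibble::tibble(
    chrom = raw$chrom[keep],
    pos = pos[keep],
    strand = raw$strand[keep],
    context = raw$context[keep],
    count_methylated = as.integer(round(meth[keep])),
    count_total = as.integer(round(total[keep]))
  )
  if (!is.null(context)) {
    stopifnot(all(context %in% CONTEXTS))
    out <- dplyr::filter(out, .data$context %in% !!context)
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  new_methylome(out, rejected = rejected, n_input = nrow(raw))
}

new_methylome <- function(df, rejected = NULL, n_input = nrow(df)) {
  df <- tibble::as_tibble(df)
  attr(df, "rejected") <- rejected %||%
    tibble::tibble(line = integer(), reason = character())
  attr(df, "n_input") <- n_input
  class(df) <- c("methylome", class(df))
  df
}

#' Write a methylome table to disk
#'
#' Writes the cytosine-report dialect consumed by [read_methylome()], with
#' a header, deterministic column order and byte-reproducible output.
#'
#' @param methylome A methylome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(methylome, path) {
  assert_columns(methylome, c("chrom", "pos", "strand", "context",
                              "count_methylated", "count_total"), "methylome")
  readr::write_tsv(
    methylome[, c("chrom", "pos", "strand", "context",
                  "count_methylated", "count_total")],
    path, progress = FALSE)
  invisible(path)
}

#' Merge symmetric CG positions across strands
#'
#' CG dinucleotides carry a cytosine on each strand; by default the package
#' keeps both records separate. This helper pools the counts of the two
#' strands onto the plus-strand coordinate (positions p and p+1 on opposite
#' strands are treated as one symmetric CG).
#'
#' @param methylome A methylome tibble.
#' @return A methylome tibble with merged CG records (strand set to `"+"`)
#'   and other contexts untouched.
#' @export
merge_cg_strands <- function(methylome) {
  cg <- dplyr::filter(methylome, .data$context == "CG")
  rest <- dplyr::filter(methylome, .data$context != "CG")
  # anchor a minus-strand CG to the plus-strand cytosine one base upstream
  cg <- dplyr::mutate(cg,
    anchor = ifelse(.data$strand == "-", .data$pos - 1L, .data$pos))
  cg <- dplyr::summarise(
    dplyr::group_by(cg, .data$chrom, .data$anchor),
    count_methylated = sum(.data$count_methylated),
    count_total = sum(.data$count_total),
    .groups = "drop")
  cg <- dplyr::transmute(cg,
    chrom = .data$chrom, pos = .data$anchor, strand = "+", context = "CG",
    count_methylated = .data$count_methylated,
    count_total = .data$count_total)
  out <- dplyr::arrange(dplyr::bind_rows(cg, rest), .data$chrom, .data$pos)
  new_methylome(out)
}
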