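# --- gene body methylation (gbM) classification -------------------------

#' Read gene models from a GFF3 annotation
#'
#' Extracts per-gene exon intervals (1-based closed) from a GFF3 file and
#' derives introns as the gaps between consecutive exons. Exons are
#' unioned per gene across transcripts.
#'
#' @param path GFF3 file path.
#' @return A gene-model tibble: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, plus list-columns `exons` and `introns` of interval tibbles
#'   (`start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) abort("no exon features in GFF3")
  parent <- vapply(as.list(ex$Parent), function(p) as.character(p[1]),
                   character(1))
  # map transcript parents up to gene ids where gene features exist
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  if (length(tx) > 0) {
    tx_parent <- vapply(as.list(tx$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    names(tx_parent) <- tx$ID
    hit <- parent %in% names(tx_parent)
    parent[hit] <- tx_parent[parent[hit]]
  }
  df <- tibble::tibble(
    gene_id = sub("^gene:", "", parent),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex))
  build_gene_models(df)
}

#' Build gene models from an exon table
#'
#' @param exons A tibble with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (one row per exon, 1-based closed).
#' @return A gene-model tibble as described in [read_gene_models()].
#' @export
build_gene_models <- function(exons) {
  assert_columns(exons, c("gene_id", "chrom", "strand", "start", "end"),
                 "exon table")
  exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::group_modify(function(df, key) {
      iv <- merge_intervals(df$start, df$end)
      introns <- if (nrow(iv) > 1) {
        tibble::tibble(start = iv$end[-nrow(iv)] + 1L, end = iv$start[-1] - 1L)
      } else tibble::tibble(start = integer(), end = integer())
      tibble::tibble(start = min(iv$start), end = max(iv$end),
                     exons = list(iv), introns = list(introns))
    }) |>
    dplyr::ungroup()
}

# sort + merge overlapping/adjacent intervals
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  keep_s <- start[1]; keep_e <- end[1]
  out_s <- integer(); out_e <- integer()
  for (k in seq_along(start)[-1]) {
    if (start[k] <= keep_e + 1L) {
      keep_e <- max(keep_e, end[k])
    } else {
      out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
      keep_s <- start[k]; keep_e <- end[k]
    }
  }
  tibble::tibble(start = c(out_s, keep_s), end = c(out_e, keep_e))
}

# indicator: which methylome rows fall in any interval of the gene part
sites_in_intervals <- function(methylome, chrom, iv) {
  if (nrow(iv) == 0) return(integer())
  on_chrom <- which(methylome$chrom == chrom)
  pos <- methylome$pos[on_chrom]
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) {
    hit <- hit | (pos >= iv$start[k] & pos <= iv$end[k])
  }
  on_chrom[hit]
}

# per-site methylated indicator: majority of reads methylated
site_methylated <- function(methylome) {
  methylome$count_methylated > methylome$count_total / 2
}

#' Per-context exonic background methylation proportions
#'
#' The background against which individual genes are tested: the fraction
#' of methylated cytosine positions among all exonic cytosines
#' genome-wide, per context (a position counts as methylated when more
#' than half of its reads are methylated).
#'
#' @param methylome A methylome tibble.
#' @param genes A gene-model tibble ([read_gene_models()] /
#'   [build_gene_models()]).
#' @return A tibble with columns `context`, `methylated`, `total`,
#'   `proportion`.
#' @export
exonic_background <- function(methylome, genes) {
  methylome <- tibble::as_tibble(methylome)
  idx <- unlist(purrr::map2(genes$chrom, genes$exons,
                            ~sites_in_intervals(methylome, .x, .y)))
  idx <- unique(idx)
  if (length(idx) == 0) abort("no exonic cytosines found")
  ex <- methylome[idx, ]
  ex$methylated <- site_methylated(ex)
  ex |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(methylated = sum(.data$methylated),
                     total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(proportion = .data$methylated / .data$total)
}

# binomial tail test on position counts
binom_p_greater <- function(x, n, p) {
  ifelse(n == 0, NA_real_, pbinom(x - 1, n, p, lower.tail = FALSE))
}

#' Classify genes as gene-body methylated in one sample
#'
#' A gene is called gbM when the proportion of methylated exonic CG
#' positions is statistically higher than the exonic CG background
#' (one-sided binomial test, BH-adjusted across genes at `alpha_up`),
#' while the exonic CHG and CHH proportions are not significantly
#' *elevated* above their backgrounds (one-sided binomial tests,
#' unadjusted, at `alpha_diff`; adjusting a test whose desired outcome is
#' non-significance would be anti-conservative). The non-CG tests are
#' deliberately one-sided: near-zero non-CG methylation is the gbM
#' signature, so a gene significantly *below* a nonzero background must
#' not be vetoed. Contexts without exonic cytosines in a gene skip that
#' test (recorded as `NA`), which cannot veto the call.
#'
#' @param methylome A methylome tibble for one sample.
#' @param genes Gene-model tibble.
#' @param background Background proportions from [exonic_background()]
#'   (computed on the same sample, or an externally supplied reference).
#' @param alpha_up FDR level of the CG enrichment test (default 0.05).
#' @param alpha_diff Per-test level of the non-CG difference tests
#'   (default 0.05).
#' @return A tibble with one row per gene: counts per context, p-values
#'   (`p_cg_up` plus BH-adjusted `q_cg_up`, `p_chg_diff`, `p_chh_diff`)
#'   and the `gbm` call.
#' @export
classify_gbm <- function(methylome, genes, background,
                         alpha_up = 0.05, alpha_diff = 0.05) {
  methylome <- tibble::as_tibble(methylome)
  bg <- setNames(background$proportion, background$context)
  rows <- purrr::pmap_dfr(
    list(genes$gene_id, genes$chrom, genes$exons),
    function(gid, chrom, exons) {
      idx <- sites_in_intervals(methylome, chrom, exons)
      ex <- methylome[idx, ]
      ex$methylated <- site_methylated(ex)
      cnt <- function(ctx) {
        sub <- ex[ex$context == ctx, ]
        c(x = sum(sub$methylated), n = nrow(sub))
      }
      cg <- cnt("CG"); chg <- cnt("CHG"); chh <- cnt("CHH")
      tibble::tibble(
        gene_id = gid,
        cg_methylated = cg[["x"]], cg_total = cg[["n"]],
        chg_methylated = chg[["x"]], chg_total = chg[["n"]],
        chh_methylated = chh[["x"]], chh_total = chh[["n"]],
        p_cg_up = binom_p_greater(cg[["x"]], cg[["n"]], bg[["CG"]]),
        p_chg_diff = binom_p_greater(chg[["x"]], chg[["n"]], bg[["CHG"]]),
        p_chh_diff = binom_p_greater(chh[["x"]], chh[["n"]], bg[["CHH"]]))
    })
  rows$q_cg_up <- p.adjust(rows$p_cg_up, method = "BH")
  rows$gbm <- !is.na(rows$q_cg_up) & rows$q_cg_up < alpha_up &
    (is.na(rows$p_chg_diff) | rows$p_chg_diff > alpha_diff) &
    (is.na(rows$p_chh_diff) | rows$p_chh_diff > alpha_diff)
  rows
}

#' Union per-sample gbM calls and apply the intronic non-CG filter
#'
#' Takes the union of per-sample gbM calls as a liberal candidate set,
#' computes each candidate's intronic non-CG methylation level (pooled
#' methylated/total read fraction over intronic CHG and CHH cytosines,
#' averaged across samples), and retains only candidates strictly below
#' the median of that distribution (computed over the candidates).
#' Candidates without intronic non-CG cytosines cannot fail a filter they
#' have no data for: they are retained with `missing_introns = TRUE`.
#'
#' @param calls_by_sample A list of per-sample call tibbles from
#'   [classify_gbm()].
#' @param methylomes A list of the matching methylome tibbles.
#' @param genes Gene-model tibble.
#' @param min_informative Candidates with fewer intronic non-CG cytosines
#'   than this are flagged `low_information` (default 5).
#' @return A tibble with one row per candidate gene: `gene_id`,
#'   `n_samples_called`, `intronic_noncg_level`, `missing_introns`,
#'   `low_information`, `retained`.
#' @export
union_and_intron_filter <- function(calls_by_sample, methylomes, genes,
                                    min_informative = 5L) {
  stopifnot(length(calls_by_sample) >= 1,
            length(methylomes) == length(calls_by_sample))
  union_ids <- sort(unique(unlist(
    purrr::map(calls_by_sample, ~.x$gene_id[.x$gbm]))))
  if (length(union_ids) == 0) {
    return(tibble::tibble(gene_id = character(), n_samples_called = integer(),
                          intronic_noncg_level = numeric(),
                          missing_introns = logical(),
                          low_information = logical(), retained = logical()))
  }
  n_called <- purrr::map_dfr(calls_by_sample, ~.x[.x$gbm, "gene_id"]) |>
    dplyr::count(.data$gene_id, name = "n_samples_called")

  gsub_ <- genes[match(union_ids, genes$gene_id), ]
  lvl <- purrr::pmap_dbl(
    list(gsub_$chrom, gsub_$introns),
    function(chrom, introns) {
      num <- 0; den <- 0; sites <- 0L
      for (m in methylomes) {
        m <- tibble::as_tibble(m)
        idx <- sites_in_intervals(m, chrom, introns)
        sub <- m[idx, ]
        sub <- sub[sub$context %in% c("CHG", "CHH"), ]
        num <- num + sum(sub$count_methylated)
        den <- den + sum(sub$count_total)
        sites <- sites + nrow(sub)
      }
      if (den == 0) NA_real_ else num / den
    })
  n_sites <- purrr::pmap_int(
    list(gsub_$chrom, gsub_$introns),
    function(chrom, introns) {
      s <- 0L
      for (m in methylomes) {
        m <- tibble::as_tibble(m)
        idx <- sites_in_intervals(m, chrom, introns)
        s <- s + sum(m$context[idx] %in% c("CHG", "CHH"))
      }
      s
    })
  med <- median(lvl, na.rm = TRUE)
  out <- tibble::tibble(
    gene_id = union_ids,
    intronic_noncg_level = lvl,
    missing_introns = is.na(lvl),
    low_information = !is.na(lvl) & n_sites < min_informative,
    retained = is.na(lvl) | lvl < med)
  dplyr::left_join(out, n_called, by = "gene_id") |>
    dplyr::relocate("n_samples_called", .after = "gene_id")
}
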