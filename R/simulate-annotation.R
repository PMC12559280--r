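#' Simulate a gene annotation with methylation classes
#'
#' Builds a set of gene models (exons and introns on one chromosome)
#' together with a class-consistent methylome, for exercising gene-body
#' methylation (gbM) classification. Three classes are generated:
#' * `gbM`: high exonic CG methylation, near-zero CHG/CHH everywhere;
#' * `teM`: elevated methylation in all three contexts (transposon-like);
#' * `unmethylated`: near-zero methylation everywhere.
#'
#' @param n_genes Number of genes.
#' @param fractions Named numeric vector of class fractions
#'   (`gbM`, `teM`, `unmethylated`), summing to 1.
#' @param seed Integer seed.
#' @param depth Mean read depth of the emitted counts.
#' @param p_exonic_cg Per-position methylation probability of exonic CGs
#'   in gbM genes.
#' @param n_exons Exons per gene.
#' @return A list with `genes` (a gene-model tibble as used by the gbm
#'   functions: `gene_id`, `chrom`, `strand`, `start`, `end`, and
#'   list-columns `exons`, `introns` of interval tibbles), `methylome`
#'   (a `methylome` tibble) and `truth` (tibble `gene_id`, `class`).
#' @export
make_annotation <- function(n_genes = 50,
                            fractions = c(gbM = 0.3, teM = 0.2,
                                          unmethylated = 0.5),
                            seed = 1L, depth = 20, p_exonic_cg = 0.9,
                            n_exons = 3) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9,
            setequal(names(fractions), c("gbM", "teM", "unmethylated")))
  withr::local_seed(seed)
  n_by_class <- round(fractions * n_genes)
  # rounding drift goes to the largest class
  n_by_class[which.max(n_by_class)] <-
    n_by_class[which.max(n_by_class)] + n_genes - sum(n_by_class)
  classes <- sample(rep(names(n_by_class), n_by_class))

  exon_len <- 300L; intron_len <- 150L; gap <- 500L
  gene_span <- n_exons * exon_len + (n_exons - 1L) * intron_len

  genes <- list(); meth <- list()
  cursor <- 1000L
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", g)
    ex_start <- cursor + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
    exons <- tibble::tibble(start = ex_start, end = ex_start + exon_len - 1L)
    introns <- if (n_exons > 1) {
      tibble::tibble(start = exons$end[-n_exons] + 1L,
                     end = exons$start[-1] - 1L)
    } else tibble::tibble(start = integer(), end = integer())
    genes[[g]] <- tibble::tibble(
      gene_id = gid, chrom = "chr1", strand = "+",
      start = cursor, end = cursor + gene_span - 1L,
      exons = list(exons), introns = list(introns))

    cls <- classes[g]
    # per-context per-position methylation probabilities by compartment
    probs <- switch(cls,
      gbM = list(exon = c(CG = p_exonic_cg, CHG = 0.01, CHH = 0.01),
                 intron = c(CG = 0.05, CHG = 0.01, CHH = 0.01)),
      teM = list(exon = c(CG = 0.8, CHG = 0.7, CHH = 0.6),
                 intron = c(CG = 0.8, CHG = 0.7, CHH = 0.6)),
      unmethylated = list(exon = c(CG = 0.01, CHG = 0.01, CHH = 0.01),
                          intron = c(CG = 0.01, CHG = 0.01, CHH = 0.01)))
    site_rows <- function(iv, compartment, density = 0.08) {
      purrr::map_dfr(seq_len(nrow(iv)), function(k) {
        span <- iv$start[k]:iv$end[k]
        n_c <- max(3L, round(length(span) * density))
        pos <- sort(sample(span, min(n_c * 3L, length(span))))
        ctx <- sample(CONTEXTS, length(pos), replace = TRUE,
                      prob = c(0.34, 0.33, 0.33))
        p <- probs[[compartment]][ctx]
        methylated <- rbinom(length(pos), 1L, p)
        total <- rnbinom(length(pos), mu = depth, size = 10) + 1L
        tibble::tibble(
          chrom = "chr1", pos = pos, strand = "+", context = ctx,
          count_methylated = rbinom(length(pos), total,
                                    ifelse(methylated == 1L, 0.97, 0.02)),
          count_total = total)
      })
    }
    meth[[g]] <- dplyr::bind_rows(site_rows(exons, "exon"),
                                  if (nrow(introns) > 0)
                                    site_rows(introns, "intron"))
    cursor <- cursor + gene_span + gap
  }
  list(
    genes = dplyr::bind_rows(genes),
    methylome = new_methylome(dplyr::arrange(dplyr::bind_rows(meth),
                                             .data$chrom, .data$pos)),
    truth = tibble::tibble(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                           class = classes)
  )
}
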