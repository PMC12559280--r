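make_gene <- function(gene_id = "g1", exon_starts = 1000L,
                      exon_ends = 1500L) {
  build_gene_models(tibble::tibble(
    gene_id = gene_id, chrom = "chr1", strand = "+",
    start = exon_starts, end = exon_ends))
}

meth_rows <- function(pos, context, frac, depth = 20L) {
  tibble::tibble(chrom = "chr1", pos = pos, strand = "+", context = context,
                 count_methylated = as.integer(round(frac * depth)),
                 count_total = depth)
}

test_that("exonic background tallies methylated positions per context", {
  genes <- make_gene()
  m <- dplyr::bind_rows(
    meth_rows(seq(1010, 1100, by = 10), "CG", 1),   # 10 methylated CGs
    meth_rows(seq(1210, 1300, by = 10), "CHG", 0),  # 10 unmethylated CHGs
    meth_rows(seq(2000, 2050, by = 10), "CG", 1))   # outside the gene
  bg <- exonic_background(m, genes)
  expect_equal(bg$proportion[bg$context == "CG"], 1)
  expect_identical(bg$total[bg$context == "CG"], 10L)
  expect_equal(bg$proportion[bg$context == "CHG"], 0)

  empty <- meth_rows(5000L, "CG", 1)
  expect_error(exonic_background(empty, genes), "no exonic")

  # brute-force tally on a random fixture
  m2 <- random_methylome(150, seed = 3)
  g2 <- make_gene(exon_starts = 1L, exon_ends = 2500L)
  bg2 <- exonic_background(m2, g2)
  inside <- m2[m2$chrom == "chr1" & m2$pos <= 2500, ]
  for (ctx in unique(inside$context)) {
    sub <- inside[inside$context == ctx, ]
    expect_equal(bg2$proportion[bg2$context == ctx],
                 mean(sub$count_methylated > sub$count_total / 2))
  }
})

test_that("the binomial classification separates gbM from background and teM", {
  genes <- make_gene()
  bg <- tibble::tibble(context = c("CG", "CHG", "CHH"),
                       methylated = NA, total = NA,
                       proportion = c(0.3, 0.02, 0.02))
  gbm_gene <- dplyr::bind_rows(
    meth_rows(seq(1010, 1300, by = 10), "CG", 1),  # 30/30 methylated
    meth_rows(seq(1310, 1400, by = 10), "CHG", 0),
    meth_rows(seq(1410, 1490, by = 10), "CHH", 0))
  calls <- classify_gbm(gbm_gene, genes, bg)
  # oracle: exact binomial tail for 30/30 at p = 0.3
  expect_equal(calls$p_cg_up, pbinom(29, 30, 0.3, lower.tail = FALSE))
  expect_true(calls$gbm)

  # a gene matching the background exactly is not enriched
  match_gene <- dplyr::bind_rows(
    meth_rows(seq(1010, 1300, by = 10), "CG", 1)[1:9, ],
    meth_rows(seq(1100, 1300, by = 10), "CG", 0),
    meth_rows(seq(1310, 1400, by = 10), "CHG", 0))
  calls2 <- classify_gbm(match_gene, genes, bg)
  expect_false(calls2$gbm)

  # transposon-like methylation fails the CHG test
  tem_gene <- dplyr::bind_rows(
    meth_rows(seq(1010, 1300, by = 10), "CG", 1),
    meth_rows(seq(1310, 1400, by = 10), "CHG", 1),
    meth_rows(seq(1410, 1490, by = 10), "CHH", 1))
  calls3 <- classify_gbm(tem_gene, genes, bg)
  expect_false(calls3$gbm)
  expect_lt(calls3$p_chg_diff, 0.05)
})

test_that("a stricter enrichment level never enlarges the gbM set", {
  ann <- make_annotation(n_genes = 40, seed = 31)
  bg <- exonic_background(ann$methylome, ann$genes)
  loose <- classify_gbm(ann$methylome, ann$genes, bg, alpha_up = 0.1)
  strict <- classify_gbm(ann$methylome, ann$genes, bg, alpha_up = 0.001)
  expect_true(all(strict$gene_id[strict$gbm] %in% loose$gene_id[loose$gbm]))
})

test_that("union and intron filtering follow the liberal-then-filter rule", {
  ann <- make_annotation(n_genes = 60, seed = 17)
  bg <- exonic_background(ann$methylome, ann$genes)
  calls <- classify_gbm(ann$methylome, ann$genes, bg)
  final <- union_and_intron_filter(list(s1 = calls), list(s1 = ann$methylome),
                                   ann$genes)
  # union of one sample is that sample's call set
  expect_setequal(final$gene_id, calls$gene_id[calls$gbm])
  # strict inequality: candidates at the median are removed
  med <- median(final$intronic_noncg_level, na.rm = TRUE)
  expect_true(all(final$intronic_noncg_level[final$retained &
                                               !final$missing_introns] < med))

  # label recovery on the mixed fixture: the liberal candidate set should
  # recover the true gbM class almost perfectly
  truth_gbm <- ann$truth$gene_id[ann$truth$class == "gbM"]
  expect_gte(mean(truth_gbm %in% calls$gene_id[calls$gbm]), 0.95)
  expect_gte(mean(calls$gene_id[calls$gbm] %in% truth_gbm), 0.95)

  # a candidate without introns is retained and flagged
  single_exon <- make_gene("solo", 10000L, 10400L)
  m_solo <- dplyr::bind_rows(
    meth_rows(seq(10010, 10300, by = 10), "CG", 1),
    meth_rows(seq(10310, 10390, by = 10), "CHH", 0))
  bg2 <- tibble::tibble(context = c("CG", "CHG", "CHH"),
                        methylated = NA, total = NA,
                        proportion = c(0.3, 0.02, 0.02))
  calls_solo <- classify_gbm(m_solo, single_exon, bg2)
  fin_solo <- union_and_intron_filter(list(a = calls_solo),
                                      list(a = m_solo), single_exon)
  expect_true(fin_solo$missing_introns)
  expect_true(fin_solo$retained)
})
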