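test_that("FPKM follows its defining formula", {
  expect_equal(fpkm(100, 2000, 1e7), 5)
  expect_equal(fpkm(0, 2000, 1e7), 0)
  # scale invariance: doubling count and library size cancels
  expect_equal(fpkm(200, 2000, 2e7), fpkm(100, 2000, 1e7))
  expect_error(fpkm(10, 0, 1e6), "positive")
  expect_error(fpkm(10, 1000, 0), "positive")
})

test_that("fpkm_matrix uses per-sample column totals", {
  counts <- matrix(c(100, 900, 50, 950), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fm <- fpkm_matrix(counts, c(g1 = 2000, g2 = 1000))
  expect_equal(fm["g1", "s1"], 100 / (2 * (1000 / 1e6)))
  expect_equal(fm["g2", "s2"], 950 / (1 * (1000 / 1e6)))
})

test_that("assign_regions partitions a one-gene chromosome as defined", {
  ann <- structure(list(
    features = data.frame(chrom = "chr1", start = 5000, end = 8000,
                          strand = "+", type = "gene", feature_id = "g1",
                          stringsAsFactors = FALSE),
    exons = data.frame(feature_id = "g1", exon_id = "g1.e1", chrom = "chr1",
                       start = 5000, end = 6000, strand = "+",
                       stringsAsFactors = FALSE)), class = "annotation")
  p <- assign_regions(ann, c(chr1 = 20000))
  expect_equal(p$promoters[c("start", "end")],
               data.frame(start = 3000, end = 5000))
  expect_equal(p$introns[c("start", "end")],
               data.frame(start = 6000, end = 8000))
  ig <- p$classes[p$classes$class == "intergenic", ]
  expect_equal(ig$start, c(0, 8000))
  expect_equal(ig$end, c(3000, 20000))
  # the four classes tile the chromosome exactly
  cl <- p$classes[order(p$classes$start), ]
  expect_equal(cl$start[1], 0)
  expect_equal(cl$end[nrow(cl)], 20000)
  expect_true(all(cl$start[-1] == cl$end[-nrow(cl)]))
  expect_equal(sum(cl$end - cl$start), 20000)
})

test_that("edge genes get empty promoters and single-exon genes no introns", {
  ann <- structure(list(
    features = data.frame(chrom = "chr1", start = 0, end = 3000,
                          strand = "+", type = "gene", feature_id = "g1",
                          stringsAsFactors = FALSE),
    exons = data.frame(feature_id = "g1", exon_id = "g1.e1", chrom = "chr1",
                       start = 0, end = 3000, strand = "+",
                       stringsAsFactors = FALSE)), class = "annotation")
  expect_warning(p <- assign_regions(ann, c(chr1 = 10000)), "empty promoter")
  expect_equal(nrow(p$promoters), 0)
  expect_equal(nrow(p$introns), 0)
  cl <- p$classes
  expect_equal(sum(cl$end - cl$start), 10000)
})

test_that("promoters yield to adjacent gene bodies", {
  ann <- structure(list(
    features = data.frame(chrom = "chr1", start = c(1000, 5000),
                          end = c(4500, 9000), strand = "+", type = "gene",
                          feature_id = c("g1", "g2"),
                          stringsAsFactors = FALSE),
    exons = data.frame(feature_id = c("g1", "g2"),
                       exon_id = c("g1.e1", "g2.e1"), chrom = "chr1",
                       start = c(1000, 5000), end = c(4500, 9000),
                       strand = "+", stringsAsFactors = FALSE)),
    class = "annotation")
  p <- assign_regions(ann, c(chr1 = 20000))
  g2p <- p$promoters[p$promoters$gene_id == "g2", ]
  expect_equal(g2p$start, 4500)  # truncated at g1's body
  expect_equal(g2p$end, 5000)
  expect_equal(sum(p$classes$end - p$classes$start), 20000)
})

test_that("region methylation pools reads within a gene's region class", {
  ann <- structure(list(
    features = data.frame(chrom = "chr1", start = 5000, end = 8000,
                          strand = "+", type = "gene", feature_id = "g1",
                          stringsAsFactors = FALSE),
    exons = data.frame(feature_id = "g1", exon_id = "g1.e1", chrom = "chr1",
                       start = 5000, end = 6000, strand = "+",
                       stringsAsFactors = FALSE)), class = "annotation")
  p <- assign_regions(ann, c(chr1 = 20000))
  calls <- make_calls("chr1", c(3500, 4500), "+", c(8, 2), c(2, 8),
                      c("CG", "CG"))
  rm_ <- region_methylation(calls, p, contexts = "CG")
  prom <- rm_[rm_$region == "promoter", ]
  expect_equal(prom$level, 0.5)
  expect_equal(prom$n_sites, 2)
  # no covered site in the intron -> NA level
  expect_true(is.na(rm_$level[rm_$region == "intron"]))
  # pooling is invariant to splitting reads across sites at the same level
  calls2 <- make_calls("chr1", c(3500, 3600, 4500), "+", c(4, 4, 2),
                       c(1, 1, 8), c("CG", "CG", "CG"))
  rm2 <- region_methylation(calls2, p, contexts = "CG")
  expect_equal(rm2$level[rm2$region == "promoter"], 0.5)
})

test_that("perfect anticorrelation is recovered exactly", {
  meth <- matrix(c(0.1, 0.5, 0.9,
                   0.2, 0.2, 0.2), 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expr <- matrix(c(0.9, 0.5, 0.1,
                   1.0, 2.0, 3.0), 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  res <- methylation_expression_correlation(meth, expr)
  expect_equal(res$results$r[res$results$gene_id == "g1"], -1)
  # constant methylation vector: skipped and counted
  expect_false("g2" %in% res$results$gene_id)
  expect_equal(res$n_skipped, 1)
  expect_equal(sum(res$density$rel_freq), 1)
  expect_error(methylation_expression_correlation(meth[, 1:2],
                                                  expr[, 1:2]),
               "3 shared samples")
})

test_that("Pearson and Spearman agree in sign on monotone inputs", {
  meth <- matrix(seq(0.1, 0.9, length.out = 6), 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  expr <- matrix(exp(-seq(1, 6)), 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  rp <- methylation_expression_correlation(meth, expr, "pearson")$results$r
  rs <- methylation_expression_correlation(meth, expr, "spearman")$results$r
  expect_lt(rp, 0)
  expect_equal(rs, -1)
})

test_that("log2 fold-change filter and its anti-symmetry", {
  r <- simple_log2fc_filter(3, 1)
  expect_equal(r$lfc, 1)
  expect_true(r$flagged)
  r0 <- simple_log2fc_filter(5, 5)
  expect_equal(r0$lfc, 0)
  expect_false(r0$flagged)
  expect_equal(simple_log2fc_filter(1, 3)$lfc, -1)
  expect_error(simple_log2fc_filter(1, 1, pseudocount = 0), "pseudocount")
})

test_that("2^-ddCt relative expression", {
  expect_equal(ddct_relative_expression(25, 20, 24, 20), 0.5)
  expect_equal(ddct_relative_expression(24, 20, 24, 20), 1)   # calibrator
  expect_equal(ddct_relative_expression(22, 20, 24, 20), 4)   # ddCt = -2
})
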