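test_that("simulated genome has the configured size and GC content", {
  cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length_bp = 10000,
                    gc_fraction = 0.5, n_genes = 2, n_tes = 1,
                    n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  expect_equal(nchar(g[["chr1"]]), 10000)
  b <- strsplit(g[["chr1"]], "")[[1]]
  expect_true(sum(b %in% c("C", "G")) >= 4800 && sum(b %in% c("C", "G")) <= 5200)
  gc1 <- simulate_genome(sim_config(seed = 1, n_chrom = 1,
                                    chrom_length_bp = 2000, gc_fraction = 1))
  expect_true(all(strsplit(gc1[[1]], "")[[1]] %in% c("C", "G")))
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- sim_config(seed = 11, n_chrom = 1, chrom_length_bp = 40000,
                    n_genes = 3, n_tes = 2, n_planted_dmrs = 3,
                    n_samples_per_group = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_wgbs_experiment(cfg, out_dir = d1)
  simulate_wgbs_experiment(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("annotation respects clearance, non-overlap and exon containment", {
  cfg <- sim_config(seed = 2, n_chrom = 1, chrom_length_bp = 1000000,
                    n_genes = 50, n_tes = 30, n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  f <- ann$features
  expect_equal(nrow(f), 80)
  expect_true(all(f$start >= 2000))
  expect_true(all(f$end <= 1000000 - 2000))
  o <- order(f$start)
  expect_true(all(f$start[o][-1] >= f$end[o][-nrow(f)]))  # non-overlapping
  ex <- ann$exons
  expect_gt(nrow(ex), 0)
  m <- match(ex$feature_id, f$feature_id)
  expect_true(all(ex$start >= f$start[m] & ex$end <= f$end[m]))
  expect_true(all(ex$strand == f$strand[m]))
})

test_that("annotation handles a TE-only request and impossible placements", {
  cfg <- sim_config(seed = 2, n_chrom = 1, chrom_length_bp = 60000,
                    n_genes = 0, n_tes = 5, n_planted_dmrs = 0)
  ann <- simulate_annotation(simulate_genome(cfg), cfg)
  expect_true(all(ann$features$type == "TE"))
  expect_equal(nrow(ann$exons), 0)
  cfg_bad <- sim_config(seed = 2, n_chrom = 1, chrom_length_bp = 12000,
                        n_genes = 40, n_tes = 0, n_planted_dmrs = 0)
  expect_error(simulate_annotation(simulate_genome(cfg_bad), cfg_bad),
               "placement error")
})

test_that("true methylation landscape follows the planted shapes", {
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  truth <- assign_true_methylation(g, ann, cfg)
  s <- truth$sites
  expect_true(all(s$level_A >= 0 & s$level_A <= 1))
  expect_true(all(s$level_B >= 0 & s$level_B <= 1))
  # planted DMRs: configured effect, so true fold change is 4
  expect_true(all(truth$dmrs$level_A / truth$dmrs$level_B == 4))
  expect_true(all(truth$dmrs$n_sites >= cfg$dmr_min_sites))
  # outside planted DMRs the conditions share levels
  expect_equal(sum(s$level_A != s$level_B), sum(truth$dmrs$n_sites))
  # TE bodies beat their surroundings in every context
  tes <- ann$features[ann$features$type == "TE", ]
  in_te <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(tes)))
    in_te <- in_te | (s$chrom == tes$chrom[i] & s$pos > tes$start[i] &
                        s$pos <= tes$end[i])
  for (ctx in c("CG", "CHG", "CHH")) {
    expect_gt(mean(s$level_A[in_te & s$context == ctx]),
              mean(s$level_A[!in_te & s$context == ctx]))
  }
})

test_that("zero bell amplitude gives a flat gene body at the base level", {
  shp <- meth_shape(gene_body_amp = c(CG = 0, CHG = 0, CHH = 0))
  cfg <- small_sim_config(shape = shp, n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  truth <- assign_true_methylation(g, ann, cfg)
  genes <- ann$features[ann$features$type == "gene", ]
  s <- truth$sites
  gi <- genes[1, ]
  body <- s$chrom == gi$chrom & s$pos > gi$start & s$pos <= gi$end
  expect_true(all(s$level_A[body & s$context == "CG"] ==
                    shp$gene_body_base[["CG"]]))
})

test_that("CHH is enriched upstream of genes relative to downstream", {
  cfg <- small_sim_config(n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  truth <- assign_true_methylation(g, ann, cfg)
  genes <- ann$features[ann$features$type == "gene", ]
  s <- truth$sites
  up <- dn <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    if (gi$strand == "+") {
      up <- up | (s$chrom == gi$chrom & s$pos > gi$start - 2000 & s$pos <= gi$start)
      dn <- dn | (s$chrom == gi$chrom & s$pos > gi$end & s$pos <= gi$end + 2000)
    } else {
      up <- up | (s$chrom == gi$chrom & s$pos > gi$end & s$pos <= gi$end + 2000)
      dn <- dn | (s$chrom == gi$chrom & s$pos > gi$start - 2000 & s$pos <= gi$start)
    }
  }
  chh <- s$context == "CHH"
  expect_gt(mean(s$level_A[up & chh]), mean(s$level_A[dn & chh]))
})

test_that("bisulfite counts follow the observation model", {
  # degenerate: fully methylated truth, no noise -> meth == total
  cfg <- small_sim_config(non_conversion_rate = 0, seq_error_rate = 0,
                          n_samples_per_group = 1, n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  truth <- assign_true_methylation(g, ann, cfg)
  truth$sites$level_A[] <- 1
  truth$sites$level_B[] <- 1
  calls <- simulate_methylation_calls(truth, cfg)
  a1 <- calls$A[[1]]
  expect_true(all(a1$unmeth == 0))  # methylated count equals total everywhere
  # conservation: meth <= total in every sample
  calls2 <- simulate_methylation_calls(assign_true_methylation(g, ann, cfg), cfg)
  for (df in c(calls2$A, calls2$B))
    expect_true(all(df$meth >= 0 & df$unmeth >= 0))
})

test_that("non-conversion creates the expected false-methylation signal", {
  # p_true = 0 with 1% non-conversion: pooled level within 3 binomial SE
  cfg <- sim_config(seed = 5, n_chrom = 1, chrom_length_bp = 25000,
                    non_conversion_rate = 0.01, seq_error_rate = 0,
                    coverage_mean = 50, n_samples_per_group = 1,
                    n_genes = 1, n_tes = 1, n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  truth <- assign_true_methylation(g, ann, cfg)
  truth$sites$level_A[] <- 0
  calls <- simulate_methylation_calls(truth, cfg)$A[[1]]
  expect_gt(nrow(calls), 10000)
  n_reads <- sum(calls$meth + calls$unmeth)
  p_hat <- sum(calls$meth) / n_reads
  se <- sqrt(0.01 * 0.99 / n_reads)
  expect_lt(abs(p_hat - 0.01), 3 * se)
})

test_that("zero coverage emits empty calls that the filter removes", {
  cfg <- sim_config(seed = 5, n_chrom = 1, chrom_length_bp = 8000,
                    coverage_mean = 0, n_samples_per_group = 1,
                    n_genes = 0, n_tes = 1, n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  truth <- assign_true_methylation(g, ann, cfg)
  calls <- simulate_methylation_calls(truth, cfg)$A[[1]]
  expect_true(all(calls$meth + calls$unmeth == 0))
  expect_equal(nrow(filter_by_coverage(calls, 1)), 0)
})

test_that("latent expression is coupled to promoter methylation across genes", {
  cfg0 <- sim_config(seed = 9, n_chrom = 2, chrom_length_bp = 400000,
                     n_genes = 500, gene_length_bp_mean = 700,
                     n_tes = 0, n_planted_dmrs = 0,
                     expression_coupling_rho = 0)
  g <- simulate_genome(cfg0)
  ann <- simulate_annotation(g, cfg0)
  truth <- assign_true_methylation(g, ann, cfg0)
  e0 <- simulate_expression(ann, truth, cfg0)
  r0 <- cor(e0$latent$latent_log2, e0$latent$promoter_meth,
            use = "complete.obs")
  expect_lt(abs(r0), 0.15)
  cfg6 <- sim_config(seed = 9, n_chrom = 2, chrom_length_bp = 400000,
                     n_genes = 500, gene_length_bp_mean = 700,
                     n_tes = 0, n_planted_dmrs = 0,
                     expression_coupling_rho = -0.6)
  e6 <- simulate_expression(ann, truth, cfg6)
  r6 <- cor(e6$latent$latent_log2, e6$latent$promoter_meth,
            use = "complete.obs")
  expect_true(r6 >= -0.7 && r6 <= -0.5)
})

test_that("counts approach Poisson as dispersion vanishes", {
  cfg <- small_sim_config(nb_dispersion = 0, n_samples_per_group = 3)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  truth <- assign_true_methylation(g, ann, cfg)
  e <- simulate_expression(ann, truth, cfg)
  # per-gene variance/mean across replicate samples near 1 on average
  vm <- apply(e$counts, 1, function(x) if (mean(x) > 50) var(x) / mean(x) else NA)
  expect_lt(abs(mean(vm, na.rm = TRUE) - 1), 0.5)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(gc_fraction = 1.2), "\\[0,1\\]")
  expect_error(sim_config(dmr_effect = c(1.5, 0.1)), "\\[0,1\\]")
  expect_error(sim_config(chrom_length_bp = 0), "positive")
  expect_error(sim_config(expression_coupling_rho = -2), "rho")
})

test_that("annotation survives a GFF3/BED round trip", {
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_annotation(ann, gff, bed)
  back <- read_annotation(gff, bed)
  f1 <- ann$features[order(ann$features$chrom, ann$features$start), ]
  f2 <- back$features[order(back$features$chrom, back$features$start), ]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f2[c("chrom", "start", "end", "strand", "type")],
               f1[c("chrom", "start", "end", "strand", "type")])
  expect_equal(nrow(back$exons), nrow(ann$exons))
})
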