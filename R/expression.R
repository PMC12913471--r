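# Expression quantification (FPKM), genome region partitioning
# (promoter/exon/intron/intergenic) and methylation--expression correlation.

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count / ((gene_length_bp/1000) * (total_mapped_fragments/1e6))`.
#'
#' @param count Fragment count(s) for the gene.
#' @param gene_length_bp Gene (transcript) length in bp, > 0.
#' @param total_mapped_fragments Library size, > 0.
#' @return FPKM value(s).
#' @examples
#' fpkm(100, 2000, 1e7)  # 5
#' @export
fpkm <- function(count, gene_length_bp, total_mapped_fragments) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be positive")
  if (any(total_mapped_fragments <= 0))
    stop("total_mapped_fragments must be positive")
  count / ((gene_length_bp / 1000) * (total_mapped_fragments / 1e6))
}

#' FPKM matrix from a count matrix
#'
#' Per-sample library sizes are the column sums of `counts`.
#'
#' @param counts Gene x sample count matrix (row names = gene ids).
#' @param gene_lengths Named vector of gene lengths (bp).
#' @return Gene x sample FPKM matrix.
#' @export
fpkm_matrix <- function(counts, gene_lengths) {
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths))) stop("missing gene lengths")
  totals <- colSums(counts)
  sweep(counts / (gene_lengths / 1000), 2, totals / 1e6, "/")
}

.df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start + 1L, df$end))
}

.gr_to_df <- function(gr, extra = NULL) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

#' Partition the genome into promoter / exon / intron / intergenic classes
#'
#' Promoters are the `promoter_bp` (default 2 kb, matching the metagene
#' flank convention) upstream of each gene's TSS, strand-aware, truncated at
#' chromosome ends and yielding to any gene body they overlap. Introns are
#' gene bodies minus exons. Class precedence on overlap is
#' exon > intron > promoter > intergenic; intergenic is the complement of
#' gene bodies and promoters. The four classes tile every chromosome with
#' no overlap and no gap.
#'
#' @param annotation An `annotation` object (only `type == "gene"` features
#'   enter the partition; TEs fall in whatever class covers them).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param promoter_bp Promoter width upstream of the TSS.
#' @return List with per-gene interval tables `promoters`, `exons`,
#'   `introns` (`chrom`, `start`, `end`, `gene_id`) and the global `classes`
#'   table (`chrom`, `start`, `end`, `class`); class `region_partition`.
#' @export
assign_regions <- function(annotation, chrom_lengths, promoter_bp = 2000) {
  feats <- annotation$features
  genes <- feats[feats$type == "gene", , drop = FALSE]
  exons <- annotation$exons
  gr_bodies <- .df_to_gr(genes)
  bodies_union <- GenomicRanges::reduce(gr_bodies)
  # per-gene promoters: strand-aware upstream, clipped, minus any gene body
  prom_list <- list()
  if (nrow(genes)) {
    up <- .flank_intervals(genes, chrom_lengths, promoter_bp, "upstream")
    for (i in seq_len(nrow(genes))) {
      if (up$end[i] <= up$start[i]) {
        warning("gene ", genes$feature_id[i],
                " has an empty promoter (chromosome start/end)")
        next
      }
      gr_p <- GenomicRanges::setdiff(
        GenomicRanges::GRanges(up$chrom[i],
          IRanges::IRanges(up$start[i] + 1L, up$end[i])),
        bodies_union)
      if (length(gr_p) == 0L) {
        warning("promoter of gene ", genes$feature_id[i],
                " fully covered by adjacent gene bodies")
        next
      }
      prom_list[[length(prom_list) + 1L]] <-
        .gr_to_df(gr_p, data.frame(gene_id = genes$feature_id[i]))
    }
  }
  promoters <- if (length(prom_list)) do.call(rbind, prom_list) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               gene_id = character(), stringsAsFactors = FALSE)
  exon_df <- data.frame(chrom = exons$chrom, start = exons$start,
                        end = exons$end, gene_id = exons$feature_id,
                        stringsAsFactors = FALSE)
  # per-gene introns: own body minus own exons
  intron_list <- list()
  for (gid in genes$feature_id) {
    g <- genes[genes$feature_id == gid, ]
    ex_g <- exon_df[exon_df$gene_id == gid, , drop = FALSE]
    gr_i <- GenomicRanges::setdiff(.df_to_gr(g),
                                   if (nrow(ex_g)) .df_to_gr(ex_g)
                                   else GenomicRanges::GRanges())
    if (length(gr_i))
      intron_list[[length(intron_list) + 1L]] <-
        .gr_to_df(gr_i, data.frame(gene_id = gid))
  }
  introns <- if (length(intron_list)) do.call(rbind, intron_list) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               gene_id = character(), stringsAsFactors = FALSE)
  # global classes with precedence exon > intron > promoter > intergenic
  si <- GenomeInfoDb::Seqinfo(seqnames = names(chrom_lengths),
                              seqlengths = unname(chrom_lengths))
  on_si <- function(gr) {
    GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                           IRanges::IRanges(GenomicRanges::start(gr),
                                            GenomicRanges::end(gr)),
                           seqinfo = si)
  }
  ex_cls <- GenomicRanges::reduce(on_si(if (nrow(exon_df)) .df_to_gr(exon_df)
                                        else GenomicRanges::GRanges()))
  in_cls <- GenomicRanges::setdiff(GenomicRanges::reduce(on_si(bodies_union)),
                                   ex_cls)
  pr_cls <- if (nrow(promoters))
    GenomicRanges::reduce(on_si(.df_to_gr(promoters))) else
    GenomicRanges::GRanges(seqinfo = si)
  covered <- GenomicRanges::reduce(c(ex_cls, in_cls, pr_cls))
  ig_cls <- GenomicRanges::gaps(covered)
  ig_cls <- ig_cls[as.character(GenomicRanges::strand(ig_cls)) == "*"]
  cls_df <- function(gr, cl) {
    d <- .gr_to_df(gr)
    d$class <- rep(cl, nrow(d))
    d
  }
  classes <- rbind(cls_df(ex_cls, "exon"), cls_df(in_cls, "intron"),
                   cls_df(pr_cls, "promoter"), cls_df(ig_cls, "intergenic"))
  classes <- classes[order(classes$chrom, classes$start), ]
  rownames(classes) <- NULL
  structure(list(promoters = promoters, exons = exon_df, introns = introns,
                 classes = classes, chrom_lengths = chrom_lengths,
                 promoter_bp = promoter_bp),
            class = "region_partition")
}

#' Write the region partition as one BED file per class
#'
#' @param partition A `region_partition`.
#' @param dir Output directory (`promoter.bed`, `exon.bed`, `intron.bed`,
#'   `intergenic.bed`).
#' @return Invisible vector of paths.
#' @export
write_region_beds <- function(partition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in c("promoter", "exon", "intron", "intergenic")) {
    d <- partition$classes[partition$classes$class == cl, , drop = FALSE]
    p <- file.path(dir, paste0(cl, ".bed"))
    data.table::fwrite(d[c("chrom", "start", "end")], p, sep = "\t",
                       col.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Pooled methylation level per gene and region class
#'
#' Read-pooled level (sum meth / sum total) over each gene's promoter,
#' exon and intron intervals for each context. Genes with no covered site
#' in a class are reported with `NA` level.
#'
#' @param calls Coverage-filtered methylation calls (one sample).
#' @param partition A `region_partition`.
#' @param contexts Contexts to summarise.
#' @return data.frame (`gene_id`, `region`, `context`, `meth`, `total`,
#'   `n_sites`, `level`).
#' @export
region_methylation <- function(calls, partition, contexts = METH_CONTEXTS) {
  pieces <- list(promoter = partition$promoters,
                 exon = partition$exons,
                 intron = partition$introns)
  ivl <- data.table::rbindlist(lapply(names(pieces), function(cl) {
    d <- pieces[[cl]]
    if (nrow(d) == 0L) return(NULL)
    data.table::data.table(chrom = d$chrom, start = d$start, end = d$end,
                           gene_id = d$gene_id, region = cl)
  }))
  calls <- calls[calls$context %in% contexts, , drop = FALSE]
  ov <- .site_overlaps(calls, as.data.frame(ivl))
  gene_ids <- unique(ivl$gene_id)
  grid <- expand.grid(gene_id = gene_ids, region = names(pieces),
                      context = contexts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(ov)) {
    dt <- data.table::data.table(
      gene_id = ivl$gene_id[ov$ivl], region = ivl$region[ov$ivl],
      context = calls$context[ov$site], meth = calls$meth[ov$site],
      total = calls$meth[ov$site] + calls$unmeth[ov$site])
    agg <- dt[, .(meth = sum(meth), total = sum(total), n_sites = .N),
              by = .(gene_id, region, context)]
    grid <- merge(grid, data.table::setDF(agg),
                  by = c("gene_id", "region", "context"), all.x = TRUE)
  } else {
    grid$meth <- NA_real_; grid$total <- NA_real_
  }
  if (!"n_sites" %in% names(grid)) grid$n_sites <- NA_integer_
  grid$n_sites[is.na(grid$n_sites)] <- 0L
  grid$level <- ifelse(!is.na(grid$total) & grid$total > 0,
                       grid$meth / grid$total, NA_real_)
  grid[order(grid$gene_id, grid$region, grid$context), ]
}

#' Per-gene region methylation across samples, as a matrix
#'
#' @param call_list Named list of per-sample call data.frames.
#' @param partition A `region_partition`.
#' @param region One of promoter/exon/intron.
#' @param context One of CG/CHG/CHH.
#' @param min_total Coverage filter applied per sample.
#' @return Gene x sample matrix of pooled levels.
#' @export
region_methylation_matrix <- function(call_list, partition, region = "promoter",
                                      context = "CG", min_total = 4) {
  cols <- lapply(call_list, function(calls) {
    rm <- region_methylation(filter_by_coverage(calls, min_total),
                             partition, contexts = context)
    rm <- rm[rm$region == region, ]
    stats::setNames(rm$level, rm$gene_id)
  })
  genes <- names(cols[[1]])
  out <- vapply(cols, function(v) v[genes], numeric(length(genes)))
  rownames(out) <- genes
  out
}

#' Methylation--expression correlation across samples
#'
#' For each gene, the correlation between its region methylation level and
#' `log2(FPKM + 1)` across samples. Genes with fewer than 3 complete pairs
#' or a constant vector are skipped and counted. The coefficient
#' distribution is summarised as a fixed-break histogram of relative
#' frequencies (deterministic, unlike kernel densities).
#'
#' @param region_levels Gene x sample methylation matrix.
#' @param expression Gene x sample expression matrix, already transformed
#'   (e.g. `log2(FPKM + 1)`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param breaks Histogram breaks on `[-1, 1]` (default width 0.1).
#' @return List with `results` (per-gene `r` and `n`), `density`
#'   (histogram table), `n_skipped`, `method`; class `meth_expr_cor`.
#' @export
methylation_expression_correlation <- function(region_levels, expression,
                                               method = c("pearson", "spearman"),
                                               breaks = seq(-1, 1, by = 0.1)) {
  method <- match.arg(method)
  genes <- intersect(rownames(region_levels), rownames(expression))
  samples <- intersect(colnames(region_levels), colnames(expression))
  if (length(samples) < 3)
    stop("need at least 3 shared samples")
  rs <- rep(NA_real_, length(genes))
  ns <- integer(length(genes))
  for (i in seq_along(genes)) {
    x <- region_levels[genes[i], samples]
    y <- expression[genes[i], samples]
    ok <- complete.cases(x, y)
    ns[i] <- sum(ok)
    if (ns[i] < 3) next
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    rs[i] <- cor(x[ok], y[ok], method = method)
  }
  keep <- !is.na(rs)
  if (!any(keep)) stop("no gene has >= 3 shared samples with variation")
  results <- data.frame(gene_id = genes[keep], r = rs[keep], n = ns[keep],
                        stringsAsFactors = FALSE)
  h <- hist(results$r, breaks = breaks, plot = FALSE)
  density <- data.frame(lower = head(breaks, -1), upper = breaks[-1],
                        count = h$counts,
                        rel_freq = h$counts / sum(h$counts))
  structure(list(results = results, density = density,
                 n_skipped = sum(!keep), method = method),
            class = "meth_expr_cor")
}

#' @export
print.meth_expr_cor <- function(x, ...) {
  cat("Methylation-expression correlation (", x$method, "): ",
      nrow(x$results), " genes, ", x$n_skipped, " skipped; median r = ",
      signif(median(x$results$r), 3), "\n", sep = "")
  invisible(x)
}

#' Simple log2 fold-change filter
#'
#' Pseudocounted log2 fold change between two FPKM vectors with a flag at
#' `|lfc| >= min_abs_lfc`. A plumbing filter for synthetic demonstrations;
#' not a differential-expression test.
#'
#' @param fpkm_A,fpkm_B Per-gene FPKM vectors.
#' @param pseudocount Added to both before the ratio (default 1).
#' @param min_abs_lfc Flag threshold (default 1).
#' @return data.frame with `lfc` and logical `flagged`.
#' @export
simple_log2fc_filter <- function(fpkm_A, fpkm_B, pseudocount = 1,
                                 min_abs_lfc = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  lfc <- log2((fpkm_A + pseudocount) / (fpkm_B + pseudocount))
  data.frame(lfc = lfc, flagged = abs(lfc) >= min_abs_lfc)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator)`; relative expression is
#' `2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample Target/reference-gene Ct in the
#'   sample.
#' @param ct_target_calibrator,ct_ref_calibrator Target/reference-gene Ct
#'   in the calibrator.
#' @return Relative expression value(s).
#' @examples
#' ddct_relative_expression(25, 20, 24, 20)  # 0.5
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
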