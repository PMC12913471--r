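# Differentially methylated region (DMR) calling between two sample groups.
#
# A region qualifies as a DMR when, for a given context, it holds at least
# `min_sites` covered sites (covered in BOTH groups), the pooled methylation
# levels differ at least `min_fold`-fold, and a two-sided Fisher exact test
# on the pooled 2x2 read-count table gives P <= alpha. Read counts are
# summed across sites and replicates before testing; the fold change is
# computed on pseudocounted levels (one read added per table cell) so it is
# defined when one group is fully unmethylated, while the Fisher test uses
# the raw counts.

#' Tile chromosomes into analysis windows
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param width Window width in bp.
#' @param step Step between window starts; `step = width` (default) gives a
#'   non-overlapping partition.
#' @return data.frame of regions (`chrom`, `start`, `end`; 0-based
#'   half-open), last window truncated at the chromosome end.
#' @export
make_windows <- function(chrom_lengths, width = 200, step = width) {
  if (width < 1) stop("width must be >= 1")
  if (step < 1 || step > width) stop("step must satisfy 1 <= step <= width")
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, L - 1L), by = step)
    starts <- starts[starts < L]
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + width, L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# sum replicate calls within a group to per-site pooled counts
.pool_group <- function(calls) {
  if (is.data.frame(calls)) calls <- list(calls)
  dt <- data.table::rbindlist(lapply(calls, function(x)
    x[c("chrom", "pos", "strand", "context", "meth", "unmeth")]))
  dt[, .(meth = sum(meth), unmeth = sum(unmeth)),
     by = .(chrom, pos, strand, context)]
}

# per-site counts pooled within each group, restricted to sites covered
# (total > 0) in BOTH groups
.shared_site_counts <- function(calls_A, calls_B) {
  A <- .pool_group(calls_A)
  B <- .pool_group(calls_B)
  data.table::setnames(A, c("meth", "unmeth"), c("meth_A", "unmeth_A"))
  data.table::setnames(B, c("meth", "unmeth"), c("meth_B", "unmeth_B"))
  m <- merge(A, B, by = c("chrom", "pos", "strand", "context"))
  m[m$meth_A + m$unmeth_A > 0 & m$meth_B + m$unmeth_B > 0]
}

#' Pool read counts of two groups over one region
#'
#' Sums methylated/unmethylated reads (replicates summed within group) over
#' sites of the given context inside the region that are covered in both
#' groups.
#'
#' @param calls_A,calls_B A data.frame of calls or a list of replicate
#'   data.frames per group.
#' @param region List or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param context One of CG/CHG/CHH.
#' @return List with `table` (2x2 matrix, rows = groups, cols =
#'   meth/unmeth) and `n_sites`.
#' @export
pool_region_counts <- function(calls_A, calls_B, region, context) {
  stopifnot(context %in% METH_CONTEXTS)
  s <- .shared_site_counts(calls_A, calls_B)
  s <- s[s$chrom == region$chrom & s$pos > region$start &
           s$pos <= region$end & s$context == context]
  tab <- matrix(c(sum(s$meth_A), sum(s$unmeth_A),
                  sum(s$meth_B), sum(s$unmeth_B)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("meth", "unmeth")))
  list(table = tab, n_sites = nrow(s))
}

#' Two-sided Fisher exact test for a 2x2 count table
#'
#' Computes the two-sided P value by direct hypergeometric enumeration: the
#' sum of the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7). Degenerate tables (a zero row or column) return P = 1
#' with attribute `degenerate = TRUE`.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return P value in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("table cells must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  m <- a + cc; nn <- b + d; k <- a + b
  if (m == 0 || nn == 0 || k == 0 || (cc + d) == 0)
    return(structure(1, degenerate = TRUE))
  lo <- max(0, k - nn); hi <- min(k, m)
  x <- lo:hi
  p <- dhyper(x, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# pseudocounted levels (one read per table cell) used for fold change only
.pseudo_level <- function(meth, unmeth) (meth + 1) / (meth + unmeth + 2)

#' Call DMRs between two groups of samples
#'
#' Applies the region rule per window and context: at least `min_sites`
#' sites of the context covered in both groups, at least `min_fold` change
#' in (pseudocounted) pooled methylation level, and a two-sided Fisher exact
#' P on the raw pooled counts of at most `alpha` (inclusive). Direction is
#' `gain` when group A's level exceeds group B's.
#'
#' @param calls_A,calls_B Coverage-filtered calls; a data.frame or a list of
#'   replicate data.frames per group.
#' @param regions data.frame of regions (see [make_windows()]).
#' @param min_sites,min_fold,alpha The three gates (defaults 5, 2, 0.05).
#' @param contexts Contexts to test.
#' @param p_adjust `"none"` (default; the rule uses raw P) or `"BH"` for
#'   Benjamini-Hochberg adjusted P within each context.
#' @return data.frame of DMRs sorted by (`chrom`, `start`, `context`), with
#'   pooled levels, fold change, P, `n_sites` and `direction`; class
#'   `dmr_set`.
#' @export
call_dmrs <- function(calls_A, calls_B, regions, min_sites = 5,
                      min_fold = 2, alpha = 0.05,
                      contexts = METH_CONTEXTS,
                      p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(min_sites > 0, min_fold > 0, alpha > 0)
  s <- .shared_site_counts(calls_A, calls_B)
  s <- s[s$context %in% contexts]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_sites = integer(), level_A = numeric(),
                      level_B = numeric(), fold_change = numeric(),
                      p_value = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(s) == 0L) {
    warning("no sites covered in both groups; no DMRs callable")
    return(structure(empty, class = c("dmr_set", "data.frame")))
  }
  gr_s <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, width = 1L))
  gr_r <- GenomicRanges::GRanges(regions$chrom,
    IRanges::IRanges(regions$start + 1L, regions$end))
  h <- GenomicRanges::findOverlaps(gr_s, gr_r)
  dt <- s[S4Vectors::queryHits(h)]
  dt$window_id <- S4Vectors::subjectHits(h)
  agg <- dt[, .(n_sites = .N,
                meth_A = sum(meth_A), unmeth_A = sum(unmeth_A),
                meth_B = sum(meth_B), unmeth_B = sum(unmeth_B)),
            by = .(window_id, context)]
  agg <- agg[agg$n_sites >= min_sites]
  if (nrow(agg) == 0L)
    return(structure(empty, class = c("dmr_set", "data.frame")))
  lA <- .pseudo_level(agg$meth_A, agg$unmeth_A)
  lB <- .pseudo_level(agg$meth_B, agg$unmeth_B)
  agg$fold_change <- pmax(lA / lB, lB / lA)
  agg <- agg[agg$fold_change >= min_fold]
  if (nrow(agg) == 0L)
    return(structure(empty, class = c("dmr_set", "data.frame")))
  agg$p_value <- vapply(seq_len(nrow(agg)), function(i)
    as.numeric(fisher_exact_two_sided(matrix(
      c(agg$meth_A[i], agg$unmeth_A[i], agg$meth_B[i], agg$unmeth_B[i]),
      nrow = 2, byrow = TRUE))), numeric(1))
  if (p_adjust == "BH")
    agg[, p_value := stats::p.adjust(p_value, "BH"), by = context]
  agg <- agg[agg$p_value <= alpha]
  if (nrow(agg) == 0L)
    return(structure(empty, class = c("dmr_set", "data.frame")))
  level_A <- agg$meth_A / (agg$meth_A + agg$unmeth_A)
  level_B <- agg$meth_B / (agg$meth_B + agg$unmeth_B)
  dir <- ifelse(level_A == level_B,
                ifelse(.pseudo_level(agg$meth_A, agg$unmeth_A) >
                         .pseudo_level(agg$meth_B, agg$unmeth_B),
                       "gain", "loss"),
                ifelse(level_A > level_B, "gain", "loss"))
  out <- data.frame(
    chrom = regions$chrom[agg$window_id],
    start = regions$start[agg$window_id],
    end = regions$end[agg$window_id],
    context = agg$context, n_sites = agg$n_sites,
    level_A = level_A, level_B = level_B,
    fold_change = agg$fold_change, p_value = agg$p_value,
    direction = dir, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$context), ]
  rownames(out) <- NULL
  structure(out, class = c("dmr_set", "data.frame"))
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("DMR set: ", nrow(x), " regions (",
      sum(x$direction == "gain"), " gain / ",
      sum(x$direction == "loss"), " loss)\n", sep = "")
  NextMethod()
}

#' Tabulate DMR counts and gain/loss percentages by context
#'
#' @param dmrs A `dmr_set` (optionally with a `comparison` column labelling
#'   multiple paired comparisons).
#' @return data.frame with per (comparison, context) counts, gain/loss
#'   counts and percentages (summing to 100 within each row).
#' @export
dmr_context_counts <- function(dmrs) {
  if (!"comparison" %in% names(dmrs))
    dmrs$comparison <- rep("A_vs_B", nrow(dmrs))
  comps <- unique(dmrs$comparison)
  if (length(comps) == 0L) comps <- "A_vs_B"
  grid <- expand.grid(comparison = comps, context = METH_CONTEXTS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0L) {
    grid$n <- 0L; grid$n_gain <- 0L; grid$n_loss <- 0L
    grid$pct_gain <- NA_real_; grid$pct_loss <- NA_real_
    return(grid)
  }
  dt <- data.table::as.data.table(dmrs)
  agg <- dt[, .(n = .N, n_gain = sum(direction == "gain"),
                n_loss = sum(direction == "loss")),
            by = .(comparison, context)]
  out <- merge(grid, data.table::setDF(agg),
               by = c("comparison", "context"), all.x = TRUE)
  for (cl in c("n", "n_gain", "n_loss"))
    out[[cl]][is.na(out[[cl]])] <- 0L
  out$pct_gain <- ifelse(out$n > 0, 100 * out$n_gain / out$n, NA_real_)
  out$pct_loss <- ifelse(out$n > 0, 100 * out$n_loss / out$n, NA_real_)
  out[order(out$comparison, out$context), ]
}

#' Write DMRs as BED6+ with extra level/fold/site columns
#'
#' Columns: chrom, start, end, name (`context:direction`), score
#' (`-log10 P`, capped at 1000), strand (`.`), then `level_A`, `level_B`,
#' `fold_change`, `n_sites`.
#'
#' @param dmrs A `dmr_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = paste0(dmrs$context, ":", dmrs$direction),
    score = round(pmin(1000, -log10(pmax(dmrs$p_value, 1e-300))), 3),
    strand = ".",
    level_A = signif(dmrs$level_A, 6), level_B = signif(dmrs$level_B, 6),
    fold_change = signif(dmrs$fold_change, 6), n_sites = dmrs$n_sites,
    stringsAsFactors = FALSE)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
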