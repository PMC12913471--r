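# Cytosine context classification and methylation-call handling.
#
# A cytosine's context is read 5'->3' on the cytosine's own strand:
#   CG  - next base is G
#   CHG - next base is H (A/C/T) and the base after is G
#   CHH - anything else
# For minus-strand cytosines (reference base G) the trinucleotide is the
# reverse complement of reference positions pos, pos-1, pos-2.
# Internal coordinates are 0-based half-open; cytosine reports and all
# user-facing positions are 1-based (conversion confined to readers/writers).

METH_CONTEXTS <- c("CG", "CHG", "CHH")

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Read a reference genome from FASTA
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

# context from the 2nd/3rd trinucleotide base; NA bases mean the chromosome
# end truncated the trinucleotide.  CG needs only two bases; a non-G second
# base with unknown third base is ambiguous (CHG vs CHH) -> CHH, flagged.
.context_from_bases <- function(b2, b3) {
  ctx <- rep("CHH", length(b2))
  ctx[!is.na(b2) & b2 == "G"] <- "CG"
  ctx[!is.na(b2) & b2 != "G" & !is.na(b3) & b3 == "G"] <- "CHG"
  partial <- is.na(b2) | (b2 != "G" & is.na(b3))
  list(context = ctx, partial = partial)
}

.tri_string <- function(b2, b3) {
  paste0("C",
         ifelse(is.na(b2), "", b2),
         ifelse(is.na(b2) | is.na(b3), "", b3))
}

#' Classify cytosine context against a reference genome
#'
#' Reads the trinucleotide 5'->3' on the site's strand (for `-` sites, the
#' reverse complement of reference positions `pos`, `pos-1`, `pos-2`) and
#' applies the CG/CHG/CHH rule. Sites within 2 nt of the strand's 3'
#' chromosome end are classified with the available bases; cases that remain
#' ambiguous default to CHH and are flagged `partial`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,pos,strand Vectors (recycled `strand` allowed) giving the
#'   site; `pos` is 1-based.
#' @return data.frame with columns `context`, `trinucleotide`, `partial`.
#' @examples
#' g <- c(chr1 = "TTCGA")
#' classify_context(g, "chr1", 3, "+")   # CG, "CGA"
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  context <- trinucleotide <- character(n)
  partial <- logical(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
    idx <- which(chrom == ch)
    s <- genome[[ch]]
    L <- nchar(s)
    p <- pos[idx]
    if (any(p < 1 | p > L))
      stop("position out of range on ", ch)
    st <- strand[idx]
    base_at <- function(q) {
      out <- rep(NA_character_, length(q))
      ok <- which(q >= 1 & q <= L)
      if (length(ok)) out[ok] <- substring(s, q[ok], q[ok])
      out
    }
    b1 <- base_at(p)
    bad <- (st == "+" & b1 != "C") | (st == "-" & b1 != "G")
    if (any(bad))
      stop("reference base at ", ch, ":", p[bad][1], " (", st[bad][1],
           ") is not a cytosine on that strand")
    b2 <- b3 <- rep(NA_character_, length(p))
    pl <- st == "+"
    b2[pl] <- base_at(p[pl] + 1)
    b3[pl] <- base_at(p[pl] + 2)
    b2[!pl] <- unname(.COMP[base_at(p[!pl] - 1)])
    b3[!pl] <- unname(.COMP[base_at(p[!pl] - 2)])
    cc <- .context_from_bases(b2, b3)
    context[idx] <- cc$context
    partial[idx] <- cc$partial
    trinucleotide[idx] <- .tri_string(b2, b3)
  }
  data.frame(context = context, trinucleotide = trinucleotide,
             partial = partial, stringsAsFactors = FALSE)
}

#' Enumerate all cytosine sites of a genome
#'
#' Finds every cytosine on both strands (reference C on `+`, reference G on
#' `-`) and classifies its context.
#'
#' @param genome Named character vector of chromosome sequences.
#' @return data.frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `trinucleotide`, `partial`, sorted by chromosome and position.
#' @export
find_cytosines <- function(genome) {
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    ch <- names(genome)[i]
    b <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    L <- length(b)
    # pad both ends so vectorised neighbour lookups never hit index 0
    bp <- c(NA, NA, b, NA, NA)  # base at pos q is bp[q + 2]
    plus <- which(b == "C")
    minus <- which(b == "G")
    mk <- function(p, st) {
      if (length(p) == 0L) return(NULL)
      if (st == "+") {
        b2 <- bp[p + 3]; b3 <- bp[p + 4]
      } else {
        b2 <- unname(.COMP[bp[p + 1]]); b3 <- unname(.COMP[bp[p]])
      }
      cc <- .context_from_bases(b2, b3)
      data.table::data.table(
        chrom = ch, pos = p, strand = st,
        context = cc$context, trinucleotide = .tri_string(b2, b3),
        partial = cc$partial)
    }
    dt <- data.table::rbindlist(list(mk(plus, "+"), mk(minus, "-")))
    data.table::setorder(dt, pos, strand)
    out[[i]] <- dt
  }
  res <- data.table::rbindlist(out)
  data.table::setDF(res)
  res
}

#' Per-cytosine methylation level
#'
#' The methylation level of a cytosine is the number of methylated reads
#' divided by the total reads covering it. Sites with zero total coverage
#' have no defined level and return `NA` with a warning; filter them first
#' with [filter_by_coverage()].
#'
#' @param meth_count,unmeth_count Non-negative read counts (vectorised).
#' @return Numeric vector of levels in `[0, 1]` (`NA` where total is 0).
#' @examples
#' methylation_level(3, 7)  # 0.3
#' @export
methylation_level <- function(meth_count, unmeth_count) {
  if (any(meth_count < 0) || any(unmeth_count < 0))
    stop("read counts must be non-negative")
  tot <- meth_count + unmeth_count
  if (any(tot == 0))
    warning("level undefined at ", sum(tot == 0),
            " site(s) with zero coverage; returning NA")
  ifelse(tot > 0, meth_count / tot, NA_real_)
}

.CX_COLS <- c("chrom", "pos", "strand", "meth", "unmeth",
              "context", "trinucleotide")

#' Write a cytosine report (Bismark-CX-style TSV)
#'
#' Columns (no header): chrom, 1-based position, strand, methylated count,
#' unmethylated count, context, trinucleotide.
#'
#' @param calls data.frame of methylation calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  stopifnot(all(.CX_COLS %in% names(calls)))
  data.table::fwrite(calls[, .CX_COLS], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cytosine report (Bismark-CX-style TSV)
#'
#' Parses the 7-column dialect written by [write_cytosine_report()] and
#' re-validates each line's context against its trinucleotide column;
#' malformed lines are reported with their line numbers.
#'
#' @param path Path to the TSV (no header).
#' @return data.frame of methylation calls (`chrom`, `pos`, `strand`,
#'   `meth`, `unmeth`, `context`, `trinucleotide`).
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty cytosine report: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer(), context = character(),
                      trinucleotide = character(), stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 3, 6, 7),
                                            numeric = c(2, 4, 5)),
                          showProgress = FALSE)
  if (ncol(dt) != 7L)
    stop("cytosine report must have 7 columns, found ", ncol(dt))
  data.table::setnames(dt, .CX_COLS)
  bad_line <- function(cond, what) {
    if (any(cond)) stop("cytosine report ", path, ": ", what,
                        " at line(s) ", paste(head(which(cond), 5), collapse = ", "))
  }
  bad_line(!dt$strand %in% c("+", "-"), "unknown strand symbol")
  bad_line(is.na(dt$pos) | dt$pos < 1 | dt$pos != round(dt$pos),
           "position not a positive integer")
  bad_line(is.na(dt$meth) | is.na(dt$unmeth) |
             dt$meth < 0 | dt$unmeth < 0 |
             dt$meth != round(dt$meth) | dt$unmeth != round(dt$unmeth),
           "count columns must be non-negative integers")
  bad_line(!dt$context %in% METH_CONTEXTS, "unknown context")
  # context/trinucleotide consistency where the trinucleotide is complete
  tri <- dt$trinucleotide
  b2 <- substring(tri, 2, 2); b3 <- substring(tri, 3, 3)
  full <- nchar(tri) == 3L
  expect <- rep(NA_character_, nrow(dt))
  expect[full] <- .context_from_bases(b2[full], b3[full])$context
  two <- nchar(tri) == 2L & b2 == "G"
  expect[two] <- "CG"
  bad_line(substring(tri, 1, 1) != "C", "trinucleotide must start with C")
  bad_line(!is.na(expect) & expect != dt$context,
           "context inconsistent with trinucleotide")
  dt$pos <- as.integer(dt$pos)
  dt$meth <- as.integer(dt$meth)
  dt$unmeth <- as.integer(dt$unmeth)
  data.table::setDF(dt)
  dt
}

#' Filter methylation calls by minimum coverage
#'
#' Retains calls with `meth + unmeth >= min_total`. Idempotent.
#'
#' @param calls data.frame of methylation calls.
#' @param min_total Minimum total reads (default 4).
#' @return Filtered data.frame.
#' @export
filter_by_coverage <- function(calls, min_total = 4) {
  stopifnot(min_total >= 1)
  calls[calls$meth + calls$unmeth >= min_total, , drop = FALSE]
}

#' Merge symmetric CpG strand pairs
#'
#' CG sites occur as strand pairs: a plus-strand cytosine at position `p`
#' faces a minus-strand cytosine at `p + 1`. This sums the read counts of
#' each pair into one call reported at the plus-strand position. CG sites are
#' kept per strand by default throughout the package; this merge is an
#' opt-in alternative. Unpaired CG sites (chromosome ends, missing mates)
#' and non-CG calls pass through unchanged.
#'
#' @param calls data.frame of methylation calls.
#' @return data.frame with merged CG calls, sorted by position.
#' @export
merge_cpg_strands <- function(calls) {
  cg <- calls$context == "CG"
  other <- calls[!cg, , drop = FALSE]
  plus <- calls[cg & calls$strand == "+", , drop = FALSE]
  minus <- calls[cg & calls$strand == "-", , drop = FALSE]
  key_p <- paste(plus$chrom, plus$pos)
  key_m <- paste(minus$chrom, minus$pos - 1L)
  im <- match(key_p, key_m)
  paired <- !is.na(im)
  merged <- plus
  merged$meth[paired] <- plus$meth[paired] + minus$meth[im[paired]]
  merged$unmeth[paired] <- plus$unmeth[paired] + minus$unmeth[im[paired]]
  lone_minus <- minus[!seq_len(nrow(minus)) %in% im[paired], , drop = FALSE]
  out <- rbind(other, merged, lone_minus)
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Genome-wide methylation summary by context
#'
#' For each context present after coverage filtering, reports the covered
#' site count, the read-weighted mean level (sum of methylated reads over
#' sum of total reads) and the unweighted site-mean level. Contexts with no
#' covered site are absent from the result, not reported as zero.
#'
#' @param calls data.frame of methylation calls.
#' @param min_total Minimum total reads per site (default 4).
#' @return data.frame with columns `context`, `n_sites`,
#'   `weighted_mean_level`, `site_mean_level`.
#' @export
genome_context_summary <- function(calls, min_total = 4) {
  calls <- filter_by_coverage(calls, min_total)
  if (nrow(calls) == 0L) stop("no calls pass the coverage filter")
  dt <- data.table::as.data.table(calls)
  res <- dt[, {
    tot <- meth + unmeth
    .(n_sites = .N,
      weighted_mean_level = sum(meth) / sum(tot),
      site_mean_level = mean(meth / tot))
  }, by = context]
  data.table::setorder(res, context)
  data.table::setDF(res)
  res
}
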