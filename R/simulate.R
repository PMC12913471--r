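# Seeded synthetic WGBS + expression data generator.
#
# All randomness flows from one master seed through named substreams
# (one per stage / sample), so each stage is independently reproducible
# and identical configs yield byte-identical output files.

.substream_seed <- function(seed, stream) {
  v <- utf8ToInt(stream)
  h <- sum(v * seq_along(v) * 1009) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Methylation landscape shape parameters
#'
#' Defines the deterministic per-context methylation landscape the simulator
#' plants: flat background levels, a bell over gene bodies (low at TSS/TTS,
#' maximal mid-body) for CG/CHG, uniform CHH over bodies with elevated CHH in
#' the 2 kb upstream (promoter) region, and high TE-body levels in all
#' contexts. Per-gene promoter levels are additionally scaled by a
#' gene-specific factor (uniform on `promoter_factor_range` via a Gaussian
#' copula) that drives the methylation--expression coupling.
#'
#' @param background Named levels (CG, CHG, CHH) outside features.
#' @param gene_body_base Gene-body level at TSS/TTS (the dip).
#' @param gene_body_amp Bell amplitude; body level is
#'   `base + amp * sin(pi * t)` at relative position `t`.
#' @param te_body TE-body levels.
#' @param chh_upstream CHH level in the 2 kb upstream of genes (before the
#'   per-gene promoter factor).
#' @param promoter_factor_range Range of the per-gene promoter scaling
#'   factor.
#' @param flank_bp Width of the shaped flank (default 2000).
#' @return List of shape parameters, class `meth_shape`.
#' @export
meth_shape <- function(background = c(CG = 0.30, CHG = 0.20, CHH = 0.05),
                       gene_body_base = c(CG = 0.08, CHG = 0.05, CHH = 0.05),
                       gene_body_amp = c(CG = 0.37, CHG = 0.22, CHH = 0.00),
                       te_body = c(CG = 0.80, CHG = 0.65, CHH = 0.25),
                       chh_upstream = 0.15,
                       promoter_factor_range = c(0.3, 1.7),
                       flank_bp = 2000) {
  s <- list(background = background, gene_body_base = gene_body_base,
            gene_body_amp = gene_body_amp, te_body = te_body,
            chh_upstream = chh_upstream,
            promoter_factor_range = promoter_factor_range,
            flank_bp = flank_bp)
  for (nm in c("background", "gene_body_base", "gene_body_amp", "te_body"))
    stopifnot(identical(names(s[[nm]]), METH_CONTEXTS))
  if (any(unlist(s[c("background", "gene_body_base", "te_body")]) < 0) ||
      any(s$background > 1) || any(s$te_body > 1))
    stop("shape levels must lie in [0,1]")
  class(s) <- "meth_shape"
  s
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic WGBS + expression
#' experiment: genome size and composition, feature counts, sequencing
#' coverage and error rates, the two-group replicated design, planted-DMR
#' effect, and the methylation--expression coupling.
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_chrom,chrom_length_bp Number and length of chromosomes.
#' @param gc_fraction GC content of the simulated genome.
#' @param n_genes,n_tes Feature counts.
#' @param gene_length_bp_mean,te_length_bp_mean Mean feature lengths.
#' @param coverage_mean Mean per-site read depth (Poisson).
#' @param non_conversion_rate Fraction of unmethylated cytosines escaping
#'   bisulfite conversion (false-methylation noise).
#' @param seq_error_rate Rate at which methylated cytosines read as
#'   converted (includes sequencing error).
#' @param n_samples_per_group Replicates per condition.
#' @param dmr_effect Length-2 true levels `(level_A, level_B)` inside
#'   planted DMRs.
#' @param n_planted_dmrs Number of planted DMR windows.
#' @param dmr_min_sites Minimum context sites a planted DMR window must
#'   contain.
#' @param dmr_width_bp Width of planted DMR windows (aligned to the default
#'   analysis window grid).
#' @param dmr_context Context of planted DMRs.
#' @param expression_coupling_rho Target Pearson correlation (in `[-1, 0]`)
#'   between latent log2 expression and true promoter methylation.
#' @param nb_dispersion Negative-binomial dispersion of expression counts
#'   (`0` gives Poisson counts).
#' @param library_size_fragments Expected total fragments per sample.
#' @param shape A [meth_shape()] object.
#' @return List of validated parameters, class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length_bp = 500000L,
                       gc_fraction = 0.44,
                       n_genes = 80L,
                       n_tes = 40L,
                       gene_length_bp_mean = 2000L,
                       te_length_bp_mean = 1000L,
                       coverage_mean = 30,
                       non_conversion_rate = 0.005,
                       seq_error_rate = 0.001,
                       n_samples_per_group = 3L,
                       dmr_effect = c(0.6, 0.15),
                       n_planted_dmrs = 200L,
                       dmr_min_sites = 8L,
                       dmr_width_bp = 200L,
                       dmr_context = "CG",
                       expression_coupling_rho = -0.5,
                       nb_dispersion = 0.05,
                       library_size_fragments = 2e6,
                       shape = meth_shape()) {
  cfg <- as.list(environment())
  frac <- c(gc_fraction = gc_fraction,
            non_conversion_rate = non_conversion_rate,
            seq_error_rate = seq_error_rate)
  if (any(frac < 0 | frac > 1))
    stop("rates/fractions must lie in [0,1]: ",
         paste(names(frac)[frac < 0 | frac > 1], collapse = ", "))
  if (any(dmr_effect < 0 | dmr_effect > 1))
    stop("dmr_effect levels must lie in [0,1]")
  pos <- c(n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
           n_samples_per_group = n_samples_per_group,
           gene_length_bp_mean = gene_length_bp_mean,
           te_length_bp_mean = te_length_bp_mean,
           dmr_width_bp = dmr_width_bp, dmr_min_sites = dmr_min_sites,
           library_size_fragments = library_size_fragments)
  if (any(pos <= 0))
    stop("lengths and counts must be positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  if (n_genes < 0 || n_tes < 0 || n_planted_dmrs < 0 ||
      coverage_mean < 0 || nb_dispersion < 0)
    stop("counts, coverage and dispersion must be non-negative")
  if (abs(expression_coupling_rho) > 1)
    stop("expression_coupling_rho must lie in [-1,1]")
  if (!dmr_context %in% METH_CONTEXTS) stop("unknown dmr_context")
  stopifnot(inherits(shape, "meth_shape"))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$n_chrom, " x ", x$chrom_length_bp, " bp, ",
      x$n_genes, " genes / ", x$n_tes, " TEs, ",
      x$n_planted_dmrs, " planted ", x$dmr_context, " DMRs (",
      x$dmr_effect[1], " vs ", x$dmr_effect[2], "), coverage ",
      x$coverage_mean, ", ", x$n_samples_per_group,
      " replicates/group, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a reference genome
#'
#' Draws i.i.d. bases with the configured GC fraction.
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences
#'   (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "genome"))
  gc <- config$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- vapply(seq_len(config$n_chrom), function(i) {
    paste(sample(names(p), config$chrom_length_bp, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(g) <- paste0("chr", seq_len(config$n_chrom))
  g
}

# place n non-overlapping intervals of given lengths inside [lo, hi)
# with at least min_gap bp between them; random positions via stick-breaking
.place_intervals <- function(lengths, lo, hi, min_gap) {
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  span <- hi - lo
  need <- sum(lengths) + (n - 1) * min_gap
  if (need > span)
    stop("placement error: cannot fit ", n, " features (",
         need, " bp incl. gaps) into ", span, " bp")
  slack <- span - need
  extra <- diff(c(0, sort(runif(n, 0, slack)))) # n extra gaps >= 0
  starts <- lo + cumsum(extra) +
    cumsum(c(0, lengths[-n] + min_gap))
  as.integer(floor(starts))
}

#' Simulate a gene/TE annotation
#'
#' Places non-overlapping genes and transposable elements, each with at
#' least 2 kb clearance from chromosome ends (so full 2 kb flanks exist).
#' Genes carry a strand and 1--3 exons; TEs carry a strand only.
#'
#' @param genome Named character vector (from [simulate_genome()]).
#' @param config A [sim_config()].
#' @return List with data.frames `features` (`chrom`, `start`, `end`
#'   0-based half-open, `strand`, `type` in gene/TE, `feature_id`) and
#'   `exons` (`feature_id`, `exon_id`, `chrom`, `start`, `end`, `strand`),
#'   class `annotation`.
#' @export
simulate_annotation <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"), length(genome) > 0)
  set.seed(.substream_seed(config$seed, "annotation"))
  min_gap <- 600L
  chroms <- names(genome)
  spans <- vapply(genome, nchar, integer(1)) - 4000L
  if (any(spans <= 0)) stop("placement error: chromosomes shorter than 4 kb")
  n_feat <- config$n_genes + config$n_tes
  # proportional allocation of features to chromosomes (largest remainder)
  quota <- n_feat * spans / sum(spans)
  n_per <- floor(quota)
  rem <- n_feat - sum(n_per)
  if (rem > 0) {
    o <- order(quota - n_per, decreasing = TRUE)
    n_per[o[seq_len(rem)]] <- n_per[o[seq_len(rem)]] + 1L
  }
  type <- sample(rep(c("gene", "TE"), c(config$n_genes, config$n_tes)))
  glen <- function(n, mean_bp, min_bp)
    pmin(as.integer(3 * mean_bp),
         pmax(min_bp, as.integer(round(rgamma(n, shape = 6, scale = mean_bp / 6)))))
  feats <- vector("list", length(chroms))
  k <- 0L
  for (i in seq_along(chroms)) {
    ni <- n_per[i]
    if (ni == 0L) next
    ty <- type[(k + 1):(k + ni)]
    k <- k + ni
    len <- integer(ni)
    len[ty == "gene"] <- glen(sum(ty == "gene"), config$gene_length_bp_mean, 500L)
    len[ty == "TE"] <- glen(sum(ty == "TE"), config$te_length_bp_mean, 200L)
    starts <- .place_intervals(len, 2000L, nchar(genome[[i]]) - 2000L, min_gap)
    feats[[i]] <- data.frame(
      chrom = chroms[i], start = starts, end = starts + len,
      strand = sample(c("+", "-"), ni, replace = TRUE),
      type = ty, stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  if (is.null(features))
    features <- data.frame(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           type = character(), stringsAsFactors = FALSE)
  features$feature_id <- ifelse(features$type == "gene",
                                sprintf("gene%04d", cumsum(features$type == "gene")),
                                sprintf("te%04d", cumsum(features$type == "TE")))
  # exons: split each gene body into alternating exon/intron segments
  ex <- list()
  gi <- which(features$type == "gene")
  for (j in gi) {
    len <- features$end[j] - features$start[j]
    kx <- sample(seq_len(max(1L, min(3L, len %/% 300L))), 1L)
    nseg <- 2L * kx - 1L
    seg <- rep(80L, nseg)
    seg <- seg + as.integer(rmultinom(1, len - sum(seg), rep(1, nseg)))
    bnd <- features$start[j] + cumsum(c(0L, seg))
    exon_rows <- seq(1L, nseg, by = 2L)
    ex[[length(ex) + 1L]] <- data.frame(
      feature_id = features$feature_id[j],
      exon_id = paste0(features$feature_id[j], ".e", seq_along(exon_rows)),
      chrom = features$chrom[j],
      start = bnd[exon_rows], end = bnd[exon_rows + 1L],
      strand = features$strand[j], stringsAsFactors = FALSE)
  }
  exons <- if (length(ex)) do.call(rbind, ex) else
    data.frame(feature_id = character(), exon_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  structure(list(features = features, exons = exons), class = "annotation")
}

#' Write an annotation as GFF3 (genes + exons) and BED6 (TEs)
#'
#' @param annotation An `annotation` object.
#' @param gff3_path,bed_path Output paths.
#' @return Invisible list of the paths written.
#' @export
write_annotation <- function(annotation, gff3_path, bed_path) {
  f <- annotation$features
  genes <- f[f$type == "gene", , drop = FALSE]
  tes <- f[f$type == "TE", , drop = FALSE]
  ex <- annotation$exons
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end), strand = genes$strand)
  S4Vectors::mcols(gr_gene)$type <- "gene"
  S4Vectors::mcols(gr_gene)$ID <- genes$feature_id
  gr_ex <- GenomicRanges::GRanges(ex$chrom,
    IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand)
  if (length(gr_ex)) {
    S4Vectors::mcols(gr_ex)$type <- "exon"
    S4Vectors::mcols(gr_ex)$ID <- ex$exon_id
    S4Vectors::mcols(gr_ex)$Parent <- ex$feature_id
  }
  gr <- if (length(gr_ex)) suppressWarnings(c(gr_gene, gr_ex)) else gr_gene
  rtracklayer::export(gr, gff3_path, format = "gff3")
  gr_te <- GenomicRanges::GRanges(tes$chrom,
    IRanges::IRanges(tes$start + 1L, tes$end), strand = tes$strand)
  S4Vectors::mcols(gr_te)$name <- tes$feature_id
  S4Vectors::mcols(gr_te)$score <- 0L
  rtracklayer::export(gr_te, bed_path, format = "bed")
  invisible(list(gff3 = gff3_path, bed = bed_path))
}

#' Read an annotation from GFF3 (genes + exons) and optional BED6 (TEs)
#'
#' @param gff3_path GFF3 with `gene` and `exon` records (exons carrying
#'   `Parent`).
#' @param bed_path Optional BED6 of TE intervals.
#' @return An `annotation` object (0-based half-open coordinates).
#' @export
read_annotation <- function(gff3_path, bed_path = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  is_gene <- as.character(m$type) == "gene"
  is_exon <- as.character(m$type) == "exon"
  features <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    type = "gene",
    feature_id = as.character(m$ID[is_gene]),
    stringsAsFactors = FALSE)
  parent <- m$Parent[is_exon]
  parent <- vapply(as.list(parent), function(p) as.character(p)[1], character(1))
  exons <- data.frame(
    feature_id = parent,
    exon_id = as.character(m$ID[is_exon]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_exon]),
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    strand = as.character(GenomicRanges::strand(gr)[is_exon]),
    stringsAsFactors = FALSE)
  if (!is.null(bed_path)) {
    b <- rtracklayer::import(bed_path, format = "bed")
    te <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(b)),
      start = GenomicRanges::start(b) - 1L,
      end = GenomicRanges::end(b),
      strand = as.character(GenomicRanges::strand(b)),
      type = "TE",
      feature_id = S4Vectors::mcols(b)$name,
      stringsAsFactors = FALSE)
    te$strand[te$strand == "*"] <- "+"
    features <- rbind(features, te)
  }
  structure(list(features = features, exons = exons), class = "annotation")
}

# overlap helper: sites (1-based pos) vs intervals (0-based half-open)
# returns data.table(site = site row index, ivl = interval row index)
.site_overlaps <- function(sites, ivl) {
  if (nrow(ivl) == 0L || nrow(sites) == 0L)
    return(data.table::data.table(site = integer(), ivl = integer()))
  gr_s <- GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(sites$pos, width = 1L))
  gr_i <- GenomicRanges::GRanges(ivl$chrom,
    IRanges::IRanges(ivl$start + 1L, pmax(ivl$start + 1L, ivl$end)))
  h <- GenomicRanges::findOverlaps(gr_s, gr_i)
  dt <- data.table::data.table(site = S4Vectors::queryHits(h),
                               ivl = S4Vectors::subjectHits(h))
  # empty (zero-width) intervals contain no site
  keep <- ivl$end[dt$ivl] > ivl$start[dt$ivl]
  dt[keep]
}

# strand-aware flank intervals (0-based half-open), clipped at [0, chrom len]
.flank_intervals <- function(features, chrom_lengths, flank_bp, side) {
  up <- (side == "upstream") == (features$strand == "+")
  start <- ifelse(up, features$start - flank_bp, features$end)
  end <- ifelse(up, features$start, features$end + flank_bp)
  L <- chrom_lengths[features$chrom]
  data.frame(chrom = features$chrom,
             start = pmax(0L, as.integer(start)),
             end = pmin(as.integer(L), as.integer(end)),
             feature_id = features$feature_id,
             stringsAsFactors = FALSE)
}

#' Assign true methylation levels to every cytosine
#'
#' Builds the ground-truth methylation landscape for two conditions: a
#' context-specific background, CG/CHG bells over gene bodies with dips at
#' TSS/TTS, elevated CHH in the 2 kb upstream of genes, high TE-body levels,
#' a per-gene promoter scaling factor (the handle for expression coupling),
#' and `n_planted_dmrs` intergenic windows where the two conditions get the
#' configured `dmr_effect` levels. Outside planted DMRs the two conditions
#' share levels.
#'
#' @param genome Named character vector.
#' @param annotation An `annotation` object.
#' @param config A [sim_config()].
#' @return List with `sites` (cytosine table with `level_A`, `level_B`),
#'   `dmrs` (planted windows with context, levels, direction, n_sites),
#'   `genes` (per-gene promoter factor and true promoter methylation),
#'   class `meth_truth`.
#' @export
assign_true_methylation <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  shape <- config$shape
  set.seed(.substream_seed(config$seed, "truth"))
  sites <- find_cytosines(genome)
  n <- nrow(sites)
  lvl <- unname(shape$background[sites$context])
  feats <- annotation$features
  genes <- feats[feats$type == "gene", , drop = FALSE]
  tes <- feats[feats$type == "TE", , drop = FALSE]
  chrom_lengths <- vapply(genome, nchar, integer(1))
  fb <- shape$flank_bp

  # per-gene promoter factor via Gaussian copula handle z_i
  z <- rnorm(nrow(genes))
  pf_rng <- shape$promoter_factor_range
  pf <- pf_rng[1] + (pf_rng[2] - pf_rng[1]) * pnorm(z)

  # 1) gene flanks (ramps), 2) gene bodies, 3) TE bodies, 4) planted DMRs --
  # later assignments overwrite earlier ones where regions collide.
  if (nrow(genes)) {
    upstream <- .flank_intervals(genes, chrom_lengths, fb, "upstream")
    downstream <- .flank_intervals(genes, chrom_lengths, fb, "downstream")
    ov_up <- .site_overlaps(sites, upstream)
    if (nrow(ov_up)) {
      g <- ov_up$ivl
      p0 <- sites$pos[ov_up$site] - 1L
      d <- ifelse(genes$strand[g] == "+",
                  genes$start[g] - p0, p0 - genes$end[g] + 1L)
      rel <- d / fb                       # 0 at TSS, 1 far upstream
      ctx <- sites$context[ov_up$site]
      base <- shape$gene_body_base[ctx]
      bg <- shape$background[ctx]
      v <- base + (bg - base) * rel       # CG/CHG ramp into the TSS dip
      v[ctx == "CHH"] <- shape$chh_upstream
      lvl[ov_up$site] <- .clamp01(v * pf[g])
    }
    ov_dn <- .site_overlaps(sites, downstream)
    if (nrow(ov_dn)) {
      g <- ov_dn$ivl
      p0 <- sites$pos[ov_dn$site] - 1L
      d <- ifelse(genes$strand[g] == "+",
                  p0 - genes$end[g] + 1L, genes$start[g] - p0)
      rel <- d / fb
      ctx <- sites$context[ov_dn$site]
      base <- shape$gene_body_base[ctx]
      bg <- shape$background[ctx]
      v <- base + (bg - base) * rel       # ramp back up from the TTS dip
      v[ctx == "CHH"] <- bg[ctx == "CHH"] # CHH: no downstream enrichment
      lvl[ov_dn$site] <- .clamp01(v)
    }
    ov_b <- .site_overlaps(sites, genes)
    if (nrow(ov_b)) {
      g <- ov_b$ivl
      p0 <- sites$pos[ov_b$site] - 1L
      t <- (p0 - genes$start[g] + 0.5) / (genes$end[g] - genes$start[g])
      t[genes$strand[g] == "-"] <- 1 - t[genes$strand[g] == "-"]
      ctx <- sites$context[ov_b$site]
      v <- shape$gene_body_base[ctx] + shape$gene_body_amp[ctx] * sin(pi * t)
      lvl[ov_b$site] <- .clamp01(v)
    }
  }
  if (nrow(tes)) {
    ov_t <- .site_overlaps(sites, tes)
    if (nrow(ov_t))
      lvl[ov_t$site] <- unname(shape$te_body[sites$context[ov_t$site]])
  }
  level_A <- lvl
  level_B <- lvl

  # planted DMRs: grid-aligned intergenic windows with enough context sites
  dmrs <- data.frame(chrom = character(), start = integer(), end = integer(),
                     context = character(), level_A = numeric(),
                     level_B = numeric(), direction = character(),
                     n_sites = integer(), stringsAsFactors = FALSE)
  if (config$n_planted_dmrs > 0) {
    w <- config$dmr_width_bp
    grid <- do.call(rbind, lapply(names(genome), function(ch) {
      st <- seq(0L, chrom_lengths[[ch]] - w, by = w)
      data.frame(chrom = ch, start = st, end = st + w,
                 stringsAsFactors = FALSE)
    }))
    # exclude windows near any feature (feature +/- flank)
    if (nrow(feats)) {
      excl <- data.frame(chrom = feats$chrom,
                         start = pmax(0L, feats$start - fb),
                         end = feats$end + fb, stringsAsFactors = FALSE)
      gr_g <- GenomicRanges::GRanges(grid$chrom,
        IRanges::IRanges(grid$start + 1L, grid$end))
      gr_e <- GenomicRanges::GRanges(excl$chrom,
        IRanges::IRanges(excl$start + 1L, excl$end))
      hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_g, gr_e)))
      if (length(hit)) grid <- grid[-hit, , drop = FALSE]
    }
    ctx_sites <- sites[sites$context == config$dmr_context, , drop = FALSE]
    ov <- .site_overlaps(ctx_sites, grid)
    cnt <- tabulate(ov$ivl, nbins = nrow(grid))
    ok <- which(cnt >= config$dmr_min_sites)
    if (length(ok) < config$n_planted_dmrs)
      stop("placement error: only ", length(ok), " intergenic windows with >= ",
           config$dmr_min_sites, " ", config$dmr_context,
           " sites; cannot plant ", config$n_planted_dmrs, " DMRs")
    pick <- sort(sample(ok, config$n_planted_dmrs))
    grid_pick <- grid[pick, , drop = FALSE]
    sel <- ov$site[ov$ivl %in% pick]
    # ov$site indexes rows of the context subset; map back to all sites
    idx_ctx <- which(sites$context == config$dmr_context)
    gsel <- idx_ctx[sel]
    level_A[gsel] <- config$dmr_effect[1]
    level_B[gsel] <- config$dmr_effect[2]
    dmrs <- data.frame(
      chrom = grid_pick$chrom, start = grid_pick$start, end = grid_pick$end,
      context = config$dmr_context,
      level_A = config$dmr_effect[1], level_B = config$dmr_effect[2],
      direction = if (config$dmr_effect[1] > config$dmr_effect[2]) "gain" else "loss",
      n_sites = cnt[pick], stringsAsFactors = FALSE)
  }

  # per-gene true promoter methylation (mean true level over upstream sites)
  gene_truth <- data.frame(feature_id = character(), z = numeric(),
                           promoter_factor = numeric(),
                           promoter_meth = numeric(),
                           promoter_meth_CG = numeric(),
                           promoter_meth_CHG = numeric(),
                           promoter_meth_CHH = numeric(),
                           stringsAsFactors = FALSE)
  if (nrow(genes)) {
    upstream <- .flank_intervals(genes, chrom_lengths, fb, "upstream")
    ov_up <- .site_overlaps(sites, upstream)
    pm <- function(keep) {
      s <- ov_up[keep]
      v <- rep(NA_real_, nrow(genes))
      if (nrow(s)) {
        agg <- s[, .(m = mean(level_A[site])), by = ivl]
        v[agg$ivl] <- agg$m
      }
      v
    }
    ctx_of <- sites$context[ov_up$site]
    gene_truth <- data.frame(
      feature_id = genes$feature_id, z = z, promoter_factor = pf,
      promoter_meth = pm(rep(TRUE, nrow(ov_up))),
      promoter_meth_CG = pm(ctx_of == "CG"),
      promoter_meth_CHG = pm(ctx_of == "CHG"),
      promoter_meth_CHH = pm(ctx_of == "CHH"),
      stringsAsFactors = FALSE)
  }
  sites$level_A <- level_A
  sites$level_B <- level_B
  structure(list(sites = sites, dmrs = dmrs, genes = gene_truth,
                 shape = shape), class = "meth_truth")
}

# forward model of observed methylation: bisulfite non-conversion adds false
# methylation on unmethylated Cs; seq_error folds conversion of methylated Cs
.p_observed <- function(p_true, seq_error_rate, non_conversion_rate) {
  p_true * (1 - seq_error_rate) + (1 - p_true) * non_conversion_rate
}

#' Simulate per-sample cytosine methylation reports
#'
#' For every cytosine and sample, total coverage is Poisson(`coverage_mean`)
#' and the methylated count is Binomial(total, p_obs) with
#' `p_obs = p_true (1 - seq_error_rate) + (1 - p_true) non_conversion_rate`.
#' Zero-coverage sites are emitted with both counts 0.
#'
#' @param truth A `meth_truth` object.
#' @param config A [sim_config()].
#' @param out_dir Optional directory; if given, one cytosine-report TSV per
#'   sample plus a truth TSV are written there.
#' @return List with elements `A` and `B`, each a named list of per-replicate
#'   call data.frames.
#' @export
simulate_methylation_calls <- function(truth, config, out_dir = NULL) {
  stopifnot(inherits(truth, "meth_truth"), inherits(config, "sim_config"))
  sites <- truth$sites
  n <- nrow(sites)
  base <- sites[c("chrom", "pos", "strand", "context", "trinucleotide")]
  one <- function(group, rep_i) {
    set.seed(.substream_seed(config$seed, paste0("calls_", group, "_", rep_i)))
    p <- .p_observed(if (group == "A") sites$level_A else sites$level_B,
                     config$seq_error_rate, config$non_conversion_rate)
    tot <- rpois(n, config$coverage_mean)
    m <- rbinom(n, tot, p)
    df <- base
    df$meth <- m
    df$unmeth <- tot - m
    df[c("chrom", "pos", "strand", "meth", "unmeth", "context",
         "trinucleotide")]
  }
  out <- list(A = list(), B = list())
  for (group in c("A", "B"))
    for (r in seq_len(config$n_samples_per_group)) {
      id <- paste0(group, "_", r)
      out[[group]][[id]] <- one(group, r)
    }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (group in c("A", "B"))
      for (id in names(out[[group]]))
        write_cytosine_report(out[[group]][[id]],
                              file.path(out_dir, paste0("sample_", id, ".cx.tsv")))
    data.table::fwrite(truth$sites, file.path(out_dir, "truth_sites.tsv"),
                       sep = "\t")
    data.table::fwrite(truth$dmrs, file.path(out_dir, "truth_dmrs.tsv"),
                       sep = "\t")
  }
  out
}

#' Simulate expression counts coupled to promoter methylation
#'
#' Draws a per-gene latent log2 expression whose Pearson correlation with
#' true promoter methylation across genes targets
#' `expression_coupling_rho` (the promoter methylation vector is
#' standardised, so the coupling is exact in expectation), then generates
#' negative-binomial fragment counts for every sample of both groups.
#'
#' @param annotation An `annotation` object.
#' @param truth A `meth_truth` object.
#' @param config A [sim_config()].
#' @param out_dir Optional directory for counts/lengths/latent TSVs.
#' @return List with `counts` (gene x sample integer matrix),
#'   `gene_lengths` (named, summed exon bp), `latent` (per-gene latent
#'   log2 expression and promoter methylation).
#' @export
simulate_expression <- function(annotation, truth, config, out_dir = NULL) {
  stopifnot(inherits(truth, "meth_truth"), inherits(config, "sim_config"))
  rho <- config$expression_coupling_rho
  if (abs(rho) > 1) stop("|rho| > 1")
  g <- truth$genes
  if (nrow(g) == 0L) stop("no genes to simulate expression for")
  set.seed(.substream_seed(config$seed, "expression"))
  p <- g$promoter_meth
  p[is.na(p)] <- mean(p, na.rm = TRUE)
  zp <- as.numeric(scale(p))
  if (any(!is.finite(zp))) zp <- rep(0, length(p))  # constant promoters
  eps <- rnorm(length(p))
  latent <- 3 + 2 * (rho * zp + sqrt(1 - rho^2) * eps)
  ex <- annotation$exons
  len <- tapply(ex$end - ex$start, ex$feature_id, sum)
  gene_lengths <- as.integer(len[g$feature_id])
  names(gene_lengths) <- g$feature_id
  wgt <- 2^latent * gene_lengths / 1000
  mu <- config$library_size_fragments * wgt / sum(wgt)
  samples <- paste0(rep(c("A", "B"), each = config$n_samples_per_group), "_",
                    rep(seq_len(config$n_samples_per_group), 2))
  counts <- sapply(samples, function(s) {
    if (config$nb_dispersion < 1e-8) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  })
  rownames(counts) <- g$feature_id
  latent_df <- data.frame(feature_id = g$feature_id, latent_log2 = latent,
                          promoter_meth = g$promoter_meth,
                          stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cdf <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    data.table::fwrite(cdf, file.path(out_dir, "counts.tsv"), sep = "\t")
    data.table::fwrite(data.frame(gene_id = names(gene_lengths),
                                  length_bp = gene_lengths),
                       file.path(out_dir, "gene_lengths.tsv"), sep = "\t")
    data.table::fwrite(latent_df, file.path(out_dir, "truth_expression.tsv"),
                       sep = "\t")
  }
  list(counts = counts, gene_lengths = gene_lengths, latent = latent_df)
}

#' Simulate a complete two-condition WGBS + expression experiment
#'
#' Runs the whole generator: genome, annotation, methylation truth with
#' planted DMRs, per-sample cytosine reports for both conditions, and
#' coupled expression counts. With `out_dir` set, writes FASTA, GFF3, BED,
#' per-sample cytosine reports, count/length tables and all truth tables.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List with `config`, `genome`, `annotation`, `truth`, `calls`
#'   (groups A/B), `expression`; class `wgbs_experiment`.
#' @export
simulate_wgbs_experiment <- function(config = sim_config(), out_dir = NULL) {
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(genome, config)
  truth <- assign_true_methylation(genome, annotation, config)
  calls <- simulate_methylation_calls(truth, config, out_dir)
  expression <- if (config$n_genes > 0)
    simulate_expression(annotation, truth, config, out_dir) else NULL
  if (!is.null(out_dir)) {
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
    write_annotation(annotation, file.path(out_dir, "annotation.gff3"),
                     file.path(out_dir, "tes.bed"))
  }
  structure(list(config = config, genome = genome, annotation = annotation,
                 truth = truth, calls = calls, expression = expression),
            class = "wgbs_experiment")
}

#' @export
print.wgbs_experiment <- function(x, ...) {
  cat("Synthetic WGBS experiment\n")
  print(x$config)
  cat("  cytosine sites: ", nrow(x$truth$sites),
      "; planted DMRs: ", nrow(x$truth$dmrs), "\n", sep = "")
  invisible(x)
}

#' Simulate a multi-sample panel with per-sample methylation--expression
#' coupling
#'
#' A single-condition panel of `n_samples` samples in which each gene's
#' promoter methylation fluctuates across samples and its expression is
#' coupled to that fluctuation through a Gaussian copula with correlation
#' `rho`, while gene-body (exon) methylation fluctuates independently of
#' expression. This is the design for per-gene correlation analysis across
#' samples: the expected promoter coefficient is `rho` (attenuated only by
#' counting noise) and the expected exon coefficient is 0.
#'
#' @param config A [sim_config()] (its `expression_coupling_rho` is the
#'   default `rho`).
#' @param n_samples Number of samples in the panel.
#' @param rho Target per-gene correlation across samples.
#' @param meth_sd Across-sample SD of the promoter methylation shift.
#' @param body_sd Across-sample SD of the (independent) gene-body shift.
#' @param expr_sd Across-sample SD of latent log2 expression.
#' @return List with `genome`, `annotation`, `truth`, `calls` (one per
#'   sample), `counts`, `gene_lengths`, `latent` (gene x sample),
#'   `z_meth` (gene x sample promoter copula variable).
#' @export
simulate_coupled_panel <- function(config, n_samples = 20,
                                   rho = config$expression_coupling_rho,
                                   meth_sd = 0.12, body_sd = 0.05,
                                   expr_sd = 1.0) {
  stopifnot(inherits(config, "sim_config"), abs(rho) <= 1, n_samples >= 3)
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(genome, config)
  truth <- assign_true_methylation(genome, annotation, config)
  sites <- truth$sites
  genes <- annotation$features[annotation$features$type == "gene", , drop = FALSE]
  chrom_lengths <- vapply(genome, nchar, integer(1))
  fb <- config$shape$flank_bp
  upstream <- .flank_intervals(genes, chrom_lengths, fb, "upstream")
  ov_up <- .site_overlaps(sites, upstream)
  ov_body <- .site_overlaps(sites, genes)
  ng <- nrow(genes)
  set.seed(.substream_seed(config$seed, "panel"))
  z_meth <- matrix(rnorm(ng * n_samples), ng, n_samples)
  w_body <- matrix(rnorm(ng * n_samples), ng, n_samples)
  eps <- matrix(rnorm(ng * n_samples), ng, n_samples)
  mu_gene <- 3 + 1.5 * rnorm(ng)
  latent <- mu_gene + expr_sd * (rho * z_meth + sqrt(1 - rho^2) * eps)
  ex <- annotation$exons
  len <- tapply(ex$end - ex$start, ex$feature_id, sum)
  gene_lengths <- as.integer(len[genes$feature_id])
  names(gene_lengths) <- genes$feature_id
  base_lvl <- sites$level_A
  nsite <- nrow(sites)
  base_cols <- sites[c("chrom", "pos", "strand", "context", "trinucleotide")]
  calls <- vector("list", n_samples)
  counts <- matrix(0L, ng, n_samples,
                   dimnames = list(genes$feature_id,
                                   paste0("S", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    set.seed(.substream_seed(config$seed, paste0("panel_sample_", s)))
    lvl <- base_lvl
    if (nrow(ov_up))
      lvl[ov_up$site] <- lvl[ov_up$site] + meth_sd * z_meth[ov_up$ivl, s]
    if (nrow(ov_body))
      lvl[ov_body$site] <- lvl[ov_body$site] + body_sd * w_body[ov_body$ivl, s]
    lvl <- .clamp01(lvl)
    p <- .p_observed(lvl, config$seq_error_rate, config$non_conversion_rate)
    tot <- rpois(nsite, config$coverage_mean)
    m <- rbinom(nsite, tot, p)
    df <- base_cols
    df$meth <- m
    df$unmeth <- tot - m
    calls[[s]] <- df[c("chrom", "pos", "strand", "meth", "unmeth",
                       "context", "trinucleotide")]
    wgt <- 2^latent[, s] * gene_lengths / 1000
    mu <- config$library_size_fragments * wgt / sum(wgt)
    counts[, s] <- if (config$nb_dispersion < 1e-8) rpois(ng, mu)
      else rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
  }
  names(calls) <- colnames(counts)
  list(genome = genome, annotation = annotation, truth = truth,
       calls = calls, counts = counts, gene_lengths = gene_lengths,
       latent = latent, z_meth = z_meth)
}
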