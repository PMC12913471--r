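# Metagene methylation profiles: mean level per context across scaled
# feature bodies and fixed-width flanks, optionally stratified by
# expression rank. Bin 0 conventions: bin 1 is always the far 5' upstream
# bin along the direction of transcription; TSS sits between the upstream
# and body zones, TTS between body and downstream.

#' Binning scheme for metagene profiles
#'
#' @param flank_bp Flank width in bp (default 2000, i.e. +/- 2 kb).
#' @param n_flank_bins Bins per flank (must divide `flank_bp`).
#' @param n_body_bins Bins across the scaled feature body.
#' @return List with the (validated) scheme, class `bin_scheme`.
#' @export
bin_scheme <- function(flank_bp = 2000L, n_flank_bins = 20L,
                       n_body_bins = 60L) {
  stopifnot(flank_bp >= 1, n_flank_bins >= 1, n_body_bins >= 1)
  if (flank_bp %% n_flank_bins != 0)
    stop("flank_bp must be divisible by n_flank_bins")
  structure(list(flank_bp = as.integer(flank_bp),
                 n_flank_bins = as.integer(n_flank_bins),
                 n_body_bins = as.integer(n_body_bins)),
            class = "bin_scheme")
}

# bins for one feature; start/end 0-based half-open, bin_index 1-based along
# the transcription direction
.feature_bins <- function(chrom, start, end, strand, scheme, chrom_length) {
  fw <- scheme$flank_bp %/% scheme$n_flank_bins
  nf <- scheme$n_flank_bins
  nb <- scheme$n_body_bins
  L <- end - start
  bb <- start + floor((0:nb) * L / nb)  # body boundaries, fractional floored
  if (strand == "+") {
    up_s <- start - scheme$flank_bp + (seq_len(nf) - 1L) * fw
    body_s <- bb[-(nb + 1L)]; body_e <- bb[-1L]
    dn_s <- end + (seq_len(nf) - 1L) * fw
    starts <- c(up_s, body_s, dn_s)
    ends <- c(up_s + fw, body_e, dn_s + fw)
  } else {
    up_s <- end + scheme$flank_bp - seq_len(nf) * fw
    # mirror of the plus-strand scheme: bin i from the TSS (at `end`) is
    # [end - floor(iL/n), end - floor((i-1)L/n)), so profiles are exactly
    # strand-invariant despite floored fractional boundaries
    bbm <- end - floor((0:nb) * L / nb)
    body_s <- bbm[-1L]; body_e <- bbm[-(nb + 1L)]
    dn_s <- start - seq_len(nf) * fw
    starts <- c(up_s, body_s, dn_s)
    ends <- c(up_s + fw, body_e, dn_s + fw)
  }
  zone <- rep(c("upstream", "body", "downstream"), c(nf, nb, nf))
  cs <- pmax(0L, as.integer(starts))
  ce <- pmin(as.integer(chrom_length), as.integer(ends))
  absent <- ce <= cs
  data.frame(bin_index = seq_len(nf + nb + nf), zone = zone,
             chrom = chrom, start = pmin(cs, ce), end = ce,
             absent = absent, stringsAsFactors = FALSE)
}

#' Compute the bin intervals of one feature
#'
#' Splits the upstream flank into `n_flank_bins` fixed-width bins 5' of the
#' TSS, the body into `n_body_bins` equal bins (fractional boundaries
#' floored), and the downstream flank 3' of the TTS. For minus-strand
#' features the order is reversed so bin 1 is always the far 5' upstream
#' bin. Bins truncated away by chromosome ends, and zero-width body bins of
#' features shorter than `n_body_bins` bp, are marked `absent`.
#'
#' @param feature One-row data.frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param scheme A [bin_scheme()].
#' @param chrom_length Length of the feature's chromosome.
#' @return data.frame of ordered bins: `bin_index`, `zone`
#'   (upstream/body/downstream), `chrom`, `start`, `end`, `absent`.
#' @export
bin_feature <- function(feature, scheme = bin_scheme(), chrom_length) {
  b <- .feature_bins(feature$chrom, feature$start, feature$end,
                     feature$strand, scheme, chrom_length)
  if (feature$end - feature$start < scheme$n_body_bins)
    warning("feature shorter than n_body_bins; ",
            sum(b$absent[b$zone == "body"]), " empty body bin(s) marked absent")
  b
}

#' Metagene methylation profile over a feature set
#'
#' For every bin and context, the read-weighted mean level (sum of
#' methylated reads over sum of total reads; `weight = "sites"` switches to
#' the unweighted site mean) over all (feature, site) incidences assigned to
#' the bin. A site inside two overlapping features counts once per feature.
#' Bins with no covered site have `NA` level and support 0.
#'
#' @param calls Coverage-filtered methylation calls (data.frame).
#' @param features data.frame of features (`chrom`, `start`, `end`,
#'   `strand`).
#' @param scheme A [bin_scheme()].
#' @param contexts Contexts to profile.
#' @param chrom_lengths Named chromosome lengths; defaults to the maximum
#'   coordinate seen per chromosome (supply explicitly for exact
#'   end-of-chromosome handling).
#' @param weight `"reads"` (default) or `"sites"`.
#' @return data.frame (`context`, `bin_index`, `zone`, `mean_level`,
#'   `support`), class `profile_matrix`, with the scheme as attribute.
#' @export
profile_features <- function(calls, features, scheme = bin_scheme(),
                             contexts = METH_CONTEXTS,
                             chrom_lengths = NULL,
                             weight = c("reads", "sites")) {
  weight <- match.arg(weight)
  stopifnot(nrow(features) > 0)
  if (is.null(chrom_lengths)) {
    mx <- tapply(c(calls$pos, features$end),
                 c(calls$chrom, features$chrom), max)
    chrom_lengths <- mx + scheme$flank_bp
  }
  bins <- data.table::rbindlist(lapply(seq_len(nrow(features)), function(i)
    .feature_bins(features$chrom[i], features$start[i], features$end[i],
                  features$strand[i], scheme,
                  chrom_lengths[[features$chrom[i]]])))
  bins$absent_row <- bins$absent
  calls <- calls[calls$context %in% contexts, , drop = FALSE]
  nbin <- 2L * scheme$n_flank_bins + scheme$n_body_bins
  grid <- expand.grid(context = contexts, bin_index = seq_len(nbin),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  zone <- rep(c("upstream", "body", "downstream"),
              c(scheme$n_flank_bins, scheme$n_body_bins,
                scheme$n_flank_bins))
  grid$zone <- zone[grid$bin_index]
  live <- which(!bins$absent)
  ov <- .site_overlaps(calls, as.data.frame(bins[live, ]))
  if (nrow(ov) == 0L) {
    warning("no covered site falls in any feature bin")
    grid$mean_level <- NA_real_
    grid$support <- 0L
  } else {
    dt <- data.table::data.table(
      context = calls$context[ov$site],
      bin_index = bins$bin_index[live[ov$ivl]],
      meth = calls$meth[ov$site],
      total = calls$meth[ov$site] + calls$unmeth[ov$site])
    agg <- dt[, .(mean_level = if (weight == "reads") sum(meth) / sum(total)
                  else mean(meth / total),
                  support = .N),
              by = .(context, bin_index)]
    grid <- merge(grid, data.table::setDF(agg),
                  by = c("context", "bin_index"), all.x = TRUE)
    grid$support[is.na(grid$support)] <- 0L
  }
  grid <- grid[order(grid$context, grid$bin_index),
               c("context", "bin_index", "zone", "mean_level", "support")]
  rownames(grid) <- NULL
  structure(grid, class = c("profile_matrix", "data.frame"),
            scheme = scheme)
}

#' Plot a metagene profile
#'
#' One line per context over the upstream / scaled body / downstream axis,
#' with TSS and TTS marked.
#'
#' @param x A `profile_matrix`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.profile_matrix <- function(x, ...) {
  scheme <- attr(x, "scheme")
  ctxs <- unique(x$context)
  cols <- stats::setNames(seq_along(ctxs) + 1L, ctxs)
  plot(NA, xlim = range(x$bin_index),
       ylim = c(0, max(x$mean_level, na.rm = TRUE)),
       xlab = "bin (5' flank | body | 3' flank)",
       ylab = "methylation level", ...)
  for (ct in ctxs) {
    d <- x[x$context == ct, ]
    lines(d$bin_index, d$mean_level, col = cols[[ct]], lwd = 2)
  }
  abline(v = c(scheme$n_flank_bins + 0.5,
               scheme$n_flank_bins + scheme$n_body_bins + 0.5),
         lty = 2, col = "grey40")
  legend("topright", legend = ctxs, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Rank genes into expression quantile groups
#'
#' Splits genes into `n_ranks` groups of size differing by at most one.
#' `rank1` is the highest-expression group and `rank<n>` the lowest (the
#' common convention for expression-stratified methylation profiles); ties
#' are broken by stable input order.
#'
#' @param fpkm Numeric per-gene expression values (names preserved).
#' @param n_ranks Number of groups (default 4 quartiles).
#' @return Factor of labels `rank1`..`rank<n>` aligned with the input.
#' @export
rank_genes_by_expression <- function(fpkm, n_ranks = 4) {
  n <- length(fpkm)
  if (n_ranks < 2) stop("n_ranks must be >= 2")
  if (n < n_ranks) stop("fewer genes (", n, ") than ranks (", n_ranks, ")")
  if (anyDuplicated(fpkm))
    warning("ties in expression values; broken by stable input order")
  sizes <- rep(n %/% n_ranks, n_ranks)
  extra <- n %% n_ranks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- paste0("rank", seq_len(n_ranks))
  o <- order(-fpkm)  # stable: ties keep input order
  lab <- rep(labels, sizes)
  out <- character(n)
  out[o] <- lab
  factor(stats::setNames(out, names(fpkm)), levels = labels)
}

#' Metagene profiles stratified by expression rank
#'
#' Computes [profile_features()] separately for each rank's genes. Empty
#' ranks are omitted with a warning.
#'
#' @param calls Coverage-filtered methylation calls.
#' @param features data.frame of genes, aligned with `ranks`.
#' @param ranks Factor from [rank_genes_by_expression()].
#' @param scheme A [bin_scheme()].
#' @param ... Passed to [profile_features()].
#' @return Named list of `profile_matrix` objects, one per rank.
#' @export
profile_by_rank <- function(calls, features, ranks, scheme = bin_scheme(),
                            ...) {
  stopifnot(nrow(features) == length(ranks))
  out <- list()
  for (lv in levels(ranks)) {
    f <- features[ranks == lv, , drop = FALSE]
    if (nrow(f) == 0L) {
      warning("rank ", lv, " holds no genes; omitted")
      next
    }
    out[[lv]] <- profile_features(calls, f, scheme, ...)
  }
  out
}
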