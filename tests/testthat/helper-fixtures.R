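# shared fixtures: tiny call tables and an independent context oracle

# independent statement of the CG/CHG/CHH rule on a full trinucleotide
oracle_context <- function(tri) {
  b2 <- substr(tri, 2, 2)
  b3 <- substr(tri, 3, 3)
  if (b2 == "G") "CG" else if (b3 == "G") "CHG" else "CHH"
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# build a calls data.frame from parallel vectors, with valid trinucleotides
make_calls <- function(chrom, pos, strand, meth, unmeth, context) {
  tri <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")[context]
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             context = context, trinucleotide = unname(tri),
             stringsAsFactors = FALSE)
}

# n CG sites evenly spaced in (start, end]; constant counts
region_calls <- function(n, meth, unmeth, start = 0, end = 200,
                         chrom = "chr1") {
  pos <- start + round(seq_len(n) * (end - start) / (n + 1))
  make_calls(chrom, pos, "+", rep(meth, n), rep(unmeth, n), rep("CG", n))
}

small_sim_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_chrom = 1L, chrom_length_bp = 120000L,
               n_genes = 8L, n_tes = 4L, n_planted_dmrs = 20L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
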