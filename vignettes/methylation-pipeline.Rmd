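---
title: "Comparative WGBS methylation analysis with expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative WGBS methylation analysis with expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`methexpr` implements a desk-scale comparative whole-genome bisulfite
sequencing (WGBS) workflow of the kind used to contrast DNA methylation
landscapes between two plant conditions (for example two developmental
stages, or a wild type and a variant), together with its integration with
gene expression:

1. **Cytosine contexts.** Every cytosine is classified by the trinucleotide
   read 5'→3' on its own strand: CG (next base G), CHG (H ∈ {A, C, T}
   followed by G), CHH (otherwise). Plants methylate all three contexts, so
   all downstream summaries are context-resolved.
2. **Methylation level.** The level of a cytosine is the number of
   methylated reads divided by the total reads covering it; pooled levels
   over a region are the ratio of the summed counts.
3. **DMR rule.** A window is a differentially methylated region (DMR)
   between two groups when it contains at least 5 covered sites of one
   context, the pooled levels differ at least 2-fold, and a two-sided
   Fisher exact test on the pooled read counts gives P ≤ 0.05. A DMR is a
   *gain* when the first group's level is higher.
4. **Metagene profiles.** Mean methylation per context over scaled gene or
   TE bodies plus fixed ±2 kb flanks, with TSS/TTS boundaries, optionally
   stratified by expression quartile.
5. **Expression integration.** FPKM quantification, a
   promoter/exon/intron/intergenic partition of the genome, per-gene pooled
   region methylation, and per-gene correlation between region methylation
   and `log2(FPKM + 1)` across samples, summarised as a fixed-break
   histogram of coefficients. A 2^−ΔΔCt helper covers relative qPCR
   quantification.

A fully seeded simulator generates the complete input set — genome,
annotation, methylation truth with planted DMRs, per-sample cytosine
reports, and coupled expression counts — so each stage is validated
against planted ground truth rather than against unavailable raw reads.

# The statistical test

For a window, reads are summed over sites (covered in *both* groups) and
over replicates within each group, giving the 2×2 table

|        | methylated | unmethylated |
|--------|-----------:|-------------:|
| group A| $m_A$      | $u_A$        |
| group B| $m_B$      | $u_B$        |

The two-sided Fisher P is computed by direct hypergeometric enumeration:
the sum of probabilities of all tables with the observed margins whose
probability does not exceed the observed table's (relative tie tolerance
1e−7). Degenerate tables (a zero row or column) return P = 1 and are
flagged. The fold change is computed on *pseudocounted* levels — one read
added to each table cell — so it is finite when one group is completely
unmethylated; the test itself always uses raw counts. This separation
avoids infinite folds without perturbing the P value.

Pooling one test per region (rather than per site) reflects how the rule
is stated; per-site testing, smoothing-based segmentation and
beta-binomial dispersion modelling are deliberately out of scope.

# Key parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `min_total` | 4 reads | per-site coverage filter; a common shallow-WGBS choice, configurable because no canonical value exists |
| window `width`, `step` | 200 bp, 200 bp | the region unit; non-overlapping tiles make counts independent across windows. Gene/TE features can be passed as regions instead |
| `min_sites`, `min_fold`, `alpha` | 5, 2, 0.05 | the DMR rule's three gates; `alpha` is inclusive (P ≤ α) |
| `p_adjust` | "none" | the rule is stated on raw P; Benjamini–Hochberg is available behind a flag |
| `flank_bp`, `n_flank_bins`, `n_body_bins` | 2000, 20, 60 | ±2 kb flanks in 100 bp bins and 60 scaled body bins; flank width matches the promoter convention below |
| `promoter_bp` | 2000 | promoter = 2 kb upstream of the TSS, strand-aware, truncated at chromosome ends and yielding to overlapping gene bodies |
| `n_ranks` | 4 | expression quartiles; `rank1` = highest expression, `rank4` = lowest. The label-to-quartile mapping is a documented package convention |
| correlation `method` | Pearson on `log2(FPKM+1)` | Spearman available; correlation is per gene across samples, requiring ≥ 3 samples and non-constant vectors |

CG sites are kept per strand by default; `merge_cpg_strands()` optionally
sums the counts of facing CpG pairs, since either convention appears in
practice.

# What the simulator emulates

`sim_config()` fixes the study conditions; all randomness flows from one
master seed through named substreams (one per stage and per sample), so
identical configurations yield byte-identical files and each stage is
independently reproducible.

* **Genome:** i.i.d. bases at 44% GC over 2 × 500 kb chromosomes — the
  scale at which the full pipeline runs in well under a minute while every
  200 bp window still holds ≈ 19 CG cytosines.
* **Annotation:** 80 genes (mean 2 kb, 1–3 exons) and 40 TEs (mean 1 kb)
  placed without overlap, each ≥ 2 kb from chromosome ends so full flanks
  exist.
* **Methylation landscape:** context backgrounds CG/CHG/CHH =
  0.30/0.20/0.05; CG and CHG bells over gene bodies
  (`base + amp · sin(πt)`, minima 0.08/0.05 at TSS and TTS, ramping back to
  background across the flanks); uniform CHH over bodies with CHH = 0.15 in
  the 2 kb upstream (promoter) region only; TE bodies at 0.80/0.65/0.25.
  These values reproduce the canonical angiosperm picture — gene-body CG
  bells with boundary dips, promoter-restricted CHH enrichment, heavily
  methylated TEs — at desk scale.
* **Planted DMRs:** 200 grid-aligned 200 bp intergenic windows (clear of
  all features ± 2 kb so they cannot confound profiles or promoters), each
  with ≥ 8 CG sites, set to true levels 0.60 vs 0.15 — a true fold change
  of 4, comfortably but not trivially above the 2-fold gate. Outside the
  planted windows the two conditions share levels exactly.
* **Counts:** per site and sample, total ~ Poisson(30) and methylated
  ~ Binomial(total, p_obs) with
  p_obs = p(1 − e) + (1 − p)c, where c = 0.005 is the bisulfite
  non-conversion rate (false methylation on unmethylated cytosines) and
  e = 0.001 folds conversion of methylated cytosines and sequencing error
  together. Three replicates per group by default — the two-group,
  replicated generalisation of a four-library design that gives the
  correlation analyses usable power.
* **Expression:** per-gene latent log2 expression coupled to true promoter
  methylation through a Gaussian copula. Two coupling modes exist because
  two different analyses need them: `simulate_expression()` couples
  *across genes* (target Pearson ρ, default −0.5, exact in expectation
  because the promoter vector is standardised before mixing), which drives
  rank-stratified profiles; `simulate_coupled_panel()` additionally lets
  each gene's promoter methylation fluctuate *across samples* (SD 0.12)
  with expression tracking it at correlation ρ, while exon methylation
  fluctuates independently (SD 0.05) — the design for per-gene
  methylation–expression correlation densities. Counts are negative
  binomial (dispersion 0.05, Poisson in the dispersion → 0 limit) at
  library size 2 × 10⁶.

**What it does not emulate:** read-level FASTQ data, alignment artefacts,
PCR duplicates, copy-number or mappability biases, correlated coverage
along the genome, chromatin-state heterogeneity, or biological replicate
variation beyond counting noise. Passing the planted-truth tests therefore
demonstrates that the *analysis logic* is correct under the stated
forward model, not that the thresholds are optimal for any real dataset.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; 1-based conversions are
  confined to readers and writers (cytosine reports, GFF3, BED).
* Fisher ties: probabilities within relative 1e−7 of the observed table's
  count as "as extreme"; the implementation agrees with exhaustive
  enumeration to < 1e−9 relative error for all margins ≤ 25.
* Sites with zero total coverage have undefined level (`NA` + warning);
  zero-support profile bins are `NA` and excluded from averages, never
  imputed.
* Chromosome-end partial trinucleotides are classified from the available
  bases (CG needs only two); ambiguous CHG-vs-CHH cases default to CHH and
  are flagged `partial`, so site counts are conserved and auditable.
* Minus-strand body bins are constructed as the exact mirror of the
  plus-strand scheme (boundaries floored from the TSS end), which makes
  profiles exactly invariant under reverse-complementing the genome.
* Expression ranking breaks ties by stable input order and warns; group
  sizes differ by at most one, with remainders going to the top ranks.
* Empty promoters (genes at chromosome edges, promoters fully covered by
  neighbouring gene bodies) are flagged with warnings and simply absent
  from the partition, which still tiles each chromosome exactly.

# Problem sizes

The validation suite runs the full pipeline on 1 Mb genomes (≈ 440,000
cytosine sites, 6 samples) for DMR recovery, and a 0.9 Mb, 200-gene,
20-sample panel for the correlation analysis — sizes chosen so that the
planted effects are estimated with small standard errors while the whole
suite completes in a few minutes on one CPU.

# Known limitations

* The Fisher test treats pooled replicate counts as one sample, so
  between-replicate overdispersion inflates significance on real data;
  the rule is implemented as stated, and users with many replicates may
  prefer dispersion-aware methods.
* FPKM is used as stated rather than TPM or model-based normalisation;
  the log2 fold-change helper is a plumbing filter, not a
  differential-expression test.
* The density summary of correlation coefficients is a fixed-break
  histogram (width 0.1 on [−1, 1]); it is deterministic, at the cost of
  the smoothness a kernel density would give.
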