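---
title: "Methods: gamete DMR calling, imprint fate tracking and methylome segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamete DMR calling, imprint fate tracking and methylome segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylfate)
library(dplyr)
```

# Scope and model

`methylfate` implements the computational core of a developmental
whole-genome bisulfite (WGBS) analysis for a species with imprinted
X-chromosome inactivation, such as a marsupial: per-CpG call processing,
a tile-based screen for gamete (sperm-versus-oocyte) differentially
methylated regions, tracking of those DMRs through embryonic stages and
adult tissues to nominate candidate imprints, change-point segmentation
of methylomes with partially-methylated-domain (PMD) detection, and
chromosome-level analyses (embryo sexing from pseudo-Y read counts,
X-versus-autosome and allele-specific methylation, expression-linked
gene-body methylation, X/A expression ratios).

The measurement model throughout is the per-CpG count pair
$(m_i, u_i)$ of methylated and unmethylated reads; the site-level
methylation estimate is $m_i / (m_i + u_i)$ and region-level estimates
pool counts before dividing. Alignment, methylation extraction and
allele splitting of reads are upstream of this package: it consumes
per-cytosine report or coverage-format text tables, including
allele-labelled ones.

# The substrate layer

`read_calls()` ingests the two standard per-cytosine dialects.
`destrand()` merges the two strand calls of a CpG dinucleotide into the
plus-strand coordinate by summing counts — total counts are conserved
exactly, and the operation is idempotent. `pool_calls()` sums counts per
site across libraries of one condition (pooling maximizes coverage in
low-input samples at the cost of sex-mixing embryo pools, which is why
fate tracking excludes the X chromosome by default). `filter_coverage()`
applies the conventional 5-read site filter *after* pooling. We report
sample means as unweighted per-site means of the site fractions, not
read-weighted means: the choice matters at uneven coverage, it matches
the percentage-matrix semantics of the common toolchains, and it is the
one that makes the histogram and the mean refer to the same population
of sites. Both the mean definition and the filter threshold are
arguments, not constants.

# The gamete DMR screen

The screen tiles the genome in fixed, non-overlapping 100-bp windows
laid from coordinate 0 (the final partial window is kept). A tile enters
testing only if it holds at least one CpG and at least 3 reads in *both*
gametes. With a single pooled library per gamete there is no replication
to estimate biological dispersion from, so the test is the two-sided
Fisher exact test on the pooled 2x2 count table — the exact analogue of
the no-replicate proportion comparison. Our implementation sums
hypergeometric point probabilities not exceeding that of the observed
table (relative comparison tolerance $10^{-12}$); a zero-margin table is
uninformative and returns $p = 1$ by convention. The test suite checks
equality against brute-force enumeration over all tables with the
observed margins and against `stats::fisher.test()`.

Multiple testing uses Benjamini–Hochberg, chosen over permutation-based
alternatives for exact reproducibility; the method name travels in the
result's attributes so downstream records are self-describing. DMRs are
tiles with $|\Delta| \ge 80$ percentage points and $q < 0.01$, labelled
by the sign of $\Delta$ (condition A minus condition B, A being the
first argument). `annotate_dmrs()` assigns one genomic class per DMR by
$\ge$ 1-bp half-open overlap with fixed precedence CGI > promoter >
intragenic > intergenic; when only gene bodies are available, promoters
are defined as the 1 kb upstream of the TSS, strand-aware.

Because a locus-level DMR spans several tiles and single tiles at
10x coverage carry only ~50–100 reads, `merge_dmrs()` fuses adjacent
same-label tiles into regions before fate tracking, bridging up to 300
bp (three consecutive interior tiles that narrowly missed a threshold);
pooled region counts then run to many hundreds of reads, which is what
makes the 40–60% intermediate band decidable.

# Fate classification

A gamete DMR whose one-allele mark survives fertilization shows
*intermediate* methylation in diploid tissue — the 40–60% band, read
inclusively at both ends. Classification is hierarchical:
E3.5 not intermediate → `not_established`; otherwise intermediate at
E7.5 embryonic disc *and* brain, liver and spleen → `lifelong` (the
candidate imprint class); otherwise the respective E7.5 lineage →
`ED_retained` / `TE_retained` (ED takes precedence, with joint retention
reported in its own `retained_both_lineages` column rather than as a
separate class); otherwise `transient_embryonic`. A stage whose pooled
coverage in the DMR is below 3 reads is treated as missing, and a
missing stage makes the clause it gates false rather than erroring —
low-input embryo pools drop out of individual regions routinely, and a
candidate imprint should not be nominated on absent evidence. Life-long
DMRs get a nearest-gene annotation (half-open gap, overlap = 0,
ties broken by smaller gene start then identifier).

# Methylome segmentation and PMDs

`segment_methylome()` divides each chromosome's ordered site fractions
into contiguous stretches of similar methylation by greedy binary
segmentation: the candidate split of a segment is the one minimizing the
within-segment sum of squared errors, accepted when both children keep
`min_seg = 5` CpGs and the Gaussian log-likelihood gain beats a
$4\log n$ penalty (a BIC-type charge for the two extra parameters *and*
the max-over-candidates selection; the plain $2\log n$ BIC
oversegments). A final coordinate-descent pass re-optimizes each
boundary between its neighbours, because a greedy first split in a
multi-change sequence can land a site or two off the joint SSE optimum;
after refinement, detected boundaries match exhaustive SSE search
exactly on the two-change-point calibration sequences in the test suite.
Segment means are then clustered into at most `max_classes = 3` classes
by a one-dimensional Gaussian mixture with G chosen by BIC (mclust),
classes are indexed by increasing mean, and adjacent same-class segments
are merged. Assembly gaps are not split automatically; a `max_gap`
parameter (suggested 10 kb, off by default) imposes breaks at larger
inter-CpG gaps, and neighbour joining never bridges such breaks.

PMDs — the long, intermediately and noisily methylated blocks
characteristic of trophectoderm and placenta — are flagged as segments
at least 100 kb long with mean methylation in 0.3–0.7. The length and
band thresholds are package defaults for the synthetic genome scale, not
published constants, and both are arguments.

# Chromosome-level analyses

**Sexing.** Embryo sex is called from pseudo-Y reads per million
(y-CPM). The threshold is estimated per batch (≥ 4 samples) as the
arithmetic midpoint of the two cluster means found by splitting the
sorted y-CPM at its largest gap; with fewer samples a fixed 1-CPM
default applies. The guard band (`guard = 0.45`) is sized from the
Poisson arithmetic of the simulator's library model so that sexed
libraries sit far outside it while a 50/50 sex-mixed pool — whose y-CPM
is about half the male level — falls inside and is flagged `ambiguous`
rather than mis-sexed.

**X methylation.** `chrom_distributions()` contrasts autosomal and
X-linked site distributions; `allele_compare()` contrasts
maternal/paternal allele tables (each filtered at 5x on its own sites).
Under imprinted XCI with a hypomethylated inactive X, the female X is an
equal mixture of a high (Xa) and a low (Xi) allele, so the female/male
X mean ratio falls below 1 — approaching one half as Xi methylation
approaches zero. Paternal-X call tables from male samples are not
meaningful (males carry a single, maternal X) and the simulator emits
none.

**Expression-linked methylation.** `classify_gene_activity()` applies
the TPM > 5 (active) / TPM ≤ 1 (inactive) rule with the (1, 5] gap
excluded; `gene_region_methylation()` pools counts per region with a
3-read floor; `escapee_methylation()` compares allele methylation of
externally labelled escapee versus subject genes among expressed
(FPKM > 1) genes; `xa_ratio()` is the median X TPM over median autosomal
TPM after dropping TPM < 1 genes, and is scale-invariant.

# The synthetic-methylome generator

Every stage above is validated against `simulate_study()`, which plants
known features and ledgers them (`sim_truth`). What it emulates, and its
defaults:

* **CpG landscape.** Geometric inter-site gaps (mean 100 bp, minimum 2
  so dinucleotides never overlap) with CpG-island blocks densified
  eight-fold. Islands are placed on autosomes, keeping the sex
  chromosomes' allele-level truth uniform for the X analyses. Real
  dinucleotide sequence structure is not modelled.
* **Counts.** Latent per-site methylation is Beta-distributed around the
  regional target with concentration θ = 100 (moderate biological
  noise; the data offer no published estimate, so this is a free
  parameter); coverage is Poisson (mean 10 per sample); methylated reads
  are binomial with bisulfite conversion error folded in as
  $p' = p + (1-p)\varepsilon$, ε = 0.005; counts split across strands
  and across the two alleles binomially (0.5).
* **Stage trajectory.** Global means follow the published developmental
  series (sperm 0.77, oocyte 0.65, E1.5 0.625, E4.5 0.64, E5.5 0.54,
  E6.5 0.45, E7.5 0.49, brain 0.72, liver 0.69, spleen 0.55). E3.5
  (0.63) is interpolated between its printed neighbours; the separate
  E7.5 embryonic-disc/trophectoderm backgrounds (0.75) are free choices
  giving PMDs (planted at 0.45) a clean contrast. Because islands are
  forced low, the non-island background is compensated per chromosome so
  each chromosome's mean *target* equals the configured global mean —
  the sample mean is then an unbiased recovery of its printed value.
  Adult panel tissues default to male; a planted inactive-X block
  necessarily lowers a female sample's genome mean below its configured
  baseline, so the X analyses use explicitly added sexed samples.
* **Gamete DMRs** are planted on island blocks (germline DMRs are
  CGI-associated in vivo) at 0.85 on the methylated gamete versus 0.05
  on the other; post-fertilization samples in which the mark is retained
  get the diploid mid-level 0.45 (arithmetic mean of the parental
  targets, with the allele tables carrying the parental states), and
  0.85 where it has resolved. Fates are allocated per configured counts;
  DMR islands are chosen outside PMDs so domain-level and island-level
  truth stay disjoint.
* **Xi block** covers the X (configurable fraction) at 0.35 on the
  paternal allele of female somatic/embryonic samples; gametes are
  exempt (the germline X is not somatically inactivated); escapee genes
  keep active-allele methylation on both alleles.
* **Sexing counts.** Male libraries draw pseudo-Y reads at
  λ = 2000 per 10^6, females at 1% of that (mismapping), pools at half
  the male rate; female X reads are doubled.

What the generator does *not* emulate — sequence-driven CpG density,
fragment-level autocorrelation, mapping bias, incomplete conversion
hotspots, replicate structure — bounds what the passing tests show:
they demonstrate the pipeline's statistical machinery recovers planted
truth under its stated sampling model, not that the model captures every
artefact of real libraries.

# Numerical and design notes

* The null-calibration simulations use θ = ∞ (no latent noise), so both
  conditions share the same latent methylation per site: that isolates
  the exact test's sampling-noise calibration, which is the property
  being checked. With finite θ the two pooled libraries genuinely differ
  and rare island-edge tiles can reach significance — visible as the
  small non-zero empirical FDR in the DMR recovery run.
* Histogram bins are right-open except the last, so fully methylated
  sites land in the 90–100 bin.
* Problem sizes used by the test suite and the acceptance script — a
  5 Mb main genome (~60k CpGs, 100 planted DMRs, 3 PMDs) and a 9 Mb
  fate genome (200 planted DMRs, 25 per fate per origin) — were chosen
  so every recovery statistic rests on enough planted features to be
  stable while a full run stays in the minutes range on one core.
* Determinism: a single seed drives genome, truth, per-sample draws and
  file bytes; rerunning the demo pipeline with the same seed reproduces
  every output file byte-identically.
* Known limitations: the segmentation engine is single-sample (no joint
  multi-sample segmentation or HMM PMD model); the fate tracker assumes
  the supplied stage set; escapee/subject labels are inputs, not
  inferred; non-CpG contexts are carried but not analysed.

# A worked miniature

```{r demo, eval = FALSE}
out <- run_demo(tempfile("demo"), seed = 1729)
out$report
glance(out$segments_te)
```

`run_demo()` writes the simulated call files, then re-reads them and
runs the full analysis chain, writing TSVs for sample summaries, DMRs,
fates, segments, sex calls and the allele-level X comparison.
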