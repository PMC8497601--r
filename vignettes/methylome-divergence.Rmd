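---
title: "Comparative methylome divergence: models, parameters and design choices"
author: "methdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative methylome divergence: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methdiverge` implements a comparative methylome-divergence analysis for
whole-genome bisulfite sequencing (WGBS) of closely related species, with
replicated samples from one or more tissues. The pipeline starts from
per-CpG cytosine reports (counts of methylated and unmethylated reads per
cytosine) and a reference genome, and produces:

* species-specific, SNP-corrected reference genomes for bisulfite mapping;
* destranded, coverage-filtered CpG methylation tables, window tracks and
  a conserved-CpG sample matrix;
* differentially methylated regions (DMRs) between groups, and their
  classification into species-specific, tissue-specific and multi-tissue
  sets;
* permutation-based observed/expected (O/E) enrichment of DMRs in genomic
  features (promoters, gene bodies, intergenic space, CpG islands,
  transposable elements), per-TE-family enrichment, and a TE-age
  (divergence) comparison;
* integration with expression: gene-assigned DMRs, putative functional
  DMRs (pfDMRs) via a hypergeometric overlap test with differentially
  expressed genes, expression/methylation binning with Spearman
  correlation, and methylome clustering.

Read mapping and methylation extraction are out of scope: the pipeline
begins at the cytosine report. A synthetic-data module generates complete
input sets with planted, machine-readable truth so that every stage is
testable end to end without any external data.

# Coordinate conventions

All intervals are held internally as `GRanges`/`IRanges`, i.e. 1-based
closed intervals, the native Bioconductor convention; this keeps every
interval operation (overlap, union, complement, distance) on the stock
machinery rather than a parallel hand-rolled convention. Files keep their
native coordinate systems: cytosine reports and VCF are 1-based, BED and
bedGraph exports 0-based half-open. A CpG site is identified by the
position of its plus-strand C.

# The per-CpG test and DMR calling

## Count model

Per CpG, sample and site, the methylated count is modelled as
beta-binomial: coverage $n$, mean methylation $p$, overdispersion
$\varphi \in [0,1)$ with $\alpha = p(1-\varphi)/\varphi$,
$\beta = (1-p)(1-\varphi)/\varphi$, so that
$\mathrm{Var}(X) = np(1-p)\,(1 + (n-1)\varphi)$ and $\varphi = 0$
collapses to the binomial. This is the standard overdispersion model for
WGBS replicates and has closed-form moments, which the tests exploit.

## Site test

`percpg_test()` (and the vectorised engine behind `call_dmrs()`) tests
the difference of group mean methylation with a Wald-type z statistic
whose variance is evaluated under the null:

* group means are pooled counts, $\hat p_g = \sum_i m_i / \sum_i n_i$;
* the null proportion $p_0$ pools both groups; using $p_0(1-p_0)$ in the
  variance (a score-test flavour) gives markedly better type-I control
  at low replicate numbers than the unpooled Wald variance;
* $\varphi$ is estimated per site by method of moments from the replicate
  proportions, then averaged over a 500-bp smoothing neighbourhood
  *before* clamping to $[0, 0.95]$. Smoothing first lets negative
  sampling noise cancel; clamping per-site first would bias the
  dispersion upward and make the test conservative (we measured the null
  rejection rate at nominal 0.05 moving from ~0.036 to ~0.054 with this
  ordering, at 2 + 2 replicates and 15x coverage);
* with a single replicate in both groups the test falls back to Fisher's
  exact test on the pooled 2x2 table.

## Segmentation

Candidate CpGs (site $p <$ `site_p`, default 0.05) are chained while
consecutive candidate-to-candidate gaps are at most `max_gap` (default
100 bp). A chained region is reported iff **all** of:

* length $\ge$ `min_length` (default 50 bp),
* number of CpGs in the region $\ge$ `min_cpgs` (default 4),
* absolute mean methylation difference over the region $\ge$ `min_diff`
  (default 0.25),
* fraction of individually significant CpGs $\ge$ `min_sig_fraction`
  (default 0.5).

The first three thresholds are the field-standard DMR definition this
package adopts; the chaining gap and the significant-CpG fraction are
segmentation parameters chosen from common DMR-calling practice and are
exposed in `dmr_params()`. The region p-value combines direction-signed
site z-scores by Stouffer's method. Reported regions never overlap by
construction; every reported region is re-asserted against all four
thresholds on every call.

## Classification

`classify_species_dmrs()` labels a region specific to species S when DMRs
overlapping it (by at least 1 bp, the bedtools convention) exist in both
pairwise comparisons involving S with a consistent direction relative to
S, and no DMR between the other two species overlaps it; the output
region is the coordinate union of the supporting DMRs.
`classify_tissue_scope()` then merges same-species, same-direction
regions found in both tissues into multi-tissue records; unmatched
regions stay tissue-specific. Whether pairwise DMRs must agree exactly in
coordinates was an open design point; the 1-bp overlap reading was
chosen because exact coordinate agreement is fragile under independent
segmentations of noisy data.

# Genomic features

* Promoters are TSS ± 500 bp (width exactly 1000 bp unless clipped at a
  contig end).
* Gene bodies are the gene extent minus the first 500 bp downstream of
  the TSS in transcription direction, avoiding promoter overlap.
* Intergenic space is the complement of genes padded by 500 bp.
* CpG islands are predicted with the classical sliding-window rule
  (200-bp windows at 1-bp step; GC $\ge$ 0.5; observed/expected CpG
  $\ge$ 0.6 with $\mathrm{O/E} = N \cdot \#\mathrm{CpG} / (n_C n_G)$;
  qualifying windows merged and the merged interval re-checked,
  minimum length 200 bp). A hidden-Markov island caller would draw
  different borderline islands; the window rule was chosen because it is
  deterministic, dependency-free and auditable, and no attempt is made to
  reproduce any particular published island count. Merging whole
  windows means an island boundary can extend up to one window width
  into flanking sequence.
* TE annotations come from RepeatMasker `.out` files (or an equivalent
  6-column TSV), keeping the percent divergence column (CpG-adjusted
  Kimura substitution level) as the TE age proxy.

Feature annotation of query intervals is multi-label — a DMR inside a
promoter that also contains a TE counts in both categories — because the
categories are genuinely not mutually exclusive. Only the DMR-to-gene
assignment used for pfDMRs applies a precedence (promoter > gene body >
vicinity at 0.5–4 kb) so that each DMR contributes one gene at most and
the location classes partition the pfDMR set.

# Permutation enrichment

Expected overlap counts come from shuffling the DMRs across the genome —
preserving their number and lengths, placing each uniformly (contig
chosen proportional to length among contigs long enough) — with 1000
iterations by default (500 for the TE-age shuffle group). A DMR
overlapping a category counts once (count mode; a base-pair mode is
available). Empirical p-values use the add-one rule
$(1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{iter}}+1)$, mirrored
for depletion, so they are never zero; expected counts are permutation
means. Shuffled intervals may overlap each other, and no assembly-gap or
GC-matched null is attempted — the null is uniform placement, which is
what the O/E ratio is defined against here.

Note a statistical fact that matters when reading single O/E values: for
$m$ DMRs and a category of genomic fraction $q$, the observed count is
roughly binomial, so a single O/E has standard error
$\approx \sqrt{(1-q)/(mq)}$ — about 0.2 for 200 DMRs on a 10% category.
Calibration checks in the test suite therefore average O/E over
independent draws rather than judging one noisy draw.

# Expression integration

DEGs are genes with multiple-testing-adjusted q below 0.01 **and** a
maximum pairwise difference of species-mean TPM of at least 50 (means
average replicates within a tissue). The differential-expression fit
itself is an input — any external tool producing per-gene q-values can
feed it; the synthetic module derives q-values from its generative truth.

pfDMRs are gene-assigned DMRs whose gene is a DEG; the association is
tested with the exact hypergeometric upper tail at gene level
($N$ = genes in the expression matrix — the universe is configurable
since no canonical choice exists, $K$ = DEGs, $n$ = genes with at least
one assigned DMR, $k$ = the intersection).

Expression/methylation binning uses 11 expression categories — OFF (TPM
exactly 0 in every replicate) plus 10 equal-count bins of the expressed
genes — and 11 methylation categories — exactly 0% plus ten 10%
increments (an "11 versus 10 categories" ambiguity resolved as a zero
bin plus ten increments on both axes). Spearman correlations between
per-gene mean methylation (from averaged 50-bp window tracks over the
promoter or gene body) and mean TPM are computed gene-wise.

Methylome clustering computes the sample-by-sample Spearman correlation
matrix at conserved CpGs (sites covered in every sample and not touching
any bisulfite-confounded SNP), then complete-linkage hierarchical
clustering on Euclidean distances between correlation-matrix rows, with
sample order fixed by id for deterministic tie-breaking.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with planted truth for every component:

* **Genome**: i.i.d. bases at ~41% GC giving a realistic CpG density of
  ~4 per 100 bp; designated CGI intervals are drawn CG-rich (~76% GC), so
  the island predictor faces a real signal. Defaults: 2 contigs of
  500 kb.
* **Methylation baselines**: high background (0.8, the globally
  methylated vertebrate genome); per-gene promoter and gene-body levels
  tied to a latent activity so that active genes have unmethylated
  promoters and methylated bodies — the source of the negative
  promoter and positive gene-body expression correlations downstream.
* **Counts**: coverage Poisson (default mean 15, matching 10–15x
  experiments), beta-binomial methylated counts (default dispersion
  0.05 — a free choice, since within-species replicate variance is not
  quantified anywhere we could anchor it), both strands emitted with
  counts split binomially, plus an unmethylated spike-in contig (default
  non-conversion 0.005) for the conversion-efficiency estimator.
* **Planted species-DMRs**: default 100 non-overlapping regions of
  300–800 bp with at least 4 CpGs (so every planted region is callable
  by definition), effect size 0.5, target species cycling, 45%
  multi-tissue (the scale reported for real between-species divergence),
  the rest split between the two tissues. A configurable fraction sits
  on promoters of strongly expressed genes (activity boosted into
  [0.8, 1]) — planted regulatory divergence must be measurable on the
  TPM scale of the DEG filter, as the showcased real examples are
  strongly expressed metabolic genes — and another fraction inside young
  TEs, mirroring the enrichment of methylome divergence in evolutionarily
  young transposons.
* **Tissue regions**: 150 regions differing between tissues in all
  species; between-tissue differences dominating between-species
  differences is what real multi-tissue methylome clustering shows, and
  it is what makes the top dendrogram split a tissue split.
* **TEs**: a young/old mixture (Kimura-style divergence means 5% and
  25%) across six family labels.
* **Expression**: log-normal TPM driven by the same latent activity
  (~0.4–400 TPM), an OFF fraction (default 0.2) of silent genes,
  promoter-DMR genes shifted against the methylation direction with
  strength `expr_coupling` (default 4, i.e. a 4-fold change at
  delta 0.5), and a fraction of methylation-independent species DE as
  background for the overlap test.

What the generator does **not** emulate: read-level artefacts (M-bias,
non-conversion beyond a scalar rate, mapping bias), linkage between SNPs
and methylation, realistic TE sequence content (TE intervals are
annotations, not sequence), phylogenetic covariance among species, and
compositional isochores. Passing tests on this generator therefore show
that the algorithms recover what they are defined to recover under the
stated noise model — not that any biological conclusion about real data
is reproduced.

# Numerical and degenerate-input choices

* Coverage filtering keeps destranded CpGs with coverage strictly above
  4 and at most 100; the filter runs after destranding because the
  symmetric CpG is the biological unit (applying it per strand would
  discard CpGs whose evidence is split across strands).
* Window means are unweighted means of site-level fractions (not pooled
  counts), so deeply covered sites do not dominate a window.
* Minus-strand records without a plus-strand partner are kept (shifted
  onto the C position) with a warning rather than dropped.
* Sites where the pooled proportion is 0 or 1 get a zero null variance
  and p = 1 — both groups are identical there by construction.
* Site p-values are floored at 1e-300 before Stouffer combination.
* Empirical p-values use the add-one rule and cannot be zero.
* A genome base already equal to a SNP's alternate allele is treated as
  an applied substitution, which makes reference correction idempotent.
* All randomised stages (generator, shuffles) take explicit seeds; the
  same seed reproduces byte-identical output files.

# Problem sizes used in the checks

The packaged test suite exercises the pipeline at desk scale, chosen so
the full suite runs in minutes on one CPU: a 1-Mb genome with 100
planted DMRs at 15x coverage for recovery (sensitivity and precision
are measured at 50% reciprocal coverage, union-based so that a region
reported as two adjacent calls is not scored as a miss), a 1.5-Mb
two-tissue study with 200 planted species-DMRs for classification and
clustering, 10,000 CpGs for null calibration of the site test, and
2,000 genes on a 6.4-Mb genome for the expression-coupling checks.
`scripts/acceptance.R` re-runs the same experiments from scratch at
these sizes and writes the resulting quantities as JSON.

# Known limitations

* The beta-binomial Wald test is asymptotic; with single-digit coverage
  and 2 replicates its calibration relies on the pooled-variance form
  and dispersion smoothing, and it is not exact the way a full
  likelihood test would be.
* The window-rule CGI caller and an HMM caller disagree on borderline
  islands; island counts are not comparable across callers.
* Uniform shuffling ignores GC and gap structure; on real genomes an
  isochore-matched null would be more conservative for GC-correlated
  features.
* DMR calling requires every site to be covered in all samples of both
  groups after filtering; with many samples this intersection shrinks.
* Heterozygous SNPs are substituted like fixed differences in the
  reference correction; whether that matches any particular upstream
  variant-calling convention is the caller's responsibility.
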