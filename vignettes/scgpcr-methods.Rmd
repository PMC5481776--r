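---
title: "Methods: single-cell GPCR expression profiling with scgpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell GPCR expression profiling with scgpcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgpcr)
```

## The problem

G-protein-coupled receptors (GPCRs) are expressed at low copy number and
highly heterogeneously across individual vascular smooth muscle cells (SMC)
and endothelial cells (EC). Microfluidic single-cell RT-qPCR over a
receptor panel measures, per cell and gene, a cycle threshold (Ct) — the
amplification cycle at which signal crosses threshold — or records no
amplification at all. scgpcr implements the analysis chain for such data:
cell-identity gating, expression quantification anchored at the limit of
detection, heterogeneity statistics, clustering with cluster-marker testing,
gene–gene co-expression networks, promoter motif enrichment for the
regulatory interpretation of receptor modules, and normalization of
companion bulk NanoString counts.

Every stage is exercised against synthetic data with planted ground truth,
so the statistical behaviour of the chain is testable without access to any
instrument export.

## Expression model

The limit of detection (LoD) of the qPCR platform is taken as Ct = 24
cycles. A detected reaction with cycle threshold $Ct$ is mapped to

$$\mathrm{expression} = 2^{\,\mathrm{LoD\ Ct} - Ct},$$

so one cycle earlier doubles the value and the scale spans roughly
$2^0$–$2^{14}$ for real reactions. Entries at or beyond the LoD carry no
more information than a failed reaction: `lod_transform()` censors them to
0, and the detection rule `detect()` (strictly below the LoD) agrees with
the transform, so a value is positive exactly when the gene counts as
detected. On detected entries the transform is exactly invertible,
$Ct = \mathrm{LoD} - \log_2(\mathrm{value})$, which the tests verify to
machine precision.

## Cell-identity gating

Sorted EC or SMC preparations carry 10–18% contaminating cells. Gating
uses three marker classes (see `gating_config()`):

* quality control — reference genes `Gapdh` and `Hprt` must both be
  detected, otherwise the cell is `qc_fail`. Requiring both is the stricter
  of the plausible readings and is configurable.
* lineage exclusion — detection of `Ptprc`, `Itgam`, `Cd4`, `Cd8`, `Cd19`,
  `Ly6g`, `Cdh1` or `Tnni2` marks a contaminating lineage
  (`other_markers`).
* identity — exactly one of the target markers `Cdh5` (EC) or `Myh11`
  (SMC) must be detected (`cdh5_only` / `myh11_only`); neither gives
  `no_marker`.

Cells positive for both target markers are not retained and are binned as
`other_markers`, with a separate diagnostic count, since the exclusive
"only" categories of the contamination report imply double positives were
never kept. Aortic EC, which carry trace `Myh11`, are handled by an
explicit exception: the cross marker is tolerated when its LoD-scale
expression stays at or below a configurable threshold, default
$2^4 = 16$ (within 4 cycles of the LoD). No numeric cutoff for "low" is
established in the field; the default is deliberately conservative and is
surfaced in the configuration rather than hidden.

The contamination report tabulates per-group percentages over QC-passing
cells, so its four category columns sum to 100.

## Heterogeneity statistics

`expression_frequency()` reports the fraction of retained cells in which a
gene is detected. `receptors_per_cell()` counts detected intron-spanning
GPCRs per cell and summarizes mean ± s.e.m. (s.d./√n over retained cells).
Single-exon GPCR assays cannot be designed intron-spanning and amplify
residual genomic DNA in every cell; `filter_intron_spanning()` removes them
from the analyzable set (a 154-receptor panel with 22 single-exon assays
leaves 132). `group_compare()` wraps the two reporting conventions for
group contrasts: Student's two-sample t-test (Welch by flag) and a
one-sample t-test against 1 for control-normalized data. Both groups
constant and equal yields p = 1 by convention.

## Clustering and cluster-specific genes

Cells are clustered in the space of their mutual correlations: per-cell
profiles are `log2(value + 1)`-transformed (stabilizing the 14-bit dynamic
range; raw scale by flag), all pairwise Pearson correlations are computed
(Spearman by flag), and cell *i*'s feature vector is row *i* of the
correlation matrix. k-means with Euclidean distance runs on these rows with
50 random restarts, keeping the best within-cluster sum of squares;
everything is deterministic given the seed, and labels are renumbered by
first appearance so the arbitrary restart numbering cannot leak through.
When `k = "auto"`, the Calinski–Harabasz index is computed for
k = 2..k_max and the k preceding its largest drop is chosen; the analyses
that mirror known subtype structure pass explicit k (typically 2 or 3).
Cells with constant profiles receive correlation 0 against all others and
are flagged. t-SNE maps (`tsne_embed()`) use perplexity
min(30, (n−1)/3) by default and are deterministic given their seed.

Cluster-specific genes are found by an exact binomial test on
transcript-count proxies: expression values are rounded to pseudo-counts,
gene *g*'s count $n_{gc}$ in cluster *c* is compared against
$\mathrm{Binomial}(N_c, \pi_g)$ with $N_c$ the cluster's total count and
$\pi_g$ the gene's share of the global total, and the two-sided p-value is
$\min(1,\, 2\min(\text{lower tail}, \text{upper tail}))$, computed exactly
rather than by normal approximation because per-cluster totals can be
small. A gene is flagged cluster-specific when p < 0.05 *and* its fold
change (cluster mean over all-cells mean) exceeds 1.5 or falls below 0.7.
P-values are reported raw by default (Benjamini–Hochberg by flag), matching
the reporting convention the thresholds come from. Size-weighted cluster
means reconstruct the global mean exactly, so fold changes for one gene can
never all sit above 1 — a conservation property the tests enforce.

### What the binomial test does and does not guarantee

The binomial null treats the cluster's transcripts as drawn independently
from the global pool. Two deviations from that idealization matter:

* When expression values are far above 1 (e.g. reference genes near
  $2^{12}$), each cell contributes its counts as a block, and the
  randomization variance under label shuffling exceeds the binomial
  variance many-fold: p-values on LoD-scale values are anti-conservative
  and must be read jointly with the fold-change gate. This is inherent to
  applying a transcript-count test to amplified expression proxies, not an
  implementation artifact.
* When clusters are large relative to the population, sampling without
  replacement *deflates* the randomization variance (factor
  $1 - m/M$ for a cluster of m out of M cells), making the test
  conservative.

The calibration test therefore uses the regime the test is designed for:
count-scale data (Poisson counts, 200 cells × 100 genes, rates 2–20) and
clusters small relative to the population (20 random clusters of 10). There
the measured false-positive rate at p < 0.05 is ~0.04, within the
expected [0.03, 0.07] band, the residual conservatism coming from the
discreteness of the exact test and the finite-population factor 0.95.

### Planted subpopulation design

The recovery benchmark plants three subpopulations of 60/57/29 cells —
group sizes of the scale seen in real SMC panels — each expressing its own
module of 20 receptors at detection frequency 0.8 versus 0.2 in the other
groups, i.e. 4-fold mean separation. Receptor-repertoire differences of
this kind, rather than uniform shifts in expression strength of
identically-detected genes, are what distinguishes vascular cell subtypes
in practice; a pure 2-cycle Ct shift at equal detection frequency is
swamped by dropout noise in correlation space and does not, and should
not, separate cells. Under the repertoire design the clustering attains
ARI ≥ 0.9 and marker sensitivity ≥ 0.9 at the p < 0.05 & fold-change
rule.

## Co-expression networks

Gene–gene association uses Spearman's rank correlation, computed from
first principles as the Pearson correlation of average ranks (reducing to
$1 - 6\sum d^2 / (n(n^2-1))$ without ties). Undetected cells enter as
zeros and hence tied ranks, consistent with frequency-driven biology; a
detected-only mode is available. The network keeps edges with
$\rho > 0.3$ by default — the conventional display threshold, read as
signed — with an absolute-value mode for anti-correlations. Edges are
exported as a deterministic, lexicographically ordered TSV edge list for
downstream graph tools. Because ranks are invariant under strictly
monotone transforms, so is the network.

## Promoter TF-binding-site enrichment

Promoter windows span −950 to +50 bp around the transcription start site
(1000 bp; `extract_promoters()` builds them strand-aware from a genome and
TSS table if precomputed FASTA is not supplied). Motifs come from JASPAR
PFM text files (both the labelled bracketed dialect and the plain four-row
dialect are auto-detected). Scoring follows the promoter-scanning scheme of
set-versus-global tools: counts plus pseudocount are converted to log2
odds against the background base composition of the global promoter set
(recomputed per run), every offset on both strands is scanned, and the
best window score is min–max normalized by the PWM's attainable range so
that a promoter containing the consensus scores 1. Windows containing N
are skipped.

For a gene set, the enrichment statistic is a z-test of the set's mean
best-hit score against the global mean,
$z = (\bar s_{set} - \bar s_{glob}) / (sd_{glob}/\sqrt{n_{set}})$, with a
two-sided normal p-value; a Welch-style alternative is pluggable. For
heat-map display, p-values are z-transformed to
$\pm\Phi^{-1}(1 - p/2)$ (positive = overrepresented), clipped at ±8.
Calibration is checked with random 20-gene sets drawn from a 500-promoter
pool: the sampling-without-replacement variance factor (0.96) keeps the
empirical rejection rate near 0.045. Recovery is checked by planting a
consensus-sampled 10-bp motif in all 20 set promoters against 200
background promoters: the planted TF must rank first by |z| among ten
random decoy PWMs.

## NanoString normalization

The bulk-count chain is order-fixed: (1) positive-spike normalization —
each lane is scaled by (across-lane arithmetic mean of positive-control
geometric means) / (lane's own geometric mean), after which all lanes'
spike geometric means agree to machine precision; (2) background
subtraction — per lane, mean + 2 s.d. (sample s.d.) of the eight negative
controls, floored at 0; (3) low-value flooring — corrected values below 20
are fixed to 20 and flagged as not expressed (an alternate mode sets them
to the lane's computed background). Planted lane factors are recovered
exactly in the noiseless case — up to the common scale that any
across-lane target convention absorbs, so comparisons normalize both
factor vectors to mean 1.

Reference-gene stability is assessed with the geNorm measure: pairwise
variation $V_{jk}$ is the s.d. over samples of $\log_2$ count ratios, and
$M_j$ is the mean of gene j's pairwise variations; proportional genes give
$V = 0$, and the measure is invariant to per-sample scaling. A low-stability
panel justifies *not* normalizing to reference genes.

## Synthetic data

`simulate_ct_matrix()` generates the study conditions all tests run under:
per gene and cell a Bernoulli detection event, and for detected entries a
Ct from a normal distribution truncated to (0, LoD) — truncation rather
than rejection keeps generation O(cells × genes) and mirrors the observed
$2^0$–$2^{14}$ expression range. Defaults: LoD Ct 24; detected-Ct s.d.
1.5 cycles; mean detected Ct 18 for receptors, 12 for reference genes, 15
for identity markers; 132 GPCR genes with a Beta(0.35, 2)-shaped
frequency spectrum rescaled so the expected receptor count per cell is
20.3 — the published per-cell average for healthy aortic SMC; three
subpopulations of 60/57/29 cells. Contaminants replace a configurable
fraction of cells (12% in the pipeline default, mid-range of the 10–18%
seen in sorted preparations) and either express one random lineage marker
or lack the target marker, in an 80/20 split. Dropout is independent
Bernoulli per gene and cell, with no zero-inflation coupling to expression
level — sufficient for testing gating, frequency and clustering logic, but
deliberately simpler than transcriptional bursting; passing tests
demonstrate correctness of the statistical machinery on this model, not
biological realism of any particular dataset.

`simulate_correlated_pair()` (latent bivariate normal pushed through the
detection/expression model), `simulate_promoters()` (i.i.d. background
with consensus-sampled motif insertions at uniform position and strand)
and `simulate_nanostring()` (shared profile, per-lane reciprocal-factor
scaling, Poisson noise, fixed spike ladder) cover the remaining stages.
All generators are bit-reproducible given their seed.

## Numerical and design choices

* No-amplification tokens default to `"", "NA", "999", "Undetermined"`,
  configurable, since export dialects differ; parsing accepts scientific
  notation and is locale-independent (decimal points only).
* Ct tables are wide (cells × genes) as microfluidic exports commonly are;
  a long-format reader sits behind a flag.
* Text round-trips write doubles with `%.17g`, so write-then-read is exact.
* Degenerate inputs have defined behaviour rather than errors where a
  result is still meaningful: all-zero cells are dropped with a warning
  before normalization, constant profiles correlate 0, an empty retained
  set after gating warns, a k-means split of identical points returns a
  single cluster with a warning, and a zero-variance enrichment background
  gives z = 0, p = 1.
* Problem sizes in the validation suite (146–500 cells, 1000 cells for
  frequency recovery, 10,000 replicates for the two calibration checks,
  500–220 promoters) were chosen as the smallest sizes at which the
  planted effects are resolved with comfortable margins.

## Limitations

The pipeline does not model amplification efficiency, absolute copy
number, melting curves, or doublets beyond the marker rules; imaging-based
chamber QC happens upstream. The binomial marker test inherits the caveats
above on amplified expression scales. The NanoString reader accepts plain
count tables only, not instrument binaries, and the TFBS stage requires
user-supplied promoters and motif files rather than downloading genomes or
motif releases.
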