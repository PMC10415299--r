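---
title: "Copy-number transition-point fingerprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number transition-point fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In lethal metastatic prostate cancer, many spatially and temporally
separated tumor samples can be collected from one patient — metastases
at autopsy, archival biopsies, plasma. Shallow whole-genome sequencing
of such samples yields binned read counts from which copy-number
profiles can be derived cheaply, but the samples vary enormously in
tumor content and quality. `scratchcn` implements an analysis chain
that turns these profiles into statements about clonal structure:

* per-sample tumor purity from phased haplotype B-allele frequencies
  and from a penalized purity/ploidy fit,
* copy-number segmentation on a fixed 500-kb bin grid,
* *transition points* — the genomic boundaries where adjacent segments
  change copy number — as a clonal fingerprint,
* SCRATCH (Start of Copy number change for Relationship Assessment and
  Testing Clone Histories): hierarchical clustering of a patient's
  samples on the correlation of copy numbers at the union of its
  transition points,
* congruence testing between the autosome-derived and chromosome
  X-derived sample trees (Baker's Gamma; a maximum-agreement-subtree
  congruence index with a permutation null),
* androgen-receptor (AR) copy number, gain classification and a ternary
  AR transcriptional-activity score,
* cancer cell fractions for structural-variant breakpoints and
  clonal-mutation overlap statistics.

Everything is validated end-to-end against a clone-tree simulator with
planted truth, so the package is testable without any external data.

# Purity estimation

## Haplotype-BAF anchors

In a region with allele-specific tumor copies $(n_A, n_B)$, $n_A > n_B$
(for example one-copy loss of heterozygosity, $(1,0)$), the expected
B-allele frequency of the retained haplotype $A$ at tumor fraction
$\rho$ is

$$B = \frac{\rho\, n_A + (1-\rho)}{\rho\,(n_A+n_B) + 2(1-\rho)},$$

which inverts to

$$\rho = \frac{1-2B}{B\,(n_A+n_B-2) - (n_A-1)}.$$

Long, allelically imbalanced, read-depth-depleted *anchor regions* pin
this down: `select_anchor_regions()` replaces the visual inspection a
human analyst would perform with explicit thresholds (segment ratio at
least 0.1 below the sample median; pooled phased BAF at least 0.08 away
from 0.5; minimum length 10 Mb — all configurable). Haplotype labels
inherited from statistical phasing carry switch errors;
`correct_switch_errors()` re-orients each SNP against a designated
high-purity sample, in which the two haplotype BAF modes are well
separated, and drops SNPs whose reference BAF is within 0.05 of 0.5.
Counts are pooled within an anchor before inversion (weighting SNPs by
depth, appropriate at shallow coverage), the per-sample estimate is the
median over anchors, and at least three usable anchors are required.

## Grid fit and consensus

`grid_fit_purity_ploidy()` scores a $(\rho, \psi)$ grid by the
length-weighted distance of the implied segment copy numbers from
integers,

$$E(\rho,\psi) \;=\; \frac{\sum_s w_s\,\bigl|\mathrm{CN}_s -
\mathrm{round}(\mathrm{CN}_s)\bigr|}{\rho^{0.5}}\;(1+|\psi-2|)^{0.5},$$

with both penalty exponents 0.5 (a lower-cellularity penalty and a
ploidy penalty). Ties break toward higher purity, then ploidy nearer 2
— this resolves the whole-genome-doubling ambiguity in favour of the
parsimonious solution. A flat profile cannot constrain the fit and is
returned as $\rho=1,\psi=2$ with a degeneracy flag.
`consensus_purity()` averages the two estimates when they agree within
0.1 and otherwise prefers the haplotype-BAF value with a discordance
flag; the 0.1 window is a package decision, as is the preference (the
haplotype estimate is anchored in germline phase information).
Samples with consensus tumor fraction below 0.2 are excluded from
fingerprinting (`filter_by_tumor_fraction()`, boundary inclusive).

# Copy-number profiles

Bin counts are normalized to the autosomal median
(`normalize_counts()`), segmented by a greedy left-to-right running-mean
merge (`segment_profile()`): a bin joins the current segment iff its
ratio is within `merge_tol` (default 0.3) of the running mean, segments
never cross chromosome boundaries, and adjacent segments whose means
fall within tolerance are merged iteratively afterwards so the operator
is idempotent. Before merging, isolated single-bin spikes — a bin more
than `merge_tol` away from both neighbours while the neighbours agree
with each other — are winsorized to the neighbour mean. Such spikes are
count noise, not copy-number structure (copy-number events at 500-kb
resolution span multiple bins), and would otherwise seed spurious
one-bin segments; the smoothing is the same idea as the outlier
smoothing step of standard shallow-WGS bin pipelines and can be
disabled (`smooth_outliers = FALSE`).

Absolute copy number uses the standard purity/ploidy transform
$\mathrm{CN} = (r D - c_n(1-\rho))/\rho$ with
$D = \rho\psi_t + 2(1-\rho)$ and normal copies $c_n = 2$ on autosomes
and $1$ on the male X (the package assumes a male genome throughout, as
appropriate for prostate cancer). AR copy number is the
overlap-length-weighted median copy number over the segments covering
the AR interval, and AR gain is called when that value is at least 2
*and* the gained fraction of Xq is below 80% — broad whole-arm gains
are not counted as AR-targeted events. Whether "copy number $\ge 2$" on
a one-copy male X should be read as total copies or fold change is
ambiguous; the package implements total copies, with the threshold
exposed as an argument.

# SCRATCH

`extract_transition_points()` reports every internal segment boundary
at which the copy number changes (chromosome ends are not transition
points). Because all samples share one bin grid, boundary positions are
compared exactly — no fuzzy windows.

`build_transition_matrix()` forms the patient-level revised profile:
columns are the union of all samples' boundary positions; the entry for
sample $s$ at boundary $b$ is the sample's mean copy number over the
interval from $b$ to the next union boundary (computed from bin-level
data when available, otherwise from the segment values — the two agree
exactly on noiseless data). Averaging over the union intervals, rather
than quoting the sample's own covering-segment value, matters for
low-purity samples: at tumor fraction 0.2 a one-copy event moves the
ratio by only ~0.1, the sample's own segmentation is essentially flat,
and only the interval average retains the event signal that
higher-purity samples' boundaries reveal.

`correlation_distance()` is $1 - r$ with Pearson correlation between
sample rows (Spearman available). For transition matrices the Pearson
version is precision-weighted by interval length: an entry averaged
over $L$ bins has noise variance proportional to $1/L$, so short
spurious intervals should not carry the weight of long real segments.
The weighting leaves the spec-level invariances untouched (identical
rows at distance 0, positive-affine invariance, anti-correlation at 2).

`scratch_cluster()` runs agglomerative clustering (complete linkage by
default, configurable) on that distance; the number of clusters
maximizes the mean silhouette width over $k = 2,\dots,\min(k_{max},
n-1)$ with ties to the smallest $k$; clusters with fewer than two
samples are merged into the cluster sharing their most recent common
ancestor (operationally: the cophenetically nearest cluster), iterated
until all clusters have two or more members or one remains.

Transition-point *sharing* between samples
(`shared_transition_fraction()`, `pairwise_shared_matrix()`) is the
fraction of a query's transition points present in targets, optionally
requiring the same change direction, and the pairwise matrix is binned
at the 20% / 80% cutpoints.

# Congruence of two sample trees

Baker's Gamma computes, for every leaf pair and each tree, the number
of clusters present when the pair first co-clusters (scanning cuts from
$n$ down to 1), and returns the Goodman–Kruskal gamma rank correlation
between the two pairwise level vectors (Spearman available). The
statistic only needs a dendrogram; trees read from newick without
branch lengths are given Grafen heights, and non-ultrametric trees are
embedded by UPGMA on their cophenetic distances.

The congruence index is built on the rooted maximum agreement subtree
(MAST): the largest leaf subset on which both trees induce identical
topologies, computed by the exact $O(n^2)$ dynamic program over node
pairs (implemented in C++ with 64-bit clade masks, hence the 64-leaf
cap). Multifurcations are resolved deterministically before the DP.
Rooted MAST is used because dendrograms are rooted; note that the
rooted value can be smaller than the unrooted one (for
$((a,b),(c,d))$ vs $((a,c),(b,d))$ it is 2, since every 3-leaf subset
induces different rooted topologies).

$I_{cong}$ is the observed MAST divided by its mean over label
permutations of the second tree, and the p-value is
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$ from the same
permutations; congruence is declared at $p < 0.01$. The permutation
null replaces precompiled expected-MAST tables: it is self-contained
and exact at this scale. One caveat is discreteness: MAST is
integer-valued and heavily tied, so the permutation test is valid but
conservative — calibration experiments at 20–36 leaves measure a type-I
rate of roughly 0.02–0.04 at nominal 0.05. The test never
over-rejects, which is the property the $p < 0.01$ congruence calls
rely on.

Detecting congruence between autosome- and chrX-derived networks needs
enough leaves: with only four samples per cluster the within-cluster
topology is noise-driven and MAST barely exceeds its null; at the scale
of the larger patients (three clusters of twelve) cluster-level
agreement dominates and planted-congruent pairs give $p \approx 0.001$
with 999 permutations. The congruence validation therefore uses a
36-sample patient.

# AR activity score

Expression counts are filtered (at least 10 reads in at least 90% of
samples), log2-CPM transformed and quantile normalized
(`limma::normalizeQuantiles`; precision weights are unnecessary here
because gene-wise z-scores are invariant to them), then z-scored per
gene. Each signature gene contributes a ternary score

$$\mathrm{score}(z, \mathrm{up}) = \begin{cases} 1 & z \ge 1\\ 0 & -1 <
z < 1\\ -1 & z \le -1 \end{cases}$$

with the converse rule for down-regulated genes, and the per-sample AR
score is the sum over signature genes present (missing genes are
skipped and logged). The bundled 27-gene androgen-response signature
(after Hieronymus et al., 2006) is shipped as an editable TSV — the
signature is data, not code — and any user file with `gene` and
`direction` columns can replace it.

# Clonality statistics

A breakpoint's cancer cell fraction normalizes the allelic fraction by
tumor content and local chromosome number:
$\mathrm{CCF} = AF\,(\rho\,\mathrm{CN}_t + c_n(1-\rho))/(\rho m)$, with
multiplicity $m$ defaulting to 1 (shallow data cannot resolve it, and
$m=1$ is conservative) and values above 1 capped with the raw value
retained. Clonal-mutation overlap between two samples is the
intersection size over the smaller set, and the within-cluster versus
cross-cluster comparison uses a one-sided rank-sum test. Because the
worked examples involve ties (identical overlap values), the small-
sample path enumerates the exact conditional rank-sum distribution with
average ranks rather than delegating to `wilcox.test`, which declines
exact computation under ties; beyond the enumeration cap it falls back
to `wilcox.test`. Fisher's exact test on 2-by-2 tables delegates to
`stats::fisher.test`; degenerate margins return $p = 1$ with a warning.

# The synthetic cohort generator

`simulate_clone_tree()` plants a patient: a configurable miniature male
genome (default four autosomes of 200 bins plus a 120-bin chrX at
500 kb, with designated AR and enhancer bins on Xq), clusters of
samples each carrying truncal, cluster-specific and private copy-number
events with $\pm 1$ deltas, truncal LOH anchors for purity work, a chrX
AR class per cluster (`none`, `broad` Xq gain, or `focal` +5..+12
amplification spanning enhancer and AR) plus small cluster-specific
chrX events, and per-sample purities drawn uniformly from
$[0.2, 0.9]$. Event boundaries are rejection-sampled so no two events
share a boundary bin, keeping planted transition points unambiguous.
Deltas that would drive total copy number negative are flipped to
gains.

Downstream simulators derive from the tree: negative-binomial bin
counts around the expected ratio $r = (\rho c_t + c_n(1-\rho))/D$
(dispersion size 100 by default, Poisson at `Inf`); phased SNP counts
in anchors, binomial around the allele-specific BAF, with a per-SNP
Markov switch process corrupting the reported haplotype labels;
mutation-id sets nested by the clone tree (defaults 30 truncal, 20 per
cluster, 10 private); and expression counts whose signature genes shift
by $\pm\,\mathrm{effect} \cdot \log_2(\mathrm{AR\ CN})$ with log-scale
Gaussian noise. Every simulator is byte-identical under a fixed seed.

Default problem sizes used by the validation suite — the 3x4-sample
default patient at depth 100 per bin for recovery, 20 seeds for the
recovery and purity sweeps, a 3x12 patient for congruence, 1000
replicates at 99 permutations for null calibration — were chosen to
exercise the study-relevant regimes at desk scale.

What the generator does *not* emulate: GC and mappability bias,
sequencing error profiles, subclonal (non-dominant) populations within
a sample, read-level structural variants, and hierarchical sub-clone
structure within a cluster (clusters are flat; all within-cluster
divergence comes from private events and noise). Passing the recovery
tests therefore demonstrates the machinery is correct under the stated
noise model, not that real FFPE or plasma profiles will behave as
cleanly; on real data segmentation quality and purity estimation are
the binding constraints.

# Numerical conventions and edge cases

* Coordinates are 0-based half-open everywhere; boundaries are reported
  as bin-edge bp positions; a breakpoint at a window end is outside.
* The transition matrix takes the value immediately to the right of a
  boundary.
* Gain thresholds on continuous copy numbers are compared with a
  `sqrt(.Machine$double.eps)` guard so an exact planted 2.0 is never
  lost to floating-point round-off.
* Silhouette ties choose the smallest $k$; grid-fit ties choose higher
  purity, then ploidy nearer 2; multifurcation resolution is
  deterministic.
* Zero-variance rows in the correlation distance get the maximum
  distance with a warning; empty mutation sets make the overlap
  undefined (NA) rather than zero.
* All simulators and permutation tests restore the caller's RNG state.

# Known limitations

The greedy segmenter is deliberately minimal (the pluggable interface
accepts externally segmented profiles); CBS/HMM segmentation, allele-
specific segmentation, GC correction and subclonal deconvolution are
out of scope. The MAST implementation is rooted-only and capped at 64
leaves. The exact rank-sum enumeration is capped at 2e5 group
assignments. The AR signature list is a reconstruction of the cited
27-gene set and is user-replaceable.
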