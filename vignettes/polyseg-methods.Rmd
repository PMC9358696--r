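---
title: "Methods: models, thresholds and design choices in polyseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in polyseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyseg)
```

`polyseg` re-implements, as tested and reusable functions, the bespoke
downstream analyses of a triplicated *Brassica* genome and transcriptome
study: bulked-segregant trait mapping, variant-effect annotation, subgenome
triad expression-bias classification with a Ka/Ks contrast, transposable
element (TE) context analysis, and PSI-based differential-splicing and NMD
analysis. This vignette records the statistical models, the parameters that
matter, and the decisions made where the underlying procedures were
under-specified.

## Bulked-segregant Δ(SNP-index) mapping

**Model.** An F2 population from a biparental cross segregates 1 AA : 2 Aa :
1 aa at every locus. For a recessive trait, the "mutant" bulk (S2) contains
only aa plants at the causal locus, while the wild-type bulk (S1) is 1 AA :
2 Aa, so the causal-allele frequency is 1 in S2 and 1/3 in S1. The SNP-index
of a marker in a pool is the alternate-allele read fraction
`alt / (ref + alt)`; Δ(index) = index(S2) − index(S1) has expectation 2/3 at
the causal locus and 0 at unlinked markers. Indels are indexed with the same
formula and the "all-index" is simply the per-marker index over the merged
SNP + indel marker set (set union, not value averaging).

**Sliding windows.** Window width 1 Mb advanced in 1-kb steps (both
configurable); the window statistic is the unweighted mean Δ over contained
markers, masked below `min_markers = 3`. The width/step reading of the
"1-Mb interval, 1-kb sliding window" convention matches standard QTL-seq
visualisation.

**Confidence envelope.** How the 95% significance level of such scans is
obtained is conventionally left to the QTL-seq tooling; we reconstruct it as
a two-level Monte-Carlo null (the Takagi-style scheme): per read depth *d*,
draw each bulk's genotype composition for `bulk_size` plants from
1:2:1 under no linkage, convert to a bulk allele frequency, draw alternate
read counts Binomial(*d*, freq) per pool, and take the 2.5/97.5 (and
0.5/99.5) percentiles of Δ over 10 000 simulations. The envelope is
tabulated on a depth grid and interpolated; windows are tested at their mean
marker depth by default (a global-depth mode is provided, since it is not
knowable which variant the original analysis used). Region calling is
one-sided on the high side by default because the design makes S2 the
homozygous bulk; a two-sided mode exists and the pool-swap antisymmetry
(swapping S1/S2 negates every Δ) is covered by tests. Marker-level checks
use the harmonic mean of the two pool depths, which matches the
read-sampling variance of the equal-depth null; under a no-locus null about
5% of markers fall outside the 95% envelope (verified at ±1.5%).

Zero-depth markers are flagged and excluded, never imputed as index 0; the
minimum-depth filter defaults to 10× per pool. Candidate regions merge
contiguous significant windows (`merge_gap = 0` windows by default). Fixed
diagnostic markers are those with index ≤ tol in S1 and ≥ 1 − tol in S2
(tol = 0).

**Allele polarisation.** The package takes the VCF's alternate allele as the
"donor" allele of the S2 bulk. Which parent's allele a given callset counts
depends on the reference assembly used upstream; users mapping against the
resistant parent should swap pool roles (`s1`/`s2` arguments) rather than
expect a hard-coded convention.

## The F2 simulator

The generator reproduces the study's stated design as its defaults: 10
chromosomes, two 50-plant bulks drawn from an F2 population (default 300
plants, a parameter because the source population size is not stated),
mean depth 50× per pool (Poisson-distributed per marker), 200 markers per
chromosome, and a single recessive causal locus. Linkage follows the
Haldane map, r = ½(1 − e^(−2d)), with a default genetic length of 1 Morgan
per chromosome; markers are conditionally independent given the causal-locus
genotype (no crossover interference or multi-marker haplotype structure —
adequate for marker-to-causal statistics, not for haplotype-based methods).
Read noise is optional (`base_error`, default 0) so envelope calibration can
be tested cleanly. What passing tests show is therefore recovery under
idealised sampling noise; real data add mapping artefacts, allele bias and
uneven marker density that the simulator deliberately omits.

## Variant-effect annotation

Effects are classified per (variant, transcript) with the precedence ladder
splice_site > coding > UTR > intronic > upstream/downstream > intergenic,
with one deliberate refinement: a variant that removes or interrupts coding
bases is classified by its coding consequence even when it also touches a
junction, so a deletion running from an exon into the intron is a
`frameshift_deletion` (with the deleted-CDS length and a boundary note in
`detail`) rather than a bare `splice_site` call. Deleted-length parity
counts only coding bases removed. Coding SNPs are translated on the coding
strand with the standard genetic code; a 200-variant property test checks
every class against brute-force translation of the whole mutated CDS, and a
mirrored-locus test checks strand symmetry. The upstream/downstream window
is 2 kb, matching the flank convention used in the TE analysis.

## Triad classification on the ternary simplex

Triads are filtered to summed FPKM strictly greater than 0.5 (the strict
inequality is asserted by tests), normalised to relative contributions
r = f / Σf, and assigned to the nearest of seven centroids by Euclidean
distance: Balanced (⅓,⅓,⅓), X-dominant = unit vector, X-suppressed = 0 on X
and ½ elsewhere. The category names imply these archetypes; the exact
centroid vectors are our choice, as is the deterministic tie-break (fixed
category order, with a `tie` flag) preferred over silent arbitrariness.
Classification is scale-invariant and label-permutation-equivariant, both
tested. Expression is averaged across sample columns before classification
by default; per-condition classification is available by passing a sample
subset — whether the original analysis pooled tissues is not stated, so the
pooled default is documented rather than asserted.

The triad simulator draws relative triples from a Dirichlet centred on the
category centroid, `alpha = concentration * centroid + alpha_floor`
(floor 0.1 keeps zero coordinates proper), scaled by log-normal magnitudes.
At concentration 50 the classifier recovers ≥ 95% of truth labels; in the
concentration → ∞ limit recovery is exact. The default mixture mirrors the
balanced-minority composition observed in such datasets (28.7% balanced,
23.7% dominant, 47.6% suppressed, split evenly within groups).

## Ka/Ks (Nei–Gojobori 1986)

The estimator is the classic counting method: per-codon synonymous site
fractions (changes to stops count as non-synonymous), sites averaged over
the two sequences; codon pairs differing at k positions resolved by
averaging synonymous/non-synonymous step counts over all k! orderings of
single-nucleotide steps with equal weight; Jukes–Cantor correction
d = −¾ ln(1 − 4p/3), flagged undefined when p ≥ ¾. Codons with gaps or
ambiguity in either sequence are excluded pairwise and counted; shared
terminal stops are trimmed; internal stops are a hard error. The upstream
script the study cites does not document its algorithm, so NG86+JC is
implemented as the standard baseline such wrappers implement; the test suite
validates it against an independent recursive pathway-enumeration oracle to
1e−9 on random 30-codon pairs. The balanced-vs-unbalanced contrast is a
one-sided Wilcoxon rank-sum test (unbalanced > balanced): Ka/Ks is bounded
and right-skewed, so a rank test is more defensible than a t-test and the
original claim is only an ordering.

## TE context and homolog comparison

Gene body = the full gene span (introns included — consistent with
intron-insertion cases counting as gene-body hits), flanks = 2 kb in gene
orientation, clipped at position 0. Syntenic membership uses the TE midpoint
so that the syntenic/non-syntenic split is a true partition (copies and
total bp conserve exactly); an any-overlap mode is available. The homolog
comparison runs a Welch t-test on log2(x + 1) replicate expression with fold
change reported on the mean scale, oriented insertion-free over
insertion-carrying; significance uses raw p < .05 with |FC| > 2 as in the
original claim, with BH-FDR reported alongside for users who prefer it.

## Splicing: events, PSI, DAS/DTU, NMD

Events are detected by pairwise exon-chain comparison within a gene: IR (an
exon of one transcript fully covers an intron of the other), ES (an internal
exon inside the other's intron), A5/A3 (introns sharing one boundary,
strand-aware). For A5/A3 the variable region must be exonic in the
shorter-intron transcript — this guard keeps the flanking introns of a
skipped exon from being double-reported. Events deduplicate by coordinates,
accumulating inclusion/exclusion transcript sets. Alternative first/last
exons are out of scope.

PSI = inclusion abundance / (inclusion + exclusion), undefined when the
denominator is at or below 1 TPM-equivalent (`min_event_abundance`).

**DAS significance.** The original analysis delegated testing to an external
tool whose internals are not restated; we use permutation of sample labels
on |ΔPSI|. A per-event exact permutation with 3+3 replicates has only 10
distinct labelings (minimum p = 0.1) and could never clear FDR < .01, so
the null is pooled across events and built from residuals: PSI values are
centred within condition (removing any true effect), labels are permuted,
and |ΔPSI*| values pooled over all events form the null, giving p-value
granularity 1/(events × permutations). Centring keeps genuinely affected
events from inflating the null; pooling assumes roughly exchangeable noise
across events, which holds in the simulator and approximately in practice.
An event is DAS at BH-FDR < .01 **and** |ΔPSI| ≥ 0.10; a DAS gene has ≥ 1
DAS event. Designs without replicates must opt into `threshold_only` mode
explicitly. ΔPSI is oriented as the alphabetically second condition minus
the first, so relabelling conditions negates ΔPSI and leaves DAS calls
unchanged (tested). DTU applies the same machinery to per-gene isoform
proportions with a strict |Δ| > 0.10 rule. Under a 500-event null the DAS
false-positive rate is ≤ 1% (observed 0–0.4% across seeds).

**NMD.** The 50-nt rule: a transcript is PTC-bearing when its stop codon
lies more than 50 nt (configurable) upstream of the last exon–exon junction
in spliced-transcript coordinates; single-exon transcripts are never
PTC-bearing. DE calling itself is out of scope — DE gene lists are inputs,
and the DE/DAS partition is exact set algebra.

## Problem sizes and numerical choices

The default test and acceptance runs use problem sizes chosen to make the
statistics stable while staying desk-scale: 100 seeded replicates of the
full 2 000-marker scan for recovery (observed 100% recovery, mean causal Δ
within 0.05 of 2/3), 10 000 envelope simulations per depth (quantile Monte
Carlo error ≪ the ±1.5% calibration tolerance), 1 000 triads, 500 null
splicing events, 100 random 30-codon Ka/Ks pairs. Envelope quantiles use
R's default empirical quantile interpolation; all generators take explicit
seeds and touch no global state beyond R's RNG, restored per call via
`set.seed`.

## Known limitations

The simulators emulate the statistical structure each method assumes, not
raw reads: no mapping error, no reference bias, no overdispersed coverage,
no correlated recombination along chromosomes, and isoform abundances are
allocated exactly rather than estimated from reads. Headline counts of the
original study that depend on its deposited sequencing data (total SNP
counts, specific gene tallies) are not reproducible at this scale and are
not claimed; the package reproduces the printed arithmetic exactly and the
statistical behaviour of each method under its stated design.
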