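---
title: "Methods: miRNA profiling across adipose depots with adipomiR"
author: "adipomiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA profiling across adipose depots with adipomiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipomiR)
```

## The analysis

adipomiR re-implements, as a tested and reusable pipeline, a small RNA-seq
workflow for comparing microRNA transcriptomes across six porcine adipose
depots: four visceral (greater omentum GOM, mesenteric MAD, pericardial
PAD, retroperitoneal RAD) and two subcutaneous (upper and inner back-fat
layers ULB, ILB). One pooled sequencing library per depot is analysed; there
are no biological replicates, which is why all inference is count-based and
two-library at a time.

The stages are:

1. **Read QC and collapsing** (`runQC()`): adapter trimming, a 14–27 nt
   insert length window, base-composition filtering, collapsing to unique
   tags, and a per-library copy-number filter.
2. **Annotation** (`annotateTags()`): contaminant removal, two-tier
   precursor mapping, classification of each tag as a known miRNA, a novel
   passenger-strand (star) miRNA, or a conserved (other-mammal) miRNA, and
   collapsing to unique mature sequences.
3. **Quantification** (`buildMatrix()`, `categorize()`): the unique-miRNA ×
   library count matrix, RPM normalization, abundance-concentration
   summaries, and the six-way tissue-presence categorization.
4. **Differential expression** (`callDE()`, `callEnrichment()`): a
   three-test consensus between each visceral and each subcutaneous
   library, and a depot-specific enrichment call across all eight
   comparisons.
5. **Clustering** (`clusterLibraries()`, `depotSplit()`): average-linkage
   dendrograms on correlation distances, with an explicit test of whether
   the two subcutaneous libraries form their own clade.

A synthetic-data generator (`simulateSmallRnaStudy()`) produces the whole
input bundle — precursor and contaminant references, mature-arm
annotations, and one FASTQ per library — together with the generative
ground truth, so that every stage can be validated end to end against known
labels.

## Read QC

Reads are trimmed at the leftmost exact occurrence of the first 8 bases of
the 3' adapter. Reads without a detectable adapter are discarded by default
(the insert boundary is unknown); this is configurable. All filter
boundaries are inclusive, reading "no more than" literally: a 14- or 27-nt
insert passes the length window, an insert with exactly 80% of a single
base passes the composition filter, and exactly two undetermined bases
pass. The composition rule is interpreted per single base — no one of A, C,
G or T may exceed 80% — because the combined reading (A+C+G+T ≤ 80%) would
be vacuously false for any DNA sequence.

Collapsed tags are copy-number filtered per library, independently: a tag
seen fewer than 3 times in a library is zeroed in that library, and tags
zero everywhere are dropped. Per-library filtering (rather than filtering
after pooling) reflects that each library is an independently sequenced and
processed unit; it also makes "presence" downstream a per-library notion.

## Annotation

Tags matching any contaminant reference as an exact substring (either
strand) are removed; the contaminant set stands in for the rRNA, tRNA,
snRNA, snoRNA, mRNA and repeat classes that a production run would screen
against curated databases.

Mapping is exact (0 mismatches) by default and strand-specific, with the
mismatch tolerance exposed (`maxMismatch`). The precursor reference has two
tiers searched in strict precedence: the porcine tier first, and the
conserved-mammal tier only for tags with no porcine hit. A tag is

* **known** if a porcine hit overlaps a documented mature interval by at
  least 16 nt — enough to tolerate the ±2 nt end-heterogeneity of
  sequenced isomiRs while excluding reads from the opposite arm;
* **novel star** if it hits a porcine precursor without overlapping any
  documented interval; the arm is inferred from which half of the hairpin
  the hit falls in, and the record is named `<precursor>-<arm>-star`.
  Undocumented annotation rows shipped by the simulator are never
  consulted — novel stars must be discovered from position alone;
* **conserved** if its only hits are on the second tier, labeled with the
  orthologous mature name.

Distinct precursors can encode the same mature sequence; records with
identical mature sequences are merged (union of precursor ids,
lexicographically first name, highest-priority class with
known > novel star > conserved). The unique-mature table is the unit of all
downstream counting.

## Tissue-presence categories

A miRNA is **present** in a library when its post-filter count is at least
one; the per-library copy filter has already zeroed unreliable entries, so
no separate expression threshold is introduced. Categories over six
libraries: present in all six (category 1), absent in exactly one, two,
three or four libraries (categories 2–5), present in exactly one library
(category 6). Percentages are reported raw and rounded half-up to two
decimals; published tables occasionally truncate instead of rounding, which
is why comparisons in the test suite allow a one-hundredth slack on the
last digit.

## The three-test consensus

For each pair of a visceral library (counts `x`, total `N1`) and a
subcutaneous library (counts `y`, total `N2`), the tested set is the
miRNAs with nonzero counts in both libraries, and each of three two-sided
tests is computed per miRNA:

**Audic–Claverie.** The posterior probability of the second count given the
first under a flat prior,
$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$
with the two-sided p-value doubling the smaller tail sum, capped at 1.
Writing $r = N_2/N_1$, $P(y \mid x)$ is the negative binomial pmf with size
$x+1$ and success probability $N_1/(N_1+N_2)$, so both tails are evaluated
exactly through `pnbinom()` (log-gamma scale internally) rather than
explicit summation. The conditional formulation is not exchangeable between
libraries — conditioning on `x` and summing over `y'` differs from the
converse — so the package always conditions on the **larger** of the two
counts (ties toward the larger total). This choice was made after a
numerical survey of the alternatives: it is symmetric by construction and
keeps the p-value monotone in the departure from proportionality throughout
the significant regime; small reversals remain possible only where the
doubled tail saturates near 1, which cannot affect calls at any reasonable
threshold. Conditioning on the smaller count, by contrast, produces tail
reversals at p-values as small as $10^{-12}$.

**Fisher exact.** On the 2×2 table `(x, N1−x; y, N2−y)`: the total
hypergeometric mass of tables no more probable than the observed one, with
the customary $1+10^{-7}$ relative slack on the comparison. For supports
larger than ~2000 the same quantity is assembled from the two tails, with
the opposite-tail cutoff located by bisection on the monotone flank of the
unimodal pmf; this keeps the per-comparison cost logarithmic for the deep
libraries where direct summation over the support would dominate the run
time.

**Pearson chi-squared.** The plain (uncorrected) statistic
$n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))$ on one degree of freedom; the Yates
correction is available behind a flag. When any expected cell is below 1 or
a margin is degenerate, the asymptotic p-value is not trusted: it is forced
to 1 and flagged, which is deliberately conservative for the consensus
rule.

Each test's p-values are Bonferroni-corrected with the family size equal to
the number of miRNAs tested in **that** comparison, and a miRNA is called
differentially expressed only when all three corrected p-values fall below
$\alpha = 10^{-5}$ simultaneously (the threshold is applied to corrected
p-values; applying it to raw p-values instead is available via
`thresholdOn = "raw"`). Tests run on raw counts with true library totals.
Direction comes from the normalized rates, with exact ties given direction
`none` (such a miRNA can never be a consensus call in practice).

A miRNA is **VAT-specifically enriched** when it is called with direction
up-in-VAT in all eight comparisons, and SAT-specifically enriched in the
symmetric case. A single failed or reversed comparison voids the call.

## Clustering

The source study reports the dendrogram but not the metric, linkage or
scaling, so the package uses the standard expression-profile configuration
and exposes every piece: co-expressed (category-1) miRNAs only, `log2(RPM +
1)` transform, `1 − Pearson` correlation distance, average linkage (UPGMA).
The pseudocount guards configuration variants; category-1 profiles are
nonzero everywhere by construction. `depotSplit()` answers the specific
topological question — does the smallest clade containing both subcutaneous
libraries exclude every visceral library — rather than eyeballing the
figure. Ties in merging are resolved deterministically by `stats::hclust`,
and dendrograms are serialized to Newick with branch lengths derived from
merge heights.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
study-design defaults chosen once:

* **Six libraries** with the GOM/MAD/PAD/RAD/ULB/ILB depot layout and a
  fixed sequencing depth of 2 × 10⁶ reads per library (fixed depth is the
  conditioning the count tests assume; sampling is multinomial per library,
  not Poisson).
* **Presence structure**: 70% of unique matures universal, 13% expressed in
  exactly one library with weight 0.55 toward GOM, the remainder in a
  random 2–5 library subset.
* **Abundance**: log-normal baseline with `sdlog = 2.8`, which makes the
  ten most abundant miRNAs carry roughly three quarters of all miRNA
  reads, as in real adipose small RNA libraries. Universal miRNAs are
  floored at 1.2 × 10⁻⁵ of depth so the co-expressed core is detectable
  everywhere at the design depth — that detectability is what makes them
  category-1 in real data too.
* **Planted effects**: 30 VAT-enriched and 30 SAT-enriched miRNAs at fold
  8, drawn from the universal pool with baseline expected counts
  log-uniform between 10⁻⁴ and 1.5 × 10⁻³ of depth (200–3000 expected
  reads at default depth). The two enriched sets share one vector of
  baseline draws ("balanced planting"), so the total planted mass is
  identical in the two depot classes: under fixed-depth sequencing an
  imbalance would shift the composition of every null miRNA
  depot-consistently and corrupt both the false-positive rate and the
  effective fold change. Library-specific and partial miRNAs are
  low-abundance by design (log-uniform between the floor and 5 × 10⁻⁴ of
  depth) for the same compositional reason.
* **Reads**: each read is the mature sequence (optionally with ±2 nt 3'
  jitter) followed by the 3' adapter, emitted at a fixed 36-nt machine
  length so trimming is always exercised, with substitution errors at
  10⁻³ per base, undetermined bases at 10⁻⁴, and a 15% contaminant read
  fraction drawn as random substrings of the contaminant references.
  Identifiers record the true source, keeping every read attributable.

Everything is a pure function of `(params, seed)`; one user seed is fanned
out to fixed per-stage streams so stages stay reproducible in isolation.

What the generator does **not** model: hairpin secondary structure, indels,
quality-score variation (constant Phred 40), per-library depth
heterogeneity (real libraries vary around 21 M raw reads; depth is a free
parameter here), PCR duplication, and cross-mapping between near-identical
miRNA family members. Tests passing on this generator therefore validate
the bookkeeping and the statistics of the pipeline, not its robustness to
alignment ambiguity in real genomes.

## Problem sizes and tolerances in the test suite

The test and acceptance suites run the generator at sizes chosen to make
the statistical checks sharp while keeping a full run in the minutes range
on one core: the enrichment-recovery check uses the full design conditions
(depth 2 × 10⁶, 30 + 30 planted effects, 20 seeds); family-wise error uses
2000 null miRNAs at depth 10⁶ over 50 replicates; the dendrogram split uses
40 replicates at depth 5 × 10⁵, where the planted effects are still far
above the noise floor; exactness checks (the statistical-test oracles, the
hand-built read cascade) are deterministic. The Audic–Claverie
implementation is verified against brute-force log-space summation to a
relative 10⁻⁸ over a count grid; Fisher against full hypergeometric
enumeration for every table with margins up to 60; the chi-squared
statistic against the closed form to 10⁻¹⁰.

## Known limitations

* With no replicates, the count tests measure sampling noise only;
  biological variability between animals is invisible to them. The
  consensus-of-three rule and the extreme threshold are blunt instruments
  that substitute for replication — the package reproduces that procedure,
  it does not endorse it for new designs.
* Exact mapping means any sequencing error unmaps a tag rather than
  mismapping it; with the default error rate this loses ~2% of reads and
  creates no bias, but `maxMismatch = 1` is available when reference and
  reads are expected to diverge.
* The enrichment caller requires strict 8/8 agreement; a single library
  with a technical problem suppresses all enrichment calls rather than
  producing wrong ones.
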