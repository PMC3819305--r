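# adipomiR

Small RNA-seq analysis of microRNA transcriptomes across adipose depots,
as a tested, reusable R package.

## The problem

Visceral (VAT) and subcutaneous (SAT) adipose tissues are metabolically and
clinically distinct, and their differences are partly written in their
microRNA complements. A classic way to probe this is one pooled small-RNA
library per depot — e.g. four visceral depots (greater omentum GOM,
mesenteric MAD, pericardial PAD, retroperitoneal RAD) and two subcutaneous
back-fat layers (ULB, ILB) — followed by a count-based comparison of every
visceral against every subcutaneous library. With one library per tissue
and no replicates, everything rests on careful filtering and on exact
two-library count statistics. adipomiR packages that workflow: read QC and
collapsing to unique tags, contaminant removal, two-tier precursor mapping
with known / novel-star / conserved classification, tissue-presence
categorization, a three-test consensus differential-expression procedure,
depot-specific enrichment calling, and hierarchical clustering — plus a
synthetic-data generator with exported ground truth that exercises all of
it end to end.

## The statistics at the core

For a miRNA with counts `x` and `y` in libraries of `N1` and `N2`
high-quality reads, three two-sided tests are computed:

- **Audic–Claverie**: tails of the posterior
  `P(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`, doubled and
  capped at 1. This posterior is the negative binomial with size `x+1` and
  probability `N1/(N1+N2)`, so tails are evaluated exactly via `pnbinom`.
  Tails are always conditioned on the larger of the two counts, making the
  statistic exchangeable between libraries.
- **Fisher exact** on the 2×2 table `(x, N1−x; y, N2−y)` — the summed
  hypergeometric mass of tables no more probable than the observed one.
- **Pearson chi-squared** (no continuity correction), with p forced to 1
  and flagged when an expected cell drops below 1.

Each test is Bonferroni-corrected with the family = the miRNAs tested in
that comparison, and a miRNA is differentially expressed only when **all
three** corrected p-values are below `1e-5` simultaneously. A miRNA called
with the same direction in **all eight** VAT-vs-SAT comparisons is
depot-specifically enriched. Co-expressed miRNAs are clustered with
1 − Pearson distance and average linkage on `log2(RPM+1)` profiles.

## Worked example

A self-contained synthetic study: 80 precursor hairpins, six libraries of
100,000 reads with 6 + 6 planted eight-fold depot effects, through the full
pipeline:

```r
library(adipomiR)

cfg <- runConfig(simulate = TRUE,
                 simParams = list(nPorcine = 60L, nConserved = 20L,
                                  nContaminants = 12L,
                                  readsPerLibrary = 100000L,
                                  nVatEnriched = 6L, nSatEnriched = 6L),
                 seed = 7L)
rep <- runAll(cfg, "demo_run")

str(rep$qc$GOM)
#> List of 5
#>  $ raw             : int 100000
#>  $ adapter_trimmed : int 99108
#>  $ length_pass     : int 99108
#>  $ composition_pass: int 99108
#>  $ high_quality    : int 89603

rep$quantify$matrix_dim        # 99 unique miRNAs x 6 libraries
rep$quantify$category_counts   # 70  3  4  4  5 13
rep$diffexp$de_counts$GOM_vs_ILB  # up 6, down 6
c(rep$diffexp$vat_specific, rep$diffexp$sat_specific)  # 6 6
rep$cluster$depot_split        # TRUE
```

Reading the output: ~99.1% of reads had a detectable adapter and a clean
14–27 nt insert, and 89,603 reads per library survived the per-library
copy-number filter ("high-quality reads"). The 99 unique miRNAs split into
presence categories with 70 co-expressed in all six libraries (category 1)
and 13 seen in exactly one (category 6). The GOM-vs-ILB comparison calls
exactly the 6 up- and 6 down-planted miRNAs; all 12 planted effects are
recovered as depot-specifically enriched with no false calls, and the
dendrogram of the 70 co-expressed miRNAs' profiles isolates {ULB, ILB}
from the four visceral depots.

Every stage writes plain TSV/JSON/FASTA/FASTQ/Newick files into the run
directory (`tags.tsv`, `annotation.tsv`, `counts.tsv`, `de_*.tsv`,
`enrichment.tsv`, `dendrogram.nwk`, `run_report.json`, ...), so stages are
independently re-runnable and diffable. A thin command-line front end over
the same functions is included at `inst/scripts/adipomir.R`.

## Package layout

- `R/` — S4 classes (`SimParams`, `MirnaReferenceSet`, `GroundTruth`,
  `MirnaExperiment` extending `SummarizedExperiment`) and the stage
  functions.
- `tests/testthat/` — unit, property and acceptance suites, including
  brute-force oracles for all three count tests and a naive UPGMA
  implementation for the clustering.
- `vignettes/adipose-mirna-methods.Rmd` — the full methods account:
  models, conventions, generator design, numerical choices, limitations.
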