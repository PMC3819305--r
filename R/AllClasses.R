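#' @include utils.R
NULL

# Default six-library design: four visceral depots, two subcutaneous.
.DEFAULT_LIBRARIES <- data.frame(
  name  = c("GOM", "MAD", "PAD", "RAD", "ULB", "ILB"),
  depot = c("VAT", "VAT", "VAT", "VAT", "SAT", "SAT"),
  stringsAsFactors = FALSE
)

#' SimParams: parameters of the synthetic small RNA study generator
#'
#' Holds every knob of the synthetic-data generator. Defaults encode the
#' study design the package emulates: six libraries (GOM, MAD, PAD, RAD
#' visceral; ULB, ILB subcutaneous), roughly 70\% of unique miRNAs
#' co-expressed in all six, a minority expressed in exactly one library
#' (concentrated in GOM), and planted eight-fold depot-enrichment effects on
#' a balanced set of visceral- and subcutaneous-enriched miRNAs.
#'
#' @slot nPorcine number of porcine (first-tier) precursor hairpins.
#' @slot nConserved number of conserved-mammal (second-tier) precursors.
#' @slot nContaminants number of contaminant reference sequences
#'   (rRNA/tRNA/snRNA/snoRNA/mRNA/repeat surrogates).
#' @slot precursorLen hairpin length in nt.
#' @slot matureLenMean,matureLenSd mature miRNA length distribution (nt).
#' @slot starFrac fraction of porcine precursors carrying a second,
#'   undocumented (star-arm) mature annotation.
#' @slot sharedMatureFrac fraction of porcine precursors whose documented
#'   mature duplicates that of another precursor (drives the many-to-one
#'   precursor-to-unique-mature collapse).
#' @slot libraries data.frame with columns `name` and `depot` (VAT/SAT).
#' @slot baseMeanlog,baseSdlog log-normal parameters of relative baseline
#'   abundance. The heavy default tail (`baseSdlog = 2.8`) reproduces the
#'   concentration of real small RNA libraries, where the ten most abundant
#'   miRNAs carry about three quarters of all miRNA reads.
#' @slot fracUniversal fraction of unique matures co-expressed in all
#'   libraries.
#' @slot fracSpecific fraction expressed in exactly one library.
#' @slot specificLibWeight named numeric; probability weight that a
#'   library-specific miRNA lands in the named library (remaining mass is
#'   spread uniformly over the other libraries).
#' @slot nVatEnriched,nSatEnriched numbers of planted depot-enriched miRNAs
#'   (drawn from the universal pool).
#' @slot foldChange multiplicative planted effect (>= 1; 1 = null).
#' @slot enrichedBaseRange length-2 numeric; planted miRNAs get baseline
#'   expected counts drawn log-uniformly from this range, expressed as a
#'   fraction of library depth (default 1e-4 to 1.5e-3, i.e. 200 to 3000
#'   expected reads at the default depth of 2e6).
#' @slot universalFloorFrac floor on the expected count of universal miRNAs,
#'   as a fraction of depth, so the co-expressed core is detectable in every
#'   library at the design depth.
#' @slot minorMaxFrac cap on the expected count of library-specific and
#'   partially expressed miRNAs (fraction of depth); keeps presence/absence
#'   structure from perturbing library composition.
#' @slot readsPerLibrary sequencing depth per library (reads).
#' @slot contaminantFrac fraction of reads drawn from contaminant sources.
#' @slot adapter 3' sequencing adapter appended to every insert.
#' @slot readLen fixed machine read length (nt).
#' @slot errorRate per-base substitution probability.
#' @slot nRate per-base probability of an undetermined (N) base.
#' @slot lenJitterSd standard deviation of mature 3'-end length jitter (nt);
#'   0 disables isomiR-style end heterogeneity.
#' @slot seed integer seed; all generator output is a pure function of
#'   (params, seed).
#' @seealso [simParams()], [simulateSmallRnaStudy()]
#' @export
setClass("SimParams", representation(
  nPorcine = "integer", nConserved = "integer", nContaminants = "integer",
  precursorLen = "integer", matureLenMean = "numeric", matureLenSd = "numeric",
  starFrac = "numeric", sharedMatureFrac = "numeric",
  libraries = "data.frame",
  baseMeanlog = "numeric", baseSdlog = "numeric",
  fracUniversal = "numeric", fracSpecific = "numeric",
  specificLibWeight = "numeric",
  nVatEnriched = "integer", nSatEnriched = "integer", foldChange = "numeric",
  enrichedBaseRange = "numeric", universalFloorFrac = "numeric",
  minorMaxFrac = "numeric",
  readsPerLibrary = "integer", contaminantFrac = "numeric",
  adapter = "character", readLen = "integer",
  errorRate = "numeric", nRate = "numeric", lenJitterSd = "numeric",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character(0)
  fr <- c(object@fracUniversal, object@fracSpecific, object@starFrac,
          object@sharedMatureFrac, object@contaminantFrac)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must lie in [0, 1]")
  if (object@fracUniversal + object@fracSpecific > 1)
    msg <- c(msg, "fracUniversal + fracSpecific must not exceed 1")
  if (object@foldChange < 1)
    msg <- c(msg, "foldChange must be >= 1 (1 encodes the null)")
  libs <- object@libraries
  if (!all(c("name", "depot") %in% names(libs)))
    msg <- c(msg, "libraries must have columns 'name' and 'depot'")
  else {
    if (anyDuplicated(libs$name)) msg <- c(msg, "library names must be unique")
    if (!all(libs$depot %in% c("VAT", "SAT")))
      msg <- c(msg, "depot must be 'VAT' or 'SAT'")
    if ((object@nVatEnriched > 0 || object@nSatEnriched > 0) &&
        (!any(libs$depot == "VAT") || !any(libs$depot == "SAT")))
      msg <- c(msg, "planted enrichment requires >= 1 library per depot class")
  }
  if (object@precursorLen < 2 * object@matureLenMean)
    msg <- c(msg, "precursorLen must be >= twice matureLenMean (arms would overlap)")
  if (length(object@enrichedBaseRange) != 2 ||
      any(object@enrichedBaseRange <= 0) ||
      diff(object@enrichedBaseRange) < 0)
    msg <- c(msg, "enrichedBaseRange must be an increasing positive pair")
  if (object@universalFloorFrac >= object@minorMaxFrac)
    msg <- c(msg, "universalFloorFrac must be below minorMaxFrac")
  if (object@readLen < 14) msg <- c(msg, "readLen must be >= 14")
  if (nchar(object@adapter) < 8)
    msg <- c(msg, "adapter must be at least 8 nt (trimming seed length)")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' See [SimParams-class] for the meaning of every field; arguments override
#' the study-design defaults.
#'
#' @param nPorcine,nConserved,nContaminants reference set sizes.
#' @param precursorLen,matureLenMean,matureLenSd,starFrac,sharedMatureFrac
#'   hairpin geometry and annotation structure.
#' @param libraries data.frame of library `name` / `depot` (VAT or SAT).
#' @param baseMeanlog,baseSdlog log-normal baseline abundance.
#' @param fracUniversal,fracSpecific,specificLibWeight presence structure.
#' @param nVatEnriched,nSatEnriched,foldChange,enrichedBaseRange planted
#'   effects.
#' @param universalFloorFrac,minorMaxFrac expected-count floor/cap (fraction
#'   of depth).
#' @param readsPerLibrary,contaminantFrac,adapter,readLen,errorRate,nRate,lenJitterSd
#'   read-level generation.
#' @param seed integer seed.
#' @return a validated [SimParams-class] object.
#' @examples
#' p <- simParams(readsPerLibrary = 5e4, seed = 7)
#' p
#' @export
simParams <- function(nPorcine = 150L, nConserved = 60L, nContaminants = 30L,
                      precursorLen = 80L, matureLenMean = 22, matureLenSd = 1,
                      starFrac = 0.5, sharedMatureFrac = 0.04,
                      libraries = .DEFAULT_LIBRARIES,
                      baseMeanlog = 0, baseSdlog = 2.8,
                      fracUniversal = 0.70, fracSpecific = 0.13,
                      specificLibWeight = c(GOM = 0.55),
                      nVatEnriched = 30L, nSatEnriched = 30L, foldChange = 8,
                      enrichedBaseRange = c(1e-4, 1.5e-3),
                      universalFloorFrac = 1.2e-5, minorMaxFrac = 5e-4,
                      readsPerLibrary = 2e6, contaminantFrac = 0.15,
                      adapter = "TCGTATGCCGTCTTCTGCTTG", readLen = 36L,
                      errorRate = 0.001, nRate = 1e-4, lenJitterSd = 0,
                      seed = 1L) {
  new("SimParams",
      nPorcine = as.integer(nPorcine), nConserved = as.integer(nConserved),
      nContaminants = as.integer(nContaminants),
      precursorLen = as.integer(precursorLen),
      matureLenMean = matureLenMean, matureLenSd = matureLenSd,
      starFrac = starFrac, sharedMatureFrac = sharedMatureFrac,
      libraries = as.data.frame(libraries),
      baseMeanlog = baseMeanlog, baseSdlog = baseSdlog,
      fracUniversal = fracUniversal, fracSpecific = fracSpecific,
      specificLibWeight = specificLibWeight,
      nVatEnriched = as.integer(nVatEnriched),
      nSatEnriched = as.integer(nSatEnriched),
      foldChange = foldChange, enrichedBaseRange = enrichedBaseRange,
      universalFloorFrac = universalFloorFrac, minorMaxFrac = minorMaxFrac,
      readsPerLibrary = as.integer(readsPerLibrary),
      contaminantFrac = contaminantFrac, adapter = adapter,
      readLen = as.integer(readLen), errorRate = errorRate, nRate = nRate,
      lenJitterSd = lenJitterSd, seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  libs <- object@libraries
  cat("SimParams:", object@nPorcine, "porcine +", object@nConserved,
      "conserved precursors,", object@nContaminants, "contaminants\n")
  cat("  libraries:", paste0(libs$name, "(", libs$depot, ")", collapse = " "), "\n")
  cat(sprintf("  presence: %.0f%% universal, %.0f%% library-specific\n",
              100 * object@fracUniversal, 100 * object@fracSpecific))
  cat(sprintf("  planted effects: %d VAT / %d SAT at fold %.3g\n",
              object@nVatEnriched, object@nSatEnriched, object@foldChange))
  cat(sprintf("  depth: %d reads/library, adapter %s, error %.2g, seed %d\n",
              object@readsPerLibrary, object@adapter, object@errorRate,
              object@seed))
})

#' MirnaReferenceSet: precursor and contaminant references
#'
#' Two-tier precursor references (porcine first tier, conserved-mammal second
#' tier) with mature-arm annotations, plus contaminant sequences standing in
#' for the rRNA/tRNA/snRNA/snoRNA/mRNA/repeat classes that are removed before
#' miRNA identification.
#'
#' @slot precursors [Biostrings::DNAStringSet] of hairpin sequences, named by
#'   precursor id.
#' @slot tier character vector parallel to `precursors`; `"porcine"` or
#'   `"conserved_mammal"`.
#' @slot arms data.frame of mature-arm annotations with columns
#'   `precursor_id`, `arm` (5p/3p), `start`, `end` (0-based half-open),
#'   `mature_name`, `documented` (yes/no).
#' @slot contaminants [Biostrings::DNAStringSet] of contaminant references.
#' @export
setClass("MirnaReferenceSet", representation(
  precursors = "DNAStringSet", tier = "character",
  arms = "data.frame", contaminants = "DNAStringSet"
))

setValidity("MirnaReferenceSet", function(object) {
  msg <- character(0)
  if (length(object@tier) != length(object@precursors))
    msg <- c(msg, "tier must be parallel to precursors")
  if (!all(object@tier %in% c("porcine", "conserved_mammal")))
    msg <- c(msg, "tier values must be 'porcine' or 'conserved_mammal'")
  need <- c("precursor_id", "arm", "start", "end", "mature_name", "documented")
  if (!all(need %in% names(object@arms))) {
    msg <- c(msg, paste("arms must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(object@arms)) {
    w <- setNames(width(object@precursors), names(object@precursors))
    a <- object@arms
    if (!all(a$precursor_id %in% names(w)))
      msg <- c(msg, "arm annotations refer to unknown precursors")
    else if (any(a$start < 0) || any(a$end > w[a$precursor_id]) ||
             any(a$end <= a$start))
      msg <- c(msg, "arm intervals must lie within their precursor")
    doc <- a[a$documented == "yes", ]
    if (nrow(doc)) {
      byPrec <- split(doc, doc$precursor_id)
      bad <- vapply(byPrec, function(d) {
        if (nrow(d) < 2) return(FALSE)
        d <- d[order(d$start), ]
        any(d$start[-1] < d$end[-nrow(d)])
      }, logical(1))
      if (any(bad))
        msg <- c(msg, "documented mature intervals overlap within a precursor")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MirnaReferenceSet", function(object) {
  cat("MirnaReferenceSet:",
      sum(object@tier == "porcine"), "porcine +",
      sum(object@tier == "conserved_mammal"), "conserved precursors;",
      nrow(object@arms), "mature-arm annotations (",
      sum(object@arms$documented == "yes"), "documented );",
      length(object@contaminants), "contaminants\n")
})

#' @describeIn MirnaReferenceSet-class precursor sequences.
#' @param x,object a `MirnaReferenceSet`.
#' @export
precursors <- function(x) x@precursors

#' @describeIn MirnaReferenceSet-class precursor tier labels.
#' @export
precursorTier <- function(x) x@tier

#' @describeIn MirnaReferenceSet-class mature-arm annotation table.
#' @export
matureArms <- function(x) x@arms

#' @describeIn MirnaReferenceSet-class contaminant sequences.
#' @export
contaminants <- function(x) x@contaminants

#' GroundTruth: the generative state behind a synthetic study
#'
#' Expected counts, presence labels, and planted effects for every unique
#' mature sequence, as produced by [simulateTruth()]. Serves as the recovery
#' oracle for the analysis stages.
#'
#' @slot expected numeric matrix of expected read counts, unique matures in
#'   rows (named), libraries in columns.
#' @slot labels data.frame with one row per unique mature: `mature_name`,
#'   `sequence`, `class` (known/novel_star/conserved),
#'   `presence` (universal/specific/partial), `specific_library` (NA unless
#'   presence == specific), `effect` (vat_enriched/sat_enriched/none).
#' @slot matureMap data.frame mapping unique mature sequences to the
#'   precursor(s) encoding them (`precursor_ids` comma-separated).
#' @slot libraries data.frame of library `name` / `depot`.
#' @export
setClass("GroundTruth", representation(
  expected = "matrix", labels = "data.frame", matureMap = "data.frame",
  libraries = "data.frame"
))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (any(object@expected < 0)) msg <- c(msg, "expected counts must be >= 0")
  if (nrow(object@labels) != nrow(object@expected))
    msg <- c(msg, "labels must have one row per expected-count row")
  if (!identical(colnames(object@expected), object@libraries$name))
    msg <- c(msg, "expected columns must match the library table")
  lab <- object@labels
  if (nrow(lab)) {
    if (any(lab$effect != "none" & lab$presence != "universal"))
      msg <- c(msg, "planted effects are only allowed on universal miRNAs")
    if (any(lab$effect == "vat_enriched" & lab$effect == "sat_enriched"))
      msg <- c(msg, "a miRNA cannot be both VAT- and SAT-enriched")
    sp <- lab$presence == "specific"
    nz <- rowSums(object@expected > 0)
    if (any(nz[sp] != 1))
      msg <- c(msg, "library-specific miRNAs must have exactly one nonzero column")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  lab <- object@labels
  cat("GroundTruth:", nrow(lab), "unique matures x",
      ncol(object@expected), "libraries\n")
  cat("  presence:", paste(names(table(lab$presence)),
                           table(lab$presence), collapse = ", "), "\n")
  cat("  effects:", paste(names(table(lab$effect)),
                          table(lab$effect), collapse = ", "), "\n")
})

#' @describeIn GroundTruth-class expected-count matrix.
#' @param x a `GroundTruth`.
#' @export
expectedCounts <- function(x) x@expected

#' @describeIn GroundTruth-class per-mature label table.
#' @export
truthLabels <- function(x) x@labels

#' MirnaExperiment: a unique-miRNA by library count container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding the
#' unique-mature count matrix. `colData` carries the depot class (`depot`,
#' VAT or SAT) and the high-quality read total of each library (`libTotal`),
#' which is the denominator for reads-per-million normalization and for the
#' two-library count tests.
#'
#' @seealso [buildMatrix()], [rpm()], [categorize()]
#' @export
setClass("MirnaExperiment", contains = "SummarizedExperiment")

setValidity("MirnaExperiment", function(object) {
  msg <- character(0)
  cd <- colData(object)
  if (!all(c("depot", "libTotal") %in% names(cd)))
    msg <- c(msg, "colData must have 'depot' and 'libTotal'")
  else {
    if (!all(cd$depot %in% c("VAT", "SAT")))
      msg <- c(msg, "depot must be 'VAT' or 'SAT'")
    if (any(cd$libTotal <= 0))
      msg <- c(msg, "library totals must be positive")
    if (any(colSums(assay(object)) > cd$libTotal))
      msg <- c(msg, "miRNA-attributed counts cannot exceed library totals")
  }
  m <- assay(object)
  if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
  if (nrow(m) && any(rowSums(m) == 0))
    msg <- c(msg, "all-zero rows are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct a MirnaExperiment
#'
#' @param counts integer matrix, unique matures in rows (named), libraries in
#'   columns (named).
#' @param depot character vector of depot classes (VAT/SAT), one per column.
#' @param libTotals numeric vector of high-quality read totals per library.
#' @param rowData optional data.frame of per-mature annotation (class,
#'   precursors, sequence).
#' @return a [MirnaExperiment-class].
#' @examples
#' m <- matrix(5L, 2, 6, dimnames = list(c("miR-a", "miR-b"),
#'             c("GOM", "MAD", "PAD", "RAD", "ULB", "ILB")))
#' MirnaExperiment(m, depot = c(rep("VAT", 4), rep("SAT", 2)),
#'                 libTotals = rep(1000, 6))
#' @export
MirnaExperiment <- function(counts, depot, libTotals, rowData = NULL) {
  cd <- DataFrame(depot = depot, libTotal = libTotals,
                  row.names = colnames(counts))
  se <- if (is.null(rowData)) {
    SummarizedExperiment(assays = list(counts = counts), colData = cd)
  } else {
    SummarizedExperiment(assays = list(counts = counts), colData = cd,
                         rowData = DataFrame(rowData))
  }
  new("MirnaExperiment", se)
}

setMethod("show", "MirnaExperiment", function(object) {
  callNextMethod()
  cd <- colData(object)
  cat("depots:", paste0(rownames(cd), "=", cd$depot, collapse = " "), "\n")
})

#' Library totals of a MirnaExperiment
#' @param x a [MirnaExperiment-class].
#' @return named numeric vector of high-quality read totals.
#' @export
libraryTotals <- function(x) {
  stopifnot(is(x, "MirnaExperiment"))
  setNames(colData(x)$libTotal, colnames(x))
}

#' Depot class of each library
#' @param x a [MirnaExperiment-class].
#' @return named character vector, "VAT" or "SAT" per library.
#' @export
depotClass <- function(x) {
  stopifnot(is(x, "MirnaExperiment"))
  setNames(as.character(colData(x)$depot), colnames(x))
}
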