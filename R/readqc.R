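#' @include utils.R
NULL

#' Read-filtering parameters
#'
#' The QC cascade retains reads that (i) contain the 3' adapter, (ii) have an
#' insert of 14-27 nt, (iii) are not dominated by a single base (no base may
#' exceed 80\% of the insert) and carry at most two undetermined (N) bases,
#' and, after collapsing to distinct sequences, (iv) reach at least 3 copies
#' in a library. Boundaries are inclusive: a 14-nt or 27-nt insert passes, an
#' insert with exactly 80\% of one base passes, exactly two Ns pass, exactly
#' 3 copies pass.
#'
#' @param adapter 3' adapter sequence (>= `seedLen` nt).
#' @param minLen,maxLen inclusive insert length window (nt).
#' @param maxBaseFrac maximum fraction any single base may take (inclusive).
#' @param maxN maximum number of N bases (inclusive).
#' @param minCopies minimum per-library copy number of a distinct tag
#'   (inclusive); lower-copy tags are zeroed in that library.
#' @param seedLen number of leading adapter bases used as the exact trimming
#'   seed.
#' @param requireAdapter drop reads without a detectable adapter (the insert
#'   boundary is otherwise unknown).
#' @return a validated list of class `FilterParams`.
#' @export
filterParams <- function(adapter = "TCGTATGCCGTCTTCTGCTTG",
                         minLen = 14L, maxLen = 27L,
                         maxBaseFrac = 0.80, maxN = 2L, minCopies = 3L,
                         seedLen = 8L, requireAdapter = TRUE) {
  stopifnot(minLen <= maxLen, maxBaseFrac > 0, maxBaseFrac <= 1,
            minCopies >= 1, maxN >= 0, nchar(adapter) >= seedLen,
            seedLen >= 1)
  structure(list(adapter = adapter, minLen = as.integer(minLen),
                 maxLen = as.integer(maxLen), maxBaseFrac = maxBaseFrac,
                 maxN = as.integer(maxN), minCopies = as.integer(minCopies),
                 seedLen = as.integer(seedLen),
                 requireAdapter = isTRUE(requireAdapter)),
            class = "FilterParams")
}

#' Trim the 3' adapter from reads
#'
#' The insert is the prefix of the read before the leftmost exact occurrence
#' of the first `seedLen` adapter bases. Reads with no adapter match are
#' dropped when `requireAdapter` is set (returned as `NA`), as is any read
#' whose insert would be empty (adapter at position 1).
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence.
#' @param seedLen exact-match seed length (default 8).
#' @param requireAdapter drop reads without an adapter match.
#' @return character vector of inserts, `NA` for dropped reads.
#' @examples
#' trimAdapter(c("ACGTACGTACGTACTCGTATGC", "TCGTATGCAAAA", "AAAA"),
#'             adapter = "TCGTATGCCGTCTTCTGCTTG")
#' @export
trimAdapter <- function(reads, adapter, seedLen = 8L, requireAdapter = TRUE) {
  stopifnot(nchar(adapter) >= seedLen, seedLen >= 1)
  seed <- substr(adapter, 1, seedLen)
  pos <- regexpr(seed, reads, fixed = TRUE)
  out <- rep(NA_character_, length(reads))
  hit <- pos > 1L
  out[hit] <- substr(reads[hit], 1L, pos[hit] - 1L)
  if (!requireAdapter) {
    none <- pos == -1L
    out[none] <- reads[none]
  }
  out
}

#' Insert length filter
#'
#' @param seqs character vector of insert sequences.
#' @param minLen,maxLen inclusive bounds (nt).
#' @return logical vector; `TRUE` when `minLen <= nchar(seq) <= maxLen`.
#' @export
passesLength <- function(seqs, minLen = 14L, maxLen = 27L) {
  n <- nchar(seqs)
  n >= minLen & n <= maxLen
}

#' Base-composition filter
#'
#' A sequence passes when no single base (A, C, G or T) makes up more than
#' `maxBaseFrac` of its length and it carries at most `maxN` undetermined
#' bases. Both bounds are inclusive, so a 15-mer with exactly twelve As
#' (80\%) or exactly two Ns passes. Sequences containing symbols outside
#' A/C/G/T/N are an error.
#'
#' @param seqs character vector over the A/C/G/T/N alphabet.
#' @param maxBaseFrac inclusive single-base fraction bound.
#' @param maxN inclusive N-count bound.
#' @return logical vector.
#' @export
passesComposition <- function(seqs, maxBaseFrac = 0.80, maxN = 2L) {
  len <- nchar(seqs)
  cnt <- function(b) len - nchar(gsub(b, "", seqs, fixed = TRUE))
  nA <- cnt("A"); nC <- cnt("C"); nG <- cnt("G"); nT <- cnt("T"); nN <- cnt("N")
  if (any(nA + nC + nG + nT + nN != len))
    stop("sequences must contain only A, C, G, T or N")
  maxBase <- pmax(nA, nC, nG, nT)
  # compare counts, with a tiny slack so the inclusive 80% boundary is exact
  maxBase <= maxBaseFrac * len + 1e-9 & nN <= maxN
}

#' Collapse reads into unique tags with per-library copy numbers
#'
#' @param readsByLib named list of character vectors (filtered inserts), one
#'   per library.
#' @return data.frame with column `sequence` plus one integer count column
#'   per library; per-library counts sum to the input read numbers.
#' @examples
#' collapseReads(list(L1 = c("ACGTACGTACGTAC", "ACGTACGTACGTAC"),
#'                    L2 = "TTTTCCCCAAAAGG"))
#' @export
collapseReads <- function(readsByLib) {
  stopifnot(is.list(readsByLib), !is.null(names(readsByLib)))
  tabs <- lapply(readsByLib, function(r) table(r[!is.na(r)]))
  seqs <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (lib in names(readsByLib)) {
    v <- integer(length(seqs))
    t <- tabs[[lib]]
    v[match(names(t), seqs)] <- as.integer(t)
    out[[lib]] <- v
  }
  out
}

#' Per-library copy-number filter
#'
#' Tags observed fewer than `minCopies` times in a library have their count
#' zeroed in that library (each library was sequenced and filtered
#' independently); tags left with no counts anywhere are dropped.
#'
#' @param tags tag table from [collapseReads()].
#' @param minCopies inclusive minimum copy number (default 3, i.e. copy
#'   number < 3 is excluded).
#' @return filtered tag table.
#' @export
copyFilter <- function(tags, minCopies = 3L) {
  stopifnot(minCopies >= 1)
  libCols <- setdiff(names(tags), "sequence")
  for (lib in libCols) {
    tags[[lib]][tags[[lib]] < minCopies] <- 0L
  }
  keep <- rowSums(as.matrix(tags[libCols])) > 0
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full QC cascade on raw reads
#'
#' Applies adapter trimming, the length filter, the composition filter,
#' collapsing into unique tags, and the per-library copy-number filter, and
#' assembles a per-library QC report. Survivor counts are monotonically
#' non-increasing through the cascade; this is asserted on every run.
#'
#' @param input either a named character vector of FASTQ paths (one per
#'   library) or a named list of raw read character vectors.
#' @param params a [filterParams()] list.
#' @return list with `tags` (surviving unique-tag table, see
#'   [collapseReads()]) and `report` (per-library cascade counts, insert
#'   length histogram of high-quality reads, and the filter parameters).
#' @export
runQC <- function(input, params = filterParams()) {
  stopifnot(inherits(params, "FilterParams"))
  readsByLib <- if (is.character(input)) {
    stopifnot(!is.null(names(input)))
    lapply(input, function(f)
      as.character(readDNAStringSet(f, format = "fastq")))
  } else input
  stopifnot(is.list(readsByLib), !is.null(names(readsByLib)))

  report <- list(libraries = list(), params = unclass(params))
  filtered <- list()
  for (lib in names(readsByLib)) {
    raw <- readsByLib[[lib]]
    ins <- trimAdapter(raw, params$adapter, params$seedLen,
                       params$requireAdapter)
    ins <- ins[!is.na(ins)]
    lenOk <- ins[passesLength(ins, params$minLen, params$maxLen)]
    compOk <- lenOk[passesComposition(lenOk, params$maxBaseFrac, params$maxN)]
    filtered[[lib]] <- compOk
    report$libraries[[lib]] <- list(
      raw = length(raw), adapter_trimmed = length(ins),
      length_pass = length(lenOk), composition_pass = length(compOk))
  }

  tags0 <- collapseReads(filtered)
  tags <- copyFilter(tags0, params$minCopies)

  for (lib in names(readsByLib)) {
    hq <- sum(tags[[lib]])
    rl <- report$libraries[[lib]]
    rl$distinct_tags <- sum(tags0[[lib]] > 0)
    rl$high_quality <- hq
    counts <- c(rl$raw, rl$adapter_trimmed, rl$length_pass,
                rl$composition_pass, hq)
    if (any(diff(counts) > 0))
      stop("QC cascade counts increased in library ", lib)
    len <- nchar(tags$sequence)
    rl$length_histogram <- as.list(tapply(tags[[lib]], len, sum))
    report$libraries[[lib]] <- rl
  }

  list(tags = tags, report = report)
}
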