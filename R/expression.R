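#' @include AllClasses.R
NULL

#' Build the unique-miRNA by library expression matrix
#'
#' Sums the per-library copy numbers of all tags assigned to each unique
#' mature. Unmapped tags are excluded (and reported via a message). The
#' matrix total therefore equals the total count of annotated tags.
#'
#' @param annot per-tag annotation from [classifyTags()] (or the `annot`
#'   element of [annotateTags()]).
#' @param tags the tag table the annotation refers to.
#' @param depot named character vector (or vector in column order) of depot
#'   classes, one per library column.
#' @param libTotals named numeric vector of high-quality read totals per
#'   library (defaults to the tag-table column sums).
#' @return a [MirnaExperiment-class]; row metadata carries the class,
#'   precursor ids and mature sequence of each unique miRNA.
#' @export
buildMatrix <- function(annot, tags, depot, libTotals = NULL) {
  libCols <- setdiff(names(tags), "sequence")
  if (is.null(libTotals)) libTotals <- colSums(as.matrix(tags[libCols]))
  libTotals <- libTotals[libCols]

  m <- merge(annot, tags, by = "sequence")
  dropped <- m$class == "unmapped"
  if (any(dropped))
    message(sum(dropped), " tag(s) assigned to no mature; excluded")
  m <- m[!dropped, , drop = FALSE]
  matures <- collapseUnique(m)
  if (!nrow(matures)) stop("no annotated tags; cannot build a matrix")

  counts <- matrix(0L, nrow(matures), length(libCols),
                   dimnames = list(matures$mature_name, libCols))
  key <- match(m$mature_seq, matures$mature_seq)
  for (j in seq_along(libCols)) {
    counts[, j] <- as.integer(
      rowsum(m[[libCols[j]]], group = key, reorder = TRUE))
  }

  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  matures <- matures[keep, , drop = FALSE]
  if (is.null(names(depot))) names(depot) <- libCols
  MirnaExperiment(counts, depot = depot[libCols], libTotals = libTotals,
                  rowData = data.frame(class = matures$class,
                                       precursor_ids = matures$precursor_ids,
                                       sequence = matures$mature_seq))
}

#' Reads-per-million normalization
#'
#' Each count is scaled by its library's high-quality read total:
#' `rpm = count / libTotal * 1e6`.
#'
#' @param x a [MirnaExperiment-class], or a count matrix.
#' @param totals library totals (only when `x` is a bare matrix).
#' @return numeric matrix of RPM values.
#' @export
setGeneric("rpm", function(x, totals) standardGeneric("rpm"))

#' @rdname rpm
setMethod("rpm", "MirnaExperiment", function(x, totals) {
  rpm(assay(x), libraryTotals(x))
})

#' @rdname rpm
setMethod("rpm", "matrix", function(x, totals) {
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(x, 2, totals, "/") * 1e6
})

#' Fraction of reads carried by the top-n miRNAs
#'
#' Per library: the summed counts of the `n` most abundant unique miRNAs
#' divided by the summed counts of all miRNAs. Ties are broken by
#' lexicographic miRNA name, so the statistic is deterministic.
#'
#' @param x a [MirnaExperiment-class] or count matrix with row names.
#' @param n number of top miRNAs (default 10).
#' @return named numeric vector of per-library fractions.
#' @export
topShare <- function(x, n = 10L) {
  stopifnot(n >= 1)
  m <- if (is(x, "MirnaExperiment")) assay(x) else x
  if (n > nrow(m)) {
    warning("n exceeds the number of miRNAs; share is 1")
    return(setNames(rep(1, ncol(m)), colnames(m)))
  }
  vapply(seq_len(ncol(m)), function(j) {
    ord <- order(-m[, j], rownames(m))
    sum(m[ord[seq_len(n)], j]) / sum(m[, j])
  }, numeric(1)) |> setNames(colnames(m))
}

#' Assign tissue-presence categories
#'
#' A miRNA is present in a library when its post-filter count is at least 1
#' (the per-library copy filter has already zeroed unreliable entries).
#' Categories follow the six-way scheme: present in all six libraries
#' (category 1), absent in exactly one (2), two (3), three (4) or four (5)
#' libraries, and present in exactly one library (6).
#'
#' @param x a [MirnaExperiment-class] or count matrix.
#' @return data.frame with `mirna`, `n_present`, `category`, and
#'   `present_libs` (comma-separated library names).
#' @export
categorize <- function(x) {
  m <- if (is(x, "MirnaExperiment")) assay(x) else x
  pres <- m >= 1
  nPresent <- rowSums(pres)
  if (any(nPresent == 0))
    stop("all-zero expression row(s): ",
         paste(head(rownames(m)[nPresent == 0]), collapse = ", "))
  nlib <- ncol(m)
  # present in all -> 1; absent in k (1..nlib-2) -> k+1; present in one -> nlib
  category <- ifelse(nPresent == nlib, 1L,
                     ifelse(nPresent == 1L, nlib, nlib - nPresent + 1L))
  data.frame(mirna = rownames(m), n_present = nPresent, category = category,
             present_libs = apply(pres, 1, function(p)
               paste(colnames(m)[p], collapse = ",")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize the tissue-presence categories
#'
#' Per-category counts and percentages (of all unique miRNAs), the pooled
#' count/percentage of the intermediate categories (2-5: expressed in more
#' than one and fewer than all libraries), and, within the single-library
#' category, the per-library breakdown with each library's share. Raw
#' percentages are carried alongside display values rounded half-up to two
#' decimals.
#'
#' @param assignment data.frame from [categorize()]; only the `category`
#'   column (and, for the single-library breakdown, `present_libs`) is used.
#' @param nCategories number of categories in the scheme (default 6).
#' @return list with `table` (category, n, pct, pct_display), `total`,
#'   `pooled_2_to_5` (n, pct, pct_display) and `specific_by_library`
#'   (library, n, pct-of-category, pct_display).
#' @examples
#' a <- data.frame(category = rep(1:6, c(284, 23, 13, 17, 19, 53)),
#'                 present_libs = "GOM")
#' s <- categorySummary(a)
#' s$table$pct_display[1]  # 69.44
#' @export
categorySummary <- function(assignment, nCategories = 6L) {
  stopifnot(all(assignment$category %in% seq_len(nCategories)))
  total <- nrow(assignment)
  n <- vapply(seq_len(nCategories), function(k)
    sum(assignment$category == k), integer(1))
  pct <- n / total * 100
  tab <- data.frame(category = seq_len(nCategories), n = n, pct = pct,
                    pct_display = roundHalfUp(pct, 2))
  mid <- seq(2L, nCategories - 1L)
  pooledN <- sum(n[mid])
  pooled <- list(n = pooledN, pct = pooledN / total * 100,
                 pct_display = roundHalfUp(pooledN / total * 100, 2))
  specific <- assignment[assignment$category == nCategories, , drop = FALSE]
  byLib <- if (nrow(specific) && "present_libs" %in% names(specific)) {
    t <- sort(table(specific$present_libs), decreasing = TRUE)
    data.frame(library = names(t), n = as.integer(t),
               pct = as.numeric(t) / nrow(specific) * 100,
               pct_display = roundHalfUp(as.numeric(t) / nrow(specific) * 100, 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(library = character(0), n = integer(0), pct = numeric(0),
               pct_display = numeric(0))
  }
  list(table = tab, total = total, pooled_2_to_5 = pooled,
       specific_by_library = byLib)
}
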