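#' @include AllClasses.R
NULL

#' Remove tags matching contaminant RNA classes
#'
#' A tag is discarded when its sequence occurs as an exact substring of any
#' contaminant reference on either strand; this removes the
#' rRNA/tRNA/snRNA/snoRNA/mRNA/repeat classes before miRNA identification.
#'
#' @param tags tag table (see [collapseReads()]).
#' @param contam a [Biostrings::DNAStringSet] of contaminant references.
#' @return the surviving tag table.
#' @export
filterContaminants <- function(tags, contam) {
  stopifnot(length(contam) > 0)
  subjects <- c(contam, reverseComplement(contam))
  hit <- vapply(tags$sequence, function(s) {
    any(vcountPattern(s, subjects, fixed = TRUE) > 0)
  }, logical(1), USE.NAMES = FALSE)
  out <- tags[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map tags to the two-tier precursor reference
#'
#' Full-length alignment of each tag within each precursor with at most
#' `maxMismatch` substitutions (default 0, exact), on the given strand only
#' (small RNA protocols are stranded). The porcine tier is searched first;
#' the conserved-mammal tier is consulted only for tags with no porcine hit.
#'
#' @param tags character vector of tag sequences (or a tag table with a
#'   `sequence` column).
#' @param refs a [MirnaReferenceSet-class].
#' @param maxMismatch maximum substitutions per alignment (default 0).
#' @return data.frame of hits: `sequence`, `precursor_id`, `tier`, `start`
#'   (0-based), `end` (half-open), `mismatches`. Tags without hits are
#'   absent.
#' @export
mapToPrecursors <- function(tags, refs, maxMismatch = 0L) {
  stopifnot(maxMismatch >= 0)
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  tierSplit <- split(seq_along(refs@precursors), refs@tier)
  porc <- refs@precursors[tierSplit[["porcine"]]]
  cons <- refs@precursors[tierSplit[["conserved_mammal"]]]

  scan <- function(s, subject, tierName) {
    if (length(subject) == 0) return(NULL)
    m <- vmatchPattern(s, subject, max.mismatch = maxMismatch, fixed = TRUE)
    si <- startIndex(m)
    n <- lengths(si)
    if (sum(n) == 0) return(NULL)
    idx <- rep(seq_along(subject), n)
    st <- unlist(si, use.names = FALSE)
    subjChars <- as.character(subject)[idx]
    frag <- substr(subjChars, st, st + nchar(s) - 1L)
    mm <- vapply(frag, function(f) {
      sum(utf8ToInt(f) != utf8ToInt(s))
    }, integer(1), USE.NAMES = FALSE)
    data.frame(sequence = s, precursor_id = names(subject)[idx],
               tier = tierName, start = st - 1L, end = st - 1L + nchar(s),
               mismatches = mm, stringsAsFactors = FALSE)
  }

  hits <- lapply(unique(seqs), function(s) {
    h <- scan(s, porc, "porcine")
    if (is.null(h)) h <- scan(s, cons, "conserved_mammal")
    h
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(sequence = character(0), precursor_id = character(0),
                      tier = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# Overlap in nt between [s1,e1) and [s2,e2).
.ivOverlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Classify mapped tags as known, novel star, or conserved miRNAs
#'
#' A tag is `known` when a porcine-tier hit overlaps a documented mature
#' interval by at least `minOverlap` nt (tolerating the few-nt end
#' heterogeneity of sequenced isomiRs while excluding opposite-arm reads);
#' `novel_star` when it hits a porcine precursor without overlapping any
#' documented interval (a read from the undocumented passenger arm); and
#' `conserved` when its only hits are on the conserved-mammal tier. Tags
#' with no hits are `unmapped`. Undocumented (star) annotation rows are
#' never consulted: novel stars are discovered from position alone and named
#' `<precursor>-<arm>-star` by which half of the hairpin they fall in.
#'
#' @param tags tag table (see [collapseReads()]).
#' @param hits hit table from [mapToPrecursors()].
#' @param refs the [MirnaReferenceSet-class] that was mapped against.
#' @param minOverlap minimum overlap (nt) with a documented mature interval
#'   to count as that mature (default 16).
#' @return data.frame with one row per tag: `sequence`, `class` (known /
#'   novel_star / conserved / unmapped), `mature_name`, `mature_seq` (the
#'   documented mature sequence, or the tag itself for novel stars), and
#'   `precursor_ids` (comma-separated).
#' @export
classifyTags <- function(tags, hits, refs, minOverlap = 16L) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  doc <- refs@arms[refs@arms$documented == "yes", , drop = FALSE]
  precSeq <- as.character(refs@precursors)
  plen <- setNames(width(refs@precursors), names(refs@precursors))
  doc$sequence <- substr(precSeq[doc$precursor_id], doc$start + 1, doc$end)

  one <- function(s) {
    h <- hits[hits$sequence == s, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(sequence = s, class = "unmapped",
                        mature_name = NA_character_,
                        mature_seq = NA_character_,
                        precursor_ids = NA_character_,
                        stringsAsFactors = FALSE))
    }
    d <- merge(h, doc, by = "precursor_id", suffixes = c("", ".arm"))
    if (nrow(d)) {
      d$ov <- .ivOverlap(d$start, d$end, d$start.arm, d$end.arm)
      d <- d[d$ov >= minOverlap, , drop = FALSE]
    }
    if (nrow(d)) {
      # documented mature: prefer the largest overlap, ties by name
      d <- d[order(-d$ov, d$mature_name), , drop = FALSE]
      cls <- if (d$tier[1] == "porcine") "known" else "conserved"
      sameMat <- d[d$sequence.arm == d$sequence.arm[1], , drop = FALSE]
      return(data.frame(sequence = s, class = cls,
                        mature_name = d$mature_name[1],
                        mature_seq = d$sequence.arm[1],
                        precursor_ids = paste(sort(unique(sameMat$precursor_id)),
                                              collapse = ","),
                        stringsAsFactors = FALSE))
    }
    if (any(h$tier == "porcine")) {
      hp <- h[h$tier == "porcine", , drop = FALSE]
      mid <- (hp$start + hp$end) / 2
      arm <- ifelse(mid < plen[hp$precursor_id] / 2, "5p", "3p")
      nm <- sort(paste0(hp$precursor_id, "-", arm, "-star"))[1]
      return(data.frame(sequence = s, class = "novel_star",
                        mature_name = nm, mature_seq = s,
                        precursor_ids = paste(sort(unique(hp$precursor_id)),
                                              collapse = ","),
                        stringsAsFactors = FALSE))
    }
    # conserved-tier hit with no sufficient documented overlap: still a
    # conserved match, keyed by the tag itself
    data.frame(sequence = s, class = "conserved",
               mature_name = sort(paste0(h$precursor_id, "-m"))[1],
               mature_seq = s,
               precursor_ids = paste(sort(unique(h$precursor_id)),
                                     collapse = ","),
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(seqs, one))
  rownames(out) <- NULL
  out
}

#' Collapse classified tags to unique mature miRNAs
#'
#' Records sharing an identical mature sequence are merged (several distinct
#' precursors can encode the same mature): precursor id lists are unioned,
#' the name is the lexicographically first contributing name, and the class
#' is the highest-priority one (known > novel_star > conserved).
#'
#' @param annot annotation table from [classifyTags()] (unmapped rows are
#'   ignored).
#' @return data.frame with one row per unique mature sequence:
#'   `mature_name`, `mature_seq`, `class`, `precursor_ids`.
#' @export
collapseUnique <- function(annot) {
  a <- annot[annot$class != "unmapped", , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(mature_name = character(0), mature_seq = character(0),
                      class = character(0), precursor_ids = character(0)))
  }
  prio <- c(known = 1L, novel_star = 2L, conserved = 3L)
  out <- lapply(split(a, a$mature_seq), function(d) {
    ids <- sort(unique(unlist(strsplit(d$precursor_ids, ","))))
    data.frame(mature_name = min(d$mature_name),
               mature_seq = d$mature_seq[1],
               class = names(prio)[min(prio[d$class])],
               precursor_ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$mature_name), ]
  rownames(out) <- NULL
  out
}

#' Annotate a tag table end to end
#'
#' Convenience wrapper: contaminant removal, two-tier precursor mapping,
#' classification, and the unique-mature collapse.
#'
#' @param tags tag table from [runQC()].
#' @param refs a [MirnaReferenceSet-class].
#' @param maxMismatch maximum substitutions in mapping (default 0).
#' @param minOverlap minimum documented-arm overlap in nt (default 16).
#' @return list with `tags` (tags surviving contaminant removal), `annot`
#'   (per-tag classification) and `matures` (unique mature table).
#' @export
annotateTags <- function(tags, refs, maxMismatch = 0L, minOverlap = 16L) {
  kept <- filterContaminants(tags, refs@contaminants)
  hits <- mapToPrecursors(kept, refs, maxMismatch)
  annot <- classifyTags(kept, hits, refs, minOverlap)
  list(tags = kept, annot = annot, matures = collapseUnique(annot))
}
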