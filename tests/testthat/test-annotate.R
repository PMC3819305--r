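# A small hand-built reference set used throughout this file.
makeRefs <- function() {
  set.seed(77)
  plen <- 80L
  pseq <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), plen, TRUE), collapse = ""),
    character(1))
  names(pseq) <- c("ssc-mir-001", "ssc-mir-002", "ssc-mir-003",
                   "oth-mir-001")
  # precursor 2 re-encodes precursor 1's documented mature verbatim
  m1 <- substr(pseq[1], 4, 25)
  substr(pseq[2], 4, 25) <- m1
  arms <- data.frame(
    precursor_id = c("ssc-mir-001", "ssc-mir-002", "ssc-mir-003",
                     "oth-mir-001"),
    arm = c("5p", "5p", "5p", "3p"),
    start = c(3L, 3L, 3L, 54L), end = c(25L, 25L, 25L, 76L),
    mature_name = c("ssc-miR-001-5p", "ssc-miR-002-5p", "ssc-miR-003-5p",
                    "oth-miR-001-3p"),
    documented = "yes", stringsAsFactors = FALSE)
  cont <- c(contam_tRNA_01 = paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                                   collapse = ""))
  new("MirnaReferenceSet",
      precursors = Biostrings::DNAStringSet(pseq),
      tier = c("porcine", "porcine", "porcine", "conserved_mammal"),
      arms = arms, contaminants = Biostrings::DNAStringSet(cont))
}

tagTable <- function(seqs) {
  data.frame(sequence = seqs, L1 = rep(5L, length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("contaminant filtering removes exact substrings on both strands", {
  refs <- makeRefs()
  cseq <- as.character(contaminants(refs))[1]
  inside <- substr(cseq, 40, 61)
  insideRc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(cseq, 10, 31))))
  unrelated <- "ACGTGGTTAACCGGTTAACCGT"
  tags <- tagTable(c(inside, insideRc, unrelated))
  kept <- filterContaminants(tags, contaminants(refs))
  expect_identical(kept$sequence, unrelated)

  # random tags against a brute-force all-pairs scan
  set.seed(5)
  rand <- replicate(30, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                              collapse = ""))
  rand <- unique(c(rand, substr(cseq, 1, 20), substr(cseq, 90, 112)))
  both <- c(cseq, as.character(Biostrings::reverseComplement(
    contaminants(refs))))
  oracle <- vapply(rand, function(s) any(grepl(s, both, fixed = TRUE)),
                   logical(1))
  got <- filterContaminants(tagTable(rand), contaminants(refs))
  expect_setequal(got$sequence, rand[!oracle])
})

test_that("mapping finds exact full-length hits at annotated offsets", {
  refs <- makeRefs()
  pseq <- as.character(precursors(refs))
  mat <- substr(pseq["ssc-mir-003"], 4, 25)
  hits <- mapToPrecursors(mat, refs)
  expect_equal(hits$precursor_id, "ssc-mir-003")
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 25L)
  expect_equal(hits$mismatches, 0L)

  # one substitution kills the exact-match hit
  mut <- mat
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mat, 10, 10))[1]
  expect_equal(nrow(mapToPrecursors(mut, refs)), 0)
  # ... but is recovered at maxMismatch = 1 with the mismatch counted
  h1 <- mapToPrecursors(mut, refs, maxMismatch = 1L)
  expect_equal(h1$precursor_id, "ssc-mir-003")
  expect_equal(h1$mismatches, 1L)
})

test_that("mismatch mapping equals a sliding-window Hamming oracle", {
  set.seed(6)
  plen <- 60L
  pseq <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), plen, TRUE), collapse = ""),
    character(1))
  names(pseq) <- sprintf("ssc-mir-%03d", 1:5)
  refs <- new("MirnaReferenceSet",
              precursors = Biostrings::DNAStringSet(pseq),
              tier = rep("porcine", 5),
              arms = data.frame(precursor_id = character(0),
                                arm = character(0), start = integer(0),
                                end = integer(0), mature_name = character(0),
                                documented = character(0)),
              contaminants = Biostrings::DNAStringSet(
                c(c1 = strrep("ACGT", 30))))
  tags <- character(12)
  for (i in seq_along(tags)) {
    src <- sample(5, 1); st <- sample(plen - 19, 1)
    t <- substr(pseq[src], st, st + 19)
    nmut <- sample(0:2, 1)
    for (m in seq_len(nmut)) {
      pos <- sample(20, 1)
      substr(t, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
    }
    tags[i] <- t
  }
  tags <- unique(tags)
  got <- mapToPrecursors(tags, refs, maxMismatch = 1L)
  # oracle: every window of every precursor, Hamming distance <= 1
  oracle <- list()
  for (s in tags) {
    L <- nchar(s); sv <- utf8ToInt(s)
    for (pid in names(pseq)) {
      for (st in 1:(plen - L + 1)) {
        w <- utf8ToInt(substr(pseq[pid], st, st + L - 1))
        mm <- sum(w != sv)
        if (mm <= 1) {
          oracle[[length(oracle) + 1]] <-
            data.frame(sequence = s, precursor_id = pid, start = st - 1L,
                       mismatches = mm)
        }
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  key <- function(d) sort(paste(d$sequence, d$precursor_id, d$start,
                                d$mismatches))
  expect_identical(key(got), key(oracle))
})

test_that("classification distinguishes known, novel star and conserved", {
  refs <- makeRefs()
  pseq <- as.character(precursors(refs))
  known <- substr(pseq["ssc-mir-003"], 4, 25)     # documented 5p arm
  star <- substr(pseq["ssc-mir-003"], 55, 76)     # opposite, undocumented
  cons <- substr(pseq["oth-mir-001"], 55, 76)     # conserved documented arm
  tags <- tagTable(c(known, star, cons))
  ann <- classifyTags(tags, mapToPrecursors(tags, refs), refs)
  expect_equal(ann$class[ann$sequence == known], "known")
  expect_equal(ann$mature_name[ann$sequence == known], "ssc-miR-003-5p")
  expect_equal(ann$class[ann$sequence == star], "novel_star")
  expect_equal(ann$mature_name[ann$sequence == star], "ssc-mir-003-3p-star")
  expect_equal(ann$class[ann$sequence == cons], "conserved")
  expect_equal(ann$mature_name[ann$sequence == cons], "oth-miR-001-3p")
})

test_that("no tag with a porcine hit is ever classified conserved", {
  # a sequence planted in both tiers resolves to the porcine tier
  refs <- makeRefs()
  pseq <- as.character(precursors(refs))
  shared <- substr(pseq["ssc-mir-003"], 4, 25)
  both <- pseq
  substr(both["oth-mir-001"], 4, 25) <- shared
  refs2 <- new("MirnaReferenceSet",
               precursors = Biostrings::DNAStringSet(both),
               tier = precursorTier(refs), arms = matureArms(refs),
               contaminants = contaminants(refs))
  hits <- mapToPrecursors(shared, refs2)
  expect_true(all(hits$tier == "porcine"))
  ann <- classifyTags(tagTable(shared), hits, refs2)
  expect_equal(ann$class, "known")
})

test_that("identical matures from distinct precursors collapse to one record", {
  refs <- makeRefs()
  pseq <- as.character(precursors(refs))
  shared <- substr(pseq["ssc-mir-001"], 4, 25)  # encoded by mir-001 and mir-002
  tags <- tagTable(shared)
  ann <- classifyTags(tags, mapToPrecursors(tags, refs), refs)
  uni <- collapseUnique(ann)
  expect_equal(nrow(uni), 1)
  expect_equal(uni$precursor_ids, "ssc-mir-001,ssc-mir-002")
  expect_equal(uni$mature_name, "ssc-miR-001-5p")  # lexicographically first

  # all-distinct input is the identity; the collapse never grows the set
  distinct <- tagTable(c(substr(pseq["ssc-mir-003"], 4, 25),
                         substr(pseq["oth-mir-001"], 55, 76)))
  annD <- classifyTags(distinct, mapToPrecursors(distinct, refs), refs)
  expect_equal(nrow(collapseUnique(annD)), 2)
  expect_lte(nrow(uni), nrow(ann))
})

test_that("annotation is invariant to tag order", {
  p <- noiselessParams(readsPerLibrary = 4000L, seed = 41L)
  d <- withr::local_tempdir()
  out <- simulateSmallRnaStudy(p, d)
  fq <- setNames(file.path(d, paste0("lib_", p@libraries$name, ".fastq")),
                 p@libraries$name)
  qc <- runQC(fq, filterParams(adapter = p@adapter))
  a1 <- annotateTags(qc$tags, out$refs)
  shuf <- qc$tags[rev(seq_len(nrow(qc$tags))), ]
  a2 <- annotateTags(shuf, out$refs)
  o1 <- a1$annot[order(a1$annot$sequence), ]
  o2 <- a2$annot[order(a2$annot$sequence), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(a1$matures, a2$matures)
})
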