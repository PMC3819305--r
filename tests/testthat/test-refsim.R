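test_that("reference and read generation is a pure function of the seed", {
  p <- simParams(nPorcine = 12L, nConserved = 4L, nContaminants = 5L,
                 readsPerLibrary = 1500L, nVatEnriched = 2L,
                 nSatEnriched = 2L, seed = 42L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateSmallRnaStudy(p, d1)
  simulateSmallRnaStudy(p, d2)
  for (f in setdiff(list.files(d1), "params.yaml")) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = paste("file", f))
  }
})

test_that("reference structure follows the configured annotation scheme", {
  p <- simParams(seed = 7L)  # 150 porcine, starFrac 0.5
  refs <- simulateReferences(p)
  arms <- matureArms(refs)
  tier <- setNames(precursorTier(refs), names(precursors(refs)))

  porc <- names(tier)[tier == "porcine"]
  cons <- names(tier)[tier == "conserved_mammal"]
  nArms <- table(factor(arms$precursor_id, levels = names(tier)))
  # every porcine precursor >= 1 annotation, conserved exactly one
  expect_true(all(nArms[porc] >= 1))
  expect_true(all(nArms[cons] == 1))

  # star-annotation rate matches the binomial expectation
  nStar <- sum(arms$documented == "no")
  pHat <- nStar / length(porc)
  tol <- 3.5 * sqrt(p@starFrac * (1 - p@starFrac) / length(porc))
  expect_lt(abs(pHat - p@starFrac), tol)

  # no mature sequence occurs inside any contaminant, either strand
  cseq <- as.character(contaminants(refs))
  crc <- as.character(Biostrings::reverseComplement(contaminants(refs)))
  mat <- matureCatalog(refs)$sequence
  hits <- vapply(mat, function(m)
    any(grepl(m, cseq, fixed = TRUE)) || any(grepl(m, crc, fixed = TRUE)),
    logical(1))
  expect_false(any(hits))
})

test_that("an empty porcine tier still yields a usable reference", {
  p <- tinyParams(nPorcine = 0L, seed = 3L)
  refs <- simulateReferences(p)
  expect_true(all(precursorTier(refs) == "conserved_mammal"))
  truth <- simulateTruth(p, refs)
  expect_true(all(truthLabels(truth)$class == "conserved"))
  cnt <- simulateCounts(truth, p, refs)
  expect_equal(colSums(cnt$mirna) + colSums(cnt$contam),
               setNames(rep(p@readsPerLibrary, 6), p@libraries$name))
})

test_that("degenerate precursor geometry is rejected", {
  expect_error(simParams(precursorLen = 40L, matureLenMean = 22),
               "precursorLen")
})

test_that("ground truth plants the configured effect structure", {
  p <- tinyParams(seed = 11L)
  refs <- simulateReferences(p)
  truth <- simulateTruth(p, refs)
  E <- expectedCounts(truth)
  lab <- truthLabels(truth)
  isVat <- p@libraries$depot == "VAT"

  for (i in which(lab$effect == "vat_enriched")) {
    expect_equal(unname(E[i, isVat] / E[i, !isVat][1]),
                 rep(p@foldChange, sum(isVat)))
  }
  for (i in which(lab$effect == "sat_enriched")) {
    expect_equal(unname(E[i, !isVat] / E[i, isVat][1]),
                 rep(p@foldChange, sum(!isVat)))
  }
  # library-specific rows: expected count zero outside their library
  for (i in which(lab$presence == "specific")) {
    expect_equal(sum(E[i, ] > 0), 1)
    expect_gt(E[i, lab$specific_library[i]], 0)
  }
  # effects are confined to the universal pool and mutually exclusive
  expect_true(all(lab$presence[lab$effect != "none"] == "universal"))

  # per-library expected totals track the miRNA depth budget
  target <- p@readsPerLibrary * (1 - p@contaminantFrac)
  expect_true(all(abs(colSums(E) - target) / target < 0.05))
})

test_that("a null fold change leaves enriched rows flat across depots", {
  p <- tinyParams(foldChange = 1, seed = 13L)
  truth <- simulateTruth(p, simulateReferences(p))
  lab <- truthLabels(truth)
  E <- expectedCounts(truth)
  enr <- lab$effect != "none"
  expect_true(any(enr))
  expect_true(all(apply(E[enr, , drop = FALSE], 1,
                        function(r) diff(range(r)) == 0)))
})

test_that("over-planting beyond the universal pool is an error", {
  p <- tinyParams(nVatEnriched = 100L, nSatEnriched = 100L, seed = 5L)
  expect_error(simulateTruth(p, simulateReferences(p)),
               "more planted effects")
})

test_that("noiseless reads are exact mature sequences and conserve depth", {
  p <- noiselessParams(readsPerLibrary = 5000L, seed = 17L)
  d <- withr::local_tempdir()
  out <- simulateSmallRnaStudy(p, d)
  lab <- truthLabels(out$truth)
  contamIds <- names(contaminants(out$refs))

  for (lib in p@libraries$name) {
    ln <- readLines(file.path(d, paste0("lib_", lib, ".fastq")))
    expect_equal(length(ln) / 4, p@readsPerLibrary)
    ids <- ln[seq(1, length(ln), by = 4)]
    seqs <- ln[seq(2, length(ln), by = 4)]
    src <- sub(".*src:", "", ids)
    mir <- !(src %in% contamIds)
    ins <- trimAdapter(seqs[mir], p@adapter)
    # every non-contaminant insert re-identifies its source mature exactly
    expect_false(any(is.na(ins)))
    expect_identical(ins,
                     lab$sequence[match(src[mir], lab$mature_name)])
  }
})

test_that("sampled counts are consistent with the multinomial model", {
  # goodness-of-fit of one library's source counts against the truth
  # proportions, across replicates; expect few rejections at alpha = 0.01
  p <- tinyParams(readsPerLibrary = 50000L)
  reject <- logical(40)
  for (i in seq_along(reject)) {
    p@seed <- 300L + i
    refs <- simulateReferences(p)
    truth <- simulateTruth(p, refs)
    cnt <- simulateCounts(truth, p, refs)
    E <- expectedCounts(truth)[, "GOM"]
    contamE <- rep(p@contaminantFrac / (1 - p@contaminantFrac) * sum(E) /
                     nrow(cnt$contam), nrow(cnt$contam))
    expct <- c(E, contamE)
    prob <- expct / sum(expct)
    obs <- c(cnt$mirna[, "GOM"], cnt$contam[, "GOM"])
    exp0 <- prob * p@readsPerLibrary
    # pool cells with small expectation to keep the chi-square valid
    small <- exp0 < 5
    o <- c(obs[!small], sum(obs[small]))
    e <- c(exp0[!small], sum(exp0[small]))
    stat <- sum((o - e)^2 / e)
    reject[i] <- pchisq(stat, df = length(o) - 1, lower.tail = FALSE) < 0.01
  }
  expect_gte(mean(!reject), 0.95 - 1e-9)
})

test_that("zero depth writes empty FASTQ files with a warning", {
  p <- noiselessParams(seed = 19L)
  refs <- simulateReferences(p)
  truth <- simulateTruth(p, refs)
  p@readsPerLibrary <- 0L
  d <- withr::local_tempdir()
  expect_warning(simulateReads(truth, refs, p, d), "readsPerLibrary")
  f <- file.path(d, "lib_GOM.fastq")
  expect_true(file.exists(f))
  expect_equal(file.size(f), 0)
})

test_that("simulation parameters round-trip through their list form", {
  p <- tinyParams(seed = 23L, foldChange = 4)
  expect_equal(simParamsFromList(simParamsToList(p)), p)
})
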