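#' @include AllClasses.R
NULL

#' Simulate precursor and contaminant references
#'
#' Generates the two-tier precursor reference (porcine hairpins searched
#' first, conserved-mammal hairpins searched for the remainder) together with
#' mature-arm annotations and a contaminant set. Every porcine precursor
#' carries one documented mature arm; a `starFrac` fraction additionally
#' carry an undocumented opposite-arm (star) annotation, which the generator
#' expresses but the annotation stage must discover as a novel star. A
#' `sharedMatureFrac` fraction of porcine precursors duplicate the documented
#' mature of an earlier precursor, so that several precursors encode one
#' unique mature sequence. Conserved precursors carry exactly one documented
#' arm. No mature sequence occurs verbatim in any contaminant.
#'
#' Output is a pure function of `(params, seed)`.
#'
#' @param params a [SimParams-class].
#' @return a [MirnaReferenceSet-class].
#' @examples
#' refs <- simulateReferences(simParams(nPorcine = 10, nConserved = 4, seed = 3))
#' refs
#' @export
simulateReferences <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  withSeed(deriveSeed(params@seed, "references"), {
    plen <- params@precursorLen
    drawLen <- function(n) {
      l <- round(rnorm(n, params@matureLenMean, params@matureLenSd))
      pmin(pmax(l, 19L), min(26L, floor((plen - 2) / 2)))
    }
    armInterval <- function(arm, len) {
      pad <- sample(1:4, 1)
      if (arm == "5p") c(pad, pad + len) else c(plen - pad - len, plen - pad)
    }

    precs <- character(0); tiers <- character(0); armRows <- list()
    putSeq <- function(seqs, i, start0, sub) {
      # overwrite [start0, start0+nchar(sub)) of sequence i
      paste0(substr(seqs[i], 1, start0),
             sub,
             substr(seqs[i], start0 + nchar(sub) + 1, nchar(seqs[i])))
    }

    nP <- params@nPorcine
    if (nP > 0) {
      pseq <- randomDna(nP, plen)
      names(pseq) <- sprintf("ssc-mir-%03d", seq_len(nP))
      docArm <- sample(c("5p", "3p"), nP, replace = TRUE)
      docLen <- drawLen(nP)
      shared <- runif(nP) < params@sharedMatureFrac
      shared[1] <- FALSE
      star <- runif(nP) < params@starFrac
      for (i in seq_len(nP)) {
        if (shared[i]) {
          # re-encode an earlier precursor's documented mature verbatim
          j <- sample(seq_len(i - 1), 1)
          docLen[i] <- armRows[[2 * j - 1]]$end - armRows[[2 * j - 1]]$start
        }
        iv <- armInterval(docArm[i], docLen[i])
        if (shared[i]) {
          prev <- armRows[[2 * j - 1]]
          mseq <- substr(pseq[j], prev$start + 1, prev$end)
          pseq[i] <- putSeq(pseq, i, iv[1], mseq)
        }
        armRows[[2 * i - 1]] <- data.frame(
          precursor_id = names(pseq)[i], arm = docArm[i],
          start = iv[1], end = iv[2],
          mature_name = sprintf("ssc-miR-%03d-%s", i, docArm[i]),
          documented = "yes", stringsAsFactors = FALSE)
        other <- if (docArm[i] == "5p") "3p" else "5p"
        armRows[[2 * i]] <- if (star[i]) {
          ivs <- armInterval(other, drawLen(1))
          data.frame(precursor_id = names(pseq)[i], arm = other,
                     start = ivs[1], end = ivs[2],
                     mature_name = sprintf("ssc-miR-%03d-%s-star", i, other),
                     documented = "no", stringsAsFactors = FALSE)
        } else NULL
      }
      precs <- pseq
      tiers <- rep("porcine", nP)
    }

    nC <- params@nConserved
    if (nC > 0) {
      cseq <- randomDna(nC, plen)
      names(cseq) <- sprintf("oth-mir-%03d", seq_len(nC))
      cArm <- sample(c("5p", "3p"), nC, replace = TRUE)
      cLen <- drawLen(nC)
      for (i in seq_len(nC)) {
        iv <- armInterval(cArm[i], cLen[i])
        armRows[[length(armRows) + 1]] <- data.frame(
          precursor_id = names(cseq)[i], arm = cArm[i],
          start = iv[1], end = iv[2],
          mature_name = sprintf("oth-miR-%03d-%s", i, cArm[i]),
          documented = "yes", stringsAsFactors = FALSE)
      }
      precs <- c(precs, cseq)
      tiers <- c(tiers, rep("conserved_mammal", nC))
    }

    arms <- do.call(rbind, armRows[!vapply(armRows, is.null, logical(1))])
    if (is.null(arms)) {
      arms <- data.frame(precursor_id = character(0), arm = character(0),
                         start = integer(0), end = integer(0),
                         mature_name = character(0), documented = character(0))
    }
    rownames(arms) <- NULL

    # mature sequences, used to keep contaminants clean of them
    matseq <- substr(precs[arms$precursor_id], arms$start + 1, arms$end)

    contamClasses <- c("rRNA", "tRNA", "snRNA", "snoRNA", "mRNA", "repeat")
    cont <- character(params@nContaminants)
    for (i in seq_len(params@nContaminants)) {
      repeat {
        s <- randomDna(1, 120L)
        rc <- as.character(reverseComplement(DNAStringSet(s)))
        hit <- any(vapply(matseq, function(m)
          grepl(m, s, fixed = TRUE) || grepl(m, rc, fixed = TRUE), logical(1)))
        if (!hit) break
      }
      cont[i] <- s
    }
    if (params@nContaminants > 0) {
      names(cont) <- sprintf("contam_%s_%02d",
                             contamClasses[(seq_along(cont) - 1) %%
                                             length(contamClasses) + 1],
                             seq_along(cont))
    }

    new("MirnaReferenceSet",
        precursors = DNAStringSet(precs), tier = tiers, arms = arms,
        contaminants = DNAStringSet(cont))
  })
}

#' Catalog of unique mature sequences encoded by a reference set
#'
#' Collapses the mature-arm annotations to one record per distinct mature
#' sequence. The representative name is the lexicographically first
#' contributing name and the class is the highest-priority one among
#' known > novel_star > conserved (known = documented porcine arm,
#' novel_star = undocumented porcine arm, conserved = conserved-tier arm).
#'
#' @param refs a [MirnaReferenceSet-class].
#' @return data.frame with columns `mature_name`, `sequence`, `class`,
#'   `precursor_ids` (comma-separated).
#' @export
matureCatalog <- function(refs) {
  a <- refs@arms
  if (!nrow(a)) {
    return(data.frame(mature_name = character(0), sequence = character(0),
                      class = character(0), precursor_ids = character(0)))
  }
  tier <- setNames(refs@tier, names(refs@precursors))
  seqs <- as.character(refs@precursors)[a$precursor_id]
  a$sequence <- substr(seqs, a$start + 1, a$end)
  a$class <- ifelse(tier[a$precursor_id] == "conserved_mammal", "conserved",
                    ifelse(a$documented == "yes", "known", "novel_star"))
  prio <- c(known = 1L, novel_star = 2L, conserved = 3L)
  out <- lapply(split(a, a$sequence), function(d) {
    data.frame(mature_name = min(d$mature_name),
               sequence = d$sequence[1],
               class = names(prio)[min(prio[d$class])],
               precursor_ids = paste(sort(unique(d$precursor_id)),
                                     collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$mature_name), ]
  rownames(out) <- NULL
  out
}

#' Simulate the generative ground truth of a synthetic study
#'
#' Assigns each unique mature a presence class (universal / library-specific
#' / partial), plants the depot-enrichment effects, and builds the
#' expected-count matrix the read sampler draws from.
#'
#' Presence structure: a `fracUniversal` fraction is expressed in every
#' library, a `fracSpecific` fraction in exactly one library (concentrated in
#' the library named by `specificLibWeight`), and the remainder in a random
#' subset of 2 to (nlib - 1) libraries. Planted VAT-/SAT-enriched miRNAs are
#' drawn from the universal pool; their own-depot columns are multiplied by
#' `foldChange`. The two enriched sets reuse one common vector of baseline
#' expected counts (drawn log-uniformly from `enrichedBaseRange` x depth), so
#' the total planted mass is identical in the two depot classes and the
#' planted effects do not shift the composition of null miRNAs under
#' fixed-depth sequencing.
#'
#' @param params a [SimParams-class].
#' @param refs a [MirnaReferenceSet-class] from [simulateReferences()].
#' @return a [GroundTruth-class].
#' @export
simulateTruth <- function(params, refs) {
  stopifnot(is(params, "SimParams"), is(refs, "MirnaReferenceSet"))
  cat0 <- matureCatalog(refs)
  if (!nrow(cat0)) stop("reference set encodes no matures")
  libs <- params@libraries
  nlib <- nrow(libs)
  n <- nrow(cat0)

  withSeed(deriveSeed(params@seed, "truth"), {
    nU <- round(params@fracUniversal * n)
    nS <- round(params@fracSpecific * n)
    if (params@nVatEnriched + params@nSatEnriched > nU)
      stop("more planted effects than universal miRNAs")
    idx <- sample.int(n)
    uni <- idx[seq_len(nU)]
    spec <- idx[nU + seq_len(nS)]
    part <- idx[-seq_len(nU + nS)]

    presence <- rep("partial", n)
    presence[uni] <- "universal"
    presence[spec] <- "specific"

    # library-specific miRNAs concentrate in one designated library
    wlib <- rep((1 - sum(params@specificLibWeight)) /
                  (nlib - length(params@specificLibWeight)), nlib)
    names(wlib) <- libs$name
    wlib[names(params@specificLibWeight)] <- params@specificLibWeight
    specLib <- rep(NA_character_, n)
    if (nS > 0) specLib[spec] <- sample(libs$name, nS, TRUE, prob = wlib)

    effect <- rep("none", n)
    nV <- params@nVatEnriched; nSe <- params@nSatEnriched
    enr <- sample(uni, nV + nSe)
    effect[enr[seq_len(nV)]] <- "vat_enriched"
    effect[enr[nV + seq_len(nSe)]] <- "sat_enriched"

    depth <- params@readsPerLibrary
    target <- depth * (1 - params@contaminantFrac)

    # planted baselines: one shared draw for both depots (balanced planting)
    npair <- max(nV, nSe)
    baseEnr <- 10^runif(npair, log10(params@enrichedBaseRange[1] * depth),
                        log10(params@enrichedBaseRange[2] * depth))
    bV <- baseEnr[seq_len(nV)]
    bS <- baseEnr[seq_len(nSe)]

    E <- matrix(0, n, nlib, dimnames = list(cat0$mature_name, libs$name))
    isVat <- libs$depot == "VAT"
    fc <- params@foldChange
    if (nV > 0) for (k in seq_len(nV)) {
      E[enr[k], ] <- bV[k] * ifelse(isVat, fc, 1)
    }
    if (nSe > 0) for (k in seq_len(nSe)) {
      E[enr[nV + k], ] <- bS[k] * ifelse(isVat, 1, fc)
    }

    # remaining rows fill the rest of the depth budget. Library-specific and
    # partially expressed miRNAs are low-abundance by design: their expected
    # count is drawn log-uniformly between the detectability floor and the
    # composition cap, so presence/absence structure cannot perturb the
    # composition seen by the co-expressed core. Universal rows keep the
    # heavy-tailed log-normal baseline, scaled to the remaining budget and
    # floored so the core is detectable everywhere at the design depth.
    floorC <- params@universalFloorFrac * depth
    capC <- params@minorMaxFrac * depth
    restUni <- setdiff(uni, enr)
    minor <- c(spec, part)
    E0 <- matrix(0, n, nlib)
    for (i in minor) {
      val <- 10^runif(1, log10(floorC), log10(capC))
      if (presence[i] == "specific") {
        E0[i, libs$name == specLib[i]] <- val
      } else {
        m <- sample(2:(nlib - 1), 1)
        E0[i, sample.int(nlib, m)] <- val
      }
    }
    b <- rlnorm(n, params@baseMeanlog, params@baseSdlog)
    remaining <- target - mean(colSums(E)) - mean(colSums(E0))
    if (remaining <= 0) stop("planted effects exceed the library depth budget")
    if (length(restUni)) {
      sc <- remaining / sum(b[restUni])
      for (i in restUni) E0[i, ] <- max(b[i] * sc, floorC)
    }
    E[c(restUni, minor), ] <- E0[c(restUni, minor), ]

    labels <- data.frame(mature_name = cat0$mature_name,
                         sequence = cat0$sequence,
                         class = cat0$class,
                         presence = presence,
                         specific_library = specLib,
                         effect = effect,
                         stringsAsFactors = FALSE)
    new("GroundTruth", expected = E, labels = labels,
        matureMap = cat0, libraries = libs)
  })
}

#' Draw per-library counts from the ground truth
#'
#' Each library is an independent multinomial draw of exactly
#' `readsPerLibrary` reads over all sources (unique matures plus contaminant
#' references), conditioning on fixed sequencing depth. The contaminant mass
#' is `contaminantFrac` of each library in expectation, spread uniformly over
#' the contaminant references.
#'
#' @param truth a [GroundTruth-class].
#' @param params the [SimParams-class] used to build it.
#' @param refs the matching [MirnaReferenceSet-class].
#' @return list with integer matrices `mirna` (unique matures x libraries)
#'   and `contam` (contaminant references x libraries); the two column sums
#'   add up to `readsPerLibrary` exactly.
#' @export
simulateCounts <- function(truth, params, refs) {
  stopifnot(is(truth, "GroundTruth"), is(params, "SimParams"))
  E <- truth@expected
  nlib <- ncol(E)
  ncont <- length(refs@contaminants)
  withSeed(deriveSeed(params@seed, "counts"), {
    mir <- matrix(0L, nrow(E), nlib, dimnames = dimnames(E))
    con <- matrix(0L, ncont, nlib,
                  dimnames = list(names(refs@contaminants), colnames(E)))
    depth <- params@readsPerLibrary
    for (l in seq_len(nlib)) {
      if (depth == 0L) next
      contMass <- if (ncont > 0 && params@contaminantFrac > 0) {
        rep(params@contaminantFrac / (1 - params@contaminantFrac) *
              sum(E[, l]) / ncont, ncont)
      } else numeric(0)
      p <- c(E[, l], contMass)
      draw <- as.integer(rmultinom(1, depth, p))
      mir[, l] <- draw[seq_len(nrow(E))]
      if (ncont > 0) con[, l] <- draw[nrow(E) + seq_len(ncont)]
    }
    list(mirna = mir, contam = con)
  })
}

# Build the raw read sequences for one library (inserts + adapter, fixed
# machine length, substitution/N noise), plus their source ids.
.buildLibraryReads <- function(lib, counts, truth, refs, params) {
  lab <- truth@labels

  mirN <- counts$mirna[, lib]
  conN <- if (nrow(counts$contam)) counts$contam[, lib] else integer(0)

  inserts <- character(0); src <- character(0)
  if (sum(mirN) > 0) {
    k <- which(mirN > 0)
    inserts <- rep(lab$sequence[k], mirN[k])
    if (params@lenJitterSd > 0) {
      # isomiR-style 3'-end heterogeneity: trim up to 2 nt from the insert
      jit <- pmin(pmax(round(rnorm(length(inserts), 0, params@lenJitterSd)),
                       -2L), 0L)
      inserts <- substr(inserts, 1, nchar(inserts) + jit)
    }
    src <- rep(lab$mature_name[k], mirN[k])
  }
  if (length(conN) && sum(conN) > 0) {
    k <- which(conN > 0)
    cseq <- as.character(refs@contaminants)[k]
    ins <- unlist(lapply(seq_along(k), function(j) {
      n <- conN[k[j]]
      len <- sample(18:25, n, replace = TRUE)
      st <- vapply(len, function(L) sample.int(nchar(cseq[j]) - L + 1, 1),
                   integer(1))
      substr(rep(cseq[j], n), st, st + len - 1)
    }), use.names = FALSE)
    inserts <- c(inserts, ins)
    src <- c(src, rep(names(refs@contaminants)[k], conN[k]))
  }

  if (!length(inserts)) return(list(seq = character(0), id = character(0)))

  ord <- sample.int(length(inserts))
  inserts <- inserts[ord]; src <- src[ord]

  reads <- paste0(inserts, params@adapter,
                  strrep("A", params@readLen))
  reads <- substr(reads, 1, params@readLen)

  # substitution errors, then undetermined bases
  L <- params@readLen
  nerr <- rbinom(1, length(reads) * L, params@errorRate)
  if (nerr > 0) {
    ri <- sample.int(length(reads), nerr, replace = TRUE)
    pi <- sample.int(L, nerr, replace = TRUE)
    for (e in seq_len(nerr)) {
      cur <- substr(reads[ri[e]], pi[e], pi[e])
      substr(reads[ri[e]], pi[e], pi[e]) <-
        sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  nN <- rbinom(1, length(reads) * L, params@nRate)
  if (nN > 0) {
    ri <- sample.int(length(reads), nN, replace = TRUE)
    pi <- sample.int(L, nN, replace = TRUE)
    for (e in seq_len(nN)) substr(reads[ri[e]], pi[e], pi[e]) <- "N"
  }

  ids <- sprintf("%s_%07d src:%s", lib, seq_along(reads), src)
  list(seq = reads, id = ids)
}

#' Simulate FASTQ reads for every library
#'
#' Draws per-library source counts with [simulateCounts()] and emits one
#' Sanger (Phred+33) FASTQ file per library. Each read is a mature (or
#' contaminant substring) insert followed by the 3' adapter, reported at the
#' fixed machine length with substitution errors at `errorRate` and
#' undetermined bases at `nRate`. Read identifiers record the true source
#' (`src:<name>`), so reads remain attributable. Exactly `readsPerLibrary`
#' reads are written per library.
#'
#' @param truth a [GroundTruth-class].
#' @param refs the matching [MirnaReferenceSet-class].
#' @param params the [SimParams-class].
#' @param outDir directory for `lib_<name>.fastq` files (created if needed).
#' @return invisibly, a list with `files` (named FASTQ paths) and `counts`
#'   (the [simulateCounts()] result used).
#' @export
simulateReads <- function(truth, refs, params, outDir) {
  stopifnot(is(truth, "GroundTruth"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- simulateCounts(truth, params, refs)
  libs <- truth@libraries$name
  files <- setNames(file.path(outDir, paste0("lib_", libs, ".fastq")), libs)
  if (params@readsPerLibrary == 0L)
    warning("readsPerLibrary is 0; writing empty FASTQ files")
  withSeed(deriveSeed(params@seed, "reads"), {
    for (lib in libs) {
      r <- .buildLibraryReads(lib, counts, truth, refs, params)
      if (length(r$seq)) {
        qual <- BStringSet(vapply(nchar(r$seq), strrep, character(1),
                                  x = "I"))
        writeXStringSet(DNAStringSet(setNames(r$seq, r$id)), files[[lib]],
                        format = "fastq", qualities = qual)
      } else {
        file.create(files[[lib]])
      }
    }
  })
  invisible(list(files = files, counts = counts))
}

#' Generate and write a complete synthetic study bundle
#'
#' Runs [simulateReferences()], [simulateTruth()] and [simulateReads()] and
#' writes the full reference/read/truth bundle: `precursors.fa`,
#' `contaminants.fa`, `mature_arms.tsv`, one `lib_<name>.fastq` per library,
#' `truth.tsv` (expected counts), `labels.tsv` (presence and effect labels),
#' `libraries.tsv` and `params.yaml`.
#'
#' @param params a [SimParams-class].
#' @param outDir output directory.
#' @return invisibly, a list with the generated objects and file paths.
#' @examples
#' \donttest{
#' p <- simParams(nPorcine = 20, nConserved = 5, readsPerLibrary = 2000,
#'                nVatEnriched = 2, nSatEnriched = 2, seed = 11)
#' out <- simulateSmallRnaStudy(p, tempfile("sim"))
#' names(out$files)
#' }
#' @export
simulateSmallRnaStudy <- function(params, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  refs <- simulateReferences(params)
  truth <- simulateTruth(params, refs)
  rd <- simulateReads(truth, refs, params, outDir)

  fa <- file.path(outDir, "precursors.fa")
  writeXStringSet(refs@precursors, fa)
  cfa <- file.path(outDir, "contaminants.fa")
  writeXStringSet(refs@contaminants, cfa)
  armsF <- file.path(outDir, "mature_arms.tsv")
  writeTsv(refs@arms, armsF)

  truthF <- file.path(outDir, "truth.tsv")
  writeTsv(data.frame(mature_name = rownames(truth@expected),
                      truth@expected, check.names = FALSE), truthF)
  labF <- file.path(outDir, "labels.tsv")
  writeTsv(truth@labels, labF)
  libF <- file.path(outDir, "libraries.tsv")
  writeTsv(params@libraries, libF)

  parF <- file.path(outDir, "params.yaml")
  yaml::write_yaml(simParamsToList(params), parF)

  invisible(list(refs = refs, truth = truth, counts = rd$counts,
                 files = c(rd$files, precursors = fa, contaminants = cfa,
                           mature_arms = armsF, truth = truthF,
                           labels = labF, libraries = libF, params = parF)))
}

#' Serialize simulation parameters to a plain list
#'
#' Round-trips through YAML: `simParamsFromList(simParamsToList(p))` equals
#' `p`.
#'
#' @param params a [SimParams-class].
#' @return a named list of plain R values.
#' @export
simParamsToList <- function(params) {
  sl <- slotNames("SimParams")
  out <- lapply(sl, function(s) {
    v <- slot(params, s)
    if (is.data.frame(v)) as.list(v) else v
  })
  names(out) <- sl
  out
}

#' @rdname simParamsToList
#' @param x a list produced by [simParamsToList()] (or read from
#'   `params.yaml`).
#' @export
simParamsFromList <- function(x) {
  x$libraries <- as.data.frame(x$libraries, stringsAsFactors = FALSE)
  x$specificLibWeight <- unlist(x$specificLibWeight)
  do.call(simParams, x)
}
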