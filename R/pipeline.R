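#' @include readqc.R annotate.R expression.R diffexp.R cluster.R refsim.R
NULL

.ALL_STAGES <- c("simulate", "qc", "annotate", "quantify", "diffexp",
                 "cluster")

#' Assemble a pipeline run configuration
#'
#' A plain, YAML-serializable list tying together the input paths and the
#' per-stage parameters. When `simulate` is `TRUE` the input bundle is
#' generated by [simulateSmallRnaStudy()] into the run directory first and
#' the path fields are filled in automatically.
#'
#' @param fastq named character vector of FASTQ paths (names = library
#'   names), or `NULL` when simulating.
#' @param precursors,contaminantsFile,matureArms,libraries reference FASTA /
#'   TSV paths (`libraries` maps library name to depot class), or `NULL`
#'   when simulating.
#' @param simulate generate the inputs synthetically.
#' @param simParams list of [simParams()] overrides used when simulating.
#' @param filter list of [filterParams()] overrides.
#' @param maxMismatch,minOverlap mapping parameters (see
#'   [mapToPrecursors()], [classifyTags()]).
#' @param alpha,thresholdOn differential-expression parameters (see
#'   [callDE()]).
#' @param linkage clustering linkage (see [clusterLibraries()]).
#' @param seed integer global seed, fanned out per stage.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(fastq = NULL, precursors = NULL,
                      contaminantsFile = NULL, matureArms = NULL,
                      libraries = NULL, simulate = is.null(fastq),
                      simParams = list(), filter = list(),
                      maxMismatch = 0L, minOverlap = 16L,
                      alpha = 1e-5, thresholdOn = "corrected",
                      linkage = "average", seed = 1L) {
  cfg <- list(fastq = fastq, precursors = precursors,
              contaminantsFile = contaminantsFile, matureArms = matureArms,
              libraries = libraries, simulate = isTRUE(simulate),
              simParams = simParams, filter = filter,
              maxMismatch = as.integer(maxMismatch),
              minOverlap = as.integer(minOverlap),
              alpha = alpha, thresholdOn = thresholdOn, linkage = linkage,
              seed = as.integer(seed))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip losslessly: `readRunConfig(writeRunConfig(x))`
#' is identical to `x`.
#'
#' @param cfg a [runConfig()] list.
#' @param path YAML file path.
#' @return `writeRunConfig` the path; `readRunConfig` a `RunConfig`.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$fastq <- if (length(x$fastq)) unlist(x$fastq) else NULL
  do.call(runConfig, x)
}

.configHash <- function(cfg) {
  hashString(yaml::as.yaml(unclass(cfg)))
}

#' Validate pipeline inputs without running anything
#'
#' Checks that referenced files exist, FASTQ records are well formed
#' (4-line records with `@`/`+` markers and matching sequence/quality
#' lengths), the reference FASTA/TSV files parse with the expected schema,
#' and the library metadata provides both depot classes. Reports issues
#' rather than raising.
#'
#' @param cfg a [runConfig()] list (non-simulating configs are checked
#'   against the file system).
#' @return data.frame of issues (`input`, `message`); zero rows when clean.
#' @export
validateInputs <- function(cfg) {
  issues <- list()
  add <- function(input, message)
    issues[[length(issues) + 1]] <<- data.frame(input = input,
                                                message = message)
  if (!cfg$simulate) {
    if (is.null(cfg$fastq) || !length(cfg$fastq)) {
      add("fastq", "no FASTQ files configured")
    } else {
      for (lib in names(cfg$fastq)) {
        f <- cfg$fastq[[lib]]
        if (!file.exists(f)) { add(f, "file not found"); next }
        ln <- readLines(f, warn = FALSE)
        if (length(ln) %% 4 != 0) {
          add(f, sprintf("truncated FASTQ record near line %d", length(ln)))
          next
        }
        if (length(ln)) {
          hdr <- seq(1, length(ln), by = 4)
          bad <- which(!startsWith(ln[hdr], "@") |
                         !startsWith(ln[hdr + 2], "+") |
                         nchar(ln[hdr + 1]) != nchar(ln[hdr + 3]))
          if (length(bad))
            add(f, sprintf("malformed FASTQ record at line %d",
                           (bad[1] - 1) * 4 + 1))
        }
      }
    }
    for (nm in c("precursors", "contaminantsFile", "matureArms",
                 "libraries")) {
      f <- cfg[[nm]]
      if (is.null(f)) add(nm, "path not configured")
      else if (!file.exists(f)) add(f, "file not found")
    }
    if (!is.null(cfg$matureArms) && file.exists(cfg$matureArms)) {
      a <- tryCatch(readTsv(cfg$matureArms), error = function(e) NULL)
      need <- c("precursor_id", "arm", "start", "end", "mature_name",
                "documented")
      if (is.null(a) || !all(need %in% names(a)))
        add(cfg$matureArms, "mature-arm table lacks the required columns")
    }
    if (!is.null(cfg$libraries) && file.exists(cfg$libraries)) {
      l <- tryCatch(readTsv(cfg$libraries), error = function(e) NULL)
      if (is.null(l) || !all(c("name", "depot") %in% names(l))) {
        add(cfg$libraries, "library table needs 'name' and 'depot' columns")
      } else {
        if (!any(l$depot == "SAT") || !any(l$depot == "VAT"))
          add(cfg$libraries, "enrichment requires >= 1 library per depot")
      }
    }
  }
  if (!length(issues))
    return(data.frame(input = character(0), message = character(0)))
  do.call(rbind, issues)
}

# Load stage output if its recorded config hash matches, else NULL.
.stageCache <- function(outDir, stage, hash) {
  f <- file.path(outDir, paste0(".", stage, ".hash"))
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash)
}
.markStage <- function(outDir, stage, hash) {
  writeLines(hash, file.path(outDir, paste0(".", stage, ".hash")))
}

#' Run the full pipeline
#'
#' Executes (optionally) simulate, then qc, annotate, quantify, diffexp and
#' cluster, writing every stage's output as plain TSV/JSON/FASTA/FASTQ/
#' Newick into `outDir` so each stage is independently re-runnable and
#' diffable. A stage whose inputs and configuration are unchanged (matching
#' stage hash on disk) is skipped on re-runs. The run is idempotent: the
#' same config and seed produce byte-identical outputs.
#'
#' @param cfg a [runConfig()] list.
#' @param outDir run directory (created if needed).
#' @param upTo last stage to execute (earlier stages always run first;
#'   default `"cluster"` runs everything).
#' @return the run report (also written to `run_report.json`): per-stage
#'   record counts, matrix dimensions, category table, per-comparison DE
#'   counts, enrichment set sizes and the depot-split verdict.
#' @export
runAll <- function(cfg, outDir, upTo = "cluster") {
  stopifnot(inherits(cfg, "RunConfig"))
  upTo <- match.arg(upTo, .ALL_STAGES)
  lastStage <- match(upTo, .ALL_STAGES)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  finish <- function(report) {
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(report)
  }

  if (cfg$simulate) {
    simDir <- file.path(outDir, "sim")
    if (!.stageCache(outDir, "simulate", hash)) {
      sp <- do.call(simParams, c(cfg$simParams, list(seed = cfg$seed)))
      simulateSmallRnaStudy(sp, simDir)
      .markStage(outDir, "simulate", hash)
    }
    libs <- readTsv(file.path(simDir, "libraries.tsv"))
    cfg$fastq <- setNames(file.path(simDir, paste0("lib_", libs$name,
                                                   ".fastq")), libs$name)
    cfg$precursors <- file.path(simDir, "precursors.fa")
    cfg$contaminantsFile <- file.path(simDir, "contaminants.fa")
    cfg$matureArms <- file.path(simDir, "mature_arms.tsv")
    cfg$libraries <- file.path(simDir, "libraries.tsv")
  }
  if (lastStage <= match("simulate", .ALL_STAGES)) {
    return(finish(list(version = as.character(
      utils::packageVersion("adipomiR")), config_hash = hash,
      simulated = cfg$simulate)))
  }

  issues <- validateInputs(runConfig(
    fastq = cfg$fastq, precursors = cfg$precursors,
    contaminantsFile = cfg$contaminantsFile, matureArms = cfg$matureArms,
    libraries = cfg$libraries, simulate = FALSE, seed = cfg$seed))
  if (nrow(issues))
    stop("input validation failed: ", issues$input[1], ": ",
         issues$message[1])

  libs <- readTsv(cfg$libraries)
  depots <- setNames(libs$depot, libs$name)
  report <- list(version = as.character(utils::packageVersion("adipomiR")),
                 config_hash = hash)

  # references
  refs <- .loadReferences(cfg)

  # qc
  fp <- do.call(filterParams, cfg$filter)
  qc <- runQC(cfg$fastq[libs$name], fp)
  writeTsv(qc$tags, file.path(outDir, "tags.tsv"))
  jsonlite::write_json(qc$report, file.path(outDir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$qc <- lapply(qc$report$libraries, function(l)
    l[c("raw", "adapter_trimmed", "length_pass", "composition_pass",
        "high_quality")])
  if (lastStage <= match("qc", .ALL_STAGES)) return(finish(report))

  # annotate
  ann <- annotateTags(qc$tags, refs, cfg$maxMismatch, cfg$minOverlap)
  writeTsv(ann$annot, file.path(outDir, "annotation.tsv"))
  report$annotate <- list(
    tags_in = nrow(qc$tags),
    tags_post_contaminant = nrow(ann$tags),
    mapped = sum(ann$annot$class != "unmapped"),
    unique_matures = nrow(ann$matures),
    by_class = as.list(table(ann$matures$class)))
  if (lastStage <= match("annotate", .ALL_STAGES)) return(finish(report))

  # quantify
  totals <- setNames(vapply(libs$name, function(l) sum(qc$tags[[l]]),
                            numeric(1)), libs$name)
  se <- buildMatrix(ann$annot, ann$tags, depots, totals)
  writeTsv(data.frame(mirna = rownames(se), assay(se), check.names = FALSE),
           file.path(outDir, "counts.tsv"))
  writeTsv(data.frame(mirna = rownames(se), rpm(se), check.names = FALSE),
           file.path(outDir, "rpm.tsv"))
  cats <- categorize(se)
  writeTsv(cats, file.path(outDir, "categories.tsv"))
  summ <- categorySummary(cats, ncol(se))
  jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")
  report$quantify <- list(
    matrix_dim = dim(se),
    category_counts = summ$table$n,
    top10_share = as.list(topShare(se, 10)))
  stopifnot(sum(report$quantify$category_counts) == nrow(se))
  if (lastStage <= match("quantify", .ALL_STAGES)) return(finish(report))

  # diffexp
  deList <- deAllComparisons(se, cfg$alpha, cfg$thresholdOn)
  for (nm in names(deList))
    writeTsv(deList[[nm]], file.path(outDir, paste0("de_", nm, ".tsv")))
  enr <- callEnrichment(deList)
  writeTsv(enr, file.path(outDir, "enrichment.tsv"))
  report$diffexp <- list(
    de_counts = lapply(deList, function(d)
      list(up = sum(d$is_de & d$direction == "up_in_A"),
           down = sum(d$is_de & d$direction == "down_in_A"))),
    vat_specific = sum(enr$status == "VAT_specific"),
    sat_specific = sum(enr$status == "SAT_specific"))
  if (lastStage <= match("diffexp", .ALL_STAGES)) return(finish(report))

  # cluster
  hc <- clusterLibraries(se, linkage = cfg$linkage)
  writeDendrogram(hc, file.path(outDir, "dendrogram.nwk"))
  split <- depotSplit(hc, depots)
  jsonlite::write_json(list(depot_split = split,
                            merge_heights = hc$height),
                       file.path(outDir, "cluster_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$cluster <- list(depot_split = split)

  finish(report)
}

# Reconstruct a MirnaReferenceSet from the on-disk bundle.
.loadReferences <- function(cfg) {
  prec <- readDNAStringSet(cfg$precursors)
  names(prec) <- sub("\\s.*", "", names(prec))
  cont <- readDNAStringSet(cfg$contaminantsFile)
  names(cont) <- sub("\\s.*", "", names(cont))
  arms <- readTsv(cfg$matureArms)
  # tier from id prefix written by the simulator; anything porcine-prefixed
  # is first tier, the rest second tier
  tier <- ifelse(startsWith(names(prec), "ssc"), "porcine",
                 "conserved_mammal")
  new("MirnaReferenceSet", precursors = prec, tier = tier, arms = arms,
      contaminants = cont)
}
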