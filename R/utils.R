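# Internal helpers shared across modules.

# Stage offsets for fanning a single user seed out to independent streams.
.STAGE_SEEDS <- c(references = 101L, truth = 211L, counts = 307L,
                  reads = 401L, qc = 503L, de = 601L, cluster = 701L)

#' Derive a stage-specific RNG seed from a global seed
#'
#' A single user-facing seed is fanned out deterministically so that stages
#' remain reproducible in isolation. The derived value stays within the
#' 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer global seed.
#' @param stage one of `r paste(sQuote(names(.STAGE_SEEDS)), collapse = ", ")`.
#' @return an integer seed.
#' @keywords internal
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  off <- .STAGE_SEEDS[[match.arg(stage, names(.STAGE_SEEDS))]]
  as.integer((abs(as.numeric(seed)) * 7919 + off) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages in expression
#' summaries follow the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Random DNA sequences as a character vector.
randomDna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# MD5 of an in-memory string (used for config hashing).
hashString <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
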