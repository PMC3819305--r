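# Shared fixtures and independent oracles for the test suite.

DEPOTS6 <- c(GOM = "VAT", MAD = "VAT", PAD = "VAT", RAD = "VAT",
             ULB = "SAT", ILB = "SAT")

# Small simulation parameter sets used across files.
tinyParams <- function(...) {
  defaults <- list(nPorcine = 30L, nConserved = 10L, nContaminants = 8L,
                   readsPerLibrary = 20000L, nVatEnriched = 3L,
                   nSatEnriched = 3L)
  do.call(simParams, utils::modifyList(defaults, list(...)))
}

noiselessParams <- function(...) {
  tinyParams(errorRate = 0, nRate = 0, lenJitterSd = 0, ...)
}

# Count-level experiment straight from the generator: multinomial counts,
# per-library copy filter, library totals = sequencing depth.
countLevelExperiment <- function(params, seed = params@seed,
                                 minCopies = 3L) {
  params@seed <- as.integer(seed)
  refs <- simulateReferences(params)
  truth <- simulateTruth(params, refs)
  cnt <- simulateCounts(truth, params, refs)
  m <- cnt$mirna
  m[m < minCopies] <- 0L
  m <- m[rowSums(m) > 0, , drop = FALSE]
  libs <- params@libraries
  se <- MirnaExperiment(m, setNames(libs$depot, libs$name),
                        setNames(rep(params@readsPerLibrary, nrow(libs)),
                                 libs$name))
  list(se = se, truth = truth, refs = refs, counts = cnt)
}

# ---- independent oracles ------------------------------------------------

# Audic-Claverie posterior pmf by explicit log-space summation.
acPmfLog <- function(yp, x, r) {
  yp * log(r) + lgamma(x + yp + 1) - lgamma(x + 1) - lgamma(yp + 1) -
    (x + yp + 1) * log1p(r)
}

# Brute-force two-sided Audic-Claverie p with the package's canonical
# conditioning (larger count, ties toward the larger total).
acBruteOne <- function(x, y, n1, n2) {
  if (y > x || (y == x && n2 > n1)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  acBruteTails(x, y, n1, n2)
}

# Brute-force two-sided Audic-Claverie p for a whole vector of y at one x,
# conditioning on x as given.
acBruteTails <- function(x, ys, n1, n2) {
  r <- n2 / n1
  ymax <- max(4000, ceiling(20 * (x + 1) * max(r, 1)), max(ys) + 4000)
  t <- exp(acPmfLog(0:ymax, x, r))
  lower <- cumsum(t)
  vapply(ys, function(y) {
    lo <- lower[y + 1]
    hi <- if (y == 0) 1 else if (lower[y] < 0.5) 1 - lower[y]
          else sum(t[(y + 1):(ymax + 1)])
    min(1, 2 * min(lo, hi))
  }, numeric(1))
}

# Fisher two-sided p by full enumeration over the hypergeometric support,
# with table probabilities built from binomial coefficients directly.
fisherEnumOracle <- function(x, y, n1, n2) {
  k <- x + y
  supp <- max(0, k - n2):min(k, n1)
  lp <- lchoose(n1, supp) + lchoose(n2, k - supp) - lchoose(n1 + n2, k)
  pr <- exp(lp)
  pobs <- pr[supp == x]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Naive O(n^3) UPGMA: average linkage by recomputing every cluster pair
# distance as the mean of all leaf-pair distances.
upgmaOracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    ids <- which(active[seq_along(clusters)])
    best <- c(NA, NA); bestD <- Inf
    for (a in ids) for (b in ids) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < bestD - 1e-12) { bestD <- dd; best <- c(a, b) }
    }
    heights[step] <- bestD
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- bestD
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- bestD
    active[best] <- FALSE
    clusters[[length(clusters) + 1]] <- merged
    active[length(clusters)] <- TRUE
  }
  list(heights = sort(heights), cophenetic = coph)
}

# Write a FASTQ file from sequences (constant quality).
writeFastq <- function(seqs, path, ids = sprintf("read_%03d", seq_along(seqs))) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}
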