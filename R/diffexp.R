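#' @include AllClasses.R
NULL

#' Audic-Claverie test for differential counts between two libraries
#'
#' Exact test for a tag observed `x` times in a library of `N1` reads and
#' `y` times in a library of `N2` reads, based on the posterior probability
#' of the second count given the first under a flat prior:
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}.}
#' Writing \eqn{r = N_2/N_1}, this is the negative binomial probability mass
#' at `y` with size `x + 1` and success probability `N1/(N1+N2)`, so the two
#' tail sums are evaluated exactly in stable form through `pnbinom()` (which
#' works on the log-gamma scale internally) rather than by explicit
#' summation. The two-sided p-value doubles the smaller tail, capped at 1:
#' \deqn{p = \min\!\left(1,\; 2\min\left(\sum_{y' \le y} P(y'\mid x),\,
#'   \sum_{y' \ge y} P(y'\mid x)\right)\right).}
#'
#' The conditional tails are not automatically exchangeable between the two
#' libraries (conditioning on `x` and summing over `y'` differs from the
#' converse), so the tails are always evaluated conditioning on the larger
#' of the two counts, i.e. the posterior of the less-observed count given
#' the more deeply observed one (ties broken toward the larger total). This
#' makes the statistic symmetric, `p(x, y, N1, N2) = p(y, x, N2, N1)`, and
#' keeps it monotone in the departure from proportionality throughout the
#' significant regime (tiny reversals can occur only where the doubled tail
#' saturates near 1). The p-value lies in (0, 1].
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param n1,n2 positive library totals.
#' @return numeric vector of two-sided p-values.
#' @examples
#' audicClaveriePValue(0, 0, 1e6, 1e6)   # 1
#' audicClaveriePValue(5, 50, 1e6, 1e6)  # ~1.17e-10
#' @export
audicClaveriePValue <- function(x, y, n1, n2) {
  if (any(x %% 1 != 0) || any(y %% 1 != 0))
    stop("counts must be integers")
  if (any(x < 0) || any(y < 0) || any(n1 <= 0) || any(n2 <= 0))
    stop("counts must be >= 0 and totals > 0")
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  swap <- y > x | (y == x & n2 > n1)
  tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
  tmp <- n1[swap]; n1[swap] <- n2[swap]; n2[swap] <- tmp
  prob <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

# Two-sided Fisher p for one 2x2 table (x, N1-x; y, N2-y): total mass of
# hypergeometric outcomes no more probable than the observed one, with the
# customary 1e-7 relative slack on the comparison. For small supports the
# mass is summed directly; for large ones the same quantity is obtained
# from the two tails, locating the opposite-tail cutoff by bisection on the
# monotone flank of the (unimodal) hypergeometric pmf.
.fisherOne <- function(x, y, n1, n2) {
  k <- x + y
  lo <- max(0, k - n2); hi <- min(k, n1)
  if (hi - lo < 2048) {
    supp <- lo:hi
    pr <- dhyper(supp, n1, n2, k)
    pobs <- pr[supp == x]
    return(min(1, sum(pr[pr <= pobs * (1 + 1e-7)])))
  }
  pobs <- dhyper(x, n1, n2, k) * (1 + 1e-7)
  mode <- floor((k + 1) * (n1 + 1) / (n1 + n2 + 2))
  cutoff <- function(a, b, leftFlank) {
    # outermost index on the flank with pmf <= pobs (NA when none)
    if (leftFlank) {
      if (dhyper(a, n1, n2, k) > pobs) return(NA_integer_)
      while (b - a > 1) {
        mid <- (a + b) %/% 2
        if (dhyper(mid, n1, n2, k) <= pobs) a <- mid else b <- mid
      }
      a
    } else {
      if (dhyper(b, n1, n2, k) > pobs) return(NA_integer_)
      while (b - a > 1) {
        mid <- (a + b) %/% 2
        if (dhyper(mid, n1, n2, k) <= pobs) b <- mid else a <- mid
      }
      b
    }
  }
  if (x <= mode) {
    left <- phyper(x, n1, n2, k)
    r <- cutoff(mode, hi, leftFlank = FALSE)
    right <- if (is.na(r)) 0 else phyper(r - 1, n1, n2, k,
                                         lower.tail = FALSE)
    min(1, left + right)
  } else {
    right <- phyper(x - 1, n1, n2, k, lower.tail = FALSE)
    l <- cutoff(lo, mode, leftFlank = TRUE)
    left <- if (is.na(l)) 0 else phyper(l, n1, n2, k)
    min(1, left + right)
  }
}

#' Fisher exact test on the two-library 2x2 table
#'
#' Tests the table `(x, N1 - x; y, N2 - y)`. The two-sided p-value sums the
#' probabilities of all tables with the same margins whose hypergeometric
#' probability does not exceed that of the observed table (with a 1e-7
#' relative slack, as in `stats::fisher.test`). Invariant under swapping the
#' two libraries.
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param n1,n2 positive library totals; `x <= n1` and `y <= n2` required.
#' @return numeric vector of two-sided p-values.
#' @examples
#' fisherPValue(5, 5, 100, 100)  # 1
#' fisherPValue(3, 0, 10, 10)
#' @export
fisherPValue <- function(x, y, n1, n2) {
  if (any(x %% 1 != 0) || any(y %% 1 != 0))
    stop("counts must be integers")
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  if (any(x > n1) || any(y > n2))
    stop("counts cannot exceed library totals")
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  vapply(seq_len(k), function(i)
    .fisherOne(x[i], y[i], n1[i], n2[i]), numeric(1))
}

#' Pearson chi-squared test on the two-library 2x2 table
#'
#' Plain Pearson statistic (no continuity correction) on the table
#' `(a, b; c, d) = (x, N1 - x; y, N2 - y)`:
#' \deqn{X^2 = \frac{n (ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},}
#' referred to the chi-squared distribution with one degree of freedom. When
#' any expected cell count is below 1, or a margin is degenerate (zero row
#' or column), the approximation is not trusted: the p-value is set to 1 and
#' the result flagged.
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param n1,n2 positive library totals.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return data.frame with `statistic`, `p.value`, `flagged`.
#' @seealso [chi2PValue()] for just the p-values.
#' @export
chi2Test <- function(x, y, n1, n2, correct = FALSE) {
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(as.numeric(x), k); y <- rep_len(as.numeric(y), k)
  n1 <- rep_len(as.numeric(n1), k); n2 <- rep_len(as.numeric(n2), k)
  a <- x; b <- n1 - x; c <- y; d <- n2 - y
  n <- n1 + n2
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  expmin <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  flagged <- degenerate | expmin < 1
  num <- abs(a * d - b * c)
  if (correct) num <- pmax(0, num - n / 2)
  stat <- ifelse(degenerate, NA_real_, n * num^2 / (r1 * r2 * c1 * c2))
  p <- ifelse(flagged, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  data.frame(statistic = stat, p.value = p, flagged = flagged)
}

#' @rdname chi2Test
#' @export
chi2PValue <- function(x, y, n1, n2, correct = FALSE) {
  chi2Test(x, y, n1, n2, correct)$p.value
}

#' Bonferroni correction
#'
#' @param p numeric vector of raw p-values.
#' @param m family size (number of tests; >= 1).
#' @return `min(1, p * m)`, elementwise.
#' @export
bonferroniCorrect <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Three-test consensus differential expression between two libraries
#'
#' For each miRNA co-expressed in the two compared libraries (nonzero
#' post-filter count in both; this set defines the Bonferroni family size
#' `m`), computes the Audic-Claverie, Fisher exact and Pearson chi-squared
#' two-sided p-values on the (count, library-total) table, corrects each by
#' Bonferroni, and calls a miRNA differentially expressed only when all
#' three corrected p-values fall below `alpha` simultaneously. Direction is
#' taken from the normalized rates: `up_in_A` when `x/N1 > y/N2`, `none` on
#' exact rate ties (such a miRNA can never be a consensus call in practice).
#'
#' @param x a [MirnaExperiment-class].
#' @param libA,libB column names of the two libraries (A is the reference
#'   orientation for `direction`).
#' @param alpha significance threshold (default 1e-5).
#' @param thresholdOn apply `alpha` to Bonferroni-`"corrected"` p-values
#'   (default) or to `"raw"` p-values.
#' @return data.frame with one row per tested miRNA: counts and totals, the
#'   three raw and corrected p-values, `is_de`, `direction`, and the
#'   comparison label.
#' @export
callDE <- function(x, libA, libB, alpha = 1e-5,
                   thresholdOn = c("corrected", "raw")) {
  stopifnot(is(x, "MirnaExperiment"))
  thresholdOn <- match.arg(thresholdOn)
  stopifnot(alpha > 0, alpha < 1)
  m0 <- assay(x)
  stopifnot(libA %in% colnames(m0), libB %in% colnames(m0))
  totals <- libraryTotals(x)
  n1 <- totals[[libA]]; n2 <- totals[[libB]]
  if (n1 <= 0 || n2 <= 0) stop("library totals must be positive")

  tested <- m0[, libA] > 0 & m0[, libB] > 0
  xs <- m0[tested, libA]; ys <- m0[tested, libB]
  m <- sum(tested)
  if (m == 0) {
    return(data.frame(mirna = character(0), comparison = character(0),
                      x = integer(0), y = integer(0),
                      n1 = numeric(0), n2 = numeric(0),
                      p_ac = numeric(0), p_fisher = numeric(0),
                      p_chi2 = numeric(0), q_ac = numeric(0),
                      q_fisher = numeric(0), q_chi2 = numeric(0),
                      is_de = logical(0), direction = character(0)))
  }

  pAc <- audicClaveriePValue(xs, ys, n1, n2)
  pFi <- fisherPValue(xs, ys, n1, n2)
  pCh <- chi2PValue(xs, ys, n1, n2)
  qAc <- bonferroniCorrect(pAc, m)
  qFi <- bonferroniCorrect(pFi, m)
  qCh <- bonferroniCorrect(pCh, m)

  thr <- if (thresholdOn == "corrected") cbind(qAc, qFi, qCh)
         else cbind(pAc, pFi, pCh)
  isDe <- thr[, 1] < alpha & thr[, 2] < alpha & thr[, 3] < alpha
  rateA <- xs / n1; rateB <- ys / n2
  direction <- ifelse(rateA > rateB, "up_in_A",
                      ifelse(rateA < rateB, "down_in_A", "none"))
  isDe <- isDe & direction != "none"

  data.frame(mirna = rownames(m0)[tested],
             comparison = paste0(libA, "_vs_", libB),
             x = xs, y = ys, n1 = n1, n2 = n2,
             p_ac = pAc, p_fisher = pFi, p_chi2 = pCh,
             q_ac = qAc, q_fisher = qFi, q_chi2 = qCh,
             is_de = isDe, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run all VAT-versus-SAT comparisons
#'
#' One [callDE()] per (VAT library, SAT library) pair, with the VAT library
#' always as library A, so `up_in_A` reads "up in the visceral depot".
#'
#' @param x a [MirnaExperiment-class] whose `colData` assigns each library a
#'   depot class.
#' @param alpha,thresholdOn passed to [callDE()].
#' @return named list of [callDE()] tables, one per comparison
#'   (`<VAT>_vs_<SAT>`).
#' @export
deAllComparisons <- function(x, alpha = 1e-5,
                             thresholdOn = c("corrected", "raw")) {
  depot <- depotClass(x)
  vats <- names(depot)[depot == "VAT"]
  sats <- names(depot)[depot == "SAT"]
  if (!length(vats) || !length(sats))
    stop("need at least one library per depot class")
  out <- list()
  for (a in vats) for (b in sats) {
    out[[paste0(a, "_vs_", b)]] <- callDE(x, a, b, alpha, thresholdOn)
  }
  out
}

#' Call depot-specifically enriched miRNAs
#'
#' A miRNA is VAT-specifically enriched when it is a consensus differential
#' call with direction up-in-VAT in every one of the VAT-versus-SAT
#' comparisons (all eight under the default six-library design), and
#' SAT-specifically enriched when it is called with direction down-in-VAT in
#' all of them; anything less consistent is `none`.
#'
#' @param deList list of [callDE()] results, one per (VAT, SAT) pair, each
#'   oriented with the VAT library as A (as produced by
#'   [deAllComparisons()]).
#' @param nExpected number of comparisons required (default
#'   `length(deList)`; supply explicitly to guard against a missing
#'   comparison).
#' @return data.frame with `mirna`, `status` (VAT_specific / SAT_specific /
#'   none), `n_up`, `n_down` (consensus-DE comparisons in each direction)
#'   and one direction column per comparison.
#' @export
callEnrichment <- function(deList, nExpected = length(deList)) {
  if (length(deList) != nExpected)
    stop("expected ", nExpected, " comparisons, got ", length(deList))
  if (!length(deList)) stop("no comparisons supplied")
  mirnas <- sort(unique(unlist(lapply(deList, `[[`, "mirna"))))
  nComp <- length(deList)
  dirMat <- matrix("absent", length(mirnas), nComp,
                   dimnames = list(mirnas, names(deList)))
  for (j in seq_len(nComp)) {
    d <- deList[[j]]
    dirMat[match(d$mirna, mirnas), j] <-
      ifelse(d$is_de, d$direction, "not_de")
  }
  nUp <- rowSums(dirMat == "up_in_A")
  nDown <- rowSums(dirMat == "down_in_A")
  status <- ifelse(nUp == nComp, "VAT_specific",
                   ifelse(nDown == nComp, "SAT_specific", "none"))
  out <- data.frame(mirna = mirnas, status = status,
                    n_up = nUp, n_down = nDown,
                    row.names = NULL, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(dirMat, stringsAsFactors = FALSE))
}
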