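test_that("Audic-Claverie p-value matches its closed forms and oracle", {
  # x = y = 0, equal totals: P(0|0) = 1/2, two-sided p = 1
  expect_equal(audicClaveriePValue(0, 0, 1e6, 1e6), 1)
  # frozen brute-force tail-sum value, computed by extended summation
  # (tails of the count 5 conditional on the deeper count 50)
  expect_equal(audicClaveriePValue(5, 50, 1e6, 1e6), 1.17029247403982e-10,
               tolerance = 1e-8)
  # posterior pmf is a proper distribution
  for (x in c(0, 3, 17)) {
    for (r in c(0.2, 1, 5)) {
      expect_equal(sum(exp(acPmfLog(0:20000, x, r))), 1, tolerance = 1e-10)
    }
  }
  expect_error(audicClaveriePValue(1.5, 2, 1e4, 1e4), "integer")
})

test_that("Audic-Claverie p agrees with brute-force summation on a grid", {
  set.seed(8)
  for (i in 1:40) {
    x <- sample(0:80, 1)
    n1 <- sample(c(1e4, 1e5, 1e6), 1); n2 <- sample(c(1e4, 1e6), 1)
    ys <- sample(0:200, 5)
    got <- audicClaveriePValue(rep(x, 5), ys, n1, n2)
    ref <- vapply(ys, function(y) acBruteOne(x, y, n1, n2), numeric(1))
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("the three tests are symmetric under swapping libraries", {
  set.seed(9)
  x <- sample(0:100, 25, TRUE); y <- sample(0:100, 25, TRUE)
  n1 <- sample(2e3:1e6, 25); n2 <- sample(2e3:1e6, 25)
  expect_equal(audicClaveriePValue(x, y, n1, n2),
               audicClaveriePValue(y, x, n2, n1))
  expect_equal(fisherPValue(x, y, n1, n2), fisherPValue(y, x, n2, n1))
  ch1 <- chi2Test(x, y, n1, n2); ch2 <- chi2Test(y, x, n2, n1)
  expect_equal(ch1$statistic, ch2$statistic)
  # the Pearson statistic is also invariant under transposing the table
  expect_equal(chi2Test(x, n1 - x, x + y, n1 + n2 - x - y)$statistic,
               ch1$statistic)
})

test_that("Audic-Claverie p decreases as y departs from proportionality", {
  # strict monotonicity is asserted wherever the doubled tail has not
  # saturated (p < 0.5); at the cap the two orientations cross over
  monotoneBelowCap <- function(p) {
    d <- diff(p)
    ok <- d <= 1e-12 | pmax(p[-1], p[-length(p)]) >= 0.5
    all(ok)
  }
  for (x in c(0, 5, 40, 100)) {
    for (r in c(0.2, 0.5, 1, 2, 5)) {
      n1 <- 1e5; n2 <- r * 1e5
      e <- round(x * r)
      up <- audicClaveriePValue(rep(x, 80), e + seq(0, 790, by = 10), n1, n2)
      dn <- audicClaveriePValue(rep(x, length(0:e)), e:0, n1, n2)
      expect_true(monotoneBelowCap(up))
      expect_true(monotoneBelowCap(dn))
    }
  }
})

test_that("Fisher p matches enumeration, fisher.test, and frozen values", {
  # proportional table: p = 1
  expect_equal(fisherPValue(5, 5, 100, 100), 1)
  # frozen enumeration value
  expect_equal(fisherPValue(3, 0, 10, 10), 0.210526315789473,
               tolerance = 1e-12)
  # against stats::fisher.test on random small tables
  set.seed(10)
  for (i in 1:30) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    x <- sample(0:n1, 1); y <- sample(0:n2, 1)
    ft <- stats::fisher.test(matrix(c(x, n1 - x, y, n2 - y), 2,
                                    byrow = TRUE))$p.value
    expect_equal(fisherPValue(x, y, n1, n2), ft, tolerance = 1e-9)
  }
  # the large-support tail path agrees with direct summation
  set.seed(11)
  for (i in 1:15) {
    n1 <- sample(1e4:1e6, 1); n2 <- sample(1e4:1e6, 1)
    x <- sample(1000:3000, 1); y <- sample(1200:3000, 1)
    k <- x + y
    supp <- max(0, k - n2):min(k, n1)
    pr <- dhyper(supp, n1, n2, k)
    ref <- min(1, sum(pr[pr <= pr[supp == x] * (1 + 1e-7)]))
    expect_equal(fisherPValue(x, y, n1, n2), ref,
                 tolerance = 1e-9)
  }
  expect_error(fisherPValue(11, 0, 10, 10), "exceed")
})

test_that("chi-squared test matches the ad-bc closed form and chisq.test", {
  # proportional table: statistic 0, p 1
  r <- chi2Test(10, 10, 1e4, 1e4)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # frozen closed-form value
  r2 <- chi2Test(10, 30, 1e4, 1e4)
  expect_equal(r2$statistic, 10.0200400801603, tolerance = 1e-10)
  expect_false(r2$flagged)
  # against stats::chisq.test without continuity correction
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(500:5000, 1); n2 <- sample(500:5000, 1)
    x <- sample(5:100, 1); y <- sample(5:100, 1)
    ct <- suppressWarnings(
      stats::chisq.test(matrix(c(x, n1 - x, y, n2 - y), 2, byrow = TRUE),
                        correct = FALSE))
    expect_equal(chi2Test(x, y, n1, n2)$statistic,
                 unname(ct$statistic), tolerance = 1e-10)
  }
  # tiny expected cells are flagged with p forced to 1
  small <- chi2Test(1, 0, 1e6, 1e6)   # expected min cell = 0.5
  expect_true(small$flagged)
  expect_equal(small$p.value, 1)
  # degenerate margins likewise
  deg <- chi2Test(0, 0, 100, 100)
  expect_true(deg$flagged)
  expect_equal(deg$p.value, 1)
})

test_that("chi-squared and Fisher p agree on well-populated tables", {
  # moderate departures from proportionality, all counts >= 50, where the
  # asymptotic and the exact test should track each other
  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(5e4:5e5, 1)
    n2 <- round(n1 * runif(1, 0.7, 1.4))
    x <- sample(80:500, 1)
    y <- rpois(1, x * n2 / n1)
    if (y < 50) next
    pc <- chi2PValue(x, y, n1, n2)
    pf <- fisherPValue(x, y, n1, n2)
    expect_lt(abs(log10(pc) - log10(pf)), 1)
  }
})

test_that("Bonferroni correction scales and caps", {
  expect_equal(bonferroniCorrect(0.001, 100), 0.1)
  expect_equal(bonferroniCorrect(0.5, 10), 1)
  expect_equal(bonferroniCorrect(1e-9, 284), 2.84e-7)
})

test_that("consensus calling requires all three corrected p-values", {
  libs <- c("V1", "S1")
  m <- rbind(strong = c(500L, 50L),   # clear change
             flat   = c(120L, 120L),  # identical counts
             onlyA  = c(30L, 0L),     # not co-expressed: excluded
             mild   = c(60L, 90L))    # present, not significant
  colnames(m) <- libs
  se <- MirnaExperiment(m, depot = c("VAT", "SAT"),
                        libTotals = c(V1 = 1e6, S1 = 1e6))
  de <- callDE(se, "V1", "S1")
  expect_setequal(de$mirna, c("strong", "flat", "mild"))  # m = 3 tested
  expect_true(de$is_de[de$mirna == "strong"])
  expect_equal(de$direction[de$mirna == "strong"], "up_in_A")
  expect_false(de$is_de[de$mirna == "flat"])
  expect_equal(de$direction[de$mirna == "flat"], "none")
  expect_false(de$is_de[de$mirna == "mild"])
  # the call is exactly the simultaneous-threshold rule
  expect_equal(de$is_de,
               de$q_ac < 1e-5 & de$q_fisher < 1e-5 & de$q_chi2 < 1e-5 &
                 de$direction != "none")
  # corrected p = raw p times the tested-set size, capped
  expect_equal(de$q_ac, pmin(1, de$p_ac * 3))
  # invariants: p <= q, direction set whenever called
  expect_true(all(de$p_ac <= de$q_ac & de$p_fisher <= de$q_fisher &
                    de$p_chi2 <= de$q_chi2))
  expect_true(all(de$direction[de$is_de] != "none"))
})

test_that("enrichment needs the same consensus direction in all comparisons", {
  mkDe <- function(dirs, des) {
    data.frame(mirna = c("mA", "mB", "mC"),
               is_de = des, direction = dirs, stringsAsFactors = FALSE)
  }
  comps <- paste0(rep(c("GOM", "MAD", "PAD", "RAD"), each = 2),
                  "_vs_", c("ULB", "ILB"))
  deList <- setNames(lapply(1:8, function(i) {
    dirs <- c("up_in_A", "up_in_A", "down_in_A")
    des <- c(TRUE, i != 3, TRUE)  # mB misses consensus in one comparison
    mkDe(dirs, des)
  }), comps)
  enr <- callEnrichment(deList)
  expect_equal(enr$status[enr$mirna == "mA"], "VAT_specific")
  expect_equal(enr$status[enr$mirna == "mB"], "none")
  expect_equal(enr$status[enr$mirna == "mC"], "SAT_specific")
  expect_error(callEnrichment(deList[1:7], nExpected = 8), "expected 8")
})

test_that("planted depot effects are recovered from counts", {
  p <- tinyParams(readsPerLibrary = 300000L, seed = 53L)
  x <- countLevelExperiment(p)
  enr <- callEnrichment(deAllComparisons(x$se))
  lab <- truthLabels(x$truth)
  pv <- lab$mature_name[lab$effect == "vat_enriched"]
  ps <- lab$mature_name[lab$effect == "sat_enriched"]
  cv <- enr$mirna[enr$status == "VAT_specific"]
  cs <- enr$mirna[enr$status == "SAT_specific"]
  expect_setequal(cv, pv)
  expect_setequal(cs, ps)
})
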