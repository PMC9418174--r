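# cohort statistics: normality gate, gated comparisons, summaries, report

test_that("normality gate separates Gaussian from bimodal samples", {
  set.seed(101)
  gauss <- rnorm(1000, 50, 4)
  expect_identical(normalityGate(gauss), "normal")
  bimodal <- c(rep(0, 50), rep(100, 50))
  expect_identical(normalityGate(bimodal), "non_normal")
  # direct-formula KS statistic oracle for the bimodal fixture
  sdb <- sd(bimodal)
  x <- sort(bimodal); n <- length(x)
  Fx <- pnorm(x, mean(bimodal), sdb)
  Dexp <- max(pmax(abs(seq_len(n) / n - Fx),
                   abs((seq_len(n) - 1) / n - Fx)))
  ks <- suppressWarnings(ks.test(bimodal, "pnorm", mean(bimodal), sdb))
  expect_equal(unname(ks$statistic), Dexp, tolerance = 1e-12)
  expect_identical(normalityGate(bimodal, method = "ks"), "non_normal")
  expect_identical(normalityGate(rep(5, 10)), "non_normal")
  expect_error(normalityGate(c(1, 2)), "n >= 3")
})

test_that("Mann-Whitney exact enumeration matches theory and wilcox.test", {
  mw <- mannWhitneyTest(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)        # 2 of the 20 rank assignments are as extreme
  expect_identical(mw$method, "exact")
  # tie-free random instances agree with the exact wilcox.test oracle
  set.seed(7)
  for (i in 1:30) {
    nA <- sample(2:7, 1); nB <- sample(2:7, 1)
    a <- sample(1:50, nA); b <- sample((51:100), nB)[seq_len(nB)]
    a <- a + runif(nA) * 1e-3; b <- b + runif(nB) * 1e-3
    ours <- mannWhitneyTest(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$U, unname(ref$statistic))
  }
  # large samples fall back to the corrected normal approximation
  set.seed(8)
  big <- mannWhitneyTest(rnorm(30), rnorm(30, 1))
  expect_identical(big$method, "normal")
  ref <- wilcox.test(rnorm(5), rnorm(5))  # just exercises the branch switch
  expect_true(big$p > 0 && big$p < 1)
})

test_that("gated comparison picks the prescribed test and stars", {
  set.seed(9)
  a <- rnorm(10, 0); b <- rnorm(10, 0)
  res <- compareGroups(a, a)
  expect_identical(res$test, "t")
  expect_lt(abs(res$statistic), 1e-12)
  expect_equal(res$p, 1)
  # bimodal data fails the gate and routes to Mann-Whitney
  bim <- c(rep(0, 5), rep(100, 5)) + rnorm(10, 0, 0.01)
  res2 <- compareGroups(bim, bim + 0.5)
  expect_identical(res2$test, "mann_whitney")
  # zero-variance groups route to Mann-Whitney (t is undefined)
  res3 <- compareGroups(rep(3, 5), rep(4, 5))
  expect_identical(res3$test, "mann_whitney")
  expect_error(compareGroups(a, b, idsA = c("x", "y"), idsB = c("y", "z")),
               "unpaired")
  expect_identical(starsForP(c(0.2, 0.05, 0.01, 0.001)),
                   c("ns", "*", "**", "***"))
})

test_that("t statistic is antisymmetric under group swap", {
  set.seed(10)
  a <- rnorm(7, 1); b <- rnorm(7, 0)
  r1 <- compareGroups(a, b, forceTest = "t")
  r2 <- compareGroups(b, a, forceTest = "t")
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p, r2$p)
})

test_that("group summaries drop and log exclusions", {
  rec <- expand.grid(animal = sprintf("a%d", 1:3), sex = "f",
                     genotype = "mutant", timepoint = 12,
                     measurement = "w", stringsAsFactors = FALSE)
  rec$value <- c(2, 4, 6); rec$excluded <- FALSE; rec$reason <- ""
  coh <- CohortTable(rec)
  s <- groupSummary(coh, "w", 12)
  cell <- s[s$sex == "f" & s$genotype == "mutant", ]
  expect_equal(cell$mean, 4)
  expect_equal(cell$sd, 2)
  expect_identical(cell$n, 3L)
  expect_identical(s$n[s$genotype == "control"], c(0L, 0L))
  # exclusion: one tumor-bearing female dropped, with the reason reported
  rec$excluded[2] <- TRUE; rec$reason[2] <- "splenic tumor"
  s2 <- groupSummary(CohortTable(rec), "w", 12)
  cell2 <- s2[s2$sex == "f" & s2$genotype == "mutant", ]
  expect_identical(cell2$n, 2L)
  expect_equal(cell2$mean, 4)
  expect_match(cell2$exclusionReasons, "splenic tumor")
  allEx <- rec; allEx$excluded <- TRUE
  expect_identical(groupSummary(CohortTable(allEx), "w", 12)$n[1], 0L)
  expect_error(groupSummary(coh, "missing", 12), "not present")
})

test_that("the longitudinal report covers both comparison families", {
  coh <- simulateCohort(nPerGroup = 7, seed = 12)
  rep <- longitudinalReport(coh, measurements = "marrow_T1")
  expect_true(all(c("genotype_within_sex", "sex_within_genotype") %in%
                  rep$tests$grouping))
  expect_true(any(rep$tests$timepoint == 12 &
                  rep$tests$grouping == "genotype_within_sex"))
  expect_true(all(rep$tests$nA >= 2 & rep$tests$nB >= 2))
  expect_length(rep$text, nrow(rep$tests))
  # empty measurement list -> empty report
  empty <- longitudinalReport(coh, measurements = character(0))
  expect_identical(nrow(empty$tests), 0L)
  # a pure sex effect shows up in the sex comparisons, not genotype
  eff <- list(w = list(baseline = 20, genotype = 0, sex = 10, sd = 1))
  bigCoh <- simulateCohort(nPerGroup = 10, timepoints = 12, effects = eff,
                           tumorModel = NULL, seed = 15)
  r2 <- longitudinalReport(bigCoh)
  sexP <- r2$tests$p[r2$tests$grouping == "sex_within_genotype"]
  genP <- r2$tests$p[r2$tests$grouping == "genotype_within_sex"]
  expect_true(all(sexP < 0.001))
  expect_true(all(genP > 0.05))
  # optional BH adjustment adds adjusted columns
  r3 <- longitudinalReport(bigCoh, mtc = "bh")
  expect_true(all(c("pAdjusted", "starsAdjusted") %in% names(r3$tests)))
  expect_true(all(r3$tests$pAdjusted >= r3$tests$p - 1e-15))
})

test_that("rejection rate grows with the configured effect size", {
  rate <- function(effect) {
    rej <- vapply(1:120, function(i) {
      set.seed(2000 + 7 * i + round(100 * effect))
      a <- rnorm(7, 0); b <- rnorm(7, effect)
      compareGroups(a, b)$p <= 0.05
    }, logical(1))
    mean(rej)
  }
  rates <- vapply(c(0, 1, 2), rate, numeric(1))
  expect_true(all(diff(rates) >= -0.05))
  expect_gt(rates[3], rates[1])
})
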