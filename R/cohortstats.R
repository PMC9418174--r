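# Cohort statistics: normality gate, gated two-group comparison
# (unpaired two-tailed t test vs two-tailed Mann-Whitney), group
# summaries, and the full longitudinal report.

#' Normality gate
#'
#' Classifies a sample as `"normal"` or `"non_normal"` by a
#' Kolmogorov–Smirnov-type test against a normal distribution with
#' mean and sd estimated from the data, at level `alpha`. Because
#' estimating the parameters makes the plain KS test anticonservative,
#' the default applies the Lilliefors correction; `method = "ks"` gives
#' the uncorrected variant. A zero-variance sample is classified
#' `"non_normal"` (it cannot be Gaussian and the test statistic is
#' undefined).
#'
#' @param values numeric sample, n >= 3.
#' @param alpha rejection level.
#' @param method `"lilliefors"` (default) or `"ks"`. The Lilliefors
#'   critical values are defined for n >= 5; smaller samples fall back to
#'   the uncorrected test.
#' @return `"normal"` or `"non_normal"`.
#' @export
normalityGate <- function(values, alpha = 0.05,
                          method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  .assert(length(values) >= 3, "normality gate requires n >= 3")
  .assert(all(is.finite(values)), "values must be finite")
  if (stats::sd(values) == 0) return("non_normal")
  if (method == "lilliefors" && length(values) < 5) method <- "ks"
  p <- if (method == "lilliefors") {
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                    stats::sd(values))$p.value)
  }
  if (p < alpha) "non_normal" else "normal"
}

# Mann-Whitney U of group a versus b, with tied ranks split
.mwU <- function(ranksA, nA) sum(ranksA) - nA * (nA + 1) / 2

#' Two-tailed Mann–Whitney test
#'
#' Computes the Mann–Whitney U statistic with midranks for ties. When
#' both groups have at most `exactMax` observations the two-tailed p
#' value is computed by full enumeration of all group assignments of the
#' pooled values: p is the fraction of assignments whose U deviates from
#' the null mean `nA*nB/2` by at least as much as the observed U (this
#' handles ties exactly). Otherwise a normal approximation with tie and
#' continuity correction is used.
#'
#' @param a,b the two samples.
#' @param exactMax enumeration threshold per group (default 8).
#' @return list with `U` (of group `a`), `p`, and `method`
#'   (`"exact"`/`"normal"`).
#' @examples
#' mannWhitneyTest(c(1, 2, 3), c(10, 11, 12))$p  # exact: 2/20 = 0.1
#' @export
mannWhitneyTest <- function(a, b, exactMax = 8) {
  .assert(length(a) >= 1 && length(b) >= 1, "both groups must be non-empty")
  nA <- length(a); nB <- length(b); n <- nA + nB
  pooled <- c(a, b)
  rk <- rank(pooled)
  Uobs <- .mwU(rk[seq_len(nA)], nA)
  mu <- nA * nB / 2
  if (nA <= exactMax && nB <= exactMax) {
    idx <- utils::combn(n, nA)
    dev <- abs(apply(idx, 2, function(i) .mwU(rk[i], nA)) - mu)
    p <- mean(dev >= abs(Uobs - mu) - 1e-9)
    list(U = Uobs, p = p, method = "exact")
  } else {
    ties <- table(pooled)
    sig2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = Uobs, p = 1, method = "normal"))
    z <- (abs(Uobs - mu) - 0.5) / sqrt(sig2)
    list(U = Uobs, p = min(1, 2 * stats::pnorm(-max(z, 0))),
         method = "normal")
  }
}

#' Gated two-group comparison
#'
#' Compares two independent groups the way the study design prescribes:
#' each group is first checked with the normality gate; if both pass, an
#' unpaired two-tailed t test (equal variances) is used, otherwise a
#' two-tailed Mann–Whitney test. Groups too small for the gate (n < 3)
#' or with zero variance are routed to Mann–Whitney. Significance stars:
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param idsA,idsB optional animal ids; any overlap is an error (the
#'   design is unpaired).
#' @param alpha gate level for the normality check.
#' @param gateMethod passed to [normalityGate()].
#' @param forceTest `NULL` (gate decides), `"t"` or `"mann_whitney"`.
#' @param measurement,timepoint,grouping metadata carried into the result.
#' @return one-row data.frame (a TestResult): `measurement`, `timepoint`,
#'   `grouping`, `test`, `statistic`, `p`, `stars`, `nA`, `nB`.
#' @export
compareGroups <- function(a, b, idsA = NULL, idsB = NULL, alpha = 0.05,
                          gateMethod = "lilliefors", forceTest = NULL,
                          measurement = NA_character_,
                          timepoint = NA_real_,
                          grouping = NA_character_) {
  .assert(length(a) >= 2 && length(b) >= 2,
          "both groups need at least 2 observations")
  .assert(all(is.finite(a)) && all(is.finite(b)), "values must be finite")
  if (!is.null(idsA) && !is.null(idsB) && length(intersect(idsA, idsB)))
    stop("groups share animal ids: the design is unpaired", call. = FALSE)
  test <- if (!is.null(forceTest)) {
    match.arg(forceTest, c("t", "mann_whitney"))
  } else {
    gateOK <- function(x) length(x) >= 3 && stats::sd(x) > 0 &&
      normalityGate(x, alpha = alpha, method = gateMethod) == "normal"
    if (gateOK(a) && gateOK(b)) "t" else "mann_whitney"
  }
  if (test == "t") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    mw <- mannWhitneyTest(a, b)
    statistic <- mw$U
    p <- mw$p
  }
  data.frame(measurement = measurement, timepoint = timepoint,
             grouping = grouping, test = test, statistic = statistic,
             p = p, stars = starsForP(p), nA = length(a), nB = length(b))
}

#' Per-cell group summary for one measurement and timepoint
#'
#' Mean, sd and n per sex x genotype cell, with excluded records dropped
#' and their reasons reported. Empty cells are reported with n = 0.
#'
#' @param cohort a [CohortTable-class].
#' @param measurement measurement name (must exist in the table).
#' @param timepoint timepoint in months.
#' @return data.frame, one row per sex x genotype cell: `measurement`,
#'   `timepoint`, `sex`, `genotype`, `n`, `mean`, `sd`, `nExcluded`,
#'   `exclusionReasons`.
#' @export
groupSummary <- function(cohort, measurement, timepoint) {
  .assert(is(cohort, "CohortTable"), "'cohort' must be a CohortTable")
  r <- cohortData(cohort)
  .assert(measurement %in% r$measurement,
          sprintf("measurement '%s' not present in the cohort", measurement))
  r <- r[r$measurement == measurement & r$timepoint == timepoint, ]
  cells <- expand.grid(sex = c("f", "m"), genotype = c("mutant", "control"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- r[r$sex == cells$sex[i] & r$genotype == cells$genotype[i], ]
    kept <- sub[!sub$excluded, ]
    data.frame(measurement = measurement, timepoint = timepoint,
               sex = cells$sex[i], genotype = cells$genotype[i],
               n = nrow(kept),
               mean = if (nrow(kept)) mean(kept$value) else NA_real_,
               sd = if (nrow(kept) > 1) stats::sd(kept$value) else NA_real_,
               nExcluded = sum(sub$excluded),
               exclusionReasons = paste(unique(
                 sub$reason[sub$excluded & nzchar(sub$reason)]),
                 collapse = "; "))
  })
  do.call(rbind, out)
}

#' Full longitudinal statistics report
#'
#' For every measurement and timepoint, produces the group summaries and
#' gated two-group comparisons the study design calls for: genotype
#' comparisons within each sex and sex comparisons within each genotype,
#' whenever both sides have at least 2 non-excluded values. No
#' multiple-testing correction is applied by default (matching a
#' per-comparison reporting convention); `mtc = "bh"` adds
#' Benjamini–Hochberg adjusted p values and stars.
#'
#' @param cohort a [CohortTable-class].
#' @param measurements measurements to report (default: all present).
#' @param alpha normality-gate level.
#' @param gateMethod passed to [normalityGate()].
#' @param mtc `"none"` (default) or `"bh"`.
#' @return list with `summaries` (data.frame), `tests` (data.frame of
#'   TestResults with `comparison`/`stratum` columns) and `text` (a
#'   human-readable report, one line per test).
#' @export
longitudinalReport <- function(cohort, measurements = NULL, alpha = 0.05,
                               gateMethod = "lilliefors",
                               mtc = c("none", "bh")) {
  mtc <- match.arg(mtc)
  .assert(is(cohort, "CohortTable"), "'cohort' must be a CohortTable")
  r <- cohortData(cohort)
  if (is.null(measurements)) measurements <- unique(r$measurement)
  summaries <- list()
  tests <- list()
  for (m in measurements) {
    for (tp in cohortTimepoints(cohort)) {
      if (!any(r$measurement == m & r$timepoint == tp)) next
      summaries[[length(summaries) + 1L]] <- groupSummary(cohort, m, tp)
      sub <- r[r$measurement == m & r$timepoint == tp & !r$excluded, ]
      pick <- function(col, val) sub[sub[[col]] == val, ]
      # genotype within sex
      for (sx in c("f", "m")) {
        gA <- sub[sub$sex == sx & sub$genotype == "mutant", ]
        gB <- sub[sub$sex == sx & sub$genotype == "control", ]
        if (nrow(gA) >= 2 && nrow(gB) >= 2) {
          res <- compareGroups(gA$value, gB$value, gA$animal, gB$animal,
                               alpha = alpha, gateMethod = gateMethod,
                               measurement = m, timepoint = tp,
                               grouping = "genotype_within_sex")
          res$stratum <- sx
          res$comparison <- "mutant_vs_control"
          tests[[length(tests) + 1L]] <- res
        }
      }
      # sex within genotype
      for (gt in c("mutant", "control")) {
        gA <- sub[sub$genotype == gt & sub$sex == "m", ]
        gB <- sub[sub$genotype == gt & sub$sex == "f", ]
        if (nrow(gA) >= 2 && nrow(gB) >= 2) {
          res <- compareGroups(gA$value, gB$value, gA$animal, gB$animal,
                               alpha = alpha, gateMethod = gateMethod,
                               measurement = m, timepoint = tp,
                               grouping = "sex_within_genotype")
          res$stratum <- gt
          res$comparison <- "m_vs_f"
          tests[[length(tests) + 1L]] <- res
        }
      }
    }
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame()
  tests <- if (length(tests)) do.call(rbind, tests) else data.frame()
  if (nrow(tests) && mtc == "bh") {
    tests$pAdjusted <- stats::p.adjust(tests$p, method = "BH")
    tests$starsAdjusted <- starsForP(tests$pAdjusted)
  }
  text <- if (nrow(tests)) {
    vapply(seq_len(nrow(tests)), function(i) with(tests[i, ], sprintf(
      "%s @ %g months [%s %s, %s]: %s test, statistic %.4g, p = %.4g %s",
      measurement, timepoint, grouping, stratum, comparison, test,
      statistic, p, stars)), character(1))
  } else character(0)
  list(summaries = summaries, tests = tests, text = text)
}
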