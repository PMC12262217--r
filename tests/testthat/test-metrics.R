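test_that("SSP and CSP decompose the site distribution", {
  set.seed(20)
  parent <- randomParent(30)
  r <- randomRates(parent)
  d <- codonAADistribution(r, 0.2)
  ssp <- siteSubstitutionProbability(d)
  wt <- match(strsplit(parentAA(d), "")[[1]], AAS)
  expect_equal(ssp, 1 - aaProbs(d)[cbind(1:10, wt)])
  csp <- conditionalSubstitutionProbability(d)
  expect_equal(rowSums(csp), rep(1, 10), tolerance = 1e-9)
  expect_equal(csp[cbind(1:10, wt)], rep(0, 10))
  # reconstruction: csp * ssp plus wildtype mass gives back the original
  rec <- csp * ssp
  rec[cbind(1:10, wt)] <- 1 - ssp
  expect_equal(rec, aaProbs(d), tolerance = 1e-9)
  # degenerate cases
  oneHot <- matrix(0, 1, 20, dimnames = list(NULL, AAS))
  oneHot[1, "G"] <- 1
  dWT <- new("CodonSiteDistribution", parentAA = "G", probs = oneHot,
             codonProbs = matrix(numeric(), 0, 64), nClamped = 0L,
             nRenormalized = 0L)
  expect_equal(siteSubstitutionProbability(dWT), 0)
  expect_warning(cspWT <- conditionalSubstitutionProbability(dWT), "SSP = 0")
  expect_true(all(is.na(cspWT)))
  uni <- matrix(1 / 20, 1, 20, dimnames = list(NULL, AAS))
  dU <- new("CodonSiteDistribution", parentAA = "G", probs = uni,
            codonProbs = matrix(numeric(), 0, 64), nClamped = 0L,
            nRenormalized = 0L)
  expect_equal(siteSubstitutionProbability(dU), 0.95)
})

test_that("overlap is the intersection over the average area", {
  expect_equal(overlapMetric(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(overlapMetric(c(2, 0), c(0, 5)), 0)
  expect_equal(overlapMetric(c(2, 0), c(1, 1)), 0.5)
  expect_equal(overlapMetric(c(a = 1, b = 2), c(b = 2, a = 1)), 1)
  # symmetry and the min(areas)/avg(areas) bound
  set.seed(23)
  for (i in 1:20) {
    o <- rpois(10, 3)
    e <- rgamma(10, 2)
    expect_equal(overlapMetric(o, e), overlapMetric(e, o))
    expect_lte(overlapMetric(o, e),
               min(sum(o), sum(e)) / ((sum(o) + sum(e)) / 2) + 1e-12)
  }
  expect_error(overlapMetric(c(0, 0), c(0, 0)), "all-zero")
})

test_that("R-precision counts observed sites among the top-k SSPs", {
  set.seed(24)
  expect_equal(rPrecision(c(0.1, 0.9, 0.3), observedSites = 2), 1)
  expect_equal(rPrecision(c(0.1, 0.9, 0.3), observedSites = 1), 0)
  expect_equal(rPrecision(c(0.5, 0.4, 0.3, 0.2), observedSites = c(1, 4)),
               0.5)
  expect_error(rPrecision(c(0.5), observedSites = integer()), "at least one")
  expect_error(rPrecision(c(0.5), observedSites = c(1, 1, 1)), "exceeds")
  # ties strictly above the k-th rank are always included
  expect_equal(rPrecision(c(0.9, 0.9, 0.1), observedSites = c(1, 2)), 1)
})

test_that("substitution accuracy and CSP perplexity behave at the extremes", {
  set.seed(25)
  oracle <- matrix(0, 5, 20, dimnames = list(NULL, AAS))
  oracle[cbind(1:5, 2:6)] <- 1
  expect_equal(substitutionAccuracy(oracle, AAS[2:6]), 1)
  expect_equal(substitutionAccuracy(oracle, rep(AAS[10], 5)), 0)
  expect_equal(cspPerplexity(rep(1, 4)), 1)
  expect_equal(cspPerplexity(rep(1 / 19, 7)), 19, tolerance = 1e-12)
  expect_equal(cspPerplexity(c(1, 1 / 4)), 2)
  expect_warning(p <- cspPerplexity(c(0.5, 0)), "floored")
  expect_gt(p, 1e4)
  # uniform CSP over 19: accuracy has Monte-Carlo mean 1/19
  uni <- matrix(1 / 19, 1, 20, dimnames = list(NULL, AAS))
  uni[1, "A"] <- 0
  hits <- vapply(1:4000, function(i)
    substitutionAccuracy(uni, "C"), 0)
  expect_lt(abs(mean(hits) - 1 / 19),
            3 * sqrt((1 / 19) * (18 / 19) / 4000))
})

test_that("counts distributions tally observed and expected by position", {
  cd <- countsDistributions(
    positions = list(as.character(48:52)),
    ssps = list(c(0.1, 0.2, 0.05, 0.3, 0.15)),
    observedSites = list(3L))
  expect_equal(cd$observed[cd$imgt_position == "50"], 1)
  expect_equal(sum(cd$observed), 1)
  expect_equal(sum(cd$expected), 0.8)
  # perfect-foresight model: SSP 1 exactly at observed sites
  cd2 <- countsDistributions(
    positions = list(as.character(1:4), as.character(1:4)),
    ssps = list(c(1, 0, 0, 1), c(0, 1, 0, 0)),
    observedSites = list(c(1L, 4L), 2L))
  expect_equal(overlapMetric(
    structure(cd2$observed, names = cd2$imgt_position),
    structure(cd2$expected, names = cd2$imgt_position)), 1)
})

test_that("SSP binning partitions sites and preserves total expectation", {
  b <- binnedSSPDistribution(ssp = 0.05, observed = TRUE)
  expect_equal(b$observed[1], 1L)
  expect_equal(b$expected[1], 0.05)
  set.seed(26)
  ssp <- runif(500)
  obs <- runif(500) < ssp
  b2 <- binnedSSPDistribution(ssp, obs)
  expect_equal(sum(b2$expected), sum(ssp))
  expect_equal(sum(b2$observed), sum(obs))
  expect_equal(sum(b2$n_sites), 500L)
  chi <- sspCalibrationChisq(b2)
  expect_gt(chi$p.value, 1e-6)  # calibrated by construction
})

test_that("conserved-site percentiles match a rank-by-sort oracle", {
  counts <- structure(c(5, 0, 3, 8, 8, 1, 2, 9, 4, 6),
                      names = as.character(1:10))
  pct <- conservedSitePercentiles(counts, names(counts))
  expect_equal(unname(pct[["2"]]), 0)   # unique minimum
  expect_equal(unname(pct[["8"]]), 90)  # unique maximum: (n-1)/n
  oracle <- vapply(names(counts), function(s)
    100 * (sum(counts < counts[[s]]) + 0.5 * (sum(counts == counts[[s]]) - 1))
    / length(counts), 0)
  expect_equal(pct, oracle)
  expect_error(conservedSitePercentiles(counts, "zz"), "unknown")
})

test_that("regional and per-stratum reports decompose the overall metrics", {
  set.seed(27)
  m <- syntheticKmerModel(seed = 4)
  sim <- generateDataset(40, length = 90, model = m, seed = 13)
  # identity position map puts every codon site (1..30) inside FWR1/CDR1
  rep <- evaluateModel(sim$pcps, model = m, framework = "NT", seed = 5)
  ov <- overallMetrics(rep)
  expect_true(ov$overlap > 0 && ov$overlap <= 1)
  expect_true(ov$r_precision >= 0 && ov$r_precision <= 1)
  expect_true(ov$substitution_accuracy >= 0 &&
                ov$substitution_accuracy <= 1)
  expect_gte(ov$csp_perplexity, 1)
  # events split across regions: accuracy is the event-weighted mean
  evs <- rep@events
  regs <- names(rep@byRegion)
  nByRegion <- vapply(regs, function(rn)
    rep@byRegion[[rn]]$n_events, 0)
  expect_equal(sum(nByRegion), nrow(evs))
  accs <- vapply(regs, function(rn)
    rep@byRegion[[rn]]$substitution_accuracy, 0)
  ok <- nByRegion > 0
  # tie-breaking draws differ between passes, so allow a small slack
  expect_equal(sum(accs[ok] * nByRegion[ok]) / sum(nByRegion),
               ov$substitution_accuracy, tolerance = 0.05)
  # strata: overall mean R-precision is the PCP-count-weighted mean
  ks <- names(rep@byK)
  nk <- vapply(ks, function(k) rep@byK[[k]]$n_pcps, 0)
  rp <- vapply(ks, function(k) rep@byK[[k]]$r_precision, 0)
  expect_equal(sum(rp * nk) / sum(nk), ov$r_precision, tolerance = 1e-9)
  # empty regions are reported as missing
  cdr3 <- rep@byRegion$CDR3
  expect_true(is.na(cdr3$overlap))
})

test_that("a single-region dataset makes the regional slice equal overall", {
  set.seed(28)
  m <- syntheticKmerModel(seed = 4)
  sim <- generateDataset(10, length = 30, model = m, seed = 14)
  rep <- evaluateModel(sim$pcps, model = m, framework = "NT", seed = 5)
  # codon sites 1..10 all lie in FWR1 under the identity map
  f1 <- rep@byRegion$FWR1
  ov <- overallMetrics(rep)
  expect_equal(f1$overlap, ov$overlap)
  expect_equal(f1$csp_perplexity, ov$csp_perplexity)
  expect_equal(f1$r_precision, ov$r_precision)
})
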