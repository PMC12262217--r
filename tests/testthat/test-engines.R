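test_that("per-site mutation probabilities follow the exponential model", {
  r <- uniformRates("acg", lambda = 1)
  sp <- siteMutationProbs(r, 1e-12)
  expect_equal(sp$stay, rep(1, 3), tolerance = 1e-9)
  expect_true(all(sp$P < 1e-11))
  spBig <- siteMutationProbs(r, 500)
  expect_equal(unname(spBig$P), unname((1 - exp(-500)) * r@condProbs),
               tolerance = 1e-12)
  # lambda = 1, tau = ln 2, p_c = 0.5: P_c = (1 - 1/2) * 0.5 = 0.25
  cp <- matrix(c(0, 0.5, 0.25, 0.25), 1, 4, dimnames = list(NULL, BASES))
  r1 <- new("NTSiteRates", parentNT = "a", lambda = 1, condProbs = cp)
  sp1 <- siteMutationProbs(r1, log(2))
  expect_equal(unname(sp1$P[1, "c"]), 0.25)
  expect_equal(sp1$stay + rowSums(sp1$P), 1, ignore_attr = TRUE)
  expect_error(siteMutationProbs(r, 0), "positive")
})

test_that("codon distribution matches the worked glycine->cysteine example", {
  set.seed(3)
  r <- randomRates("ggt")
  tau <- 0.07
  sp <- siteMutationProbs(r, tau)
  d <- codonAADistribution(r, tau)
  # pre-renormalization masses, per the direct formula
  pTGT <- sp$P[1, "t"] * sp$stay[2] * sp$stay[3]
  pTGC <- sp$P[1, "t"] * sp$stay[2] * sp$P[3, "c"]
  cp <- codonProbs(d)[1, ]
  norm <- cp["tgt"] / pTGT  # shared sense-renormalization factor
  expect_equal(unname(cp["tgc"] / pTGC), unname(norm), tolerance = 1e-12)
  expect_equal(unname(aaProbs(d)[1, "C"]),
               unname(norm * (pTGT + pTGC)), tolerance = 1e-12)
  # tau -> 0: wildtype amino acid takes all the mass
  d0 <- codonAADistribution(r, 1e-12)
  expect_equal(unname(aaProbs(d0)[1, "G"]), 1, tolerance = 1e-9)
  expect_error(codonAADistribution(uniformRates("taa"), 0.1), "stop codon")
})

test_that("codon distribution equals brute-force enumeration on random draws", {
  set.seed(17)
  senseCodons <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  for (i in 1:50) {
    pc <- tolower(sample(senseCodons, 1))
    r <- randomRates(pc)
    tau <- exp(runif(1, log(0.005), log(1)))
    d <- codonAADistribution(r, tau)
    oracle <- bruteForceCodonDist(pc, r@lambda, {
      m <- r@condProbs; rownames(m) <- NULL; m
    }, tau)
    expect_equal(unname(aaProbs(d)[1, ]), unname(oracle), tolerance = 1e-12)
  }
})

test_that("nucleotide likelihood expands site by site", {
  r <- uniformRates("aaaaaa", lambda = 2)
  tau <- 0.3
  # identical child: sum of -lambda tau
  expect_equal(ntLogLikelihood(r, "aaaaaa", tau), -6 * 2 * tau)
  # one a->c mutation at site 1
  ll <- ntLogLikelihood(r, "caaaaa", tau)
  expect_equal(ll, log((1 - exp(-2 * tau)) / 3) - 5 * 2 * tau)
  # monotone decreasing in tau for an identical pair
  taus <- c(0.01, 0.1, 0.5, 1)
  lls <- vapply(taus, function(t) ntLogLikelihood(r, "aaaaaa", t), 0)
  expect_true(all(diff(lls) < 0))
  # codons containing n are skipped in both sequences: 5 stay terms plus
  # one a->c mutation remain
  rn <- siteRates(baseKmerModel(), "aaannnaaa")
  expect_equal(ntLogLikelihood(rn, "aaannncaa", tau),
               -5 * tau + log((1 - exp(-tau)) / 3))
})

test_that("branch-length optimization recovers closed forms and argmaxes", {
  # uniform-rate MLE: tau_hat = -ln(1 - m/n) / lambda
  for (n in c(30, 150)) for (m in c(1, 5, 10)) for (lam in c(0.5, 2)) {
    parent <- strrep("a", n)
    child <- paste0(strrep("c", m), strrep("a", n - m))
    r <- uniformRates(parent, lambda = lam)
    fit <- fitBranchLength(parent, child, rates = r, framework = "NT")
    expect_equal(tauHat(fit), -log(1 - m / n) / lam, tolerance = 1e-6)
    expect_gte(fit@logLik,
               ntLogLikelihood(r, child, max(fit@initTau, 1e-9)))
  }
  # no mutations: likelihood decreasing, tau_hat at the lower bound
  r <- uniformRates(strrep("a", 30))
  fit0 <- optimizeBranchLength(
    function(t) ntLogLikelihood(r, strrep("a", 30), t), init = 0)
  expect_lt(tauHat(fit0), 1e-6)
  # concave quadratic in log tau: analytic argmax recovered
  for (t0 in c(0.02, 0.4, 3)) {
    fit <- optimizeBranchLength(function(t) -(log(t) - log(t0))^2, init = 0.1)
    expect_equal(tauHat(fit), t0, tolerance = 1e-5)
  }
})

test_that("neutral selection factors reproduce the neutral distribution", {
  set.seed(9)
  parent <- randomParent(30)
  r <- randomRates(parent)
  prof <- SelectionProfile(matrix(1, 10, 20), translateNT(parent))
  d0 <- codonAADistribution(r, 0.15)
  d1 <- applySelection(r, prof, 0.15)
  expect_equal(aaProbs(d1), aaProbs(d0), tolerance = 1e-12)
  expect_equal(codonProbs(d1), codonProbs(d0), tolerance = 1e-12)
  expect_equal(d1@nClamped + d1@nRenormalized, 0L)
})

test_that("selection multiplies, clamps and renormalizes per the contract", {
  set.seed(10)
  parent <- "ggtgaatgc"
  paa <- translateNT(parent)
  r <- randomRates(parent)
  tau <- 0.1
  # moderate random ratios: verify against the brute-force oracle
  R <- matrix(exp(rnorm(3 * 20, sd = 0.8)), 3, 20)
  R[cbind(1:3, match(strsplit(paa, "")[[1]], AAS))] <- 1
  prof <- SelectionProfile(R, paa)
  d <- applySelection(r, prof, tau)
  for (s in 1:3) {
    fac <- structure(as.list(selectionFactors(prof)[s, ]), names = AAS)
    oracle <- bruteForceCodonDist(substr(parent, 3 * s - 2, 3 * s),
                                  r@lambda[(3 * s - 2):(3 * s)],
                                  r@condProbs[(3 * s - 2):(3 * s), ],
                                  tau, factorsByAA = fac)
    expect_equal(unname(aaProbs(d)[s, ]), unname(oracle), tolerance = 1e-12)
  }
  # extreme preference for every outcome at long tau: non-wildtype mass
  # exceeds one, so it is renormalized and no-change drops to zero
  Rbig <- matrix(1e8, 3, 20)
  Rbig[cbind(1:3, match(strsplit(paa, "")[[1]], AAS))] <- 1
  dHot <- applySelection(r, SelectionProfile(Rbig, paa), 3)
  expect_gt(dHot@nRenormalized, 0)
  wt <- aaProbs(dHot)[cbind(1:3, match(strsplit(paa, "")[[1]], AAS))]
  synMass <- vapply(1:3, function(s) {
    cp <- codonProbs(dHot)[s, ]
    pc <- substr(parent, 3 * s - 2, 3 * s)
    other <- setdiff(names(cp), pc)
    sum(cp[other][translateNT(other) == substr(paa, s, s)])
  }, 0)
  # no-change probability is zero, so the parent amino acid holds only
  # its synonymous-codon mass
  expect_equal(unname(wt), synMass, tolerance = 1e-12)
  expect_equal(rowSums(aaProbs(dHot)), rep(1, 3), tolerance = 1e-12)
})

test_that("selection toward the observed child raises likelihood and shortens tau", {
  set.seed(12)
  parent <- randomParent(60)
  r <- randomRates(parent)
  child <- simulateChild(parent, r, 0.2)
  paa <- translateNT(parent)
  caa <- strsplit(translateNT(child), "")[[1]]
  pav <- strsplit(paa, "")[[1]]
  changed <- which(pav != caa & caa %in% AAS)
  skip_if(length(changed) == 0)
  R <- matrix(1, 20, 20)
  R[cbind(changed, match(caa[changed], AAS))] <- 50
  prof <- SelectionProfile(R, paa)
  neutral <- SelectionProfile(matrix(1, 20, 20), paa)
  tau <- 0.2
  expect_gt(ntaaLogLikelihood(r, prof, child, tau),
            ntaaLogLikelihood(r, neutral, child, tau))
  # global substitution pressure (every non-wildtype outcome preferred)
  # drains the no-change probability faster, so the same substitutions are
  # explained by a shorter branch
  Rall <- matrix(50, 20, 20)
  Rall[cbind(1:20, match(strsplit(paa, "")[[1]], AAS))] <- 1
  profAll <- SelectionProfile(Rall, paa)
  fitSel <- fitBranchLength(parent, child, rates = r, selection = profAll,
                            framework = "NT-AA")
  fitNeu <- fitBranchLength(parent, child, rates = r, selection = neutral,
                            framework = "NT-AA")
  expect_lt(tauHat(fitSel), tauHat(fitNeu))
  # F == 1 codon likelihood equals the per-codon product of the neutral
  # codon outcome probabilities
  d0 <- codonAADistribution(r, tau)
  idx <- match(substring(child, seq(1, 58, 3), seq(3, 60, 3)),
               colnames(codonProbs(d0)))
  manual <- sum(log(codonProbs(d0)[cbind(1:20, idx)]))
  expect_equal(ntaaLogLikelihood(r, neutral, child, tau), manual,
               tolerance = 1e-12)
})

test_that("amino-acid scaling interpolates between parent and model", {
  P <- matrix(1 / 20, 4, 20)
  paa <- "ACDE"
  d0 <- aaScaledDistribution(P, paa, 1e-12)
  expect_equal(unname(aaProbs(d0)[1, "A"]), 1, tolerance = 1e-9)
  dln2 <- aaScaledDistribution(P, paa, log(2))
  expect_equal(unname(aaProbs(dln2)[2, "C"]), 0.525)
  expect_equal(unname(aaProbs(dln2)[2, "D"]), 0.025)
  dInf <- aaScaledDistribution(P, paa, 50)
  expect_equal(unname(aaProbs(dInf)), unname(P), tolerance = 1e-9)
  expect_equal(rowSums(aaProbs(dln2)), rep(1, 4))
})

test_that("amino-acid likelihood matches a grid-search oracle", {
  set.seed(14)
  P <- logitsToProbabilities(matrix(rnorm(10 * 20), 10, 20))
  parent <- randomParent(30)
  paa <- translateNT(parent)
  child <- randomParent(30)
  caa <- translateNT(child)
  # identical pair: sum over sites of log(e^-tau + (1 - e^-tau) P_wt)
  wt <- match(strsplit(paa, "")[[1]], AAS)
  tau <- 0.4
  expect_equal(aaLogLikelihood(P, paa, paa, tau),
               sum(log(exp(-tau) + (1 - exp(-tau)) * P[cbind(1:10, wt)])))
  fit <- fitBranchLength(parent, child, aaSiteProbs = P, framework = "AA")
  grid <- exp(seq(log(1e-6), log(10), length.out = 20000))
  lls <- vapply(grid, function(t) aaLogLikelihood(P, paa, caa, t), 0)
  expect_equal(tauHat(fit), grid[which.max(lls)], tolerance = 1e-3)
  expect_gte(fit@logLik, max(lls) - 1e-9)
})
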