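test_that("k-mer lookup centres the context and pads ends with defaults", {
  m1 <- baseKmerModel(c(a = 1, c = 1, g = 1, t = 1))
  r <- siteRates(m1, "acgt")
  expect_equal(r@lambda, rep(1, 4))
  expect_equal(unname(r@condProbs[1, ]), c(0, 1, 1, 1) / 3)

  # k = 3: the "agt" entry governs the central site of "agt"
  set.seed(2)
  m3 <- syntheticKmerModel(k = 3, seed = 2)
  r3 <- siteRates(m3, "agt")
  expect_equal(unname(r3@lambda[2]), unname(m3@rates[["agt"]]))
  expect_equal(unname(r3@condProbs[2, ]), unname(m3@condProbs["agt", ]))
  # boundary sites have n-padded contexts, absent from the table
  expect_equal(unname(r3@lambda[1]), m3@defaultRate)
  # default conditional probabilities are re-zeroed at the wildtype base
  expect_equal(unname(r3@condProbs[1, "a"]), 0)
  expect_equal(sum(r3@condProbs[1, ]), 1)
  expect_error(KmerModel(c(ag = 1), matrix(c(0, 1, 0, 0), 1, 4,
                                           dimnames = list("ag", BASES))),
               "odd")
})

test_that("per-site models apply naive-coordinate rates verbatim", {
  ref <- "acgacg"
  cp <- matrix(1 / 3, 6, 4, dimnames = list(NULL, BASES))
  cp[cbind(1:6, match(strsplit(ref, "")[[1]], BASES))] <- 0
  m <- PerSiteModel(ref, rep(1 / 6, 6), cp)
  r <- siteRates(m, ref)
  expect_equal(sum(r@lambda), 1)
  expect_error(siteRates(m, "acg"), "length")
  # a mutated parent gets the same rates as the naive parent
  r2 <- siteRates(m, "tcgacg")
  expect_equal(r2@lambda, r@lambda)
  expect_equal(r2@condProbs, r@condProbs)
})

test_that("BLOSUM62 ratios follow R = 2^(M/2) with reciprocal symmetry", {
  M <- blosum62Matrix()
  expect_true(isSymmetric(unname(M)))
  expect_equal(M["A", "A"], 4L)
  expect_equal(M["W", "W"], 11L)
  prof <- selectionProfile(M, "ARN")
  # hand-checked entries: R = 2^{M/2}
  expect_equal(selectionRatios(prof)[1, "R"], 2^(M["R", "A"] / 2),
               ignore_attr = TRUE)
  expect_equal(selectionRatios(prof)[1, "A"], 1, ignore_attr = TRUE)
  # synthetic matrix: entries 0, 2, -2 give R = 1, 2, 0.5
  S <- matrix(0L, 20, 20, dimnames = list(AAS, AAS))
  S["C", "A"] <- S["A", "C"] <- 2L
  S["D", "A"] <- S["A", "D"] <- -2L
  p2 <- selectionProfile(S, "A")
  expect_equal(unname(selectionRatios(p2)[1, c("C", "D", "E")]),
               c(2, 0.5, 1))
  # symmetry of the log-odds matrix carries over: R(X -> X') = R(X' -> X)
  pA <- selectionRatios(selectionProfile(M, "A"))[1, ]
  for (aa in setdiff(AAS, "A"))
    expect_equal(pA[[aa]],
                 unname(selectionRatios(selectionProfile(M, aa))[1, "A"]))
  expect_error(selectionProfile(M, "AB"), "nonstandard")
})

test_that("DMS ratios follow the dissociation-constant formula", {
  b <- matrix(5, 2, 20, dimnames = list(NULL, AAS))  # -log10 KD
  b[1, "C"] <- 6   # child binds 1 log10 unit stronger
  b[1, "D"] <- 4   # 1 log10 unit weaker
  b[2, "E"] <- NA
  dms <- DMSModel(b)
  expect_warning(prof <- selectionProfile(dms, "AA"), "unmeasured")
  R <- selectionRatios(prof)
  expect_equal(unname(R[1, c("C", "D", "G")]), c(10, 0.1, 1))
  expect_equal(unname(R[2, "E"]), 1)  # missing entry defaults to 1
})

test_that("softmax converts logits to probabilities with shift invariance", {
  lg <- AASiteLogits(matrix(0, 3, 20))
  p <- logitsToProbabilities(lg)
  expect_equal(unname(p), matrix(1 / 20, 3, 20), tolerance = 1e-12)
  set.seed(4)
  m <- matrix(rnorm(40), 2, 20)
  expect_equal(logitsToProbabilities(m), logitsToProbabilities(m + 3.7))
  # two-hot row: ln 3 against zeros gives 3/22 vs 1/22
  hot <- matrix(0, 1, 20)
  hot[1, 1] <- log(3)
  expect_equal(unname(logitsToProbabilities(hot)[1, ]),
               c(3, rep(1, 19)) / 22)
})

test_that("selection factor transform is bounded, monotone and centred", {
  expect_equal(selectionFactor(1), 1)
  R <- 10^seq(-8, 8, length.out = 200)
  f <- selectionFactor(R)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 2))
  expect_error(selectionFactor(-1), "positive")
})

test_that("adapters never mutate their input tables", {
  m <- syntheticKmerModel(seed = 6)
  rates0 <- m@rates
  cp0 <- m@condProbs
  invisible(siteRates(m, "acgtgacgt"))
  expect_identical(m@rates, rates0)
  expect_identical(m@condProbs, cp0)
  M <- blosum62Matrix()
  M0 <- M
  invisible(selectionProfile(M, "ACD"))
  expect_identical(M, M0)
})

test_that("model tables survive a write/read round trip", {
  m <- syntheticKmerModel(seed = 8)
  path <- tempfile(fileext = ".tsv")
  writeKmerModel(m, path)
  m2 <- readKmerModel(path)
  expect_equal(m2@rates, m@rates)
  expect_equal(unname(m2@condProbs), unname(m@condProbs), tolerance = 1e-12)
  expect_equal(m2@defaultRate, m@defaultRate)

  # per-site model with reference recorded in a header comment
  ref <- "acgacg"
  cp <- matrix(1 / 3, 6, 4, dimnames = list(NULL, BASES))
  cp[cbind(1:6, match(strsplit(ref, "")[[1]], BASES))] <- 0
  ps <- tempfile(fileext = ".tsv")
  writeLines(c("# reference: acgacg",
               paste(c("site", "rate", "p_a", "p_c", "p_g", "p_t"),
                     collapse = "\t"),
               vapply(1:6, function(i)
                 paste(c(i, 1 / 6, cp[i, ]), collapse = "\t"), "")), ps)
  mp <- readPerSiteModel(ps)
  expect_equal(mp@referenceNT, ref)
  expect_equal(sum(mp@rates), 1)
})
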