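# Shared fixtures and independent oracles.

BASES <- c("a", "c", "g", "t")
AAS <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))

# NTSiteRates with uniform rate lambda and uniform conditional
# probabilities over the three non-wildtype bases
uniformRates <- function(parent, lambda = 1) {
  L <- nchar(parent)
  b <- match(strsplit(parent, "")[[1]], BASES)
  cp <- matrix(1 / 3, L, 4, dimnames = list(NULL, BASES))
  cp[cbind(seq_len(L), b)] <- 0
  new("NTSiteRates", parentNT = parent, lambda = rep(lambda, L),
      condProbs = cp)
}

# NTSiteRates with random rates and random conditional probabilities
# (zero at the wildtype base), drawn from the current RNG stream
randomRates <- function(parent, rateRange = c(0.2, 5)) {
  L <- nchar(parent)
  b <- match(strsplit(parent, "")[[1]], BASES)
  lam <- exp(runif(L, log(rateRange[1]), log(rateRange[2])))
  g <- matrix(rgamma(4 * L, shape = 1), L, 4)
  g[cbind(seq_len(L), b)] <- 0
  cp <- g / rowSums(g)
  dimnames(cp) <- list(NULL, BASES)
  new("NTSiteRates", parentNT = parent, lambda = lam, condProbs = cp)
}

# Independent brute-force oracle for the codon-site amino-acid
# distribution: enumerate all 64 codon outcomes with explicit string
# arithmetic, drop stops, renormalize, optionally apply selection factors
# with clamping/renormalization, then aggregate by the genetic code.
# Deliberately naive and loop-based; shares no code with the engine.
bruteForceCodonDist <- function(parentCodon, lambda3, cond3x4, tau,
                                factorsByAA = NULL) {
  gc <- Biostrings::GENETIC_CODE
  stay <- exp(-lambda3 * tau)
  pcv <- strsplit(parentCodon, "")[[1]]
  prs <- c()
  for (b1 in BASES) for (b2 in BASES) for (b3 in BASES) {
    term <- 1
    for (j in 1:3) {
      bj <- c(b1, b2, b3)[j]
      term <- term * if (bj == pcv[j]) stay[j]
                     else (1 - stay[j]) * cond3x4[j, bj]
    }
    prs[paste0(b1, b2, b3)] <- term
  }
  sense <- names(prs)[gc[toupper(names(prs))] != "*"]
  prs <- prs[sense] / sum(prs[sense])
  if (!is.null(factorsByAA)) {
    wt <- parentCodon
    nonwt <- setdiff(sense, wt)
    for (cd in nonwt)
      prs[cd] <- min(1, prs[cd] * factorsByAA[[gc[toupper(cd)]]])
    s <- sum(prs[nonwt])
    if (s > 1) {
      prs[nonwt] <- prs[nonwt] / s
      prs[wt] <- 0
    } else prs[wt] <- 1 - s
  }
  aa <- tapply(prs, gc[toupper(names(prs))], sum)
  out <- structure(rep(0, length(AAS)), names = AAS)
  out[names(aa)] <- aa
  out
}

# small kmer model with k = 1 (per-base rates), handy for exact fixtures
baseKmerModel <- function(rates = c(a = 1, c = 1, g = 1, t = 1)) {
  cp <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(cp) <- 0
  KmerModel(rates, cp)
}

# write a tiny valid PCP TSV and return its path
writeToyPCPTSV <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    pcp_id = c("p1", "p2"), family_id = c("f1", "f1"),
    parent_nt = c("ggtgaatgt", "atgaaacct"),
    child_nt = c("tgtgaatgt", "atgcaacct"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
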