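# Performance metrics: site substitution probabilities (SSP), conditional
# substitution probabilities (CSP), and the four dataset-level scores
# (overlap, R-precision, substitution accuracy, CSP perplexity).

#' Site substitution probability
#'
#' The probability that the amino acid at a codon site changes over the
#' branch: one minus the wildtype probability.
#'
#' @param dist a [CodonSiteDistribution].
#' @return numeric vector of SSPs, \code{NA} at skipped codons.
#' @export
siteSubstitutionProbability <- function(dist) {
  aa <- strsplit(dist@parentAA, "")[[1]]
  wt <- match(aa, .AAS)
  ssp <- rep(NA_real_, length(aa))
  ii <- which(!is.na(wt) & !is.na(dist@probs[, 1]))
  ssp[ii] <- 1 - dist@probs[cbind(ii, wt[ii])]
  # guard tiny negative values from floating-point cancellation
  pmin(pmax(ssp, 0), 1)
}

#' Conditional substitution probability
#'
#' The distribution over the 19 non-wildtype amino acids at each site,
#' conditioned on a substitution occurring:
#' \eqn{CSP_{r,X'} = P_{r,X'} / (1 - P_{r,wt})}. Sites with SSP = 0 are
#' undefined and returned as \code{NA} rows (with a warning); they are
#' excluded from CSP-based metrics.
#'
#' @param dist a [CodonSiteDistribution].
#' @return sites x 20 matrix; the wildtype column is 0 and each defined
#'   row sums to 1.
#' @export
conditionalSubstitutionProbability <- function(dist) {
  ssp <- siteSubstitutionProbability(dist)
  aa <- strsplit(dist@parentAA, "")[[1]]
  wt <- match(aa, .AAS)
  out <- dist@probs
  ii <- which(!is.na(wt) & !is.na(out[, 1]))
  out[cbind(ii, wt[ii])] <- 0
  zero <- ii[ssp[ii] == 0]
  if (length(zero)) {
    warning(length(zero), " site(s) with SSP = 0 excluded from CSP",
            call. = FALSE)
    out[zero, ] <- NA_real_
  }
  live <- setdiff(ii, zero)
  out[live, ] <- out[live, , drop = FALSE] / ssp[live]
  out[setdiff(seq_along(aa), ii), ] <- NA_real_
  out
}

#' Overlap of observed and expected count distributions
#'
#' The ratio of the area of intersection to the average area:
#' \deqn{\sum_i \min(O_i, E_i) \Big/ \sum_i (O_i + E_i)/2.}
#' Equals 1 iff the distributions are identical and 0 for disjoint
#' supports.
#'
#' @param observed,expected nonnegative numeric vectors over the same
#'   positions (aligned by names when named).
#' @return numeric scalar in \code{[0, 1]}.
#' @export
overlapMetric <- function(observed, expected) {
  if (!is.null(names(observed)) && !is.null(names(expected))) {
    pos <- union(names(observed), names(expected))
    o <- structure(rep(0, length(pos)), names = pos)
    e <- o
    o[names(observed)] <- observed
    e[names(expected)] <- expected
    observed <- o
    expected <- e
  }
  if (length(observed) != length(expected))
    stop("observed and expected must cover the same positions")
  tot <- sum(observed) + sum(expected)
  if (tot == 0) stop("both distributions are all-zero; overlap undefined")
  sum(pmin(observed, expected)) / (tot / 2)
}

#' R-precision of predicted substitution sites for one pair
#'
#' With \eqn{k} observed substitutions, the fraction of the observed sites
#' among the model's top-\eqn{k} SSP sites. Ties at the \eqn{k}-th rank are
#' resolved by uniform random choice among the tied sites, drawn from the
#' current RNG stream (seed it at the dataset level for reproducibility).
#'
#' @param ssp numeric vector of SSPs over the scored sites.
#' @param observedSites integer indices (into \code{ssp}) of the sites
#'   where a substitution was observed.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
rPrecision <- function(ssp, observedSites) {
  k <- length(observedSites)
  if (k < 1) stop("at least one observed substitution is required")
  if (k > length(ssp)) stop("k exceeds the number of scored sites")
  thr <- sort(ssp, decreasing = TRUE)[k]
  above <- which(ssp > thr)
  tied <- which(ssp == thr)
  need <- k - length(above)
  top <- c(above, tied[sample.int(length(tied), need)])
  length(intersect(top, observedSites)) / k
}

#' Substitution accuracy over a set of substitution events
#'
#' The fraction of substitution events whose observed amino-acid outcome
#' attains the maximum CSP at its site; all events are weighted equally.
#' Argmax ties are broken by uniform random choice from the current RNG
#' stream.
#'
#' @param csp events x 20 matrix of CSP vectors, one row per event.
#' @param childAA character vector of observed outcome amino acids.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
substitutionAccuracy <- function(csp, childAA) {
  n <- nrow(csp)
  if (n == 0) stop("no substitution events")
  obs <- match(childAA, .AAS)
  hits <- vapply(seq_len(n), function(i) {
    row <- csp[i, ]
    cand <- which(row == max(row))
    pick <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
    pick == obs[i]
  }, NA)
  mean(hits)
}

#' CSP perplexity over a set of substitution events
#'
#' The geometric mean of the inverse probabilities assigned to the
#' observed outcomes, \eqn{(\prod_i 1/p_i)^{1/N}}, computed in log space.
#' 1 is a hypothetically perfect score; a uniform CSP over the 19
#' non-wildtype amino acids gives 19.
#'
#' @param p numeric vector of CSPs of the observed outcomes, one per
#'   event.
#' @param floor probability substituted for nonpositive entries (flagged
#'   with a warning).
#' @return numeric scalar \eqn{\ge 1} for proper CSPs.
#' @export
cspPerplexity <- function(p, floor = 1e-10) {
  if (!length(p)) stop("no substitution events")
  if (any(p <= 0)) {
    warning(sum(p <= 0), " event(s) with zero probability floored at ",
            floor, call. = FALSE)
    p <- pmax(p, floor)
  }
  exp(-mean(log(p)))
}

#' Observed and expected substitution counts by IMGT position
#'
#' Observed counts tally amino-acid substitutions across all pairs at each
#' IMGT position; expected counts sum the SSPs. The areas (column sums)
#' are the total number of substitutions observed and expected in the
#' data set.
#'
#' @param positions list of character vectors of IMGT labels, one vector
#'   per pair (one label per scored codon site).
#' @param ssps list of SSP vectors aligned with \code{positions}.
#' @param observedSites list of integer index vectors (into each pair's
#'   sites) of observed substitutions.
#' @return data.frame with columns \code{imgt_position}, \code{observed},
#'   \code{expected}, ordered by first appearance.
#' @export
countsDistributions <- function(positions, ssps, observedSites) {
  allPos <- unique(unlist(positions, use.names = FALSE))
  o <- structure(rep(0, length(allPos)), names = allPos)
  e <- o
  for (i in seq_along(positions)) {
    pos <- positions[[i]]
    s <- ssps[[i]]
    ok <- which(!is.na(s))
    ec <- tapply(s[ok], pos[ok], sum)
    e[names(ec)] <- e[names(ec)] + ec
    if (length(observedSites[[i]])) {
      oc <- table(pos[observedSites[[i]]])
      o[names(oc)] <- o[names(oc)] + oc
    }
  }
  data.frame(imgt_position = allPos, observed = unname(o),
             expected = unname(e), stringsAsFactors = FALSE)
}

#' Observed and expected substitutions per SSP bin
#'
#' Distributes scored sites into bins of their SSP value; per bin, the
#' observed count is the number of substituted sites and the expected
#' count is the sum of SSPs. A well-calibrated model has observed close to
#' expected in every bin.
#'
#' @param ssp numeric vector of SSPs pooled over pairs and sites.
#' @param observed logical vector flagging substituted sites.
#' @param edges increasing bin edges covering \code{[0, 1]}.
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{n_sites}, \code{observed}, \code{expected}.
#' @export
binnedSSPDistribution <- function(ssp, observed, edges = seq(0, 1, 0.1)) {
  ok <- !is.na(ssp)
  ssp <- ssp[ok]
  observed <- observed[ok]
  bin <- findInterval(ssp, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  data.frame(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    n_sites = vapply(seq_len(nb), function(b) sum(bin == b), 0L),
    observed = vapply(seq_len(nb), function(b) sum(observed[bin == b]), 0L),
    expected = vapply(seq_len(nb), function(b) sum(ssp[bin == b]), 0))
}

#' Chi-square calibration statistic over SSP bins
#'
#' Compares observed to expected counts per SSP bin with a Poisson-style
#' chi-square statistic; bins with expected count below \code{minExpected}
#' are pooled into the preceding bin. The expected counts come from the
#' model, not from the data, so the degrees of freedom equal the number of
#' bins used.
#'
#' @param binned output of [binnedSSPDistribution()].
#' @param minExpected minimum expected count per bin before pooling.
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @export
sspCalibrationChisq <- function(binned, minExpected = 5) {
  o <- binned$observed
  e <- binned$expected
  keep <- e > 0
  o <- o[keep]
  e <- e[keep]
  # pool small bins from the top down
  while (length(e) > 1 && any(e < minExpected)) {
    i <- which(e < minExpected)[1]
    j <- if (i == length(e)) i - 1L else i + 1L
    e[j] <- e[j] + e[i]
    o[j] <- o[j] + o[i]
    e <- e[-i]
    o <- o[-i]
  }
  stat <- sum((o - e)^2 / e)
  df <- length(e)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Percentile ranks of named sites in a counts distribution
#'
#' Ranks each named site's count among all positions: the percentage of
#' positions with a strictly smaller count, with a midpoint adjustment for
#' ties. Used to compare how data and models rank highly conserved sites.
#'
#' @param counts named numeric vector of per-position counts (e.g. the
#'   \code{observed} or \code{expected} column of [countsDistributions()]
#'   named by position).
#' @param sites character vector of position labels to rank.
#' @return named numeric vector of percentiles in \code{[0, 100)}.
#' @export
conservedSitePercentiles <- function(counts, sites) {
  if (any(!sites %in% names(counts)))
    stop("unknown site label(s): ",
         paste(setdiff(sites, names(counts)), collapse = ", "))
  n <- length(counts)
  vapply(sites, function(s) {
    ci <- counts[[s]]
    100 * (sum(counts < ci) + 0.5 * (sum(counts == ci) - 1)) / n
  }, 0)
}
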