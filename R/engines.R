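# Engines: per-site mutation probabilities, codon-level aggregation to
# amino-acid distributions, likelihoods for the three frameworks, and
# branch-length optimization.

# indicator matrix mapping the 64 codon outcomes onto the 20 amino acids
# (stop columns map to nothing)
.CODON_TO_AA <- local({
  z <- matrix(0, 64L, 20L, dimnames = list(.CODONS, .AAS))
  ok <- !is.na(.CODON_AA_IDX)
  z[cbind(which(ok), .CODON_AA_IDX[ok])] <- 1
  z
})

.LOG_FLOOR <- log(1e-12)

#' Per-site nucleotide mutation probabilities at a branch length
#'
#' Under the exponential-waiting-time model, a site with rate
#' \eqn{\lambda_i} remains unchanged over time \eqn{\tau} with probability
#' \eqn{e^{-\lambda_i \tau}} and mutates to base \eqn{x} with probability
#' \eqn{P_{i,x}(\tau) = (1 - e^{-\lambda_i \tau})\, p_{i,x}}. For models
#' parametrized at naive coordinates, any conditional mass on the current
#' parent base is folded into the stay probability, so
#' \code{stay + rowSums(P) == 1} at every site.
#'
#' @param rates an [NTSiteRates].
#' @param tau positive branch length.
#' @return list with \code{stay} (numeric vector) and \code{P}
#'   (sites x 4 matrix, zero at the parent base). \code{NA} at sites whose
#'   parent base is \code{n}.
#' @export
siteMutationProbs <- function(rates, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  lam <- rates@lambda
  stay0 <- exp(-lam * tau)
  P <- (1 - stay0) * rates@condProbs
  baseIdx <- .ntToInt(rates@parentNT)
  ii <- which(!is.na(baseIdx))
  wt <- cbind(ii, baseIdx[ii])
  stay <- stay0
  stay[ii] <- stay0[ii] + P[wt]
  P[wt] <- 0
  list(stay = stay, P = P)
}

# Codon outcome distribution: sites x 64 matrix of probabilities for every
# codon outcome, conditioned on a non-stop outcome, optionally modified by
# selection factors. Rows for codons containing n are all-NA. Shared by
# likelihoods, amino-acid distributions and the simulator.
.codonOutcomeProbs <- function(rates, tau, selection = NULL) {
  sp <- siteMutationProbs(rates, tau)
  L <- length(sp$stay)
  C <- L %/% 3L
  baseIdx <- .ntToInt(rates@parentNT)
  siteOf <- matrix(seq_len(L), ncol = 3L, byrow = TRUE)  # C x 3
  # per-position outcome-base probabilities: T[[j]] is C x 4, holding the
  # mutation probability of each target base, with the stay probability at
  # the parent base
  M <- 1
  parentCodonIdx <- integer(C)
  pb <- matrix(baseIdx[t(siteOf)], ncol = 3L, byrow = TRUE)  # C x 3
  codonOK <- !is.na(pb[, 1]) & !is.na(pb[, 2]) & !is.na(pb[, 3])
  parentCodonIdx[codonOK] <-
    (pb[codonOK, 1] - 1L) * 16L + (pb[codonOK, 2] - 1L) * 4L + pb[codonOK, 3]
  if (any(!.SENSE[parentCodonIdx[codonOK]]))
    stop("parent contains a stop codon")
  for (j in 1:3) {
    Tj <- sp$P[siteOf[, j], , drop = FALSE]
    ok <- which(codonOK)
    Tj[cbind(ok, pb[ok, j])] <- sp$stay[siteOf[ok, j]]
    M <- M * Tj[, .CODON_BASE_IDX[, j], drop = FALSE]
  }
  M[!codonOK, ] <- NA_real_
  # condition on a non-stop outcome
  M[, !.SENSE] <- 0
  M[!codonOK, ] <- NA_real_
  M <- M / rowSums(M)
  nClamped <- 0L
  nRenorm <- 0L
  if (!is.null(selection)) {
    validObject(selection)
    F64 <- selection@factors[, ifelse(is.na(.CODON_AA_IDX), 1L,
                                      .CODON_AA_IDX), drop = FALSE]
    wtCell <- cbind(which(codonOK), parentCodonIdx[codonOK])
    wtP <- M[wtCell]
    M[wtCell] <- 0
    M <- M * F64
    over <- which(M > 1)
    nClamped <- length(over)
    if (nClamped) M[over] <- 1
    s <- rowSums(M)
    newWt <- 1 - s
    hot <- which(s > 1)
    nRenorm <- length(hot)
    if (nRenorm) {
      M[hot, ] <- M[hot, , drop = FALSE] / s[hot]
      newWt[hot] <- 0
    }
    M[wtCell] <- newWt[codonOK]
    M[, !.SENSE] <- 0
    M[!codonOK, ] <- NA_real_
  }
  structure(M, parentCodonIdx = ifelse(codonOK, parentCodonIdx, NA_integer_),
            nClamped = nClamped, nRenormalized = nRenorm)
}

#' Codon-site amino-acid distribution under a nucleotide model
#'
#' Aggregates per-site nucleotide mutation probabilities into a probability
#' distribution over amino acids at each codon site: the probability of
#' each of the 64 codon outcomes is the product of the three per-position
#' terms (stay probability for unchanged bases, mutation probability for
#' changed ones); stop-codon outcomes are removed and the 61 sense
#' outcomes renormalized (conditioning on a non-stop outcome); each amino
#' acid then collects the mass of its codons, the wildtype amino acid
#' accumulating its synonymous codons together with the no-change term.
#'
#' With a [SelectionProfile], every non-wildtype codon outcome is further
#' multiplied by the selection factor of its amino acid; individual
#' probabilities exceeding one are clamped at one, and if the non-wildtype
#' mass exceeds one it is renormalized to one with the no-change
#' probability set to zero. Clamp and renormalization events are counted
#' in the returned object.
#'
#' @param rates an [NTSiteRates] for the parent sequence.
#' @param tau positive branch length.
#' @param selection optional [SelectionProfile].
#' @return a [CodonSiteDistribution]; codons containing \code{n} have
#'   all-\code{NA} rows.
#' @export
codonAADistribution <- function(rates, tau, selection = NULL) {
  M <- .codonOutcomeProbs(rates, tau, selection)
  A <- unclass(M) %*% .CODON_TO_AA
  colnames(M) <- .CODONS
  paa <- vapply(.codonStrings(rates@parentNT), function(cd) {
    a <- .CODON2AA[cd]
    if (is.na(a)) "X" else a
  }, "", USE.NAMES = FALSE)
  new("CodonSiteDistribution", parentAA = paste(paa, collapse = ""),
      probs = A, codonProbs = unclass(M)[, , drop = FALSE],
      nClamped = attr(M, "nClamped"),
      nRenormalized = attr(M, "nRenormalized"))
}

#' Apply selection factors to a neutral codon distribution
#'
#' Convenience wrapper around [codonAADistribution()] with a mandatory
#' [SelectionProfile]; with factors identically 1 the result equals the
#' neutral distribution.
#'
#' @inheritParams codonAADistribution
#' @param selection a [SelectionProfile].
#' @export
applySelection <- function(rates, selection, tau) {
  codonAADistribution(rates, tau, selection = selection)
}

#' @rdname CodonSiteDistribution-class
#' @export
setMethod("aaProbs", "CodonSiteDistribution", function(x) x@probs)

#' @rdname CodonSiteDistribution-class
#' @export
setMethod("codonProbs", "CodonSiteDistribution", function(x) x@codonProbs)

#' @rdname CodonSiteDistribution-class
#' @export
setMethod("parentAA", "CodonSiteDistribution", function(x) x@parentAA)

setMethod("show", "CodonSiteDistribution", function(object) {
  cat("CodonSiteDistribution over", nrow(object@probs), "codon site(s)\n")
  if (object@nClamped || object@nRenormalized)
    cat("  selection events:", object@nClamped, "clamped,",
        object@nRenormalized, "renormalized\n")
})

# codon-aligned validity mask: TRUE for codons where both parent and child
# are n-free
.validCodons <- function(parent, child) {
  pOK <- is.na(.CODON2AA[.codonStrings(parent)]) == FALSE
  cOK <- is.na(.CODON2AA[.codonStrings(child)]) == FALSE
  pOK & cOK
}

#' Nucleotide-level log-likelihood of a child sequence
#'
#' The NT-framework likelihood: a product over nucleotide sites of the
#' stay probability where the child matches the parent and of
#' \eqn{P_{i,x}(\tau)} where the child carries base \eqn{x \neq} parent.
#' Sites belonging to codons that contain \code{n} in either sequence are
#' skipped.
#'
#' @param rates an [NTSiteRates] for the parent.
#' @param childNT child nucleotide string.
#' @param tau positive branch length.
#' @param warnZero warn when an observed base has zero model probability
#'   (its term is floored rather than \code{-Inf}).
#' @return log-likelihood (numeric scalar).
#' @export
ntLogLikelihood <- function(rates, childNT, tau, warnZero = TRUE) {
  sp <- siteMutationProbs(rates, tau)
  childNT <- tolower(childNT)
  cIdx <- .ntToInt(childNT)
  pIdx <- .ntToInt(rates@parentNT)
  codOK <- rep(.validCodons(rates@parentNT, childNT), each = 3L)
  terms <- ifelse(cIdx == pIdx, sp$stay,
                  sp$P[cbind(seq_along(cIdx), ifelse(is.na(cIdx), 1L, cIdx))])
  terms <- terms[codOK]
  if (any(terms <= 0)) {
    if (warnZero)
      warning(sum(terms <= 0), " observed base(s) with zero probability; ",
              "floored", call. = FALSE)
    terms <- pmax(terms, exp(.LOG_FLOOR))
  }
  sum(log(terms))
}

#' Codon-level log-likelihood under a mutation-selection model
#'
#' The NT-AA framework likelihood: a product over codon sites of the
#' probability of the observed child codon under the selection-modified
#' codon outcome distribution. Codons containing \code{n} are skipped.
#'
#' @param rates an [NTSiteRates] for the parent.
#' @param selection a [SelectionProfile] (factors identically 1 recovers
#'   the neutral codon-level likelihood).
#' @param childNT child nucleotide string.
#' @param tau positive branch length.
#' @param warnZero warn when an observed codon has zero model probability.
#' @return log-likelihood (numeric scalar).
#' @export
ntaaLogLikelihood <- function(rates, selection, childNT, tau,
                              warnZero = TRUE) {
  M <- .codonOutcomeProbs(rates, tau, selection)
  childNT <- tolower(childNT)
  childIdx <- match(.codonStrings(childNT), .CODONS)
  ok <- .validCodons(rates@parentNT, childNT)
  p <- unclass(M)[cbind(which(ok), childIdx[ok])]
  if (any(p <= 0)) {
    if (warnZero)
      warning(sum(p <= 0), " observed codon(s) with zero probability; ",
              "floored", call. = FALSE)
    p <- pmax(p, exp(.LOG_FLOOR))
  }
  sum(log(p))
}

#' Branch-scaled amino-acid distribution for amino-acid-level models
#'
#' Scales per-site amino-acid probabilities (e.g. softmaxed language-model
#' logits) by the mutability \eqn{1 - e^{-\tau}} of an exponential
#' waiting-time process:
#' \eqn{P_{r,X}(\tau) = e^{-\tau} + (1 - e^{-\tau}) P_{r,X}} for the
#' wildtype amino acid and \eqn{(1 - e^{-\tau}) P_{r,X}} otherwise.
#' Scaling changes calibration but preserves the relative ordering of
#' non-wildtype amino acids at every site.
#'
#' @param probs sites x 20 matrix of per-site amino-acid probabilities
#'   (rows sum to 1), e.g. from [logitsToProbabilities()].
#' @param parentAA parent amino-acid string (\code{X} marks skipped sites).
#' @param tau positive branch length.
#' @return a [CodonSiteDistribution] (amino-acid level; no codon slot).
#' @export
aaScaledDistribution <- function(probs, parentAA, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  aa <- strsplit(parentAA, "")[[1]]
  if (nrow(probs) != length(aa))
    stop("probs must have one row per codon site of the parent")
  out <- (1 - exp(-tau)) * probs
  wt <- match(aa, .AAS)
  ii <- which(!is.na(wt))
  out[cbind(ii, wt[ii])] <- out[cbind(ii, wt[ii])] + exp(-tau)
  out[is.na(wt), ] <- NA_real_
  colnames(out) <- .AAS
  new("CodonSiteDistribution", parentAA = parentAA, probs = out,
      codonProbs = matrix(numeric(), 0L, 64L), nClamped = 0L,
      nRenormalized = 0L)
}

#' Amino-acid-level log-likelihood of a child sequence
#'
#' The AA-framework likelihood: a product over codon sites of the
#' branch-scaled probability of the observed child amino acid. Sites where
#' either translation is ambiguous (\code{X}) are skipped.
#'
#' @param probs sites x 20 per-site amino-acid probabilities.
#' @param parentAA,childAA parent and child amino-acid strings.
#' @param tau positive branch length.
#' @param warnZero warn when an observed residue has zero probability.
#' @return log-likelihood (numeric scalar).
#' @export
aaLogLikelihood <- function(probs, parentAA, childAA, tau, warnZero = TRUE) {
  d <- aaScaledDistribution(probs, parentAA, tau)
  ca <- strsplit(childAA, "")[[1]]
  idx <- match(ca, .AAS)
  ok <- which(!is.na(idx) & !is.na(d@probs[, 1]))
  p <- d@probs[cbind(ok, idx[ok])]
  if (any(p <= 0)) {
    if (warnZero)
      warning(sum(p <= 0), " observed residue(s) with zero probability; ",
              "floored", call. = FALSE)
    p <- pmax(p, exp(.LOG_FLOOR))
  }
  sum(log(p))
}

#' Maximum-likelihood branch length by bounded scalar search
#'
#' Maximizes a log-likelihood over \eqn{\log \tau} on the interval
#' \code{[lower, upper]} by golden-section/parabolic search
#' (\code{stats::optimize}), deterministically. The initialization
#' \code{init} -- by convention the normalized nucleotide mutation
#' frequency of the pair -- is evaluated as a fallback: if the search
#' returns a poorer point (possible only for pathological likelihoods),
#' the initialization is kept, so the fitted log-likelihood is never below
#' the log-likelihood at \code{init}.
#'
#' @param loglik function of a single positive argument \code{tau}.
#' @param init nonnegative starting value.
#' @param lower,upper search bounds for \code{tau}.
#' @param tol convergence tolerance on \code{log(tau)}.
#' @return a [BranchFit].
#' @export
optimizeBranchLength <- function(loglik, init, lower = 1e-9, upper = 10,
                                 tol = 1e-8) {
  nEvals <- 0L
  f <- function(lt) {
    nEvals <<- nEvals + 1L
    v <- loglik(exp(lt))
    if (!is.finite(v)) -1e300 else v
  }
  opt <- stats::optimize(f, c(log(lower), log(upper)), maximum = TRUE,
                         tol = tol)
  tau <- exp(opt$maximum)
  ll <- opt$objective
  if (!is.finite(ll)) stop("log-likelihood is not finite anywhere in range")
  init <- min(max(init, lower), upper)
  llInit <- loglik(init)
  nEvals <- nEvals + 1L
  if (is.finite(llInit) && llInit > ll) {
    tau <- init
    ll <- llInit
  }
  new("BranchFit", tauHat = tau, logLik = ll, nEvals = nEvals,
      initTau = init)
}

#' @rdname BranchFit-class
#' @export
setMethod("tauHat", "BranchFit", function(x) x@tauHat)

setMethod("show", "BranchFit", function(object) {
  cat(sprintf("BranchFit: tau_hat = %.6g (init %.4g), logLik = %.4f, %d evals\n",
              object@tauHat, object@initTau, object@logLik, object@nEvals))
})

#' Normalized nucleotide mutation frequency of a pair
#'
#' Mismatching sites divided by sequence length (positions involving
#' \code{n} are not counted as mismatches); the standard branch-length
#' initialization.
#'
#' @param parent,child equal-length nucleotide strings.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
mutationFrequency <- function(parent, child) {
  sum(.ntMismatches(tolower(parent), tolower(child))) / nchar(parent)
}

#' Fit a branch length for one pair under a given framework
#'
#' Dispatches to the framework's likelihood ([ntLogLikelihood()],
#' [ntaaLogLikelihood()] or [aaLogLikelihood()]) and maximizes it with
#' [optimizeBranchLength()], initialized at the pair's normalized
#' nucleotide mutation frequency.
#'
#' @param parent,child nucleotide strings of the pair.
#' @param rates an [NTSiteRates] (NT and NT-AA frameworks).
#' @param selection a [SelectionProfile] (NT-AA framework) or \code{NULL}.
#' @param aaSiteProbs sites x 20 amino-acid probabilities (AA framework)
#'   or \code{NULL}.
#' @param framework one of \code{"NT"}, \code{"NT-AA"}, \code{"AA"}.
#' @return a [BranchFit].
#' @export
fitBranchLength <- function(parent, child, rates = NULL, selection = NULL,
                            aaSiteProbs = NULL,
                            framework = c("NT", "NT-AA", "AA")) {
  framework <- match.arg(framework)
  init <- mutationFrequency(parent, child)
  ll <- switch(framework,
    "NT" = function(tau) ntLogLikelihood(rates, child, tau, warnZero = FALSE),
    "NT-AA" = function(tau) ntaaLogLikelihood(rates, selection, child, tau,
                                              warnZero = FALSE),
    "AA" = {
      pa <- translateNT(parent)
      ca <- translateNT(child)
      function(tau) aaLogLikelihood(aaSiteProbs, pa, ca, tau,
                                    warnZero = FALSE)
    })
  optimizeBranchLength(ll, init)
}
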