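#' Parent-child pairs of B-cell receptor sequences
#'
#' A \code{PCPSet} holds aligned parent and child nucleotide sequences, one
#' pair per branch of a B-cell lineage, together with identifiers and an
#' optional per-pair position map assigning an IMGT position label to each
#' codon site.
#'
#' @slot pcpId character vector of pair identifiers.
#' @slot familyId character vector of clonal-family identifiers.
#' @slot parentNT,childNT lowercase nucleotide strings over \code{acgtn};
#'   within a pair the two strings have equal length, a multiple of 3.
#' @slot positionMap list, one character vector of IMGT labels per pair
#'   (one label per codon site), or an empty list when no map is available.
#'
#' @seealso [PCPSet()], [readPCPs()], [filterPCPs()]
#' @export
setClass("PCPSet",
  representation(
    pcpId = "character",
    familyId = "character",
    parentNT = "character",
    childNT = "character",
    positionMap = "list"
  )
)

setValidity("PCPSet", function(object) {
  n <- length(object@pcpId)
  if (length(object@familyId) != n || length(object@parentNT) != n ||
      length(object@childNT) != n)
    return("pcpId, familyId, parentNT and childNT must have equal length")
  if (any(nchar(object@parentNT) != nchar(object@childNT)))
    return("parent and child sequences must have equal length")
  if (any(nchar(object@parentNT) %% 3L != 0L))
    return("sequence lengths must be multiples of 3")
  if (any(grepl("[^acgtn]", c(object@parentNT, object@childNT))))
    return("sequences must be lowercase over {a,c,g,t,n}")
  if (length(object@positionMap) != 0L) {
    if (length(object@positionMap) != n)
      return("positionMap must be empty or have one entry per pair")
    nc <- nchar(object@parentNT) %/% 3L
    for (i in seq_len(n)) {
      pm <- object@positionMap[[i]]
      if (length(pm) != 0L && length(pm) != nc[i])
        return(sprintf("positionMap[[%d]] must have one label per codon", i))
    }
  }
  TRUE
})

#' Filtering tally for a set of parent-child pairs
#'
#' @slot nInput number of pairs examined.
#' @slot nRetained number of pairs kept.
#' @slot dropped named integer vector tallying pairs removed by each rule.
#' @export
setClass("FilterReport",
  representation(nInput = "integer", nRetained = "integer",
                 dropped = "integer")
)

setValidity("FilterReport", function(object) {
  if (object@nRetained + sum(object@dropped) != object@nInput)
    return("retained + dropped must equal input count")
  TRUE
})

#' Antibody region definitions over IMGT positions
#'
#' Maps each framework (FWR) and complementarity-determining (CDR) region of
#' an antibody variable domain to an inclusive range of IMGT positions. The
#' default scheme ([imgtRegionScheme()]) uses the standard IMGT definitions:
#' FWR1 1-26, CDR1 27-38, FWR2 39-55, CDR2 56-65, FWR3 66-104, CDR3 105-117,
#' FWR4 118-128.
#'
#' @slot regionBounds named list of length-2 integer vectors
#'   \code{c(start, end)} with disjoint, ordered ranges.
#' @export
setClass("RegionScheme", representation(regionBounds = "list"))

setValidity("RegionScheme", function(object) {
  b <- object@regionBounds
  if (is.null(names(b)) || any(!nzchar(names(b))))
    return("regionBounds must be a named list")
  m <- t(vapply(b, as.integer, integer(2)))
  if (any(m[, 1] > m[, 2])) return("each range must have start <= end")
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
    return("ranges must be disjoint and ordered")
  TRUE
})

#' Per-nucleotide-site mutation rates and conditional probabilities
#'
#' The common currency of nucleotide-context SHM models: for each site
#' \eqn{i} of a parent sequence, a nonnegative rate \eqn{\lambda_i} of the
#' exponential waiting time until mutation, and a conditional probability
#' vector \eqn{(p_{i,a}, p_{i,c}, p_{i,g}, p_{i,t})} over the target base
#' given that a mutation occurs. For context models the parent (wildtype)
#' entry is zero; for models parametrized at naive-sequence coordinates the
#' zero sits at the naive base instead, and downstream calculations fold any
#' mass on the current parent base into the no-change probability.
#'
#' Sites whose parent base is \code{n} carry \code{NA} rates; codons
#' containing such sites are excluded from likelihoods and metrics.
#'
#' @slot parentNT the parent nucleotide string the rates refer to.
#' @slot lambda numeric vector of per-site rates.
#' @slot condProbs numeric matrix, sites x 4, columns \code{a,c,g,t}.
#' @export
setClass("NTSiteRates",
  representation(parentNT = "character", lambda = "numeric",
                 condProbs = "matrix")
)

setValidity("NTSiteRates", function(object) {
  L <- nchar(object@parentNT)
  if (length(object@lambda) != L)
    return("lambda must have one entry per nucleotide site")
  if (!identical(dim(object@condProbs), c(L, 4L)))
    return("condProbs must be sites x 4")
  ok <- !is.na(object@lambda)
  if (any(object@lambda[ok] < 0)) return("rates must be nonnegative")
  rs <- rowSums(object@condProbs[ok, , drop = FALSE])
  if (any(abs(rs - 1) > 1e-6))
    return("conditional probability rows must sum to 1")
  if (any(object@condProbs[ok, ] < -1e-12))
    return("conditional probabilities must be nonnegative")
  TRUE
})

#' k-mer context mutability model
#'
#' An SHM model in the style of 5-mer mutability tables: the rate and
#' conditional substitution probabilities of a site are looked up from the
#' k-mer centred on it. Contexts that run past the sequence ends are padded
#' with \code{n}; any k-mer absent from the table (e.g. containing \code{n})
#' falls back to the model's default entry, whose conditional probabilities
#' are re-zeroed at the wildtype base and renormalized at lookup time.
#'
#' @slot k odd integer context width.
#' @slot rates named numeric vector, one rate per k-mer.
#' @slot condProbs numeric matrix with k-mer rownames and columns
#'   \code{a,c,g,t}; each row sums to 1 with 0 at the central base.
#' @slot defaultRate,defaultCondProbs fallback entry for unlisted contexts.
#' @export
setClass("KmerModel",
  representation(k = "integer", rates = "numeric", condProbs = "matrix",
                 defaultRate = "numeric", defaultCondProbs = "numeric")
)

setValidity("KmerModel", function(object) {
  if (object@k %% 2L != 1L) return("k must be odd")
  if (is.null(names(object@rates))) return("rates must be named by k-mer")
  if (!identical(rownames(object@condProbs), names(object@rates)))
    return("condProbs rownames must match names(rates)")
  if (any(object@rates < 0) || object@defaultRate < 0)
    return("rates must be nonnegative")
  if (any(abs(rowSums(object@condProbs) - 1) > 1e-6))
    return("condProbs rows must sum to 1")
  central <- substr(names(object@rates), (object@k + 1L) %/% 2L,
                    (object@k + 1L) %/% 2L)
  wt <- object@condProbs[cbind(seq_along(central), match(central, .BASES))]
  if (any(wt != 0)) return("central (wildtype) base probability must be 0")
  if (abs(sum(object@defaultCondProbs) - 1) > 1e-6)
    return("defaultCondProbs must sum to 1")
  TRUE
})

#' Per-site rate model at naive-sequence coordinates
#'
#' SHM model measured with respect to a fixed naive (reference) sequence,
#' as produced by passenger-allele experiments: one mutation probability per
#' site of the reference, parametrized by softmax so the rates over all
#' sites sum to 1, plus per-site conditional target-base probabilities with
#' zero at the naive base. Rates are applied verbatim to any parent of the
#' same length, regardless of accumulated mutations.
#'
#' @slot referenceNT the naive nucleotide sequence.
#' @slot rates numeric vector summing to 1.
#' @slot condProbs sites x 4 matrix, columns \code{a,c,g,t}.
#' @export
setClass("PerSiteModel",
  representation(referenceNT = "character", rates = "numeric",
                 condProbs = "matrix")
)

setValidity("PerSiteModel", function(object) {
  L <- nchar(object@referenceNT)
  if (length(object@rates) != L || !identical(dim(object@condProbs), c(L, 4L)))
    return("rates and condProbs must cover every reference site")
  if (any(object@rates < 0)) return("rates must be nonnegative")
  if (abs(sum(object@rates) - 1) > 1e-6)
    return("rates must sum to 1 (softmax parametrization)")
  if (any(abs(rowSums(object@condProbs) - 1) > 1e-6))
    return("condProbs rows must sum to 1")
  ref <- match(strsplit(object@referenceNT, "")[[1]], .BASES)
  wt <- object@condProbs[cbind(seq_len(L), ref)]
  if (any(wt[!is.na(ref)] != 0))
    return("conditional probability at the reference base must be 0")
  TRUE
})

#' Deep mutational scanning measurements
#'
#' Binding strengths \eqn{-\log_{10} K_D} for every single amino-acid
#' mutant of a fixed naive sequence, used to derive selection ratios
#' \eqn{R = K_D^{parent} / K_D^{child}}.
#'
#' @slot binding numeric matrix, codon sites x 20 amino acids (alphabetical
#'   columns); \code{NA} marks unmeasured mutants.
#' @export
setClass("DMSModel", representation(binding = "matrix"))

setValidity("DMSModel", function(object) {
  if (!identical(colnames(object@binding), .AAS))
    return("binding columns must be the 20 standard amino acids")
  TRUE
})

#' Per-site amino-acid logits
#'
#' Raw score vectors over the 20 standard amino acids for each codon site
#' of a parent protein, as produced by a masked language model under either
#' the masked-marginals strategy (each site masked and predicted in turn)
#' or the wt-marginals strategy (one unmasked forward pass). The strategy
#' is metadata only; downstream processing is identical.
#'
#' @slot logits numeric matrix, sites x 20, finite entries.
#' @slot strategy \code{"masked-marginals"} or \code{"wt-marginals"}.
#' @export
setClass("AASiteLogits",
  representation(logits = "matrix", strategy = "character")
)

setValidity("AASiteLogits", function(object) {
  if (!identical(colnames(object@logits), .AAS))
    return("logits columns must be the 20 standard amino acids")
  if (any(!is.finite(object@logits))) return("logits must be finite")
  if (!object@strategy %in% c("masked-marginals", "wt-marginals"))
    return("strategy must be 'masked-marginals' or 'wt-marginals'")
  TRUE
})

#' Per-site selection ratios and factors
#'
#' For each codon site and candidate amino acid, the preference ratio
#' \eqn{R} of the candidate over the parent amino acid and the bounded
#' selection factor \eqn{F = 2 / (1 + 1/R)}, which maps \eqn{R = 1} to 1
#' and approaches 0 and 2 in the limits. \eqn{F} multiplies non-wildtype
#' codon outcome probabilities in the NT-AA framework.
#'
#' @slot parentAA parent amino-acid sequence.
#' @slot ratios,factors numeric matrices, sites x 20 amino acids.
#' @export
setClass("SelectionProfile",
  representation(parentAA = "character", ratios = "matrix",
                 factors = "matrix")
)

setValidity("SelectionProfile", function(object) {
  L <- nchar(object@parentAA)
  if (!identical(dim(object@ratios), c(L, 20L)) ||
      !identical(dim(object@factors), c(L, 20L)))
    return("ratios and factors must be sites x 20")
  if (any(object@ratios <= 0, na.rm = TRUE))
    return("ratios must be positive")
  if (any(object@factors <= 0 | object@factors >= 2, na.rm = TRUE))
    return("factors must lie in the open interval (0, 2)")
  TRUE
})

#' Branch-length fit for one parent-child pair
#'
#' @slot tauHat optimized branch length.
#' @slot logLik log-likelihood at \code{tauHat}.
#' @slot nEvals number of likelihood evaluations used by the optimizer.
#' @slot initTau the initialization (normalized nucleotide mutation
#'   frequency of the pair).
#' @export
setClass("BranchFit",
  representation(tauHat = "numeric", logLik = "numeric",
                 nEvals = "integer", initTau = "numeric")
)

#' Per-codon-site amino-acid substitution distribution
#'
#' For each codon site of a parent sequence, a probability vector over the
#' 20 amino acids (wildtype included) at the fitted branch length,
#' conditioned on a non-stop outcome. NT and NT-AA framework objects also
#' carry the underlying 64-codon outcome distribution used for likelihoods
#' and simulation.
#'
#' @slot parentAA parent amino-acid sequence ("X" at skipped codons).
#' @slot probs sites x 20 amino-acid probability matrix; rows sum to 1
#'   (\code{NA} rows at codons containing \code{n}).
#' @slot codonProbs sites x 64 codon outcome matrix, or a 0 x 64 matrix for
#'   amino-acid-level models.
#' @slot nClamped,nRenormalized counts of selection-induced clamping and
#'   renormalization events.
#' @export
setClass("CodonSiteDistribution",
  representation(parentAA = "character", probs = "matrix",
                 codonProbs = "matrix", nClamped = "integer",
                 nRenormalized = "integer")
)

setValidity("CodonSiteDistribution", function(object) {
  p <- object@probs
  if (ncol(p) != 20L) return("probs must have 20 amino-acid columns")
  ok <- !is.na(p[, 1])
  if (any(p[ok, ] < -1e-9 | p[ok, ] > 1 + 1e-9))
    return("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p[ok, , drop = FALSE]) - 1) > 1e-6))
    return("probability rows must sum to 1")
  TRUE
})

#' Model evaluation report
#'
#' Holds the four performance metrics (overlap, mean R-precision,
#' substitution accuracy, CSP perplexity), overall and stratified by
#' region and by substitutions per pair, together with the observed and
#' expected substitution-count distributions, the substitution events with
#' their conditional substitution probabilities, and per-pair branch fits.
#'
#' @slot modelName label of the evaluated model.
#' @slot seed integer seed governing random tie-breaking.
#' @slot overall named list with the four metrics.
#' @slot byRegion named list of per-region metric lists.
#' @slot byK named list of per-stratum metric lists (substitutions per PCP).
#' @slot bySSPBin data.frame of observed and expected substitution counts
#'   per SSP bin.
#' @slot counts data.frame with one row per IMGT position: observed and
#'   expected substitution counts.
#' @slot events data.frame of substitution events.
#' @slot fits data.frame of per-pair branch-length fits.
#' @slot nPCPs number of pairs evaluated.
#' @export
setClass("MetricsReport",
  representation(modelName = "character", seed = "integer",
                 overall = "list", byRegion = "list", byK = "list",
                 bySSPBin = "data.frame", counts = "data.frame",
                 events = "data.frame", fits = "data.frame",
                 nPCPs = "integer")
)
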