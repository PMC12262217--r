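#' Per-site rates of a nucleotide model applied to a parent sequence
#'
#' Instantiates an SHM model on a concrete parent sequence, returning the
#' per-site rates and conditional mutation probabilities used by the NT and
#' NT-AA engines.
#'
#' @param model a [KmerModel] or [PerSiteModel].
#' @param parentNT lowercase parent nucleotide string.
#' @param ... passed to methods.
#' @return an [NTSiteRates] object.
#' @export
setGeneric("siteRates", function(model, parentNT, ...)
  standardGeneric("siteRates"))

#' Selection profile of a selection model for a parent protein
#'
#' Computes per-site, per-amino-acid preference ratios R and the bounded
#' selection factors F = 2/(1 + 1/R) used in the NT-AA framework.
#'
#' @param model a selection model: a 20x20 log-odds substitution matrix
#'   (e.g. [blosum62Matrix()]) or a [DMSModel].
#' @param parentAA parent amino-acid string.
#' @param ... passed to methods.
#' @return a [SelectionProfile].
#' @export
setGeneric("selectionProfile", function(model, parentAA, ...)
  standardGeneric("selectionProfile"))

#' @rdname PCPSet-class
#' @param x a \code{PCPSet}.
#' @export
setGeneric("pcpId", function(x) standardGeneric("pcpId"))

#' @rdname PCPSet-class
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

#' @rdname PCPSet-class
#' @export
setGeneric("parentNT", function(x) standardGeneric("parentNT"))

#' @rdname PCPSet-class
#' @export
setGeneric("childNT", function(x) standardGeneric("childNT"))

#' @rdname PCPSet-class
#' @export
setGeneric("positionMap", function(x) standardGeneric("positionMap"))

#' @rdname CodonSiteDistribution-class
#' @param x a \code{CodonSiteDistribution}.
#' @export
setGeneric("aaProbs", function(x) standardGeneric("aaProbs"))

#' @rdname CodonSiteDistribution-class
#' @export
setGeneric("codonProbs", function(x) standardGeneric("codonProbs"))

#' @rdname CodonSiteDistribution-class
#' @export
setGeneric("parentAA", function(x) standardGeneric("parentAA"))

#' @rdname BranchFit-class
#' @param x a \code{BranchFit}.
#' @export
setGeneric("tauHat", function(x) standardGeneric("tauHat"))

#' @rdname SelectionProfile-class
#' @param x a \code{SelectionProfile}.
#' @export
setGeneric("selectionFactors", function(x) standardGeneric("selectionFactors"))

#' @rdname SelectionProfile-class
#' @export
setGeneric("selectionRatios", function(x) standardGeneric("selectionRatios"))

#' @rdname MetricsReport-class
#' @param x a \code{MetricsReport}.
#' @export
setGeneric("overallMetrics", function(x) standardGeneric("overallMetrics"))
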