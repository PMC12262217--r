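# Dataset-level evaluation: branch fits, per-site distributions, and the
# four performance metrics with regional and per-stratum breakdowns.

.metricSet <- function(siteTab, rprecs, cspMat, childAA) {
  out <- list(overlap = NA_real_, r_precision = NA_real_,
              substitution_accuracy = NA_real_, csp_perplexity = NA_real_,
              n_pcps = length(rprecs), n_events = nrow(cspMat))
  if (nrow(siteTab)) {
    o <- tapply(siteTab$observed, siteTab$imgt_position, sum)
    e <- tapply(siteTab$ssp, siteTab$imgt_position, sum, na.rm = TRUE)
    if (sum(o) + sum(e) > 0)
      out$overlap <- overlapMetric(as.numeric(o), as.numeric(e))
  }
  if (length(rprecs)) out$r_precision <- mean(rprecs)
  if (nrow(cspMat)) {
    live <- !is.na(cspMat[, 1])
    if (any(live)) {
      out$substitution_accuracy <-
        substitutionAccuracy(cspMat[live, , drop = FALSE], childAA[live])
      pObs <- cspMat[cbind(which(live), match(childAA[live], .AAS))]
      out$csp_perplexity <- cspPerplexity(pObs)
    }
  }
  out
}

#' Evaluate a model on a set of parent-child pairs
#'
#' Runs the full evaluation for one model under one framework: per pair,
#' the branch length is fitted by maximum likelihood and the per-site
#' amino-acid distribution computed at the fitted length; site and
#' conditional substitution probabilities are derived, substitution events
#' collected, and the four performance metrics computed overall, per
#' FWR/CDR region, per substitutions-per-pair stratum, and per SSP bin.
#'
#' All random tie-breaking (R-precision rank ties, CSP argmax ties) flows
#' from the single \code{seed}.
#'
#' @param pcps a filtered [PCPSet] (see [filterPCPs()]).
#' @param model a [KmerModel] or [PerSiteModel] (NT and NT-AA frameworks).
#' @param framework \code{"NT"}, \code{"NT-AA"} or \code{"AA"}.
#' @param selection selection model for the NT-AA framework: a 20x20
#'   log-odds matrix or a [DMSModel].
#' @param logitsList named list of [AASiteLogits] keyed by pair id
#'   (AA framework).
#' @param scheme a [RegionScheme] for regional metrics.
#' @param seed integer seed for tie-breaking.
#' @param sspBins bin edges for the SSP calibration table.
#' @param modelName label recorded in the report.
#' @return a [MetricsReport].
#' @export
evaluateModel <- function(pcps, model = NULL,
                          framework = c("NT", "NT-AA", "AA"),
                          selection = NULL, logitsList = NULL,
                          scheme = imgtRegionScheme(), seed = 1L,
                          sspBins = seq(0, 1, 0.1), modelName = NULL) {
  framework <- match.arg(framework)
  if (framework %in% c("NT", "NT-AA") && is.null(model))
    stop("the ", framework, " framework requires a nucleotide model")
  if (framework == "NT-AA" && is.null(selection))
    stop("the NT-AA framework requires a selection model")
  if (framework == "AA" && is.null(logitsList))
    stop("the AA framework requires per-pair logits")
  if (is.null(modelName)) modelName <- framework
  n <- length(pcps)
  pm <- positionMap(pcps)

  siteRows <- vector("list", n)
  eventRows <- vector("list", n)
  cspRows <- vector("list", n)
  fits <- vector("list", n)
  perPCP <- vector("list", n)
  nClamped <- 0L
  nRenorm <- 0L

  for (i in seq_len(n)) {
    parent <- parentNT(pcps)[i]
    child <- childNT(pcps)[i]
    tp <- strsplit(translateNT(parent), "")[[1]]
    tc <- strsplit(translateNT(child), "")[[1]]
    C <- length(tp)
    ok <- tp %in% .AAS & tc %in% .AAS
    if (framework %in% c("NT", "NT-AA")) {
      rates <- siteRates(model, parent)
      prof <- if (framework == "NT-AA")
        selectionProfile(selection, paste(tp, collapse = "")) else NULL
      fit <- fitBranchLength(parent, child, rates = rates, selection = prof,
                             framework = framework)
      dist <- codonAADistribution(rates, tauHat(fit), selection = prof)
      nClamped <- nClamped + dist@nClamped
      nRenorm <- nRenorm + dist@nRenormalized
    } else {
      lg <- logitsList[[pcpId(pcps)[i]]]
      if (is.null(lg)) stop("no logits for pair ", pcpId(pcps)[i])
      probs <- logitsToProbabilities(lg)
      fit <- fitBranchLength(parent, child, aaSiteProbs = probs,
                             framework = "AA")
      dist <- aaScaledDistribution(probs, paste(tp, collapse = ""),
                                   tauHat(fit))
    }
    ssp <- siteSubstitutionProbability(dist)
    csp <- suppressWarnings(conditionalSubstitutionProbability(dist))
    positions <- if (length(pm) && length(pm[[i]])) pm[[i]]
                 else as.character(seq_len(C))
    regions <- annotateRegions(positions, scheme)
    observed <- which(ok & tp != tc)
    ssp[!ok] <- NA_real_
    siteRows[[i]] <- data.frame(
      pcp = i, site = seq_len(C), imgt_position = positions,
      region = regions, ssp = ssp,
      observed = seq_len(C) %in% observed, stringsAsFactors = FALSE)
    if (length(observed)) {
      pObs <- csp[cbind(observed, match(tc[observed], .AAS))]
      eventRows[[i]] <- data.frame(
        pcp_id = pcpId(pcps)[i], pcp = i, site = observed,
        imgt_position = positions[observed], region = regions[observed],
        parent_aa = tp[observed], child_aa = tc[observed],
        csp_of_outcome = pObs, stringsAsFactors = FALSE)
      cspRows[[i]] <- csp[observed, , drop = FALSE]
    }
    fits[[i]] <- data.frame(
      pcp_id = pcpId(pcps)[i], framework = framework,
      tau_init = fit@initTau, tau_hat = tauHat(fit),
      log_likelihood = fit@logLik, n_evals = fit@nEvals,
      stringsAsFactors = FALSE)
    perPCP[[i]] <- list(ssp = ssp, regions = regions, observed = observed)
  }

  sites <- do.call(rbind, siteRows)
  events <- do.call(rbind, eventRows)
  cspMat <- do.call(rbind, cspRows)
  if (is.null(events)) {
    events <- data.frame()
    cspMat <- matrix(numeric(), 0L, 20L)
  }
  fits <- do.call(rbind, fits)

  # all tie-breaking below draws from one seeded stream, in fixed order
  set.seed(seed)
  rprecOne <- function(ssp, observed, keepSites = NULL) {
    scored <- which(!is.na(ssp))
    if (!is.null(keepSites)) scored <- intersect(scored, keepSites)
    obs <- intersect(observed, scored)
    if (!length(obs) || !length(scored)) return(NA_real_)
    if (length(obs) > length(scored)) return(NA_real_)
    rPrecision(ssp[scored], match(obs, scored))
  }
  rprecs <- vapply(perPCP, function(p) rprecOne(p$ssp, p$observed), 0)
  rprecs <- rprecs[!is.na(rprecs)]
  overall <- .metricSet(sites, rprecs, cspMat, events$child_aa)
  overall$n_clamped <- nClamped
  overall$n_renormalized <- nRenorm

  byRegion <- list()
  for (rn in names(scheme@regionBounds)) {
    sr <- sites[sites$region == rn, , drop = FALSE]
    er <- which(events$region == rn)
    rp <- vapply(perPCP, function(p)
      rprecOne(p$ssp, p$observed, which(p$regions == rn)), 0)
    byRegion[[rn]] <- .metricSet(sr, rp[!is.na(rp)],
                                 cspMat[er, , drop = FALSE],
                                 events$child_aa[er])
  }

  kPer <- vapply(perPCP, function(p) length(p$observed), 0L)
  byK <- list()
  for (k in sort(unique(kPer[kPer > 0]))) {
    ii <- which(kPer == k)
    sk <- sites[sites$pcp %in% ii, , drop = FALSE]
    ek <- which(events$pcp %in% ii)
    rp <- vapply(perPCP[ii], function(p) rprecOne(p$ssp, p$observed), 0)
    byK[[as.character(k)]] <- .metricSet(sk, rp[!is.na(rp)],
                                         cspMat[ek, , drop = FALSE],
                                         events$child_aa[ek])
  }

  o <- tapply(sites$observed, sites$imgt_position, sum)
  e <- tapply(sites$ssp, sites$imgt_position, sum, na.rm = TRUE)
  pos <- unique(sites$imgt_position)
  counts <- data.frame(imgt_position = pos,
                       observed = as.numeric(o[pos]),
                       expected = as.numeric(e[pos]),
                       stringsAsFactors = FALSE)

  bySSPBin <- binnedSSPDistribution(sites$ssp, sites$observed, sspBins)

  if (nrow(events)) {
    rk <- integer(nrow(events))
    for (j in seq_len(nrow(events)))
      rk[j] <- if (is.na(cspMat[j, 1])) NA_integer_
               else sum(cspMat[j, ] > events$csp_of_outcome[j]) + 1L
    events$csp_rank <- rk
    events$pcp <- NULL
  }

  new("MetricsReport", modelName = modelName, seed = as.integer(seed),
      overall = overall, byRegion = byRegion, byK = byK,
      bySSPBin = bySSPBin, counts = counts, events = events, fits = fits,
      nPCPs = as.integer(n))
}

#' @rdname MetricsReport-class
#' @export
setMethod("overallMetrics", "MetricsReport", function(x) x@overall)

setMethod("show", "MetricsReport", function(object) {
  m <- object@overall
  cat("MetricsReport for model '", object@modelName, "' (",
      object@nPCPs, " PCPs, ", m$n_events, " substitution events)\n",
      sep = "")
  cat(sprintf("  overlap:               %.4f\n", m$overlap))
  cat(sprintf("  mean R-precision:      %.4f\n", m$r_precision))
  cat(sprintf("  substitution accuracy: %.4f\n", m$substitution_accuracy))
  cat(sprintf("  CSP perplexity:        %.4f\n", m$csp_perplexity))
  if (m$n_clamped || m$n_renormalized)
    cat("  selection events:", m$n_clamped, "clamped,",
        m$n_renormalized, "renormalized\n")
})

#' Serialize a metrics report as JSON
#'
#' Nested object with the overall metrics and the regional, per-stratum
#' and SSP-bin breakdowns, plus the seed and model label for exact rerun.
#'
#' @param report a [MetricsReport].
#' @param path optional output path; if omitted the JSON string is
#'   returned.
#' @export
writeMetricsJSON <- function(report, path = NULL) {
  x <- list(model = report@modelName, seed = report@seed,
            n_pcps = report@nPCPs, overall = report@overall,
            by_region = report@byRegion, by_k = report@byK,
            by_ssp_bin = report@bySSPBin)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Write the observed/expected counts distribution as TSV
#' @param report a [MetricsReport].
#' @param path output path.
#' @export
writeCounts <- function(report, path) {
  utils::write.table(report@counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the substitution events table as TSV
#' @param report a [MetricsReport].
#' @param path output path.
#' @export
writeEvents <- function(report, path) {
  utils::write.table(report@events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the per-pair branch fits as TSV
#' @param report a [MetricsReport].
#' @param path output path.
#' @export
writeBranchFits <- function(report, path) {
  utils::write.table(report@fits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
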