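#' Construct a k-mer context mutability model
#'
#' @param rates named numeric vector of per-k-mer rates; all names must
#'   have the same odd length k.
#' @param condProbs numeric matrix with the same rownames as
#'   \code{names(rates)} and columns \code{a,c,g,t}; rows sum to 1 with 0
#'   at the central base of the k-mer.
#' @param defaultRate,defaultCondProbs fallback used for contexts not in
#'   the table (e.g. n-padded sequence ends); the default conditional
#'   probabilities are re-zeroed at the wildtype base at lookup time.
#' @return a [KmerModel].
#' @export
KmerModel <- function(rates, condProbs,
                      defaultRate = mean(rates),
                      defaultCondProbs = rep(0.25, 4)) {
  k <- unique(nchar(names(rates)))
  if (length(k) != 1L) stop("all k-mers must have the same width")
  colnames(condProbs) <- .BASES
  new("KmerModel", k = as.integer(k), rates = rates, condProbs = condProbs,
      defaultRate = defaultRate, defaultCondProbs = defaultCondProbs)
}

#' Construct a per-site rate model
#'
#' @param referenceNT the naive nucleotide sequence the rates refer to.
#' @param rates per-site mutation probabilities summing to 1 (softmax
#'   parametrization).
#' @param condProbs sites x 4 conditional target-base probabilities,
#'   zero at the reference base.
#' @return a [PerSiteModel].
#' @export
PerSiteModel <- function(referenceNT, rates, condProbs) {
  colnames(condProbs) <- .BASES
  new("PerSiteModel", referenceNT = tolower(referenceNT),
      rates = rates, condProbs = condProbs)
}

#' @describeIn siteRates k-mer lookup centred on each site; contexts
#'   running past the ends are padded with \code{n} and unlisted contexts
#'   use the model default. Sites whose own base is \code{n} get \code{NA}
#'   rates (their codons are skipped downstream).
#' @export
setMethod("siteRates", c("KmerModel", "character"),
  function(model, parentNT, ...) {
    parentNT <- tolower(parentNT)
    L <- nchar(parentNT)
    flank <- (model@k - 1L) %/% 2L
    padded <- paste0(strrep("n", flank), parentNT, strrep("n", flank))
    kmers <- substring(padded, seq_len(L), seq_len(L) + model@k - 1L)
    idx <- match(kmers, names(model@rates))
    lambda <- ifelse(is.na(idx), model@defaultRate, model@rates[idx])
    cp <- matrix(NA_real_, L, 4L, dimnames = list(NULL, .BASES))
    known <- !is.na(idx)
    cp[known, ] <- model@condProbs[idx[known], , drop = FALSE]
    baseIdx <- .ntToInt(parentNT)
    if (any(!known)) {
      # default entry: zero out the wildtype base and renormalize
      for (i in which(!known)) {
        p <- model@defaultCondProbs
        if (!is.na(baseIdx[i])) {
          p[baseIdx[i]] <- 0
          p <- p / sum(p)
        }
        cp[i, ] <- p
      }
    }
    nsite <- is.na(baseIdx)
    lambda[nsite] <- NA_real_
    cp[nsite, ] <- NA_real_
    new("NTSiteRates", parentNT = parentNT, lambda = lambda, condProbs = cp)
  })

#' @describeIn siteRates rates and conditional probabilities are taken
#'   verbatim from the reference table regardless of mutations the parent
#'   has accumulated (naive-context assumption); the parent must have the
#'   reference length.
#' @export
setMethod("siteRates", c("PerSiteModel", "character"),
  function(model, parentNT, ...) {
    parentNT <- tolower(parentNT)
    if (nchar(parentNT) != nchar(model@referenceNT))
      stop("parent length ", nchar(parentNT),
           " does not match reference length ", nchar(model@referenceNT))
    lambda <- model@rates
    cp <- model@condProbs
    nsite <- is.na(.ntToInt(parentNT))
    lambda[nsite] <- NA_real_
    cp[nsite, ] <- NA_real_
    new("NTSiteRates", parentNT = parentNT, lambda = lambda, condProbs = cp)
  })

setMethod("show", "NTSiteRates", function(object) {
  ok <- !is.na(object@lambda)
  cat("NTSiteRates over", nchar(object@parentNT), "site(s);",
      sum(!ok), "n-site(s)\n")
  if (any(ok))
    cat(sprintf("  lambda: min %.4g, median %.4g, max %.4g\n",
                min(object@lambda[ok]), stats::median(object@lambda[ok]),
                max(object@lambda[ok])))
})

#' The BLOSUM62 substitution matrix
#'
#' Returns the 20x20 integer log-odds matrix restricted to the standard
#' amino acids, rows and columns in alphabetical order.
#'
#' @return integer matrix.
#' @export
blosum62Matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[.AAS, .AAS]
  storage.mode(m) <- "integer"
  m
}

#' @describeIn SelectionProfile-class construct a profile from a
#'   sites x 20 matrix of positive preference ratios R (factors
#'   F = 2/(1 + 1/R) are derived).
#' @param ratios sites x 20 matrix of positive preference ratios.
#' @param parentAA parent amino-acid string.
#' @export
SelectionProfile <- function(ratios, parentAA) {
  colnames(ratios) <- .AAS
  new("SelectionProfile", parentAA = parentAA, ratios = ratios,
      factors = 2 / (1 + 1 / ratios))
}

#' @rdname SelectionProfile-class
#' @export
setMethod("selectionFactors", "SelectionProfile", function(x) x@factors)

#' @rdname SelectionProfile-class
#' @export
setMethod("selectionRatios", "SelectionProfile", function(x) x@ratios)

setMethod("show", "SelectionProfile", function(object) {
  cat("SelectionProfile over", nchar(object@parentAA), "codon site(s);",
      sprintf("factor range [%.3g, %.3g]\n",
              min(object@factors, na.rm = TRUE),
              max(object@factors, na.rm = TRUE)))
})

#' The bounded selection factor transform
#'
#' F = 2/(1 + 1/R): maps the preference ratio R onto (0, 2), with
#' F(1) = 1, monotone increasing in R, approaching 2 as R grows and 0 as R
#' vanishes. Bounding keeps selection-modified codon probabilities from
#' exceeding one except in rare extreme cases, which are clamped.
#'
#' @param R positive preference ratio(s).
#' @return selection factor(s) in (0, 2).
#' @export
selectionFactor <- function(R) {
  if (any(R <= 0, na.rm = TRUE)) stop("R must be positive")
  2 / (1 + 1 / R)
}

#' @describeIn selectionProfile log-odds substitution-matrix selection:
#'   R = 2^(M[candidate, parent]/2) (the half accounts for BLOSUM's fixed
#'   log-odds scaling); R of the parent amino acid itself is 1.
#' @export
setMethod("selectionProfile", c("matrix", "character"),
  function(model, parentAA, ...) {
    aa <- strsplit(parentAA, "")[[1]]
    if (any(!aa %in% c(.AAS, "X")))
      stop("nonstandard amino acid in parent: ",
           paste(unique(aa[!aa %in% c(.AAS, "X")]), collapse = ""))
    R <- matrix(1, length(aa), 20L, dimnames = list(NULL, .AAS))
    std <- which(aa %in% .AAS)
    # ambiguous (X) sites keep a neutral row; their codons are skipped
    R[std, ] <- 2^(t(model[, aa[std], drop = FALSE]) / 2)
    R[cbind(std, match(aa[std], .AAS))] <- 1
    SelectionProfile(R, parentAA)
  })

#' Construct a deep-mutational-scanning selection model
#'
#' @param binding sites x 20 matrix of binding strengths (-log10 KD),
#'   alphabetical amino-acid columns; \code{NA} for unmeasured mutants.
#' @return a [DMSModel].
#' @export
DMSModel <- function(binding) {
  colnames(binding) <- .AAS
  new("DMSModel", binding = binding)
}

#' @describeIn selectionProfile dissociation-constant ratios from a deep
#'   mutational scan: R = KD(parent)/KD(child) = 10^(b_child - b_parent)
#'   where b is binding strength -log10 KD. Missing measurements fall back
#'   to \code{missingDefault} with a warning.
#' @param missingDefault ratio substituted for unmeasured mutants.
#' @export
setMethod("selectionProfile", c("DMSModel", "character"),
  function(model, parentAA, missingDefault = 1, ...) {
    aa <- strsplit(parentAA, "")[[1]]
    L <- length(aa)
    if (nrow(model@binding) < L)
      stop("DMS scan covers ", nrow(model@binding),
           " sites but parent has ", L)
    b <- model@binding[seq_len(L), , drop = FALSE]
    std <- which(aa %in% .AAS)
    bParent <- rep(NA_real_, L)
    bParent[std] <- b[cbind(std, match(aa[std], .AAS))]
    R <- 10^(b - bParent)
    R[setdiff(seq_len(L), std), ] <- 1  # ambiguous sites: neutral row
    if (anyNA(R)) {
      warning(sum(is.na(R)), " unmeasured mutant(s); using default ratio ",
              missingDefault)
      R[is.na(R)] <- missingDefault
    }
    R[cbind(std, match(aa[std], .AAS))] <- 1
    SelectionProfile(R, parentAA)
  })

#' Construct per-site amino-acid logits
#'
#' @param logits sites x 20 numeric matrix of scores over the standard
#'   amino acids (alphabetical columns), one row per codon site of the
#'   parent protein.
#' @param strategy how the scores were produced: \code{"masked-marginals"}
#'   (default) or \code{"wt-marginals"}.
#' @return an [AASiteLogits].
#' @export
AASiteLogits <- function(logits, strategy = "masked-marginals") {
  colnames(logits) <- .AAS
  new("AASiteLogits", logits = logits, strategy = strategy)
}

#' Convert logits to per-site amino-acid probabilities
#'
#' Row-wise softmax restricted to the 20 standard amino acids; invariant
#' to adding a constant to a row.
#'
#' @param x an [AASiteLogits] (or a bare sites x 20 matrix).
#' @return sites x 20 matrix with rows summing to 1.
#' @export
logitsToProbabilities <- function(x) {
  m <- if (is(x, "AASiteLogits")) x@logits else x
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# ---- model table file I/O ---------------------------------------------

#' Read a k-mer model table
#'
#' TSV with columns \code{kmer, rate, p_a, p_c, p_g, p_t}; an optional row
#' with \code{kmer == "default"} supplies the fallback entry.
#'
#' @param path file to read.
#' @return a [KmerModel].
#' @export
readKmerModel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  isDefault <- df$kmer == "default"
  p <- as.matrix(df[!isDefault, c("p_a", "p_c", "p_g", "p_t")])
  rownames(p) <- df$kmer[!isDefault]
  rates <- structure(df$rate[!isDefault], names = df$kmer[!isDefault])
  if (any(isDefault)) {
    d <- df[isDefault, ][1, ]
    KmerModel(rates, p, defaultRate = d$rate,
              defaultCondProbs = as.numeric(d[c("p_a", "p_c", "p_g", "p_t")]))
  } else KmerModel(rates, p)
}

#' Write a k-mer model table
#' @param model a [KmerModel].
#' @param path output path.
#' @export
writeKmerModel <- function(model, path) {
  df <- data.frame(kmer = c(names(model@rates), "default"),
                   rate = c(unname(model@rates), model@defaultRate))
  df <- cbind(df, rbind(model@condProbs, model@defaultCondProbs))
  names(df)[3:6] <- c("p_a", "p_c", "p_g", "p_t")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-site rate model table
#'
#' TSV with columns \code{site, rate, p_a, p_c, p_g, p_t}; rows ordered by
#' site. The reference sequence may be given in a comment line
#' \code{"# reference: <seq>"} or via the \code{referenceNT} argument; if
#' absent, each reference base is inferred as the base with zero
#' conditional probability.
#'
#' @param path file to read.
#' @param referenceNT optional naive sequence.
#' @return a [PerSiteModel].
#' @export
readPerSiteModel <- function(path, referenceNT = NULL) {
  header <- readLines(path, n = 5L)
  refLine <- grep("^#\\s*reference:", header, value = TRUE)
  if (is.null(referenceNT) && length(refLine))
    referenceNT <- trimws(sub("^#\\s*reference:", "", refLine[1]))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- df[order(df$site), ]
  p <- as.matrix(df[, c("p_a", "p_c", "p_g", "p_t")])
  if (is.null(referenceNT))
    referenceNT <- paste(.BASES[apply(p, 1, which.min)], collapse = "")
  PerSiteModel(referenceNT, df$rate, p)
}

#' Read deep-mutational-scanning measurements
#'
#' TSV with columns \code{site, aa, neg_log10_kd}.
#'
#' @param path file to read.
#' @return a [DMSModel].
#' @export
readDMS <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  L <- max(df$site)
  b <- matrix(NA_real_, L, 20L, dimnames = list(NULL, .AAS))
  b[cbind(df$site, match(df$aa, .AAS))] <- df$neg_log10_kd
  DMSModel(b)
}

#' Read per-site amino-acid logits
#'
#' TSV with columns \code{pcp_id, site} followed by the 20 amino-acid
#' columns; the scoring strategy is recorded in a leading comment line
#' \code{"# strategy: <masked-marginals|wt-marginals>"}.
#'
#' @param path file to read.
#' @return named list of [AASiteLogits], one per \code{pcp_id}.
#' @export
readAALogits <- function(path) {
  header <- readLines(path, n = 2L)
  strat <- "masked-marginals"
  sLine <- grep("^#\\s*strategy:", header, value = TRUE)
  if (length(sLine)) strat <- trimws(sub("^#\\s*strategy:", "", sLine[1]))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(split(df, df$pcp_id), function(d) {
    d <- d[order(d$site), ]
    m <- as.matrix(d[, .AAS])
    rownames(m) <- NULL
    AASiteLogits(m, strategy = strat)
  })
}
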