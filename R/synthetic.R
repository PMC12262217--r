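# Synthetic parent-child pairs under a known SHM(+selection) process.
#
# Children are sampled per codon from the exact codon outcome distribution
# used for likelihood evaluation, so the generating model is by
# construction the model under which the data are distributed; this makes
# parameter-recovery and model-comparison tests sharp.

# deterministic per-PCP seed derived from a master seed by counter
# splitting: changing n_pcps never reshuffles earlier pairs
.splitSeed <- function(seed, i) {
  (as.double(seed) * 1000003 + as.double(i) * 7919) %% 2147483629
}

#' Random k-mer mutability model
#'
#' Draws a synthetic context model emulating SHM hot- and coldspots:
#' per-k-mer rates are lognormal (sdlog 1, roughly a tenfold dynamic range
#' between cool and hot contexts) scaled to mean 1, and conditional
#' target-base probabilities are uniform-Dirichlet over the three
#' non-wildtype bases. Deterministic given \code{seed}.
#'
#' @param k odd context width (default 3).
#' @param seed integer seed.
#' @return a [KmerModel].
#' @export
syntheticKmerModel <- function(k = 3L, seed = 1L) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  kmers <- .CODONS
  if (k != 3L) {
    kmers <- ""
    for (j in seq_len(k)) kmers <- as.vector(outer(kmers, .BASES, paste0))
  }
  rates <- stats::rlnorm(length(kmers), meanlog = 0, sdlog = 1)
  rates <- structure(rates / mean(rates), names = kmers)
  central <- match(substr(kmers, (k + 1L) %/% 2L, (k + 1L) %/% 2L), .BASES)
  g <- matrix(stats::rgamma(length(kmers) * 4L, shape = 1), ncol = 4L)
  g[cbind(seq_along(kmers), central)] <- 0
  cp <- g / rowSums(g)
  rownames(cp) <- kmers
  KmerModel(rates, cp)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Permute the rates of a k-mer model
#'
#' Returns a mismatched model sharing the marginal rate spectrum of
#' \code{model} but with rates randomly reassigned among k-mers
#' (conditional probabilities stay attached to their context, preserving
#' the zero-at-wildtype invariant). Used as a null in model-recovery
#' tests.
#'
#' @param model a [KmerModel].
#' @param seed integer seed for the permutation.
#' @return a [KmerModel].
#' @export
permuteKmerRates <- function(model, seed = 1L) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  r <- model@rates
  perm <- sample.int(length(r))
  KmerModel(structure(unname(r)[perm], names = names(r)), model@condProbs,
            defaultRate = model@defaultRate,
            defaultCondProbs = model@defaultCondProbs)
}

#' Random stop-free parent sequence
#'
#' Uniform over sense codons (stop codons rejected per codon), drawn from
#' the current RNG stream.
#'
#' @param length sequence length in nucleotides, a multiple of 3.
#' @return lowercase nucleotide string.
#' @export
randomParent <- function(length) {
  if (length %% 3L != 0L) stop("length must be a multiple of 3")
  nc <- length %/% 3L
  sense <- which(.SENSE)
  paste(.CODONS[sense[sample.int(length(sense), nc, replace = TRUE)]],
        collapse = "")
}

#' Simulate a child sequence over one branch
#'
#' Samples each codon of the child from the same codon outcome
#' distribution the likelihood engine assigns to the parent at branch
#' length \code{tau} (stop outcomes excluded; selection factors applied
#' when a profile is given), guaranteeing model-consistency between
#' simulation and evaluation.
#'
#' @param parent parent nucleotide string.
#' @param rates an [NTSiteRates] for the parent.
#' @param tau positive branch length.
#' @param selection optional [SelectionProfile].
#' @return child nucleotide string.
#' @export
simulateChild <- function(parent, rates, tau, selection = NULL) {
  M <- unclass(.codonOutcomeProbs(rates, tau, selection))
  idx <- apply(M, 1, function(p) sample.int(64L, 1L, prob = p))
  paste(.CODONS[idx], collapse = "")
}

#' Generate a synthetic PCP dataset with known ground truth
#'
#' Draws stop-free random parents, branch lengths from a fixed value or a
#' log-uniform range, and children from the generating model's codon
#' outcome distribution. When \code{requireAASub} is set, children are
#' resampled (up to \code{maxRetries}) until the pair carries at least one
#' amino-acid substitution and a nucleotide substitution frequency within
#' \code{maxSubFrequency}, so every emitted pair passes [filterPCPs()];
#' resample counts are recorded in the truth record because this
#' conditioning inflates observed relative to expected counts.
#'
#' Per-pair RNG streams are split off the master seed by counter, so
#' increasing \code{nPCPs} extends the dataset without reshuffling earlier
#' pairs.
#'
#' @param nPCPs number of pairs.
#' @param length sequence length in nucleotides (multiple of 3).
#' @param tau a fixed branch length (scalar) or a log-uniform range
#'   \code{c(lo, hi)}.
#' @param model generating [KmerModel] or [PerSiteModel].
#' @param selection optional selection model (20x20 log-odds matrix or
#'   [DMSModel]) applied during simulation.
#' @param seed master seed.
#' @param requireAASub resample until at least one amino-acid
#'   substitution (and the frequency filter) is satisfied.
#' @param maxSubFrequency nucleotide substitution frequency cap enforced
#'   during resampling.
#' @param maxRetries resampling cap per pair.
#' @return list with \code{pcps} (a [PCPSet]) and \code{truth}, a list
#'   with per-pair true \code{tau}, true SSP vectors under the generating
#'   model, mutated nucleotide site lists, and resample counts.
#' @export
generateDataset <- function(nPCPs, length = 300L, tau = c(0.01, 0.3),
                            model = syntheticKmerModel(), selection = NULL,
                            seed = 1L, requireAASub = TRUE,
                            maxSubFrequency = 0.30, maxRetries = 100L) {
  stopifnot(nPCPs >= 1, length %% 3L == 0L)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  parents <- children <- character(nPCPs)
  taus <- numeric(nPCPs)
  resamples <- integer(nPCPs)
  sspTrue <- vector("list", nPCPs)
  mutated <- vector("list", nPCPs)
  for (i in seq_len(nPCPs)) {
    set.seed(.splitSeed(seed, i))
    parent <- randomParent(length)
    rates <- siteRates(model, parent)
    prof <- if (!is.null(selection))
      selectionProfile(selection, translateNT(parent)) else NULL
    t_i <- if (base::length(tau) == 1L) tau
           else exp(stats::runif(1, log(tau[1]), log(tau[2])))
    tries <- 0L
    repeat {
      child <- simulateChild(parent, rates, t_i, prof)
      if (!requireAASub) break
      mm <- sum(.ntMismatches(parent, child))
      aaDiff <- translateNT(parent) != translateNT(child)
      if (aaDiff && mm / length <= maxSubFrequency) break
      tries <- tries + 1L
      if (tries >= maxRetries)
        stop("pair ", i, ": no admissible child after ", maxRetries,
             " resamples (tau too small?)")
    }
    parents[i] <- parent
    children[i] <- child
    taus[i] <- t_i
    resamples[i] <- tries
    dist <- codonAADistribution(rates, t_i, selection = prof)
    sspTrue[[i]] <- siteSubstitutionProbability(dist)
    mutated[[i]] <- which(.ntMismatches(parent, child))
  }
  pcps <- PCPSet(sprintf("pcp%04d", seq_len(nPCPs)),
                 sprintf("fam%04d", seq_len(nPCPs)), parents, children)
  list(pcps = pcps,
       truth = list(tau = taus, ssp = sspTrue, mutatedSites = mutated,
                    resamples = resamples, seed = as.integer(seed)))
}

#' Serialize a truth record as JSON
#'
#' @param truth the \code{truth} element of [generateDataset()] output.
#' @param path optional output path; if omitted the JSON string is
#'   returned.
#' @export
writeTruth <- function(truth, path = NULL) {
  js <- jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
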