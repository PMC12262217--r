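#' Construct a set of parent-child pairs
#'
#' @param pcp_id,family_id character identifiers, recycled if scalar.
#' @param parent_nt,child_nt nucleotide strings (case-insensitive, stored
#'   lowercase) of equal length, a multiple of 3.
#' @param position_map optional list of character vectors of IMGT position
#'   labels, one label per codon site of the corresponding pair.
#' @return a [PCPSet].
#' @examples
#' PCPSet("p1", "f1", "ggtgga", "tgtgga")
#' @export
PCPSet <- function(pcp_id, family_id, parent_nt, child_nt,
                   position_map = NULL) {
  n <- length(parent_nt)
  new("PCPSet",
      pcpId = as.character(rep_len(pcp_id, n)),
      familyId = as.character(rep_len(family_id, n)),
      parentNT = tolower(parent_nt),
      childNT = tolower(child_nt),
      positionMap = if (is.null(position_map)) list() else position_map)
}

#' @rdname PCPSet-class
#' @export
setMethod("pcpId", "PCPSet", function(x) x@pcpId)

#' @rdname PCPSet-class
#' @export
setMethod("familyId", "PCPSet", function(x) x@familyId)

#' @rdname PCPSet-class
#' @export
setMethod("parentNT", "PCPSet", function(x) x@parentNT)

#' @rdname PCPSet-class
#' @export
setMethod("childNT", "PCPSet", function(x) x@childNT)

#' @rdname PCPSet-class
#' @export
setMethod("positionMap", "PCPSet", function(x) x@positionMap)

#' @rdname PCPSet-class
#' @export
setMethod("length", "PCPSet", function(x) length(x@pcpId))

#' @rdname PCPSet-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PCPSet", function(x, i, j, ..., drop = FALSE) {
  ii <- seq_along(x@pcpId)[i]
  new("PCPSet", pcpId = x@pcpId[ii], familyId = x@familyId[ii],
      parentNT = x@parentNT[ii], childNT = x@childNT[ii],
      positionMap = if (length(x@positionMap)) x@positionMap[ii] else list())
})

setMethod("show", "PCPSet", function(object) {
  cat("PCPSet with", length(object), "parent-child pair(s)\n")
  if (length(object) > 0) {
    L <- nchar(object@parentNT)
    cat("  sequence length:", paste(range(L), collapse = "-"), "nt;",
        length(unique(object@familyId)), "clonal family(ies)\n")
    cat("  position map:",
        if (length(object@positionMap)) "present" else "absent", "\n")
  }
})

#' @rdname PCPSet-class
#' @param row.names,optional ignored (method consistency only).
#' @export
setMethod("as.data.frame", "PCPSet", function(x, ...) {
  data.frame(pcp_id = x@pcpId, family_id = x@familyId,
             parent_nt = x@parentNT, child_nt = x@childNT,
             position_map = if (length(x@positionMap))
               vapply(x@positionMap, paste, "", collapse = ",") else "",
             stringsAsFactors = FALSE)
})

#' Read parent-child pairs from a file
#'
#' Two dialects are supported. The TSV dialect has columns \code{pcp_id},
#' \code{family_id}, \code{parent_nt}, \code{child_nt} and optionally
#' \code{position_map} (comma-separated IMGT labels, one per codon site).
#' The FASTA-pairs dialect interleaves records named \code{">id|parent"}
#' and \code{">id|child"}.
#'
#' Nucleotides are lowercased on input. Structurally malformed rows
#' (unequal parent/child lengths, length not a multiple of 3) are dropped
#' with a warning naming their line numbers; the dropped rows are attached
#' as the \code{"rowErrors"} attribute. A missing required column is fatal.
#'
#' @param path file to read.
#' @param format \code{"tsv"} or \code{"fasta-pairs"}.
#' @return a [PCPSet]; records are not otherwise validated or filtered
#'   (see [filterPCPs()]).
#' @export
readPCPs <- function(path, format = c("tsv", "fasta-pairs")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE)
    need <- c("pcp_id", "family_id", "parent_nt", "child_nt")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    pm <- if ("position_map" %in% names(df)) df$position_map else NULL
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    nm <- names(seqs)
    role <- sub("^.*\\|", "", nm)
    id <- sub("\\|[^|]*$", "", nm)
    if (!all(role %in% c("parent", "child")))
      stop("fasta-pairs records must be named '>id|parent' or '>id|child'")
    pid <- unique(id)
    p <- as.character(seqs[match(paste0(pid, "|parent"), nm)])
    k <- as.character(seqs[match(paste0(pid, "|child"), nm)])
    if (anyNA(p) || anyNA(k))
      stop("each id must appear with both a parent and a child record")
    df <- data.frame(pcp_id = pid, family_id = pid, parent_nt = p,
                     child_nt = k, stringsAsFactors = FALSE)
    pm <- NULL
  }
  df$parent_nt <- tolower(df$parent_nt)
  df$child_nt <- tolower(df$child_nt)
  bad <- nchar(df$parent_nt) != nchar(df$child_nt) |
    nchar(df$parent_nt) %% 3L != 0L |
    grepl("[^acgtn]", df$parent_nt) | grepl("[^acgtn]", df$child_nt)
  rowErrors <- NULL
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(lines, collapse = ", "))
    rowErrors <- data.frame(line = lines, pcp_id = df$pcp_id[bad])
    df <- df[!bad, , drop = FALSE]
    if (!is.null(pm)) pm <- pm[!bad]
  }
  pmList <- NULL
  if (!is.null(pm) && any(nzchar(pm)))
    pmList <- lapply(pm, function(s)
      if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1]] else character())
  out <- PCPSet(df$pcp_id, df$family_id, df$parent_nt, df$child_nt, pmList)
  attr(out, "rowErrors") <- rowErrors
  out
}

#' Write parent-child pairs as canonical TSV
#'
#' Inverse of [readPCPs()] for the TSV dialect; reading and re-writing a
#' canonical file reproduces it byte-identically.
#'
#' @param pcps a [PCPSet].
#' @param path output path.
#' @export
writePCPs <- function(pcps, path) {
  df <- as.data.frame(pcps)
  if (!length(positionMap(pcps))) df$position_map <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate a nucleotide sequence to amino acids
#'
#' Standard genetic code; codons containing \code{n} translate to the
#' ambiguity symbol \code{X} (unless the code resolves them regardless) and
#' stop codons to \code{*}.
#'
#' @param nt character vector of nucleotide strings, lengths multiples of 3.
#' @return character vector of amino-acid strings.
#' @examples
#' translateNT(c("ggt", "tattac", "taa"))
#' @export
translateNT <- function(nt) {
  if (any(nchar(nt) %% 3L != 0L))
    stop("sequence length must be a multiple of 3")
  # direct lookup against the standard code table; codons outside the
  # 64-codon alphabet (i.e. containing n) become X
  vapply(tolower(nt), function(s) {
    if (!nchar(s)) return("")
    aa <- .CODON2AA[.codonStrings(s)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# mismatch count between two equal-length strings, NA-aware:
# positions where either base is n are not counted as mismatches
.ntMismatches <- function(a, b, ignoreN = TRUE) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  d <- av != bv
  if (ignoreN) d[av == "n" | bv == "n"] <- FALSE
  d
}

#' Filter parent-child pairs
#'
#' Applies, in order, the three retention rules used when preparing pairs
#' for model evaluation: drop pairs whose parent or child translation
#' contains a stop codon; drop pairs whose nucleotide substitution
#' frequency (mutated sites / sequence length) exceeds
#' \code{maxSubFrequency}; drop pairs with no amino-acid substitution.
#' Codons containing \code{n} are ignored when counting amino-acid
#' differences.
#'
#' @param pcps a [PCPSet].
#' @param maxSubFrequency maximum tolerated nucleotide substitution
#'   frequency (default 0.30).
#' @return list with elements \code{pcps} (the retained [PCPSet]) and
#'   \code{report} (a [FilterReport]).
#' @export
filterPCPs <- function(pcps, maxSubFrequency = 0.30) {
  n <- length(pcps)
  keep <- rep(TRUE, n)
  dropped <- c(stop_codon = 0L, high_sub_frequency = 0L,
               no_aa_substitution = 0L)
  tp <- translateNT(parentNT(pcps))
  tc <- translateNT(childNT(pcps))
  hasStop <- grepl("*", tp, fixed = TRUE) | grepl("*", tc, fixed = TRUE)
  dropped["stop_codon"] <- sum(hasStop)
  keep[hasStop] <- FALSE
  for (i in which(keep)) {
    mm <- sum(.ntMismatches(parentNT(pcps)[i], childNT(pcps)[i]))
    if (mm / nchar(parentNT(pcps)[i]) > maxSubFrequency) {
      keep[i] <- FALSE
      dropped["high_sub_frequency"] <- dropped["high_sub_frequency"] + 1L
    }
  }
  for (i in which(keep)) {
    pa <- strsplit(tp[i], "")[[1]]
    ca <- strsplit(tc[i], "")[[1]]
    ok <- pa != "X" & ca != "X"
    if (!any(pa[ok] != ca[ok])) {
      keep[i] <- FALSE
      dropped["no_aa_substitution"] <- dropped["no_aa_substitution"] + 1L
    }
  }
  list(pcps = pcps[keep],
       report = new("FilterReport", nInput = n, nRetained = sum(keep),
                    dropped = dropped))
}

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@nInput, "in,", object@nRetained, "retained\n")
  for (nm in names(object@dropped))
    cat(sprintf("  dropped %-20s %d\n", nm, object@dropped[[nm]]))
})

#' Serialize a filter report as JSON
#'
#' @param report a [FilterReport].
#' @param path optional output path; if omitted the JSON string is returned.
#' @export
writeFilterReport <- function(report, path = NULL) {
  x <- list(n_input = report@nInput, n_retained = report@nRetained,
            dropped = as.list(report@dropped))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Sliding-window mutation filter
#'
#' Keep a sequence only if no window of \code{window} consecutive sites
#' contains more than \code{maxMut} mismatches against a reference
#' (typically the inferred naive sequence). Used as an optional pre-filter
#' to remove sequences whose dense mutation clusters suggest artifacts.
#'
#' @param parent,reference equal-length nucleotide strings.
#' @param window window width in nucleotides.
#' @param maxMut maximum mismatches tolerated within any window.
#' @return \code{TRUE} (keep) or \code{FALSE} (drop).
#' @export
windowMutationFilter <- function(parent, reference, window = 20L,
                                 maxMut = 10L) {
  if (nchar(parent) != nchar(reference))
    stop("parent and reference must have equal length")
  d <- as.integer(.ntMismatches(parent, reference, ignoreN = FALSE))
  L <- length(d)
  w <- min(window, L)
  cs <- c(0L, cumsum(d))
  worst <- max(cs[(w + 1L):(L + 1L)] - cs[1L:(L - w + 1L)])
  worst <= maxMut
}

#' Default IMGT region scheme
#'
#' @return a [RegionScheme] with the standard IMGT ranges for the seven
#'   FWR/CDR regions of an antibody variable domain.
#' @export
imgtRegionScheme <- function() {
  new("RegionScheme", regionBounds = list(
    FWR1 = c(1L, 26L), CDR1 = c(27L, 38L), FWR2 = c(39L, 55L),
    CDR2 = c(56L, 65L), FWR3 = c(66L, 104L), CDR3 = c(105L, 117L),
    FWR4 = c(118L, 128L)))
}

setMethod("show", "RegionScheme", function(object) {
  b <- object@regionBounds
  cat("RegionScheme:",
      paste(sprintf("%s %d-%d", names(b),
                    vapply(b, `[`, 0L, 1), vapply(b, `[`, 0L, 2)),
            collapse = ", "), "\n")
})

#' Region labels for a vector of IMGT position labels
#'
#' IMGT labels are strings to accommodate insertion codes such as
#' \code{"111.1"}; the integer part determines the region. Labels outside
#' all ranges, or non-numeric labels, map to \code{"unassigned"}.
#'
#' @param positions character vector of IMGT position labels (one per
#'   codon site), e.g. a [positionMap()] entry.
#' @param scheme a [RegionScheme].
#' @return character vector of region names.
#' @examples
#' annotateRegions(c("1", "105", "111.1", "129"), imgtRegionScheme())
#' @export
annotateRegions <- function(positions, scheme = imgtRegionScheme()) {
  num <- suppressWarnings(floor(as.numeric(positions)))
  out <- rep("unassigned", length(positions))
  for (rn in names(scheme@regionBounds)) {
    b <- scheme@regionBounds[[rn]]
    out[!is.na(num) & num >= b[1] & num <= b[2]] <- rn
  }
  out
}
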