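# Internal lookup tables for codon arithmetic.
#
# Codons are ordered lexicographically over a < c < g < t so that
# .CODON_BASE_IDX[k, j] gives the base index (1..4) of codon k at
# position j. The genetic code is taken from Biostrings.

.BASES <- c("a", "c", "g", "t")

.codonGrid <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)

#' @noRd
.CODON_BASE_IDX <- cbind(.codonGrid$b1, .codonGrid$b2, .codonGrid$b3)

.CODONS <- paste0(.BASES[.codonGrid$b1], .BASES[.codonGrid$b2],
                  .BASES[.codonGrid$b3])

.CODON_AA <- unname(Biostrings::GENETIC_CODE[toupper(.CODONS)])

# the 20 standard amino acids, alphabetical; this ordering is used for all
# probability matrices and file columns
.AAS <- sort(unique(.CODON_AA[.CODON_AA != "*"]))

.SENSE <- .CODON_AA != "*"

# column index into a C x 20 amino-acid matrix for each codon (NA for stops)
.CODON_AA_IDX <- match(.CODON_AA, .AAS)

.STOP_CODONS <- .CODONS[!.SENSE]

# fast codon -> amino acid lookup (codons with other letters, e.g. n, fall
# through to NA and are mapped to "X" by the caller)
.CODON2AA <- structure(.CODON_AA, names = .CODONS)

# split a nucleotide string into its codon strings
.codonStrings <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.ntToInt <- function(nt) {
  # integer base codes, NA for anything outside acgt (e.g. n)
  match(strsplit(nt, "", fixed = TRUE)[[1]], .BASES)
}
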