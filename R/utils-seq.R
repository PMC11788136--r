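#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of DNA sequences (alphabet A,C,G,T,N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a nucleotide sequence
#'
#' Standard-code translation in a given frame. Codons containing N translate
#' to X; stop codons translate to '*'; a trailing partial codon is dropped.
#'
#' @param nt Character vector of DNA sequences over A,C,G,T,N.
#' @param frame Integer 0, 1 or 2: number of leading bases skipped.
#' @return Character vector of amino-acid sequences.
#' @export
#' @examples
#' translate_nt("TGTGCT")       # "CA"
#' translate_nt("ATGTAA", 1L)   # "C"
translate_nt <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  sub <- substring(nt, frame + 1L)
  len <- nchar(sub)
  sub <- substring(sub, 1L, len - (len %% 3L))
  out <- character(length(sub))
  nz <- nchar(sub) > 0L
  if (any(nz)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(sub[nz]),
                                if.fuzzy.codon = "X")
    out[nz] <- as.character(aa)
  }
  out
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' printed percentage tables; base round() rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Proportion of identical positions between two equal-length strings
#' @keywords internal
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

#' Global-alignment nucleotide identity between two sequences
#'
#' Identity is matches / alignment columns of a global (Needleman-Wunsch)
#' alignment; gap columns count as mismatches. Used for family clustering.
#'
#' @param a,b DNA sequences (character scalars).
#' @return Identity fraction in [0, 1].
#' @export
alignment_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pv <- strsplit(p, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  sum(pv == sv & pv != "-") / length(pv)
}

#' Random DNA sequence
#' @param n Length in bases.
#' @return A character scalar; draws from the session RNG stream.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Count mismatches of a pattern at a fixed position of a subject (equal length)
#' @keywords internal
count_mismatch <- function(observed, consensus) {
  ov <- strsplit(observed, "")[[1]]
  cv <- strsplit(consensus, "")[[1]]
  sum(ov != cv)
}
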