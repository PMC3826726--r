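`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' N stays N; the input must be uppercase ACGTN text.
#'
#' @param x single DNA string.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# raw byte codes for the DNA alphabet
.BYTE <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L)

# counts of A/C/G/T/N in a sequence (raw-byte scan, fast at Mb scale)
.base_counts <- function(seq) {
  r <- as.integer(charToRaw(seq))
  vapply(.BYTE, function(b) sum(r == b), integer(1))
}

.check_dna <- function(seq, id = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' in %s at position %d",
                 substr(seq, bad, bad), id, bad), call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic sub-seed derivation (kept below 2^31)
.subseed <- function(seed, i) (as.integer(seed) + 104729L * as.integer(i)) %% 2147483587L
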