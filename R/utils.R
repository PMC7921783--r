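DNA_BASES <- c("A", "C", "G", "T")
IUPAC_CHARS <- c(DNA_BASES, "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Reverse complement of DNA strings
#'
#' Plain-character wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (IUPAC alphabet).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Sample random DNA sequences
#'
#' Draws i.i.d. bases with a given GC content; used by the synthetic-data
#' generator for ancestors and genomic background. Consumes the R RNG stream.
#'
#' @param n number of sequences.
#' @param length sequence length in bp (recycled).
#' @param gc target GC fraction in `[0, 1]`.
#' @return character vector of uppercase DNA.
#' @export
random_dna <- function(n, length, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  length <- rep_len(length, n)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(length, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

gc_fraction <- function(x) {
  b <- strsplit(x, "", fixed = TRUE)
  vapply(b, function(ch) mean(ch %in% c("G", "C", "S")), numeric(1))
}

at_fraction <- function(x) {
  b <- strsplit(x, "", fixed = TRUE)
  vapply(b, function(ch) mean(ch %in% c("A", "T", "W")), numeric(1))
}

## longest run (bp) of AT-dinucleotide tandem repeat, e.g. "ATATAT..." or "TATATA..."
longest_at_dinucleotide_run <- function(x) {
  vapply(x, function(s) longest_at_run_cpp(s), numeric(1), USE.NAMES = FALSE)
}

check_dna_alphabet <- function(x, allowed = c(DNA_BASES, "N"), what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(allowed, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC/disallowed characters (first offender: index %d)",
                 what, which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic seed derivation; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483629L
}
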