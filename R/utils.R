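#' @useDynLib AmpliCas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats aov TukeyHSD shapiro.test sd setNames rbinom rgeom runif
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom withr with_seed
NULL

DNA_BASES_CHR <- c("A", "C", "G", "T")

#' Reverse complement of DNA character vectors
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()] so sequence plumbing elsewhere in the
#' package can stay in plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length with each element
#'   reverse-complemented.
#' @examples
#' revComp(c("ACGT", "GGATCC"))
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assertDna <- function(x, what = "sequence", allowN = FALSE) {
  pat <- if (allowN) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains symbols outside {A,C,G,T%s}: %s",
                 what, if (allowN) ",N" else "",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Hamming distance between two equal-length strings (byte comparison).
hammingDist <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb))
    stop("hammingDist requires equal-length strings", call. = FALSE)
  sum(ra != rb)
}

# Polynomial rolling hash of a character scalar, returned as 8 hex digits;
# used to fingerprint run configurations in output file headers.
strFingerprint <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Draw a random DNA string of length n under the current RNG state.
randomDna <- function(n) {
  paste(sample(DNA_BASES_CHR, n, replace = TRUE), collapse = "")
}

# Derive a per-unit seed from a master seed; kept below 2^31.
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}
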