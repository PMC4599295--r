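#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. All miRNA/seed arithmetic inside the
#' package happens in the RNA alphabet; genome and transcript files may be
#' DNA and are converted on entry.
#'
#' @param x character vector of sequences.
#' @return character vector in uppercase RNA alphabet.
#' @export
#' @examples
#' as_rna("acgt")
as_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Normalize a nucleotide string to the DNA alphabet
#'
#' @param x character vector of sequences.
#' @return character vector in uppercase DNA alphabet.
#' @export
as_dna <- function(x) {
  chartr("Uu", "Tt", toupper(x))
}

#' Reverse complement in the RNA alphabet
#'
#' @param x character vector of RNA (or DNA; normalized first) sequences.
#' @return reverse complement, RNA alphabet.
#' @export
#' @examples
#' rc_rna("AAUACUG")
rc_rna <- function(x) {
  x <- as_rna(x)
  vapply(x, function(s) {
    rev_s <- paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    chartr("ACGUN", "UGCAN", rev_s)
  }, character(1), USE.NAMES = FALSE)
}

# TRUE when a sequence mixes T and U: cannot tell DNA from RNA typesetting.
is_alphabet_ambiguous <- function(x) {
  x <- toupper(x)
  grepl("T", x, fixed = TRUE) & grepl("U", x, fixed = TRUE)
}

# random sequence helper (uniform base composition unless weights given)
random_seq <- function(n, alphabet = c("A", "C", "G", "U"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
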