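# misc sequence and RNG helpers shared across modules

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and converts U to T. All reads and references are compared in
#' DNA space; RNA input (e.g. miRBase mature sequences) is accepted
#' transparently.
#'
#' @param x character vector of sequences.
#' @return character vector, uppercase, U replaced by T.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Uniform random DNA strings of the given lengths.
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Longest run of a single character in each string.
max_char_run <- function(x, ch = "A") {
  vapply(x, function(s) {
    if (!nzchar(s)) return(0L)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    runs <- r$lengths[r$values == ch]
    if (length(runs)) max(runs) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

# Fraction of a given character per string (0 for empty strings).
char_frac <- function(x, ch = "A") {
  n <- nchar(x)
  k <- n - nchar(gsub(ch, "", x, fixed = TRUE))
  ifelse(n == 0, 0, k / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
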