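# Internal string/sequence helpers. Sequences are plain uppercase character
# scalars over {A,C,G,T,N}; Biostrings does the biologically fiddly parts.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring of a sequence scalar
seq_slice <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

dna_alphabet <- c("A", "C", "G", "T", "N")

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}",
                 what, paste(if (allow_n) dna_alphabet else dna_alphabet[-5],
                             collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

# Seed the RNG for the calling function's scope and restore the caller's
# stream (or its absence) on exit, so generators never disturb global state.
local_rng <- function(seed, envir = parent.frame()) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  withr::defer({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, envir = envir)
  set.seed(seed)
}

# all start positions (0-based) of exact occurrences of `pattern` in `text`,
# including overlapping ones
exact_matches <- function(text, pattern) {
  n <- nchar(text)
  m <- nchar(pattern)
  if (m == 0L || m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  hits <- substring(text, starts, starts + m - 1L) == pattern
  starts[hits] - 1L
}
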