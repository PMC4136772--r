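#' @keywords internal
#' @noRd
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# Validate and normalise a DNA string: single character scalar, uppercased,
# restricted to {A,C,G,T,N}. Every user-facing operation ingests through
# this helper.
#' @keywords internal
#' @noRd
clean_dna <- function(x, arg = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(arg, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (!allow_empty && nchar(x) == 0L) {
    stop(arg, " must be non-empty", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L) {
    stop(arg, " contains characters outside {A,C,G,T,N}: '",
         substr(bad, 1L, 10L), "'", call. = FALSE)
  }
  x
}

#' Reverse complement of a DNA string
#'
#' @param x a DNA string over `{A,C,G,T,N}` (lowercase accepted).
#' @return the reverse-complemented string; `N` maps to `N`.
#' @examples
#' reverse_complement("AAGC") # "GCTT"
#' @export
reverse_complement <- function(x) {
  x <- clean_dna(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Hamming distance between equal-length DNA strings
#'
#' @param a,b DNA strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  a <- clean_dna(a, "a"); b <- clean_dna(b, "b")
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance requires equal-length strings", call. = FALSE)
  }
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Edit (Levenshtein) distance between DNA strings
#'
#' Unit-cost substitutions, insertions and deletions.
#'
#' @param a,b DNA strings (any lengths).
#' @return integer edit distance.
#' @export
edit_distance <- function(a, b) {
  a <- clean_dna(a, "a"); b <- clean_dna(b, "b")
  as.integer(adist(a, b))
}
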