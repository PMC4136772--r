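# Local Rank Distance and classical rank distance.
#
# LRD pairs each k-mer of one string with the nearest identical k-mer of
# the other and sums the positional offsets, each capped at the maximal
# offset m; a k-mer with no identical partner anywhere (including any
# k-mer containing N) contributes exactly m. The symmetric distance is the
# sum of the two one-sided scans.

#' @keywords internal
#' @noRd
check_lrd_args <- function(x, y, k, m) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  if (k > 31) stop("k-mers longer than 31 are not supported", call. = FALSE)
  if (nchar(x) < k || nchar(y) < k) {
    stop("both strings must be at least k characters long", call. = FALSE)
  }
  invisible(NULL)
}

#' One-sided Local Rank Distance partial sum
#'
#' Computes the partial sum over the k-mers of `x`: each of the
#' `nchar(x) - k + 1` k-mers is charged the absolute offset to the nearest
#' identical k-mer of `y`, capped at `m`; a k-mer absent from `y` (or
#' containing `N`) is charged `m`. This is the quantity the aligners
#' minimise over windows of a reference.
#'
#' @param x,y DNA strings over `{A,C,G,T,N}`.
#' @param k k-mer length (at most the shorter string's length).
#' @param m maximal offset: the cap and the unmatched-k-mer penalty.
#' @return a non-negative number (an exact integer value).
#' @examples
#' delta_one_sided("AC", "CA", k = 1, m = 2) # 2
#' @export
delta_one_sided <- function(x, y, k, m) {
  x <- clean_dna(x, "x"); y <- clean_dna(y, "y")
  check_lrd_args(x, y, k, m)
  .delta_one_sided_cpp(x, y, as.integer(k), as.integer(m))
}

#' Local Rank Distance between two DNA strings
#'
#' The symmetric sum of the two one-sided partial sums
#' ([delta_one_sided()] in both directions).
#'
#' @inheritParams delta_one_sided
#' @return a non-negative number; 0 iff every k-mer self-matches at offset 0.
#' @examples
#' local_rank_distance("AAA", "CCC", k = 1, m = 3) # 18
#' @export
local_rank_distance <- function(x, y, k, m) {
  x <- clean_dna(x, "x"); y <- clean_dna(y, "y")
  check_lrd_args(x, y, k, m)
  .delta_one_sided_cpp(x, y, as.integer(k), as.integer(m)) +
    .delta_one_sided_cpp(y, x, as.integer(k), as.integer(m))
}

#' Classical rank distance between two strings
#'
#' Characters are annotated by occurrence ordinal (the i-th A, i-th C, ...).
#' Each ordinal present in both strings contributes the absolute difference
#' of its positions; each occurrence present in only one string contributes
#' `unmatched_penalty`, which defaults to `(nchar(x) + nchar(y)) / 2`.
#'
#' @param x,y DNA strings.
#' @param unmatched_penalty penalty per unmatched occurrence; `NULL` for
#'   the mean-length default.
#' @return a non-negative number.
#' @export
rank_distance <- function(x, y, unmatched_penalty = NULL) {
  x <- clean_dna(x, "x"); y <- clean_dna(y, "y")
  if (is.null(unmatched_penalty)) {
    unmatched_penalty <- (nchar(x) + nchar(y)) / 2
  }
  if (!is.numeric(unmatched_penalty) || length(unmatched_penalty) != 1L ||
      unmatched_penalty < 0) {
    stop("unmatched_penalty must be a single non-negative number",
         call. = FALSE)
  }
  .rank_distance_cpp(x, y, unmatched_penalty)
}
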