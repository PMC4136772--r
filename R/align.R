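# The LRD aligners.
#
# A read is placed at the reference window minimising the one-sided LRD
# partial sum between the window and the read. The exhaustive aligner
# evaluates every window; the hash aligner builds a positional inverted
# index of the read's k-mers, counts shared k-mers per window with a
# sliding sum, and skips windows that cannot (rule 2) or are unlikely
# (rule 1) to beat the best distance found so far.

#' Alignment parameter set
#'
#' @param k k-mer length (default 3, suited to 100 bp reads).
#' @param m maximal offset / unmatched-k-mer penalty (default 24; must not
#'   exceed the read length).
#' @param threshold maximum accepted distance `D`; a read is reported
#'   aligned iff its minimum distance is `<= D`. `NULL` (default) resolves
#'   at alignment time to `0.3 * (L - k + 1) * m` for a read of length `L`,
#'   i.e. 30% of the worst attainable one-sided sum.
#' @param skip_fraction rule-1 skip fraction `S` in `[0, 1]`: window `i` is
#'   skipped when `counts[i] < S * max_count`. `S = 0` disables rule 1;
#'   `S = 1` visits only windows attaining the maximal shared-k-mer count.
#' @param rc_factor reverse-complement acceptance factor in `(0, 1]`: the
#'   reverse complement is tried only when the forward minimum distance
#'   exceeds `T = rc_factor * (L - k + 1) * m`.
#' @param mode `"hash"` (approximate, fast) or `"exhaustive"` (exact).
#' @param use_rule2 enable the admissible lower-bound skip
#'   (`(missing k-mers) * m > best`); hash mode only.
#' @param use_abort abandon a window once its running sum exceeds the best
#'   distance so far; hash mode only. Never changes the returned minimum.
#' @param partial_sum_side which one-sided sum is minimised:
#'   `"window_to_read"` (default; the window's k-mers are looked up in the
#'   read index) or `"read_to_window"` (exhaustive mode only — the skip
#'   rules are defined, and rule 2 is admissible, only on the default side).
#' @param score_method genome-scoring rule used by the clustering layer:
#'   `"literal"` (sum of distances divided by the squared number of aligned
#'   reads) or `"mean"` (plain mean distance).
#' @return an object of class `"lrd_align_params"`.
#' @export
align_params <- function(k = 3, m = 24, threshold = NULL,
                         skip_fraction = 1.0, rc_factor = 0.2,
                         mode = c("hash", "exhaustive"),
                         use_rule2 = TRUE, use_abort = TRUE,
                         partial_sum_side = c("window_to_read",
                                              "read_to_window"),
                         score_method = c("literal", "mean")) {
  mode <- match.arg(mode)
  partial_sum_side <- match.arg(partial_sum_side)
  score_method <- match.arg(score_method)
  stopifnot(k >= 1, k == round(k), m >= 1, m == round(m),
            skip_fraction >= 0, skip_fraction <= 1,
            rc_factor > 0, rc_factor <= 1)
  if (!is.null(threshold)) stopifnot(threshold >= 0)
  if (mode == "hash" && partial_sum_side != "window_to_read") {
    stop("the hash aligner supports only partial_sum_side = 'window_to_read'",
         call. = FALSE)
  }
  structure(list(k = as.integer(k), m = as.integer(m), threshold = threshold,
                 skip_fraction = skip_fraction, rc_factor = rc_factor,
                 mode = mode, use_rule2 = use_rule2, use_abort = use_abort,
                 partial_sum_side = partial_sum_side,
                 score_method = score_method),
            class = "lrd_align_params")
}

#' @keywords internal
#' @noRd
resolve_threshold <- function(params, read_length) {
  if (!is.null(params$threshold)) return(params$threshold)
  0.3 * (read_length - params$k + 1) * params$m
}

#' @keywords internal
#' @noRd
check_read_ref <- function(read, reference, params) {
  if (nchar(read) < params$k) {
    stop("read shorter than k", call. = FALSE)
  }
  if (nchar(reference) < nchar(read)) {
    stop("reference shorter than read", call. = FALSE)
  }
  if (params$m > nchar(read)) {
    stop("maximal offset m must not exceed the read length", call. = FALSE)
  }
  invisible(NULL)
}

#' Positional inverted index of a read's k-mers
#'
#' @param read a DNA string.
#' @param k k-mer length.
#' @return an object of class `"kmer_index"`: a list with `k`,
#'   `read_length` and `table`, a named list mapping each k-mer to the
#'   ascending 0-based start positions at which it occurs in the read.
#' @examples
#' build_read_index("ACAC", k = 2)$table # AC: 0 2; CA: 1
#' @export
build_read_index <- function(read, k) {
  read <- clean_dna(read, "read")
  if (nchar(read) < k) stop("read shorter than k", call. = FALSE)
  n <- nchar(read) - k + 1L
  kmers <- substring(read, seq_len(n), seq_len(n) + k - 1L)
  tab <- split(0:(n - 1L), kmers)
  tab <- tab[order(names(tab))]
  structure(list(k = as.integer(k), read_length = nchar(read),
                 table = lapply(tab, as.integer)),
            class = "kmer_index")
}

#' Nearest occurrence in an ascending position list
#'
#' Returns the element of `positions` minimising the absolute offset to
#' `q`; ties are broken toward the smaller position. `NA` for an empty
#' list. Equivalent to (but faster than) a linear scan.
#'
#' @param positions ascending integer vector (e.g. one entry of a
#'   [build_read_index()] table).
#' @param q query position.
#' @return the nearest position, or `NA_integer_`.
#' @export
nearest_occurrence <- function(positions, q) {
  if (length(positions) == 0L) return(NA_integer_)
  i <- findInterval(q, positions)
  cand <- unique(positions[pmax(1L, pmin(length(positions), c(i, i + 1L)))])
  # cand is ascending and which.min takes the first minimum, so an exact
  # tie resolves to the smaller position
  cand[which.min(abs(cand - q))]
}

#' Shared k-mer presence and window counts
#'
#' For each reference k-mer start `j`, `presence[j+1]` records whether that
#' k-mer occurs anywhere in the read; `counts[i+1]` is the number of
#' present k-mers in the window starting at `i`, maintained by a sliding
#' sum so total work is linear in the reference length.
#'
#' @param read,reference DNA strings with `nchar(reference) >= nchar(read)`.
#' @param k k-mer length.
#' @return list with `presence` (logical), `counts` (integer, one per
#'   window start) and `max_count`.
#' @export
shared_kmer_counts <- function(read, reference, k) {
  read <- clean_dna(read, "read")
  reference <- clean_dna(reference, "reference")
  if (nchar(read) < k) stop("read shorter than k", call. = FALSE)
  if (nchar(reference) < nchar(read)) {
    stop("reference shorter than read", call. = FALSE)
  }
  .shared_kmer_counts_cpp(read, reference, as.integer(k))
}

#' One-sided LRD at a single reference window, with early abort
#'
#' Computes the window-to-read partial sum at window start `i` (0-based)
#' using the read's inverted index; identical to
#' `delta_one_sided(substr(reference, i+1, i+L), read, k, m)`. When
#' `abort_above` is non-negative the computation is abandoned as soon as
#' the running sum exceeds it and `NA` is returned.
#'
#' @param read,reference DNA strings.
#' @param i 0-based window start; the window `[i, i + nchar(read))` must
#'   lie inside the reference.
#' @param k,m LRD parameters.
#' @param abort_above abort bound; negative disables.
#' @return the exact partial sum, or `NA` when aborted.
#' @export
delta_at_window <- function(read, reference, i, k, m, abort_above = -1) {
  read <- clean_dna(read, "read")
  reference <- clean_dna(reference, "reference")
  if (i < 0 || i + nchar(read) > nchar(reference)) {
    stop("window out of bounds", call. = FALSE)
  }
  .delta_at_window_cpp(read, reference, as.integer(i), as.integer(k),
                       as.integer(m), as.numeric(abort_above))
}

#' @keywords internal
#' @noRd
align_core <- function(read, reference, params, exhaustive) {
  res <- .align_core_cpp(read, reference, params$k, params$m,
                         exhaustive,
                         if (exhaustive) 0 else params$skip_fraction,
                         if (exhaustive) FALSE else isTRUE(params$use_rule2),
                         if (exhaustive) FALSE else isTRUE(params$use_abort),
                         params$partial_sum_side == "read_to_window")
  D <- resolve_threshold(params, nchar(read))
  pos <- if (res$position < 0) NA_integer_ else as.integer(res$position)
  dist <- res$distance
  aligned <- !is.na(pos) && dist <= D
  list(position = pos, distance = dist, aligned = aligned,
       visited = res$visited, threshold = D)
}

#' Exhaustive LRD alignment of one read
#'
#' Evaluates the one-sided LRD at every window start
#' `0 .. nchar(reference) - nchar(read)` and returns the leftmost window
#' attaining the minimum. The read is aligned iff the minimum is at most
#' the distance threshold `D`.
#'
#' @param read,reference DNA strings.
#' @param params an [align_params()] object.
#' @return list with `position` (0-based), `distance`, `aligned`,
#'   `visited` (windows evaluated) and `threshold` (resolved `D`).
#' @export
align_exhaustive <- function(read, reference, params = align_params()) {
  read <- clean_dna(read, "read")
  reference <- clean_dna(reference, "reference")
  check_read_ref(read, reference, params)
  align_core(read, reference, params, exhaustive = TRUE)
}

#' Approximate hash-indexed LRD alignment of one read
#'
#' Builds the read's positional inverted index, counts shared k-mers per
#' window, and visits windows left to right, skipping window `i` when
#' `counts[i] < S * max_count` (rule 1) or when
#' `(read k-mer count - counts[i]) * m` already exceeds the best distance
#' found (rule 2 — an admissible bound: each missing k-mer costs exactly
#' `m`, so it never discards the true optimum). Surviving windows may
#' abandon their sum once it exceeds the current best. With `S = 0`,
#' rule 2 and abort disabled, the result is identical to
#' [align_exhaustive()].
#'
#' @inheritParams align_exhaustive
#' @return as [align_exhaustive()].
#' @export
align_hash <- function(read, reference, params = align_params()) {
  read <- clean_dna(read, "read")
  reference <- clean_dna(reference, "reference")
  check_read_ref(read, reference, params)
  if (params$partial_sum_side != "window_to_read") {
    stop("the hash aligner supports only partial_sum_side = 'window_to_read'",
         call. = FALSE)
  }
  align_core(read, reference, params, exhaustive = FALSE)
}

#' Strand-aware alignment with reverse-complement fallback
#'
#' Aligns the forward read; if its minimum distance is at most the
#' internal threshold `T = rc_factor * (L - k + 1) * m` the forward result
#' is returned and the reverse complement is never examined. Otherwise the
#' reverse complement is aligned too and the strand with the smaller
#' minimum distance wins (ties go to the forward strand).
#'
#' @inheritParams align_exhaustive
#' @return as [align_exhaustive()] plus `strand` (`"+"` or `"-"`).
#' @export
align_with_strands <- function(read, reference, params = align_params()) {
  read <- clean_dna(read, "read")
  reference <- clean_dna(reference, "reference")
  check_read_ref(read, reference, params)
  one <- if (params$mode == "hash") align_hash else align_exhaustive
  fwd <- one(read, reference, params)
  n_kmers <- nchar(read) - params$k + 1
  rc_T <- params$rc_factor * n_kmers * params$m
  if (fwd$distance <= rc_T) {
    fwd$strand <- "+"
    return(fwd)
  }
  rev <- one(reverse_complement(read), reference, params)
  if (rev$distance < fwd$distance) {
    rev$strand <- "-"
    rev
  } else {
    fwd$strand <- "+"
    fwd
  }
}

#' Align a set of reads against one or more reference sequences
#'
#' Each read is aligned independently against every reference sequence
#' (strand-aware, per [align_with_strands()]); the reference attaining the
#' smallest minimum distance is reported (ties toward the earlier
#' reference in `references`). Reads never span a boundary between
#' reference sequences.
#'
#' @param reads named character vector of read sequences (names become
#'   `read_id`; unnamed reads are numbered `read1, read2, ...`).
#' @param references named character vector of reference sequences.
#' @param params an [align_params()] object.
#' @return a data.frame with columns `read_id`, `ref_id`, `strand`,
#'   `position` (0-based start, `NA` if unaligned), `lrd` and `aligned`.
#' @export
align_reads <- function(reads, references, params = align_params()) {
  if (is.null(names(reads)) || any(names(reads) == "")) {
    names(reads) <- paste0("read", seq_along(reads))
  }
  if (is.null(names(references)) || any(names(references) == "")) {
    names(references) <- paste0("ref", seq_along(references))
  }
  rows <- lapply(seq_along(reads), function(i) {
    best <- NULL
    best_ref <- NA_character_
    for (rn in names(references)) {
      res <- align_with_strands(reads[[i]], references[[rn]], params)
      if (is.null(best) || res$distance < best$distance) {
        best <- res
        best_ref <- rn
      }
    }
    data.frame(read_id = names(reads)[i], ref_id = best_ref,
               strand = best$strand,
               position = if (best$aligned) best$position else NA_integer_,
               lrd = best$distance, aligned = best$aligned,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
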