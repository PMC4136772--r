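# Nearest-genome scoring and leave-one-out order recovery.
#
# A read set is aligned against every genome of a labelled collection;
# each genome is scored from its aligned reads and the genome with the
# lowest defined score names the predicted order.

#' Score one genome from the alignment results of a read set
#'
#' Let `A` be the subset of reads reported aligned. The default
#' (`method = "literal"`) score is the average minimum distance of the
#' reads in `A` divided once more by `|A|`, i.e.
#' `sum(distances) / |A|^2` — so a genome aligning more reads at the same
#' mean distance scores lower (more similar). `method = "mean"` stops at
#' the plain mean distance. The score is undefined (`NA`) when no read
#' aligns.
#'
#' @param results data.frame with logical `aligned` and numeric `lrd`
#'   columns (one row per read, all against the same genome), e.g. one
#'   genome's slice of an [align_reads()] result.
#' @param method `"literal"` or `"mean"`.
#' @return list with `n_aligned`, `sum_min_dist` and `score` (`NA` when
#'   `n_aligned == 0`).
#' @export
score_genome <- function(results, method = c("literal", "mean")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(results), all(c("aligned", "lrd") %in% names(results)))
  a <- results[results$aligned, , drop = FALSE]
  n <- nrow(a)
  s <- sum(a$lrd)
  score <- if (n == 0L) NA_real_ else if (method == "literal") s / n^2 else s / n
  list(n_aligned = n, sum_min_dist = s, score = score)
}

#' Nearest genome in a labelled collection
#'
#' Aligns every read (strand-aware) against every genome, scores each
#' genome with [score_genome()], and returns the genome with the minimal
#' defined score; ties break to the lexicographically smaller genome id.
#' Genomes with no aligned reads rank strictly last; when no genome aligns
#' any read the prediction is the explicit "no similar genome" outcome
#' (`nearest = NA`).
#'
#' @param reads character vector of read sequences.
#' @param manifest data.frame with columns `genome_id`, `order`,
#'   `sequence` (and optionally `group`, pooling multi-chromosome genomes:
#'   distances and aligned counts are summed across a group before the
#'   final division).
#' @param params an [align_params()] object.
#' @return list with `nearest` (genome or group id, `NA` if none),
#'   `predicted_order` and `scores`, a data.frame of per-genome
#'   `n_aligned`, `sum_min_dist`, `score`.
#' @export
nearest_genome <- function(reads, manifest, params = align_params()) {
  stopifnot(is.data.frame(manifest),
            all(c("genome_id", "order", "sequence") %in% names(manifest)))
  group <- if ("group" %in% names(manifest)) manifest$group else
    manifest$genome_id
  per_genome <- lapply(seq_len(nrow(manifest)), function(i) {
    res <- do.call(rbind, lapply(reads, function(rd) {
      r <- align_with_strands(rd, manifest$sequence[i], params)
      data.frame(aligned = r$aligned, lrd = r$distance)
    }))
    a <- res[res$aligned, , drop = FALSE]
    data.frame(genome_id = manifest$genome_id[i], group = group[i],
               order = manifest$order[i], n_aligned = nrow(a),
               sum_min_dist = sum(a$lrd), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_genome)
  # pool by group, then apply the final division
  agg <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    n <- sum(d$n_aligned); s <- sum(d$sum_min_dist)
    score <- if (n == 0L) NA_real_ else if (params$score_method == "literal")
      s / n^2 else s / n
    data.frame(group = d$group[1L], order = d$order[1L], n_aligned = n,
               sum_min_dist = s, score = score, stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$group), , drop = FALSE]
  rownames(agg) <- NULL
  defined <- which(!is.na(agg$score))
  if (length(defined) == 0L) {
    return(list(nearest = NA_character_, predicted_order = NA_character_,
                scores = agg))
  }
  best <- defined[order(agg$score[defined], agg$group[defined])][1L]
  list(nearest = agg$group[best], predicted_order = agg$order[best],
       scores = agg)
}

#' Leave-one-out order recovery over a genome collection
#'
#' Each genome in turn plays the unknown organism: a read set is simulated
#' from it, scored against all remaining genomes, and the order of the
#' nearest genome is the prediction. Accuracy is reported as
#' `correct / total`.
#'
#' @param manifest data.frame with columns `genome_id`, `order`,
#'   `sequence` (e.g. from [synth_phylogeny()]); at least 2 genomes and 2
#'   orders.
#' @param sim an [sim_params()] object; `sim$seed` (when set) seeds the
#'   simulation of the i-th read set as `sim$seed + i`.
#' @param params an [align_params()] object.
#' @return list with `predictions` (data.frame: `query`, `true_order`,
#'   `nearest`, `predicted_order`, `correct`), `n_correct`, `n_total` and
#'   `accuracy`.
#' @export
leave_one_out <- function(manifest, sim = sim_params(),
                          params = align_params()) {
  stopifnot(nrow(manifest) >= 2L, length(unique(manifest$order)) >= 2L)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    seed_i <- if (is.null(sim$seed)) NULL else sim$seed + i
    reads <- simulate_reads(manifest$sequence[i], sim,
                            genome_id = manifest$genome_id[i],
                            seed = seed_i)
    pred <- nearest_genome(reads$read, manifest[-i, , drop = FALSE], params)
    data.frame(query = manifest$genome_id[i],
               true_order = manifest$order[i],
               nearest = pred$nearest,
               predicted_order = pred$predicted_order,
               correct = identical(pred$predicted_order, manifest$order[i]),
               stringsAsFactors = FALSE)
  })
  predictions <- do.call(rbind, rows)
  n_correct <- sum(predictions$correct)
  list(predictions = predictions, n_correct = n_correct,
       n_total = nrow(predictions),
       accuracy = n_correct / nrow(predictions))
}
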