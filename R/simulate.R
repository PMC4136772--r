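# wgsim-style read simulation and synthetic genome collections.
#
# All randomness flows through R's RNG; every top-level generator takes an
# optional seed so outputs are bit-reproducible.

#' Read-simulation parameter set
#'
#' Defaults follow wgsim's published defaults: per-base sequencing error
#' 0.02, per-base genome mutation 0.001, 15% of mutations are indels,
#' indel extension probability 0.30, 100 bp reads.
#'
#' @param error_rate per-base sequencing error probability (substitutions
#'   only, as in wgsim).
#' @param mutation_rate per-base genome mutation probability.
#' @param indel_fraction fraction of mutations that are indels (the rest
#'   are SNPs).
#' @param indel_extend probability of extending an indel by one base.
#' @param read_length read length in bases.
#' @param n_reads number of reads to simulate.
#' @param rc_fraction fraction of reads emitted as reverse complements,
#'   applied as an exact count (`round(rc_fraction * n_reads)` reads), not
#'   a per-read coin.
#' @param seed optional integer seed.
#' @return an object of class `"lrd_sim_params"`.
#' @export
sim_params <- function(error_rate = 0.02, mutation_rate = 0.001,
                       indel_fraction = 0.15, indel_extend = 0.30,
                       read_length = 100, n_reads = 1000,
                       rc_fraction = 0.5, seed = NULL) {
  probs <- c(error_rate, mutation_rate, indel_fraction, indel_extend,
             rc_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1), read_length >= 1, n_reads >= 0)
  structure(list(error_rate = error_rate, mutation_rate = mutation_rate,
                 indel_fraction = indel_fraction,
                 indel_extend = indel_extend,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 rc_fraction = rc_fraction, seed = seed),
            class = "lrd_sim_params")
}

#' @keywords internal
#' @noRd
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Random DNA string
#'
#' Uniform i.i.d. bases over `{A,C,G,T}`.
#'
#' @param length genome length.
#' @param seed optional integer seed.
#' @return a DNA string.
#' @export
random_genome <- function(length, seed = NULL) {
  maybe_seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Mutate a genome at a given per-base rate
#'
#' Each base independently mutates with probability
#' `params$mutation_rate`. A mutation is a SNP (substitution to a
#' uniformly chosen different base) with probability
#' `1 - indel_fraction`, otherwise an indel (insertion or deletion with
#' equal odds) whose length is geometric with continuation probability
#' `indel_extend`.
#'
#' @param genome a DNA string.
#' @param params an [sim_params()] object (fields `mutation_rate`,
#'   `indel_fraction`, `indel_extend` are used).
#' @param seed optional integer seed (defaults to `params$seed`).
#' @return list with `sequence` (the mutated genome) and `log`, a
#'   data.frame of `(position, type, ref, alt)` with 0-based positions.
#' @export
mutate_genome <- function(genome, params = sim_params(), seed = params$seed) {
  genome <- clean_dna(genome, "genome")
  maybe_seed(seed)
  bases <- strsplit(genome, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  hit <- which(runif(n) < params$mutation_rate)
  out <- as.list(bases)
  dropped <- rep(FALSE, n)
  log_rows <- list()
  alphabet <- c("A", "C", "G", "T")
  for (i in hit) {
    if (dropped[i]) next # position consumed by an earlier deletion
    if (runif(1) >= params$indel_fraction) {
      alt <- sample(setdiff(alphabet, bases[i]), 1L)
      out[[i]] <- alt
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(position = i - 1L, type = "snp", ref = bases[i],
                   alt = alt, stringsAsFactors = FALSE)
    } else {
      len <- 1L + rgeom(1L, prob = 1 - params$indel_extend)
      if (runif(1) < 0.5) { # insertion after base i
        ins <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
        out[[i]] <- paste0(out[[i]], ins)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(position = i - 1L, type = "ins", ref = bases[i],
                     alt = paste0(bases[i], ins), stringsAsFactors = FALSE)
      } else { # deletion of bases i .. i+len-1
        del_to <- min(n, i + len - 1L)
        dropped[i:del_to] <- TRUE
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(position = i - 1L, type = "del",
                     ref = paste(bases[i:del_to], collapse = ""), alt = "",
                     stringsAsFactors = FALSE)
      }
    }
  }
  keep <- !dropped
  seq_out <- paste(unlist(out[keep]), collapse = "")
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(position = integer(), type = character(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  list(sequence = seq_out, log = log)
}

#' @keywords internal
#' @noRd
apply_sequencing_errors <- function(read, error_rate) {
  if (error_rate <= 0) return(read)
  bases <- strsplit(read, "", fixed = TRUE)[[1L]]
  err <- which(runif(length(bases)) < error_rate & bases != "N")
  for (i in err) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate reads from a genome with ground-truth coordinates
#'
#' Read start positions are uniform over the genome (no wrap-around; the
#' circularity of e.g. mtDNA is ignored). Sequencing errors are
#' substitutions applied at `error_rate` per base. An exact count
#' `round(rc_fraction * n_reads)` of reads is emitted reverse-complemented
#' with strand `"-"`; `truth` always stores the forward genome substring,
#' so the per-read error count is `hamming_distance(read, truth)` for
#' forward reads and `hamming_distance(reverse_complement(read), truth)`
#' for reverse ones.
#'
#' @param genome a DNA string of length at least `params$read_length`.
#' @param params an [sim_params()] object.
#' @param genome_id label recorded in the output.
#' @param seed optional integer seed (defaults to `params$seed`).
#' @return a data.frame with columns `read_id`, `read`, `genome_id`,
#'   `start` (0-based), `strand` and `truth`.
#' @export
simulate_reads <- function(genome, params = sim_params(),
                           genome_id = "genome", seed = params$seed) {
  genome <- clean_dna(genome, "genome")
  L <- params$read_length
  if (nchar(genome) < L) stop("genome shorter than read length", call. = FALSE)
  maybe_seed(seed)
  n <- params$n_reads
  if (n == 0L) {
    return(data.frame(read_id = character(), read = character(),
                      genome_id = character(), start = integer(),
                      strand = character(), truth = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- sample.int(nchar(genome) - L + 1L, n, replace = TRUE) - 1L
  truth <- substring(genome, starts + 1L, starts + L)
  reads <- vapply(truth, apply_sequencing_errors, character(1L),
                  error_rate = params$error_rate, USE.NAMES = FALSE)
  n_rc <- round(params$rc_fraction * n)
  rc_idx <- if (n_rc > 0) sample.int(n, n_rc) else integer()
  strand <- rep("+", n)
  strand[rc_idx] <- "-"
  for (i in rc_idx) reads[i] <- reverse_complement(reads[i])
  data.frame(read_id = sprintf("%s_read%04d", genome_id, seq_len(n)),
             read = reads, genome_id = genome_id, start = starts,
             strand = strand, truth = truth, stringsAsFactors = FALSE)
}

#' Synthetic labelled genome collection (orders of related genomes)
#'
#' Emulates a collection such as a set of mammalian mitochondrial genomes
#' grouped by taxonomic order: a single random root genome diverges into
#' one ancestor per order at `between_divergence`, and each order's
#' members diverge from their ancestor at `within_divergence`.
#'
#' @param n_orders number of orders.
#' @param genomes_per_order members per order.
#' @param genome_length length of the root genome.
#' @param within_divergence per-base mutation rate within an order.
#' @param between_divergence per-base mutation rate separating orders from
#'   the root; must exceed `within_divergence`.
#' @param indel_fraction,indel_extend indel model passed to
#'   [mutate_genome()].
#' @param seed optional integer seed.
#' @return a data.frame manifest with columns `genome_id`, `order` and
#'   `sequence`.
#' @export
synth_phylogeny <- function(n_orders, genomes_per_order, genome_length,
                            within_divergence, between_divergence,
                            indel_fraction = 0.15, indel_extend = 0.30,
                            seed = NULL) {
  if (between_divergence <= within_divergence) {
    stop("between_divergence must exceed within_divergence", call. = FALSE)
  }
  maybe_seed(seed)
  root <- random_genome(genome_length)
  p_between <- sim_params(mutation_rate = between_divergence,
                          indel_fraction = indel_fraction,
                          indel_extend = indel_extend)
  p_within <- sim_params(mutation_rate = within_divergence,
                         indel_fraction = indel_fraction,
                         indel_extend = indel_extend)
  rows <- list()
  for (o in seq_len(n_orders)) {
    ancestor <- mutate_genome(root, p_between, seed = NULL)$sequence
    for (g in seq_len(genomes_per_order)) {
      member <- if (within_divergence > 0) {
        mutate_genome(ancestor, p_within, seed = NULL)$sequence
      } else {
        ancestor
      }
      rows[[length(rows) + 1L]] <-
        data.frame(genome_id = sprintf("order%02d_genome%02d", o, g),
                   order = sprintf("order%02d", o), sequence = member,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mix target and contaminant reads with truth labels
#'
#' Simulates `n_target` reads from the target genome (label `positive`)
#' and `n_contaminant` reads split evenly across the contaminant genomes
#' (label `negative`), then shuffles the pooled set.
#'
#' @param target_genome DNA string the positive reads come from.
#' @param contaminant_genomes named list or character vector of
#'   contaminant genomes.
#' @param n_target,n_contaminant read counts; `n_contaminant` must be
#'   divisible by the number of contaminants.
#' @param params an [sim_params()] object.
#' @param seed optional integer seed (defaults to `params$seed`).
#' @return a [simulate_reads()]-style data.frame with an extra `label`
#'   column (`"positive"`/`"negative"`).
#' @export
contamination_mix <- function(target_genome, contaminant_genomes,
                              n_target, n_contaminant,
                              params = sim_params(), seed = params$seed) {
  maybe_seed(seed)
  contaminant_genomes <- as.list(contaminant_genomes)
  if (is.null(names(contaminant_genomes)) && length(contaminant_genomes)) {
    names(contaminant_genomes) <-
      paste0("contaminant", seq_along(contaminant_genomes))
  }
  if (n_contaminant > 0 && length(contaminant_genomes) == 0L) {
    stop("no contaminant genomes supplied", call. = FALSE)
  }
  if (length(contaminant_genomes) &&
      n_contaminant %% length(contaminant_genomes) != 0L) {
    stop("n_contaminant must split evenly across contaminants", call. = FALSE)
  }
  pt <- params; pt$n_reads <- as.integer(n_target)
  pool <- simulate_reads(target_genome, pt, genome_id = "target", seed = NULL)
  pool$label <- rep("positive", nrow(pool))
  per <- if (length(contaminant_genomes)) {
    n_contaminant %/% length(contaminant_genomes)
  } else 0L
  for (nm in names(contaminant_genomes)) {
    pc <- params; pc$n_reads <- as.integer(per)
    neg <- simulate_reads(contaminant_genomes[[nm]], pc, genome_id = nm,
                          seed = NULL)
    neg$label <- rep("negative", nrow(neg))
    pool <- rbind(pool, neg)
  }
  pool[sample.int(nrow(pool)), , drop = FALSE]
}
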