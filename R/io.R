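# Readers and writers: FASTA/FASTQ via Biostrings, alignment TSV, a
# minimal SAM dialect, manifest and truth tables.

#' Read a FASTA file
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named character vector of uppercased sequences; empty files
#'   yield an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(setNames(character(), character()))
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

#' Read a FASTQ file (qualities discarded)
#'
#' @param path path to a FASTQ file.
#' @return named character vector of uppercased sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(setNames(character(), character()))
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                  error = function(e) {
                    stop("malformed FASTQ '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write sequences to FASTQ with constant placeholder qualities
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fastq <- function(sequences, path) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("read", seq_along(sequences))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(c(paste0("@", names(sequences)[i]), sequences[[i]], "+",
                 strrep("I", nchar(sequences[[i]]))), con)
  }
  invisible(path)
}

#' Write alignment results as TSV or minimal SAM
#'
#' TSV columns: `read_id`, `ref_id`, `strand`, `position_0based`, `lrd`,
#' `aligned` (0/1). The SAM dialect carries `@HD`/`@SQ` headers, FLAG 0
#' (forward), 16 (reverse) or 4 (unaligned), 1-based POS (0 and RNAME `*`
#' when unaligned), CIGAR `<L>M` for aligned reads and `*` otherwise, and
#' the minimum LRD in the `ld:i` optional tag. Reverse-strand SEQ is
#' stored reverse-complemented, per SAM convention.
#'
#' @param results an [align_reads()]-style data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"sam"`.
#' @param reads named character vector of read sequences (required for
#'   SAM).
#' @param references named character vector of reference sequences
#'   (required for SAM headers).
#' @export
write_alignments <- function(results, path, format = c("tsv", "sam"),
                             reads = NULL, references = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(read_id = results$read_id, ref_id = results$ref_id,
                      strand = results$strand,
                      position_0based = results$position,
                      lrd = results$lrd,
                      aligned = as.integer(results$aligned))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(reads) || is.null(references)) {
    stop("SAM output needs the read and reference sequences", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (rn in names(references)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, nchar(references[[rn]])), con)
  }
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    seq_out <- reads[[r$read_id]]
    if (!r$aligned) {
      line <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*\tld:i:%d",
                      r$read_id, seq_out, as.integer(r$lrd))
    } else {
      flag <- if (r$strand == "-") 16L else 0L
      if (r$strand == "-") seq_out <- reverse_complement(seq_out)
      line <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tld:i:%d",
                      r$read_id, flag, r$ref_id, r$position + 1L,
                      nchar(seq_out), seq_out, as.integer(r$lrd))
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a genome-collection manifest
#'
#' Tab-separated columns `genome_id`, `order_label`, `group_id`,
#' `fasta_path` (header optional). Each FASTA is loaded; multi-record
#' files contribute one manifest row per record, all sharing the genome's
#' group id.
#'
#' @param path manifest TSV path.
#' @param base_dir directory FASTA paths are resolved against (defaults to
#'   the manifest's directory).
#' @return data.frame with columns `genome_id`, `order`, `group`,
#'   `sequence`.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 4L) {
    stop("manifest must have 4 tab-separated columns: ",
         "genome_id, order_label, group_id, fasta_path", call. = FALSE)
  }
  names(tab) <- c("genome_id", "order", "group", "fasta_path")
  if (identical(tolower(tab$genome_id[1L]), "genome_id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    fp <- tab$fasta_path[i]
    if (!file.exists(fp)) fp <- file.path(base_dir, tab$fasta_path[i])
    seqs <- read_fasta(fp)
    ids <- if (length(seqs) == 1L) tab$genome_id[i] else
      paste0(tab$genome_id[i], "_", names(seqs))
    data.frame(genome_id = ids, order = tab$order[i], group = tab$group[i],
               sequence = unname(seqs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read simulated-read truth tables
#'
#' Tab-separated columns `read_id`, `genome_id`, `start_0based`, `strand`.
#'
#' @param sim_reads a [simulate_reads()]-style data.frame.
#' @param path TSV path.
#' @export
write_truth <- function(sim_reads, path) {
  out <- data.frame(read_id = sim_reads$read_id,
                    genome_id = sim_reads$genome_id,
                    start_0based = sim_reads$start,
                    strand = sim_reads$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
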