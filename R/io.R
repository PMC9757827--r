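#' Read / write a signal table
#'
#' The signal table is a simple two-column tab-separated text format standing
#' in for raw-signal containers: `read_id` and the read's raw current samples
#' as a comma-separated list of picoamp values.
#'
#' @param path File path.
#' @return `read_signal_table()` returns a named list of numeric vectors
#'   (one per read); `write_signal_table()` returns `path` invisibly.
#' @export
read_signal_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character"))
  if (anyDuplicated(tab$read_id)) abort("duplicate read_id in signal table")
  sig <- map(strsplit(tab$samples, ","), as.numeric)
  if (any(lengths(sig) < 1)) abort("every read needs >= 1 sample")
  setNames(sig, tab$read_id)
}

#' @rdname read_signal_table
#' @param signals Named list of numeric sample vectors.
#' @export
write_signal_table <- function(signals, path) {
  stopifnot(!is.null(names(signals)), !anyDuplicated(names(signals)))
  lines <- c("read_id\tsamples",
             sprintf("%s\t%s", names(signals),
                     map_chr(signals, ~ paste(sprintf("%.3f", .x),
                                              collapse = ","))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Join reads, alignments, reference and signals into a read table
#'
#' Reads the FASTQ (plain or gzip), the BAM, the reference FASTA and the
#' signal table, and joins them by read name. Only primary mapped alignment
#' records are used; unmapped, secondary and supplementary records are
#' skipped and counted. Reads present in the FASTQ but missing from the
#' signal table (or without a BAM record) are skipped with a warning count.
#'
#' @param reads_path FASTQ(.gz) of basecalled reads.
#' @param bam_path BAM of read-to-reference alignments.
#' @param ref_path Reference FASTA.
#' @param signals_path Signal table (see [read_signal_table()]).
#' @return A tibble of reads — `read_id`, `sequence`, `signal` (list column),
#'   `mapped_chrom`, `mapped_start` (0-based), `mapped_strand` — with the
#'   reference attached as attribute `reference` and skip counters as
#'   attribute `counters`.
#' @export
read_inputs <- function(reads_path, bam_path, ref_path, signals_path) {
  fq <- Biostrings::readDNAStringSet(reads_path, format = "fastq")
  seqs <- setNames(as.character(fq), sub("\\s.*$", "", names(fq)))
  signals <- read_signal_table(signals_path)
  reference <- read_fasta(ref_path)

  bam <- Rsamtools::scanBam(
    bam_path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos")))[[1]]
  flag <- bam$flag
  primary <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  n_skipped_alignments <- sum(!primary)
  aln <- tibble(read_id = bam$qname[primary],
                mapped_chrom = as.character(bam$rname[primary]),
                mapped_start = bam$pos[primary] - 1L,  # 0-based
                mapped_strand = as.character(bam$strand[primary]))
  aln <- aln[!duplicated(aln$read_id), ]

  ids <- names(seqs)
  no_aln <- setdiff(ids, aln$read_id)
  no_sig <- setdiff(intersect(ids, aln$read_id), names(signals))
  if (length(no_sig) > 0) {
    warn(sprintf("%d read(s) present in FASTQ but absent from signal table; skipped",
                 length(no_sig)))
  }
  keep <- intersect(intersect(ids, aln$read_id), names(signals))
  out <- tibble(read_id = keep,
                sequence = unname(seqs[keep]),
                signal = unname(signals[keep]))
  out <- dplyr::left_join(out, aln, by = "read_id")
  attr(out, "reference") <- reference
  attr(out, "counters") <- c(n_fastq = length(ids),
                             n_no_alignment = length(no_aln),
                             n_no_signal = length(no_sig),
                             n_skipped_alignments = n_skipped_alignments,
                             n_used = length(keep))
  out
}

calls_tsv_header <- c("chromosome", "strand", "start", "end", "read_name",
                      "log_lik_ratio", "log_lik_methylated",
                      "log_lik_unmethylated", "num_calling_strands",
                      "num_motifs", "sequence")

#' Write methylation calls as tab-separated text
#'
#' Column layout follows the conventional read-level call table:
#' `chromosome`, `strand`, `start`, `end`, `read_name`, `log_lik_ratio`,
#' `log_lik_methylated`, `log_lik_unmethylated`, `num_calling_strands`
#' (constant 1), `num_motifs`, `sequence`. Log-likelihoods are printed with
#' fixed two-decimal formatting, so identical calls produce byte-identical
#' files.
#'
#' @param calls A tibble of methylation calls (see [score_cpg_group()]),
#'   ordered by (chrom, start, read_name).
#' @param path Output file path.
#' @return The number of data rows written, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  header <- paste(calls_tsv_header, collapse = "\t")
  if (is.null(calls) || nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(0L))
  }
  rows <- sprintf("%s\t%s\t%d\t%d\t%s\t%.2f\t%.2f\t%.2f\t%d\t%d\t%s",
                  calls$chrom, calls$strand, calls$start, calls$end,
                  calls$read_name, calls$log_lik_ratio,
                  calls$log_lik_methylated, calls$log_lik_unmethylated,
                  1L, calls$num_motifs, calls$sequence)
  writeLines(c(header, rows), path)
  invisible(length(rows))
}

#' Read a methylation call table written by [write_calls_tsv()]
#'
#' @param path File path.
#' @return A tibble with the written columns.
#' @export
read_calls_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "integer", "character", "numeric",
                                   "numeric", "numeric", "integer",
                                   "integer", "character"))
  as_tibble(tab)
}
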