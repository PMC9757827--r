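#' Methylated haplotype of a DNA sequence
#'
#' Replaces every cytosine in CpG context (a `C` immediately followed by `G`)
#' with the methylated base symbol `M`. All other bases are unchanged; the
#' output has the same length as the input.
#'
#' @param sequence A character scalar over `{A,C,G,T}`.
#' @return A character scalar over `{A,C,G,T,M}`.
#' @export
#' @examples
#' make_methylated_haplotype("ACGT") # "AMGT"
make_methylated_haplotype <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  bad <- str_replace_all(sequence, "[ACGT]", "")
  if (nchar(bad) > 0) {
    abort(sprintf(
      "sequence contains non-ACGT character(s): %s",
      paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")
    ))
  }
  str_replace_all(sequence, "CG", "MG")
}

#' Reverse complement
#'
#' @param sequence A character scalar over `{A,C,G,T}`.
#' @return The reverse complement, as a character scalar.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Group nearby CpG sites
#'
#' Scans a reference window for CG dinucleotides and merges sites whose start
#' positions are at most `group_distance` apart into one group. Each group is
#' scored jointly with one HMM matrix; its scored sequence spans the first CG
#' minus `flank` to one past the last CG plus `flank`, clipped to the window.
#'
#' @param ref_window A character scalar over `{A,C,G,T}` (forward strand).
#' @param window_start 0-based reference position of the window's first base.
#' @param group_distance Maximum distance (bp) between the start positions of
#'   CG sites merged into one group.
#' @param flank Flanking bases (bp) added on each side of the scored window;
#'   the default `k - 1` for `k = 6` keeps every k-mer overlapping a CpG
#'   inside the scored window.
#' @param chrom Chromosome name recorded on each group.
#' @param strand Strand recorded on each group.
#' @param k K-mer length; windows shorter than `k` yield no groups.
#'
#' @return A tibble with one row per group: `chrom`, `strand`, `group_start`,
#'   `group_end` (0-based reference positions of the first/last CG),
#'   `num_motifs`, `seq_start` (0-based reference position of the scored
#'   sequence) and `sequence`. Groups are disjoint and ordered.
#' @export
group_cpg_sites <- function(ref_window, window_start = 0, group_distance = 10,
                            flank = 5, chrom = "", strand = "+", k = 6) {
  stopifnot(group_distance >= 0, flank >= 0, window_start >= 0)
  empty <- tibble(chrom = character(), strand = character(),
                  group_start = integer(), group_end = integer(),
                  num_motifs = integer(), seq_start = integer(),
                  sequence = character())
  n <- nchar(ref_window)
  if (n < k) return(empty)
  loc <- str_locate_all(ref_window, "CG")[[1]]
  if (nrow(loc) == 0) return(empty)
  starts0 <- loc[, 1] - 1L  # 0-based offsets within the window
  new_group <- c(TRUE, diff(starts0) > group_distance)
  gid <- cumsum(new_group)
  first <- tapply(starts0, gid, min)
  last <- tapply(starts0, gid, max)
  seq_from <- pmax(0L, as.integer(first) - as.integer(flank))
  seq_to <- pmin(n, as.integer(last) + 2L + as.integer(flank))  # exclusive
  tibble(
    chrom = chrom,
    strand = strand,
    group_start = as.integer(first) + as.integer(window_start),
    group_end = as.integer(last) + as.integer(window_start),
    num_motifs = as.integer(tabulate(gid)),
    seq_start = seq_from + as.integer(window_start),
    sequence = str_sub(ref_window, seq_from + 1L, seq_to)
  )
}
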