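#' Simulation configuration
#'
#' Defines the generative conditions for the synthetic fixtures: a random
#' reference with planted CpG sites, reads mapped onto it, and event-level
#' signal drawn from the same stay/skip/bad-event structure and Gaussian
#' k-mer emissions the scoring HMM assumes.
#'
#' @param seed RNG seed (all outputs are byte-deterministic given the seed).
#' @param n_reads Number of simulated reads.
#' @param read_length Read length (bp).
#' @param ref_length Reference length (bp).
#' @param cpg_density Per-bp probability of planting a CG dinucleotide.
#' @param methylation_rate Probability that a CpG group is methylated on a
#'   given read (drawn per read x group; sites within a group share state).
#' @param p_stay,p_skip,p_bad Generative rates of extra events per k-mer,
#'   skipped k-mers, and injected outlier events.
#' @param noise_sd Standard deviation (pA) of event means around the scaled
#'   model level, and of per-sample noise within an event.
#' @param m_shift Emission-mean offset (pA) of M-containing k-mers in the
#'   synthetic pore model.
#' @param shift,scale,var True per-read scaling applied by the generator.
#' @param frac_reverse Fraction of reads simulated on the reverse strand.
#' @param event_len_min,event_len_lambda Event lengths are
#'   `event_len_min + Poisson(event_len_lambda)` samples (mean ~8 by
#'   default).
#' @param chrom Reference sequence name.
#' @param group_distance,flank CpG grouping parameters (see
#'   [group_cpg_sites()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42, n_reads = 50, read_length = 2000,
                       ref_length = 10000, cpg_density = 0.02,
                       methylation_rate = 0.5, p_stay = 0.1, p_skip = 0.01,
                       p_bad = 0.01, noise_sd = 1.0, m_shift = 4.0,
                       shift = 10.0, scale = 1.2, var = 1.0,
                       frac_reverse = 0.2, event_len_min = 3,
                       event_len_lambda = 5, chrom = "chrSim",
                       group_distance = 10, flank = 5) {
  stopifnot(p_stay >= 0, p_stay < 1, p_skip >= 0, p_skip <= 1,
            p_bad >= 0, p_bad <= 1, noise_sd >= 0, methylation_rate >= 0,
            methylation_rate <= 1, cpg_density >= 0, cpg_density <= 0.5,
            read_length <= ref_length, scale > 0, var > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference sequence with planted CpG sites
#'
#' Draws a random ACGT sequence, removes accidental CG dinucleotides, then
#' plants CG sites independently with probability `cpg_density` per position
#' (overlapping plants are dropped), so the CG count is binomial at the
#' requested density.
#'
#' @param config A [sim_config()].
#' @return A list: `sequences` (named character, one chromosome), `sites`
#'   (0-based CG start positions) and `chrom`.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$ref_length
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # Remove accidental CGs (replacing the C cannot create a new CG).
  repeat {
    cg <- which(bases[-L] == "C" & bases[-1] == "G")
    if (length(cg) == 0) break
    bases[cg] <- "A"
  }
  planted <- which(runif(L - 1) < config$cpg_density)
  if (length(planted) > 1) {
    keep <- c(TRUE, diff(planted) > 1)
    planted <- planted[keep]
  }
  bases[planted] <- "C"
  bases[planted + 1] <- "G"
  seq <- paste(bases, collapse = "")
  sites <- str_locate_all(seq, "CG")[[1]][, 1] - 1L
  list(sequences = setNames(seq, config$chrom),
       sites = as.integer(sites), chrom = config$chrom)
}

# Apply M substitution at given 0-based C offsets of a window.
methylate_at <- function(window, offsets0) {
  if (length(offsets0) == 0) return(window)
  ch <- strsplit(window, "")[[1]]
  stopifnot(all(ch[offsets0 + 1] == "C"))
  ch[offsets0 + 1] <- "M"
  paste(ch, collapse = "")
}

#' Simulate the event stream and raw signal of one read window
#'
#' Walks the k-mers of the (possibly methylated) window haplotype left to
#' right. Each k-mer is skipped with probability `p_skip`; otherwise it emits
#' `1 + Geometric(p_stay)` events whose means are Normal around the scaled
#' model level with `noise_sd`; with probability `p_bad` a uniform-outlier
#' event is appended. Methylated CpG k-mers use the M-substituted model
#' entry. The raw signal concatenates per-event constant segments plus
#' per-sample Gaussian noise. Uses the current RNG state (seed once at a
#' higher level).
#'
#' @param ref_window Forward-strand ACGT window sequence.
#' @param meth_flags Logical vector, one per CG site in the window (in
#'   forward order): is that site methylated on this read?
#' @param model A [pore_model()].
#' @param config A [sim_config()].
#' @param strand `"+"` or `"-"`; reverse reads traverse the reverse
#'   complement of the window (CpG methylation re-applied on the reverse
#'   complement).
#' @return A list: `events` (truth tibble with `start_sample`, `length`,
#'   `mean`, `stdv`, `kmer_index`, `bad`), `signal` (numeric samples),
#'   `haplotype` (the emitted k-mer source string).
#' @export
simulate_read_signal <- function(ref_window, meth_flags, model,
                                 config = sim_config(), strand = "+") {
  k <- model_k(model)
  L <- nchar(ref_window)
  stopifnot(L >= k)
  sites0 <- str_locate_all(ref_window, "CG")[[1]][, 1] - 1L
  stopifnot(length(meth_flags) == length(sites0))
  if (identical(strand, "-")) {
    window <- revcomp(ref_window)
    sites0 <- L - 2L - sites0  # CG is its own reverse complement
    ord <- order(sites0)
    sites0 <- sites0[ord]
    meth_flags <- meth_flags[ord]
  } else {
    window <- ref_window
  }
  hap <- methylate_at(window, sites0[meth_flags])

  kmers <- seq_kmers(hap, k)
  K <- length(kmers)
  mu <- model_lookup(model, kmers)$level_mean
  scaled_mu <- config$scale * mu + config$shift

  skipped <- runif(K) < config$p_skip
  n_ev <- ifelse(skipped, 0L,
                 1L + if (config$p_stay > 0) rgeom(K, 1 - config$p_stay)
                      else integer(K))
  bad <- runif(K) < config$p_bad
  per_kmer <- n_ev + as.integer(bad)
  total <- sum(per_kmer)
  if (total == 0) {  # degenerate; force one event from the first k-mer
    n_ev[1] <- 1L
    per_kmer <- n_ev + as.integer(bad)
    total <- sum(per_kmer)
  }
  kmer_idx <- rep.int(seq_len(K), per_kmer)
  within <- sequence(per_kmer)
  is_bad <- bad[kmer_idx] & within == per_kmer[kmer_idx]
  means <- numeric(total)
  n_good <- sum(!is_bad)
  means[!is_bad] <- rnorm(n_good, scaled_mu[kmer_idx[!is_bad]],
                          config$noise_sd)
  if (any(is_bad)) {
    lo <- min(scaled_mu) - 20
    hi <- max(scaled_mu) + 20
    means[is_bad] <- runif(sum(is_bad), lo, hi)
  }
  lens <- config$event_len_min + rpois(total, config$event_len_lambda)
  starts <- cumsum(c(1L, lens[-total]))
  signal <- rep.int(means, lens)
  if (config$noise_sd > 0) {
    signal <- signal + rnorm(length(signal), 0, config$noise_sd)
  }
  list(
    events = tibble(start_sample = as.integer(starts),
                    length = as.integer(lens), mean = means,
                    stdv = rep(config$noise_sd, total),
                    kmer_index = kmer_idx, bad = is_bad),
    signal = signal,
    haplotype = hap
  )
}

#' Simulate a full read set with per-CpG methylation truth
#'
#' Places reads uniformly on the reference, draws a methylation state per
#' (read, CpG group) at `methylation_rate` (sites within a group share the
#' state, mimicking locally coherent CpG methylation), and generates each
#' read's event stream and raw signal with [simulate_read_signal()].
#'
#' @param reference Output of [simulate_reference()].
#' @param model A [pore_model()].
#' @param config A [sim_config()].
#' @return A list: `reads` (tibble with `read_id`, `sequence` (read
#'   orientation, ACGT), `signal` list column, `true_events` list column,
#'   `mapped_chrom`, `mapped_start`, `mapped_strand`) and `truth` (tibble
#'   `chrom`, `cpg_position` (0-based), `read_id`, `methylated`).
#' @export
simulate_reads <- function(reference, model, config = sim_config()) {
  set.seed(config$seed + 1L)
  ref_seq <- reference$sequences[[1]]
  L_ref <- nchar(ref_seq)
  n <- config$n_reads
  starts0 <- if (n > 0) {
    sample.int(L_ref - config$read_length + 1L, n, replace = TRUE) - 1L
  } else integer(0)
  strands <- ifelse(runif(n) < config$frac_reverse, "-", "+")
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    window <- str_sub(ref_seq, starts0[i] + 1L,
                      starts0[i] + config$read_length)
    sites0 <- str_locate_all(window, "CG")[[1]][, 1] - 1L
    if (length(sites0) > 0) {
      gid <- cumsum(c(TRUE, diff(sites0) > config$group_distance))
      gflag <- runif(max(gid)) < config$methylation_rate
      flags <- gflag[gid]
    } else {
      flags <- logical(0)
    }
    sim <- simulate_read_signal(window, flags, model, config,
                                strand = strands[i])
    rid <- sprintf("read_%04d", i)
    rows[[i]] <- tibble(
      read_id = rid,
      sequence = if (strands[i] == "-") revcomp(window) else window,
      signal = list(sim$signal),
      true_events = list(sim$events),
      mapped_chrom = reference$chrom,
      mapped_start = starts0[i],
      mapped_strand = strands[i]
    )
    truth[[i]] <- if (length(sites0) > 0) {
      tibble(chrom = reference$chrom,
             cpg_position = as.integer(sites0 + starts0[i]),
             read_id = rid, methylated = flags)
    } else NULL
  }
  reads_proto <- tibble(read_id = character(), sequence = character(),
                        signal = list(), true_events = list(),
                        mapped_chrom = character(), mapped_start = integer(),
                        mapped_strand = character())
  truth_proto <- tibble(chrom = character(), cpg_position = integer(),
                        read_id = character(), methylated = logical())
  list(reads = bind_rows(reads_proto, rows),
       truth = bind_rows(truth_proto, truth))
}

#' Write a complete synthetic fixture set
#'
#' Generates a reference, reads, signals and truth under `config` and writes
#' them as: `ref.fa` (FASTA), `reads.fastq.gz` (gzip FASTQ), `reads.bam`
#' (BAM with primary alignments), `signals.tsv` (signal table) and
#' `truth.tsv` (per-site methylation truth). Every byte is determined by
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if missing).
#' @param model A [pore_model()]; defaults to the synthetic model at
#'   `config$m_shift`.
#' @return A manifest tibble: `file`, `path`, `md5`, `bytes`.
#' @export
emit_fixture_set <- function(config = sim_config(), out_dir,
                             model = synthetic_pore_model(
                               m_shift = config$m_shift)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  sim <- simulate_reads(reference, model, config)
  reads <- sim$reads

  ref_path <- file.path(out_dir, "ref.fa")
  refset <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(refset, ref_path)

  fq_path <- file.path(out_dir, "reads.fastq.gz")
  fq <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  quals <- Biostrings::BStringSet(
    map_chr(nchar(reads$sequence), ~ strrep("I", .x)))
  Biostrings::writeXStringSet(fq, fq_path, format = "fastq",
                              qualities = quals, compress = TRUE)

  bam_path <- file.path(out_dir, "reads.bam")
  sam_path <- file.path(out_dir, "reads.sam")
  L_ref <- nchar(reference$sequences[[1]])
  sam_seq <- ifelse(reads$mapped_strand == "-",
                    map_chr(reads$sequence, revcomp), reads$sequence)
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$chrom, L_ref),
    {
      ord <- order(reads$mapped_start, reads$read_id, method = "radix")
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
              reads$read_id[ord],
              ifelse(reads$mapped_strand[ord] == "-", 16L, 0L),
              reads$mapped_chrom[ord], reads$mapped_start[ord] + 1L,
              nchar(sam_seq[ord]), sam_seq[ord],
              map_chr(nchar(sam_seq[ord]), ~ strrep("I", .x)))
    }
  )
  writeLines(sam, sam_path)
  Rsamtools::asBam(sam_path, destination = sub("\\.bam$", "", bam_path),
                   overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)

  sig_path <- file.path(out_dir, "signals.tsv")
  write_signal_table(setNames(reads$signal, reads$read_id), sig_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  tr <- sim$truth
  writeLines(c("chrom\tcpg_position\tread_id\tmethylated",
               if (nrow(tr) > 0) {
                 sprintf("%s\t%d\t%s\t%d", tr$chrom, tr$cpg_position,
                         tr$read_id, as.integer(tr$methylated))
               }),
             truth_path)

  paths <- c(ref = ref_path, fastq = fq_path, bam = bam_path,
             signals = sig_path, truth = truth_path)
  tibble(file = basename(paths), path = unname(paths),
         md5 = unname(tools::md5sum(paths)),
         bytes = unname(file.size(paths)))
}

#' Read a truth table written by [emit_fixture_set()]
#'
#' @param path File path.
#' @return A tibble with `chrom`, `cpg_position`, `read_id`, `methylated`.
#' @export
read_truth_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "integer"))
  tab$methylated <- tab$methylated == 1L
  as_tibble(tab)
}
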