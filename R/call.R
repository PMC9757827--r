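#' Call CpG methylation on a set of reads
#'
#' Runs the full four-stage workflow over batches of reads under the
#' pipelined executor: (1) event detection from the raw signal; (2) banded
#' alignment of events to the read's k-mer sequence (seeded by a
#' moment-matching scaling estimate); (3) recalibration of the per-read
#' scaling from the alignment; (4) methylation scoring — each CpG group
#' overlapped by the read is scored with the profile HMM against the
#' unmethylated and methylated haplotypes and reported as a log-likelihood
#' ratio.
#'
#' @param reads A tibble of reads as returned by [read_inputs()] or
#'   [simulate_reads()]: `read_id`, `signal` (list column), `mapped_chrom`,
#'   `mapped_start` (0-based), `mapped_strand`.
#' @param reference Named character vector of reference sequences (see
#'   [read_fasta()]); taken from `attr(reads, "reference")` when `NULL`.
#' @param model A [pore_model()].
#' @param trans A [trans_params()].
#' @param config A [pipeline_config()].
#' @param seg A [seg_params()].
#' @param band A [band_params()].
#' @param group_distance,flank CpG grouping parameters.
#' @param engine HMM fill engine, `"serial"` or `"parallel"`.
#' @return A list of class `methylation_result`: `calls` (tibble ordered by
#'   chrom, start, read_name), `trace` (`pipeline_trace`), `failed` (tibble
#'   of failed batches), `counters` (named integer vector), `ok`.
#' @export
call_methylation <- function(reads, reference = NULL, model,
                             trans = trans_params(),
                             config = pipeline_config(),
                             seg = seg_params(), band = band_params(),
                             group_distance = 10, flank = 5,
                             engine = "parallel") {
  if (is.null(reference)) reference <- attr(reads, "reference")
  if (is.null(reference)) abort("a reference is required")
  k <- model_k(model)

  n <- nrow(reads)
  batch_of <- if (n > 0) ((seq_len(n) - 1L) %/% config$batch_size) + 1L
              else integer(0)
  batches <- map(split(seq_len(n), batch_of), ~ reads[.x, , drop = FALSE])
  batches <- unname(batches)

  stage_fns <- make_stage_fns(reference, model, trans, config, seg, band,
                              group_distance, flank, engine)
  run <- run_pipeline(batches, config, stage_fns)

  done <- run$results[!map_lgl(run$results, is.null)]
  calls <- bind_rows(map(done, "calls"))
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$start, calls$read_name, method = "radix")
    calls <- calls[ord, ]
  }
  counters <- c(
    n_reads = n,
    n_batches = length(batches),
    n_failed_batches = nrow(run$failed),
    n_alignment_failures = sum(map_int(done, "n_alignment_failures")),
    n_suppressed_groups = sum(map_int(done, "n_suppressed_groups")),
    n_calls = nrow(calls)
  )
  structure(list(calls = calls, trace = run$trace, failed = run$failed,
                 counters = counters, ok = run$ok),
            class = "methylation_result")
}

# The four per-batch stage closures. Each takes and returns a batch
# workspace (an isolated list), so stages are pure in the executor's sense.
make_stage_fns <- function(reference, model, trans, config, seg, band,
                           group_distance, flank, engine) {
  k <- model_k(model)

  oriented_window <- function(read) {
    chrom_seq <- reference[[read$mapped_chrom]]
    if (is.null(chrom_seq)) {
      abort(sprintf("read %s maps to unknown chromosome %s",
                    read$read_id, read$mapped_chrom))
    }
    window_len <- nchar(read$sequence)
    fwd <- str_sub(chrom_seq, read$mapped_start + 1L,
                   read$mapped_start + window_len)
    list(fwd = fwd,
         oriented = if (read$mapped_strand == "-") revcomp(fwd) else fwd)
  }

  stage1_detect <- function(batch) {
    ws <- list(reads = batch)
    ws$events <- map(batch$signal, ~ detect_events(.x, seg))
    ws
  }

  stage2_align <- function(ws) {
    n <- nrow(ws$reads)
    ws$windows <- vector("list", n)
    ws$alignments <- vector("list", n)
    for (i in seq_len(n)) {
      read <- as.list(ws$reads[i, ])
      win <- oriented_window(read)
      ws$windows[[i]] <- win
      ev <- ws$events[[i]]
      if (nrow(ev) == 0) next
      sc0 <- moment_scaling(ev, win$oriented, model)
      ws$alignments[[i]] <- align_events(ev, win$oriented, model, sc0,
                                         band, trans)
    }
    ws
  }

  stage3_calibrate <- function(ws) {
    n <- nrow(ws$reads)
    ws$scalings <- vector("list", n)
    for (i in seq_len(n)) {
      aln <- ws$alignments[[i]]
      if (is.null(aln)) next
      ws$scalings[[i]] <- calibrate(ws$events[[i]], aln,
                                    ws$windows[[i]]$oriented, model)
    }
    ws
  }

  stage4_score <- function(ws) {
    n <- nrow(ws$reads)
    calls <- vector("list", n)
    n_suppressed <- 0L
    for (i in seq_len(n)) {
      read <- as.list(ws$reads[i, ])
      aln <- ws$alignments[[i]]
      if (is.null(aln)) next
      win <- ws$windows[[i]]
      L <- nchar(win$fwd)
      groups <- group_cpg_sites(win$fwd, window_start = read$mapped_start,
                                group_distance = group_distance,
                                flank = flank, chrom = read$mapped_chrom,
                                strand = read$mapped_strand, k = k)
      if (nrow(groups) == 0) next
      ev <- ws$events[[i]]
      scaling <- ws$scalings[[i]]
      out <- vector("list", nrow(groups))
      for (g in seq_len(nrow(groups))) {
        grp <- as.list(groups[g, ])
        gs_rel <- grp$seq_start - read$mapped_start
        ge_rel <- gs_rel + nchar(grp$sequence)  # exclusive
        if (read$mapped_strand == "-") {
          j_lo <- L - ge_rel + 1L
          j_hi <- L - k - gs_rel + 1L
        } else {
          j_lo <- gs_rel + 1L
          j_hi <- ge_rel - k + 1L
        }
        sel <- aln$event_index[aln$kmer_index >= j_lo &
                               aln$kmer_index <= j_hi]
        if (length(sel) == 0) {
          n_suppressed <- n_suppressed + 1L
          next
        }
        ev_slice <- ev[seq.int(min(sel), max(sel)), , drop = FALSE]
        out[[g]] <- score_cpg_group(grp, ev_slice, model, scaling, trans,
                                    read_name = read$read_id,
                                    engine = engine,
                                    workers = config$threads)
      }
      calls[[i]] <- bind_rows(out)
    }
    list(calls = bind_rows(calls),
         n_alignment_failures = sum(map_lgl(ws$alignments, is.null)),
         n_suppressed_groups = n_suppressed)
  }

  list(stage1_detect, stage2_align, stage3_calibrate, stage4_score)
}

#' @export
print.methylation_result <- function(x, ...) {
  cat(sprintf("<methylation_result> %d call(s) from %d read(s) in %d batch(es)\n",
              x$counters["n_calls"], x$counters["n_reads"],
              x$counters["n_batches"]))
  if (!x$ok) cat(sprintf("  %d failed batch(es)\n", nrow(x$failed)))
  invisible(x)
}

#' One-row summary of a methylation result
#'
#' @param x A `methylation_result`.
#' @param ... Unused.
#' @return A tibble with call counts, the fraction of positive
#'   log-likelihood ratios, and pipeline concurrency.
#' @export
glance.methylation_result <- function(x, ...) {
  tibble(
    n_reads = unname(x$counters["n_reads"]),
    n_calls = unname(x$counters["n_calls"]),
    frac_positive_llr = if (nrow(x$calls) > 0) {
      mean(x$calls$log_lik_ratio > 0)
    } else NA_real_,
    max_concurrency = max_concurrency(x$trace),
    ok = x$ok
  )
}

#' Histogram of read-level log-likelihood ratios
#'
#' @param object A `methylation_result`.
#' @param ... Passed to `geom_histogram()`.
#' @return A ggplot object.
#' @export
autoplot.methylation_result <- function(object, ...) {
  ggplot(object$calls, aes(x = .data$log_lik_ratio)) +
    geom_histogram(bins = 60, ...) +
    labs(x = "log-likelihood ratio (methylated vs unmethylated)",
         y = "CpG-group calls") +
    theme_minimal()
}
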