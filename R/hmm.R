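#' Transition parameters of the methylation-scoring HMM
#'
#' The scoring HMM moves through the k-mers of a haplotype with four kinds of
#' moves: *stay* (another event from the same k-mer), *step* (next event,
#' next k-mer), *bad* (an event unexplained by the model) and *skip* (a k-mer
#' traversed without any event). The step probability is the remainder
#' `1 - p_stay - p_skip - p_bad`. The BAD_EVENT state emits a flat
#' probability `bad_emit` instead of a Gaussian density. The end transition
#' (out of MATCH of the last k-mer) carries `lp_end = log(p_step)` and the
#' begin transition carries `lp_start = 0`.
#'
#' @param p_stay,p_skip,p_bad Move probabilities, each in (0, 1).
#' @param bad_emit Flat emission probability of the BAD_EVENT state.
#' @return A list of class `trans_params` with the probabilities and their
#'   natural logs (`lp_stay`, `lp_step`, `lp_skip`, `lp_bad`, `lp_bad_emit`,
#'   `lp_end`, `lp_start`).
#' @export
trans_params <- function(p_stay = 0.1, p_skip = 0.01, p_bad = 0.01,
                         bad_emit = 0.01) {
  stopifnot(p_stay > 0, p_stay < 1, p_skip > 0, p_skip < 1,
            p_bad > 0, p_bad < 1, bad_emit > 0, bad_emit <= 1)
  p_step <- 1 - p_stay - p_skip - p_bad
  if (p_step <= 0) abort("p_stay + p_skip + p_bad must be < 1")
  structure(list(
    p_stay = p_stay, p_skip = p_skip, p_bad = p_bad, p_step = p_step,
    bad_emit = bad_emit,
    lp_stay = log(p_stay), lp_skip = log(p_skip), lp_bad = log(p_bad),
    lp_step = log(p_step), lp_bad_emit = log(bad_emit),
    lp_end = log(p_step), lp_start = 0
  ), class = "trans_params")
}

#' Per-read scaling parameters
#'
#' Affine calibration mapping pore-model current levels to the scale of an
#' individual read: an event matched to a k-mer with model level `mu` and
#' spread `sigma` is scored against `N(scale * mu + shift, var * sigma)`.
#'
#' @param shift Additive offset (pA).
#' @param scale Multiplicative factor (dimensionless, > 0).
#' @param var Standard-deviation multiplier (dimensionless, > 0).
#' @param drift Current drift per sample (pA/sample); 0 disables drift
#'   correction.
#' @return A list of class `scaling_params`.
#' @export
scaling_params <- function(shift = 0, scale = 1, var = 1, drift = 0) {
  stopifnot(scale > 0, var > 0)
  structure(list(shift = shift, scale = scale, var = var, drift = drift),
            class = "scaling_params")
}

#' Stable log-space addition
#'
#' `add_log(a, b)` returns `log(exp(a) + exp(b))`, computed as
#' `max + log1p(exp(-|a - b|))` so it is stable for very negative inputs.
#' `-Inf` is the identity element. Vectorized with recycling.
#'
#' @param a,b Log-scale values (finite or `-Inf`).
#' @return `log(exp(a) + exp(b))`.
#' @export
#' @examples
#' add_log(log(0.3), log(0.2)) # log(0.5)
add_log <- function(a, b) {
  n <- max(length(a), length(b))
  cpp_add_log(rep_len(as.numeric(a), n), rep_len(as.numeric(b), n))
}

#' Match-emission log-density
#'
#' Log of the Gaussian density of an event mean under the scaled pore-model
#' distribution of a k-mer: mean `scale * level_mean + shift`, standard
#' deviation `var * level_stdv`.
#'
#' @param event_mean Event mean current(s) (pA).
#' @param kmer K-mer(s) to score against.
#' @param model A [pore_model()].
#' @param scaling A [scaling_params()].
#' @return Log-density value(s).
#' @export
lp_emit_match <- function(event_mean, kmer, model, scaling = scaling_params()) {
  lv <- model_lookup(model, kmer)
  dnorm(event_mean,
        mean = scaling$scale * lv$level_mean + scaling$shift,
        sd = scaling$var * lv$level_stdv, log = TRUE)
}

# Scaled per-block emission parameters for a haplotype.
scaled_block_params <- function(haplotype, model, scaling) {
  kmers <- seq_kmers(haplotype, model_k(model))
  lv <- model_lookup(model, kmers)
  list(kmers = kmers,
       mu = scaling$scale * lv$level_mean + scaling$shift,
       sd = scaling$var * lv$level_stdv)
}

as_event_means <- function(events) {
  if (is.data.frame(events)) {
    stopifnot("mean" %in% names(events))
    as.numeric(events$mean)
  } else {
    as.numeric(events)
  }
}

hmm_fill_impl <- function(events, haplotype, model, scaling, trans,
                          engine, workers) {
  means <- as_event_means(events)
  if (length(means) < 1) abort("at least one event is required")
  bp <- scaled_block_params(haplotype, model, scaling)
  res <- cpp_hmm_fill(means, bp$mu, bp$sd,
                      trans$lp_stay, trans$lp_step, trans$lp_skip,
                      trans$lp_bad, trans$lp_bad_emit, trans$lp_end,
                      engine = if (engine == "serial") 0L else 1L,
                      workers = as.integer(workers))
  structure(list(
    fm = res$fm,
    end_score = res$end_score,
    log_lik = res$end_score,
    n_events = length(means),
    n_block = length(bp$mu),
    kmers = bp$kmers,
    haplotype = haplotype,
    engine = engine
  ), class = "hmm_fill")
}

#' Fill the methylation-scoring HMM probability matrix
#'
#' Each k-mer of the haplotype contributes one *block* of three state columns
#' (KMER_SKIP, BAD_EVENT, MATCH in order); row 0 is the initial row and rows
#' `1..n_events` correspond to events. `hmm_fill_serial()` fills the matrix
#' row-major, block left-to-right. `hmm_fill_parallel()` uses the two-phase
#' fill: per row, MATCH and BAD_EVENT of every block are block-independent
#' (they read only the previous row) and are computed in phase A with blocks
#' assigned round-robin to `workers`; after a barrier, a single designated
#' worker scans blocks left-to-right filling the block-dependent KMER_SKIP
#' column and accumulating the end state (phase B). Both engines share one
#' `add_log` with a fixed operand order, so their results are bit-identical.
#'
#' The returned log-likelihood is the forward-style sum over all monotone
#' alignments of the event subsequence to the haplotype's k-mers, with the
#' alignment allowed to end (from MATCH of the last k-mer) after any event.
#'
#' @param events A tibble of events (column `mean` is used) or a numeric
#'   vector of event means (pA).
#' @param haplotype A character scalar over `{A,C,G,T,M}`, length >= k.
#' @param model A [pore_model()].
#' @param scaling A [scaling_params()].
#' @param trans A [trans_params()].
#' @param workers Worker count for the phase-A block assignment (>= 1).
#' @return An object of class `hmm_fill`: list with the probability matrix
#'   `fm` (`n_events + 1` rows, `3 * n_block` columns of log-probabilities),
#'   `end_score`, `log_lik`, `n_events`, `n_block` and `kmers`.
#' @export
hmm_fill_serial <- function(events, haplotype, model,
                            scaling = scaling_params(),
                            trans = trans_params()) {
  hmm_fill_impl(events, haplotype, model, scaling, trans, "serial", 1L)
}

#' @rdname hmm_fill_serial
#' @export
hmm_fill_parallel <- function(events, haplotype, model,
                              scaling = scaling_params(),
                              trans = trans_params(), workers = 1L) {
  hmm_fill_impl(events, haplotype, model, scaling, trans, "parallel", workers)
}

#' @export
print.hmm_fill <- function(x, ...) {
  cat(sprintf(
    "<hmm_fill> %d events x %d blocks (%d state columns), log_lik = %.4f\n",
    x$n_events, x$n_block, 3L * x$n_block, x$log_lik))
  invisible(x)
}

#' Tidy an HMM fill into one row per matrix cell
#'
#' @param x An `hmm_fill` object.
#' @param ... Unused.
#' @return A tibble with columns `row`, `block`, `state`, `log_prob`.
#' @export
tidy.hmm_fill <- function(x, ...) {
  states <- c("KMER_SKIP", "BAD_EVENT", "MATCH")
  col0 <- seq_len(ncol(x$fm)) - 1L
  tibble(
    row = rep(seq_len(nrow(x$fm)) - 1L, times = ncol(x$fm)),
    block = rep(col0 %/% 3L, each = nrow(x$fm)),
    state = rep(states[col0 %% 3L + 1L], each = nrow(x$fm)),
    log_prob = as.vector(x$fm)
  )
}

#' One-row summary of an HMM fill
#'
#' @param x An `hmm_fill` object.
#' @param ... Unused.
#' @return A tibble with `log_lik`, `n_events`, `n_block`, `n_state_columns`.
#' @export
glance.hmm_fill <- function(x, ...) {
  tibble(log_lik = x$log_lik, n_events = x$n_events,
         n_block = x$n_block, n_state_columns = 3L * x$n_block)
}

#' Heatmap of an HMM probability matrix
#'
#' @param object An `hmm_fill` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmm_fill <- function(object, ...) {
  df <- tidy(object)
  df$log_prob[!is.finite(df$log_prob)] <- NA_real_
  ggplot(df, aes(x = .data$block, y = .data$row, fill = .data$log_prob)) +
    geom_tile() +
    facet_wrap(~state) +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(x = "k-mer block", y = "event row", fill = "log prob") +
    theme_minimal()
}

#' Score one CpG group: methylated vs unmethylated log-likelihood ratio
#'
#' Fills the HMM twice over the group's scored sequence — once as-is
#' (unmethylated) and once with every CpG cytosine replaced by `M`
#' (methylated) — and reports the natural-log likelihood ratio
#' `log_lik_methylated - log_lik_unmethylated`. For reverse-strand reads the
#' scored sequence is the reverse complement of the forward reference window
#' and CpG methylation is re-applied on the reverse complement (the CpG
#' motif is strand-symmetric); reported coordinates stay on the forward
#' strand.
#'
#' @param group A one-row tibble (or list) as produced by
#'   [group_cpg_sites()], with fields `chrom`, `strand`, `group_start`,
#'   `group_end`, `num_motifs`, `sequence`.
#' @param events Events covering the group's scored window (tibble with
#'   column `mean`, or numeric vector of means), in signal order.
#' @param model A [pore_model()].
#' @param scaling A [scaling_params()].
#' @param trans A [trans_params()].
#' @param read_name Read identifier recorded on the call.
#' @param engine `"serial"` or `"parallel"`.
#' @param workers Worker count for the parallel engine.
#' @return A one-row tibble (`methylation_call`): `chrom`, `strand`, `start`,
#'   `end`, `read_name`, `log_lik_ratio`, `log_lik_methylated`,
#'   `log_lik_unmethylated`, `num_motifs`, `sequence`; or `NULL` (with a
#'   warning) when no events are available.
#' @export
score_cpg_group <- function(group, events, model,
                            scaling = scaling_params(),
                            trans = trans_params(),
                            read_name = "", engine = "serial", workers = 1L) {
  if (is.data.frame(group)) group <- as.list(group[1, ])
  means <- as_event_means(events)
  if (length(means) == 0) {
    warn(sprintf("no events for CpG group %s:%d-%d of read %s; call suppressed",
                 group$chrom, group$group_start, group$group_end, read_name))
    return(NULL)
  }
  seq_fwd <- group$sequence
  hap_u <- if (identical(group$strand, "-")) revcomp(seq_fwd) else seq_fwd
  hap_m <- make_methylated_haplotype(hap_u)
  fill <- function(h) {
    hmm_fill_impl(means, h, model, scaling, trans,
                  engine = engine, workers = workers)$log_lik
  }
  ll_u <- fill(hap_u)
  # Identical haplotypes (no CpG in window) give a ratio of exactly 0.
  ll_m <- if (identical(hap_m, hap_u)) ll_u else fill(hap_m)
  tibble(
    chrom = group$chrom,
    strand = group$strand,
    start = as.integer(group$group_start),
    end = as.integer(group$group_end),
    read_name = read_name,
    log_lik_ratio = ll_m - ll_u,
    log_lik_methylated = ll_m,
    log_lik_unmethylated = ll_u,
    num_motifs = as.integer(group$num_motifs),
    sequence = seq_fwd
  )
}
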