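#' Segmentation parameters for event detection
#'
#' @param window Samples on each side of the two-window change detector.
#' @param threshold Welch t-statistic cutoff for a boundary.
#' @param min_event_len Minimum event length in samples.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(window = 4, threshold = 4.0, min_event_len = 3) {
  stopifnot(window >= 2, threshold > 0, min_event_len >= 1)
  structure(list(window = as.integer(window), threshold = threshold,
                 min_event_len = as.integer(min_event_len)),
            class = "seg_params")
}

#' Band parameters for event-to-kmer alignment
#'
#' @param bandwidth Number of diagonal cells kept per anti-diagonal of the
#'   banded DP (full band width, >= 3).
#' @return A list of class `band_params`.
#' @export
band_params <- function(bandwidth = 200) {
  stopifnot(bandwidth >= 3)
  structure(list(bandwidth = as.integer(bandwidth)), class = "band_params")
}

#' Detect events in a raw signal
#'
#' Segments a raw current trace at sudden level changes. For every candidate
#' boundary the Welch t-statistic between the `window` samples on its left
#' and right is computed; boundaries are placed at local maxima of the
#' statistic exceeding `threshold`, at least `min_event_len` samples apart.
#' Each resulting segment is emitted as one event with its sample mean and
#' standard deviation. Events tile the signal without overlap.
#'
#' @param signal Numeric vector of raw current samples (pA).
#' @param params A [seg_params()].
#' @return A tibble of events: `start_sample` (1-based index into `signal`),
#'   `length`, `mean`, `stdv`. A signal of at most `2 * window` samples
#'   yields an empty tibble.
#' @export
detect_events <- function(signal, params = seg_params()) {
  w <- params$window
  n <- length(signal)
  empty <- tibble(start_sample = integer(), length = integer(),
                  mean = numeric(), stdv = numeric())
  if (n <= 2 * w) return(empty)

  # Rolling means/variances of the w samples left and right of each boundary.
  cs <- cumsum(c(0, signal))
  cs2 <- cumsum(c(0, signal^2))
  win_mean <- function(from) (cs[from + w] - cs[from]) / w
  win_var <- function(from) {
    m <- win_mean(from)
    pmax((cs2[from + w] - cs2[from]) / w - m^2, 0) * w / (w - 1)
  }
  # Boundary b means: left window is samples [b-w, b-1], right is [b, b+w-1].
  b <- seq.int(w + 1L, n - w + 1L)
  m1 <- win_mean(b - w); m2 <- win_mean(b)
  v1 <- win_var(b - w); v2 <- win_var(b)
  se <- sqrt(v1 / w + v2 / w)
  tstat <- ifelse(se > 0, abs(m1 - m2) / se,
                  ifelse(m1 == m2, 0, Inf))

  # Local maxima above threshold.
  k <- length(tstat)
  is_peak <- tstat > params$threshold &
    tstat > c(-Inf, tstat[-k]) &
    tstat >= c(tstat[-1], -Inf)
  cand <- b[is_peak]
  # Enforce minimum event length greedily, left to right.
  bounds <- integer(0)
  last <- 1L
  for (x in cand) {
    if (x - last >= params$min_event_len) {
      bounds <- c(bounds, x)
      last <- x
    }
  }
  starts <- c(1L, bounds)
  ends <- c(bounds - 1L, n)
  lens <- ends - starts + 1L
  means <- (cs[ends + 1L] - cs[starts]) / lens
  vars <- pmax((cs2[ends + 1L] - cs2[starts]) / lens - means^2, 0)
  tibble(start_sample = starts, length = lens, mean = means,
         stdv = sqrt(vars))
}

#' Align events to the k-mer sequence of a read
#'
#' Banded dynamic program over (event, k-mer) cells with stay, step and skip
#' moves, scored by the match-emission log-density plus the move's log
#' transition probability. The band is a fixed width centred on the ideal
#' diagonal (a simplification of adaptive banding). The best-scoring monotone
#' path assigning every event to one k-mer is returned.
#'
#' @param events A tibble of events (column `mean`) or numeric event means.
#' @param sequence A character scalar over `{A,C,G,T}` (length >= k).
#' @param model A [pore_model()].
#' @param scaling A [scaling_params()].
#' @param params A [band_params()].
#' @param trans A [trans_params()] supplying the move log-probabilities.
#' @return A tibble with columns `event_index`, `kmer_index` (both 1-based,
#'   non-decreasing), or `NULL` with a warning if the band collapses (no
#'   complete path through the DP).
#' @export
align_events <- function(events, sequence, model,
                         scaling = scaling_params(),
                         params = band_params(),
                         trans = trans_params()) {
  means <- as_event_means(events)
  if (length(means) < 1) abort("at least one event is required")
  bp <- scaled_block_params(sequence, model, scaling)
  pairs <- cpp_banded_align(means, bp$mu, bp$sd,
                            trans$lp_step, trans$lp_stay, trans$lp_skip,
                            params$bandwidth)
  if (nrow(pairs) == 0) {
    warn("banded alignment failed: no reachable cell at the terminus")
    return(NULL)
  }
  tibble(event_index = pairs[, 1], kmer_index = pairs[, 2])
}

#' Calibrate per-read scaling from an event alignment
#'
#' Least-squares fit of aligned event means against pore-model level means:
#' the slope is `scale`, the intercept `shift`, and `var` is the residual
#' standard deviation divided by the mean model `level_stdv` (floored at a
#' small positive constant). Drift is not estimated (left at 0).
#'
#' @param events A tibble of events (column `mean`) or numeric event means.
#' @param alignment A tibble with `event_index`, `kmer_index`, as returned by
#'   [align_events()]; needs >= 2 distinct k-mers.
#' @param sequence The k-mer source sequence the alignment refers to.
#' @param model A [pore_model()].
#' @return A [scaling_params()]; the fit's standard errors are attached as
#'   attribute `se` (`shift`, `scale`).
#' @export
calibrate <- function(events, alignment, sequence, model) {
  means <- as_event_means(events)
  kmers <- seq_kmers(sequence, model_k(model))
  lv <- model_lookup(model, kmers)
  x <- lv$level_mean[alignment$kmer_index]
  y <- means[alignment$event_index]
  if (length(unique(alignment$kmer_index)) < 2 || diff(range(x)) == 0) {
    warn("degenerate calibration fit (all model means equal); identity scaling")
    return(scaling_params())
  }
  fit <- lm(y ~ x)
  cf <- coef(fit)
  resid_sd <- sqrt(sum(fit$residuals^2) / fit$df.residual)
  v <- max(resid_sd / mean(lv$level_stdv), 0.01)
  out <- scaling_params(shift = unname(cf[1]), scale = unname(cf[2]), var = v)
  # a noiseless fit triggers a harmless "essentially perfect fit" note
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  attr(out, "se") <- c(shift = unname(se[1]), scale = unname(se[2]))
  out
}

#' @importFrom stats vcov
NULL

#' Rough moment-matching scaling estimate
#'
#' Matches the mean and spread of observed event means to the model level
#' means of a read's k-mer sequence. Used to seed the banded alignment before
#' proper calibration.
#'
#' @inheritParams calibrate
#' @param sequence The read's k-mer source sequence.
#' @return A [scaling_params()].
#' @export
moment_scaling <- function(events, sequence, model) {
  means <- as_event_means(events)
  kmers <- seq_kmers(sequence, model_k(model))
  mu <- model_lookup(model, kmers)$level_mean
  s_ev <- sd(means); s_mu <- sd(mu)
  sc <- if (is.na(s_ev) || is.na(s_mu) || s_mu == 0 || s_ev == 0) 1
        else s_ev / s_mu
  scaling_params(shift = mean(means) - sc * mean(mu), scale = sc, var = 1)
}
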