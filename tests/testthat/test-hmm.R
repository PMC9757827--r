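test_that("add_log is a stable log-space sum with -Inf as identity", {
  expect_equal(add_log(log(0.5), log(0.5)), 0)
  expect_equal(add_log(log(0.3), log(0.2)), log(0.5))
  expect_identical(add_log(-3.5, -Inf), -3.5)
  expect_identical(add_log(-Inf, -3.5), -3.5)
  expect_identical(add_log(-Inf, -Inf), -Inf)
  # commutative, stable far below exp() range
  expect_identical(add_log(-1000, -1001), add_log(-1001, -1000))
  expect_equal(add_log(-1000, -1001), -1000 + log1p(exp(-1)))
})

test_that("match emission is the scaled Gaussian log-density", {
  m <- test_model_k3()
  lv <- model_lookup(m, "ACG")
  # density peak at the scaled model mean
  sc <- scaling_params(shift = 5, scale = 1.1, var = 2)
  peak <- sc$scale * lv$level_mean + sc$shift
  expect_equal(lp_emit_match(peak, "ACG", m, sc),
               -log(sc$var * lv$level_stdv * sqrt(2 * pi)))
  # identity scaling reproduces the unscaled density
  expect_equal(lp_emit_match(101.3, "ACG", m, scaling_params()),
               dnorm(101.3, lv$level_mean, lv$level_stdv, log = TRUE))
  # hand-computed at arbitrary scaling
  x <- 97.2
  expect_equal(lp_emit_match(x, "ACG", m, sc),
               -log(sc$var * lv$level_stdv) - 0.5 * log(2 * pi) -
                 (x - peak)^2 / (2 * (sc$var * lv$level_stdv)^2))
  expect_error(lp_emit_match(100, "QQQ", m), "not in pore model")
})

test_that("the probability matrix has three state columns per k-mer block", {
  m <- test_model_k3()
  set.seed(21)
  for (len in c(3L, 5L, 9L, 17L)) {
    hap <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    f <- hmm_fill_serial(runif(4, 90, 120), hap, m)
    expect_identical(ncol(f$fm), 3L * (len - 3L + 1L))
    expect_identical(f$n_block, len - 3L + 1L)
    expect_identical(nrow(f$fm), 5L)  # row 0 + one row per event
    expect_true(all(is.finite(f$fm) | f$fm == -Inf))
  }
})

test_that("single event, single block reduces to the closed-form path", {
  m <- test_model_k3()
  tr <- trans_params()
  lv <- model_lookup(m, "GTA")
  e <- 104.7
  f <- hmm_fill_serial(e, "GTA", m, scaling_params(), tr)
  expect_equal(f$log_lik,
               tr$lp_start + dnorm(e, lv$level_mean, lv$level_stdv,
                                   log = TRUE) + tr$lp_end,
               tolerance = 1e-12)
})

test_that("a frozen two-event, two-block instance matches its enumerated value", {
  # Expected value computed by explicit path enumeration (oracle_log_lik)
  # over: events (100.2, 103.9), blocks N(100,1), N(104,1.5),
  # p_stay=0.1, p_skip=0.01, p_bad=0.01, bad_emit=0.01.
  inst <- list(events = c(100.2, 103.9), mu = c(100, 104), sd = c(1, 1.5),
               trans = trans_params(0.1, 0.01, 0.01, 0.01))
  frozen <- -2.38254385249855  # enumeration result, frozen
  expect_equal(oracle_log_lik(inst$events, inst$mu, inst$sd, inst$trans),
               frozen, tolerance = 1e-9)
  im <- instance_model(inst)
  f <- hmm_fill_serial(inst$events, im$haplotype, im$model,
                       scaling_params(), inst$trans)
  expect_equal(f$log_lik, frozen, tolerance = 1e-9)
})

test_that("the serial fill equals brute-force path enumeration on small instances", {
  set.seed(31)
  for (i in 1:60) {
    inst <- random_hmm_instance(4, 4)
    im <- instance_model(inst)
    lv <- model_lookup(im$model, seq_kmers(im$haplotype, 2))
    f <- hmm_fill_serial(inst$events, im$haplotype, im$model,
                         scaling_params(), inst$trans)
    expect_equal(f$log_lik,
                 oracle_log_lik(inst$events, lv$level_mean, lv$level_stdv,
                                inst$trans),
                 tolerance = 1e-9)
  }
})

test_that("the two-phase parallel fill is bit-identical to the serial fill", {
  set.seed(32)
  for (i in 1:30) {
    inst <- random_hmm_instance(12, 10)
    im <- instance_model(inst)
    s <- hmm_fill_serial(inst$events, im$haplotype, im$model,
                         scaling_params(), inst$trans)
    for (w in c(1L, 2L, 8L)) {
      p <- hmm_fill_parallel(inst$events, im$haplotype, im$model,
                             scaling_params(), inst$trans, workers = w)
      expect_identical(p$fm, s$fm)
      expect_identical(p$end_score, s$end_score)
    }
  }
  # a larger instance: 100 events, 20 blocks
  set.seed(33)
  inst <- list(events = runif(100, 85, 115), mu = runif(20, 90, 110),
               sd = runif(20, 0.5, 2), trans = trans_params())
  im <- instance_model(inst)
  s <- hmm_fill_serial(inst$events, im$haplotype, im$model,
                       scaling_params(), inst$trans)
  p <- hmm_fill_parallel(inst$events, im$haplotype, im$model,
                         scaling_params(), inst$trans, workers = 8)
  expect_identical(p$fm, s$fm)
  expect_identical(p$end_score, s$end_score)
})

test_that("degenerate inputs are rejected", {
  m <- test_model_k3()
  expect_error(hmm_fill_serial(numeric(0), "ACG", m), "at least one event")
  expect_error(hmm_fill_serial(100, "AC", m), "shorter than k")
})

test_that("swapping haplotype labels negates the log-likelihood ratio exactly", {
  m <- test_model_k6()
  tr <- trans_params()
  sc <- scaling_params()
  grp <- group_cpg_sites("TTAACGTTAA", chrom = "c", k = 6)
  ev <- c(108, 112, 116, 121, 118)
  call <- score_cpg_group(grp, ev, m, sc, tr, read_name = "r1")
  expect_equal(call$log_lik_ratio,
               call$log_lik_methylated - call$log_lik_unmethylated)
  # recompute with the labels swapped by scoring the haplotypes directly
  hap_u <- grp$sequence
  hap_m <- make_methylated_haplotype(hap_u)
  ll_u <- hmm_fill_serial(ev, hap_u, m, sc, tr)$log_lik
  ll_m <- hmm_fill_serial(ev, hap_m, m, sc, tr)$log_lik
  expect_identical(call$log_lik_ratio, ll_m - ll_u)
  expect_identical(-(call$log_lik_ratio), ll_u - ll_m)
})

test_that("a window without CpG yields a log-likelihood ratio of exactly zero", {
  m <- test_model_k6()
  grp <- list(chrom = "c", strand = "+", group_start = 2L, group_end = 2L,
              num_motifs = 1L, seq_start = 0L, sequence = "TTAATTAATT")
  call <- score_cpg_group(grp, c(100, 105, 110), m)
  expect_identical(call$log_lik_ratio, 0)
})

test_that("events simulated from each haplotype recover the expected ratio sign", {
  m <- test_model_k6()
  tr <- trans_params()
  grp_seq <- "TTAACGTTAA"
  grp <- group_cpg_sites(grp_seq, chrom = "c", k = 6)
  hap_m <- make_methylated_haplotype(grp_seq)
  mu_u <- model_lookup(m, seq_kmers(grp_seq, 6))$level_mean
  mu_m <- model_lookup(m, seq_kmers(hap_m, 6))$level_mean
  set.seed(41)
  signs_m <- signs_u <- logical(40)
  for (i in 1:40) {
    ev_m <- rnorm(length(mu_m), mu_m, 1)
    ev_u <- rnorm(length(mu_u), mu_u, 1)
    signs_m[i] <- score_cpg_group(grp, ev_m, m, trans = tr)$log_lik_ratio > 0
    signs_u[i] <- score_cpg_group(grp, ev_u, m, trans = tr)$log_lik_ratio < 0
  }
  expect_gte(mean(signs_m), 0.95)
  expect_gte(mean(signs_u), 0.95)
})

test_that("no events in range suppresses the call with a warning", {
  m <- test_model_k6()
  grp <- group_cpg_sites("TTAACGTTAA", chrom = "c", k = 6)
  expect_warning(out <- score_cpg_group(grp, numeric(0), m), "suppressed")
  expect_null(out)
})

test_that("scaling the model and inverse-transforming events shifts log_lik by n log(c)", {
  # With scale c, shift s and var = c the emission density obeys
  # N(e; c mu + s, c sigma) = N((e - s)/c; mu, sigma) / c, so on instances
  # dominated by all-match paths the two scores differ by n * log(c).
  m <- test_model_k3()
  tr <- trans_params(p_stay = 0.1, p_skip = 1e-12, p_bad = 1e-12,
                     bad_emit = 1e-12)
  hap <- "ACGTA"
  lv <- model_lookup(m, seq_kmers(hap, 3))
  set.seed(51)
  ev0 <- rnorm(3, lv$level_mean, lv$level_stdv)  # raw-scale events
  s <- 12.5; c_ <- 1.3
  f_scaled <- hmm_fill_serial(c_ * ev0 + s, hap, m,
                              scaling_params(shift = s, scale = c_, var = c_),
                              tr)
  f_id <- hmm_fill_serial(ev0, hap, m, scaling_params(), tr)
  expect_equal(f_scaled$log_lik, f_id$log_lik - length(ev0) * log(c_),
               tolerance = 1e-6)
})

test_that("an outlier event inserted mid-stream never increases the likelihood", {
  m <- test_model_k3()
  tr <- trans_params()
  set.seed(52)
  for (i in 1:20) {
    hap <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                 collapse = "")
    lv <- model_lookup(m, seq_kmers(hap, 3))
    ev <- rnorm(length(lv$level_mean), lv$level_mean, 1)
    base <- hmm_fill_serial(ev, hap, m, trans = tr)$log_lik
    pos <- sample(seq_len(length(ev) - 1), 1)
    ev2 <- append(ev, 1000, after = pos)  # far from every model level
    with_outlier <- hmm_fill_serial(ev2, hap, m, trans = tr)$log_lik
    expect_lte(with_outlier, base)
  }
})

test_that("tidy, glance and autoplot expose the fill matrix", {
  m <- test_model_k3()
  f <- hmm_fill_serial(c(100, 104), "ACGT", m)
  td <- tidy(f)
  expect_identical(nrow(td), nrow(f$fm) * ncol(f$fm))
  expect_setequal(unique(td$state), c("KMER_SKIP", "BAD_EVENT", "MATCH"))
  expect_identical(max(td$block), f$n_block - 1L)
  gl <- glance(f)
  expect_identical(gl$n_state_columns, 3L * f$n_block)
  expect_identical(gl$log_lik, f$log_lik)
  expect_s3_class(autoplot(f), "ggplot")
})
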