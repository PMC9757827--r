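test_that("reference simulation plants CpG sites at the requested density", {
  cfg0 <- sim_config(seed = 3, ref_length = 4000, cpg_density = 0)
  ref0 <- simulate_reference(cfg0)
  expect_false(grepl("CG", ref0$sequences[[1]], fixed = TRUE))
  expect_identical(length(ref0$sites), 0L)

  cfg <- sim_config(seed = 4, ref_length = 10000, cpg_density = 0.02)
  ref <- simulate_reference(cfg)
  n <- length(ref$sites)
  # 99% binomial bounds around d * L (overlap-dropping shaves a few)
  bounds <- qbinom(c(0.005, 0.995), cfg$ref_length, cfg$cpg_density)
  expect_gte(n, bounds[1] - 10)
  expect_lte(n, bounds[2])
  # the site list is exactly the CG occurrences
  expect_identical(ref$sites,
                   as.integer(gregexpr("CG", ref$sequences[[1]],
                                       fixed = TRUE)[[1]] - 1L))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 9)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1, r2)
  m <- test_model_k6()
  s1 <- simulate_reads(r1, m, cfg)
  s2 <- simulate_reads(r2, m, cfg)
  expect_identical(s1, s2)
})

test_that("fixture sets are byte-deterministic and parseable", {
  cfg <- small_sim_config(n_reads = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- emit_fixture_set(cfg, d1, model = test_model_k6())
  m2 <- emit_fixture_set(cfg, d2, model = test_model_k6())
  expect_identical(m1$md5, m2$md5)
  expect_identical(m1$file, m2$file)
})

test_that("an empty fixture (zero reads) is still valid", {
  cfg <- small_sim_config(n_reads = 0)
  dir <- withr::local_tempdir()
  manifest <- emit_fixture_set(cfg, dir, model = test_model_k6())
  expect_identical(nrow(manifest), 5L)
  expect_identical(length(read_signal_table(file.path(dir, "signals.tsv"))),
                   0L)
  reads <- read_inputs(file.path(dir, "reads.fastq.gz"),
                       file.path(dir, "reads.bam"),
                       file.path(dir, "ref.fa"),
                       file.path(dir, "signals.tsv"))
  expect_identical(nrow(reads), 0L)
})

test_that("the noiseless limit gives exactly one event per k-mer at the model mean", {
  m <- test_model_k6()
  cfg <- sim_config(seed = 5, p_stay = 0, p_skip = 0, p_bad = 0,
                    noise_sd = 0, shift = 10, scale = 1.2)
  win <- "AACGTTACGGTTAACC"
  sites <- gregexpr("CG", win, fixed = TRUE)[[1]]
  set.seed(5)
  sim <- simulate_read_signal(win, rep(FALSE, length(sites)), m, cfg)
  K <- as.integer(nchar(win) - 6 + 1)
  expect_identical(nrow(sim$events), K)
  mu <- model_lookup(m, seq_kmers(win, 6))$level_mean
  expect_equal(sim$events$mean, 1.2 * mu + 10, tolerance = 1e-12)
  expect_identical(sim$events$kmer_index, seq_len(K))
})

test_that("event counts follow the stay/skip expectation", {
  m <- test_model_k6()
  cfg <- sim_config(seed = 6, p_stay = 0.2, p_skip = 0.05, p_bad = 0,
                    noise_sd = 1)
  win <- paste(rep("ACGT", 500), collapse = "")  # 2000 bp
  sites <- gregexpr("CG", win, fixed = TRUE)[[1]]
  set.seed(6)
  sim <- simulate_read_signal(win, rep(FALSE, length(sites)), m, cfg)
  K <- nchar(win) - 6 + 1
  expected <- K * (1 + cfg$p_stay / (1 - cfg$p_stay)) * (1 - cfg$p_skip)
  # mean events per k-mer 1/(1-p_stay); binomial/geometric sampling error
  sd_approx <- sqrt(K * (cfg$p_stay / (1 - cfg$p_stay)^2 +
                         cfg$p_skip * (1 - cfg$p_skip)))
  expect_lt(abs(nrow(sim$events) - expected), 4 * sd_approx)
})

test_that("methylated windows shift only the M-overlapping k-mer emissions", {
  m <- test_model_k6()
  cfg <- sim_config(p_stay = 0, p_skip = 0, p_bad = 0, noise_sd = 0,
                    shift = 0, scale = 1)
  win <- "TTTTTACGTTTTT"
  set.seed(8)
  un <- simulate_read_signal(win, FALSE, m, cfg)
  set.seed(8)
  me <- simulate_read_signal(win, TRUE, m, cfg)
  delta <- me$events$mean - un$events$mean
  # the M sits at 0-based offset 6; 6-mers 2..7 (1-based) contain it
  expect_true(all(delta[2:7] == 4))
  expect_true(all(delta[-(2:7)] == 0))
  expect_identical(me$haplotype, "TTTTTAMGTTTTT")
})

test_that("reverse-strand simulation emits the reverse-complement haplotype", {
  m <- test_model_k6()
  cfg <- sim_config(p_stay = 0, p_skip = 0, p_bad = 0, noise_sd = 0,
                    shift = 0, scale = 1)
  win <- "TTTTTACGTTTTT"
  set.seed(8)
  sim <- simulate_read_signal(win, TRUE, m, cfg, strand = "-")
  expect_identical(sim$haplotype,
                   make_methylated_haplotype(revcomp(win)))
})

test_that("larger methylation shifts separate the likelihood ratio further", {
  cfg_base <- list(seed = 13, n_reads = 4, read_length = 300,
                   ref_length = 1200)
  mean_abs_llr <- vapply(c(2, 5), function(ms) {
    cfg <- do.call(sim_config, c(cfg_base, list(m_shift = ms)))
    m <- synthetic_pore_model(k = 6, m_shift = ms)
    ref <- simulate_reference(cfg)
    sim <- simulate_reads(ref, m, cfg)
    res <- call_methylation(sim$reads, ref$sequences, m,
                            config = pipeline_config(batch_size = 2))
    mean(abs(res$calls$log_lik_ratio))
  }, numeric(1))
  expect_gt(mean_abs_llr[2], mean_abs_llr[1])
})

test_that("truth covers exactly the CG sites overlapped by each read", {
  cfg <- small_sim_config(seed = 14)
  m <- test_model_k6()
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(ref, m, cfg)
  refseq <- ref$sequences[[1]]
  for (rid in unique(sim$truth$read_id)) {
    r <- sim$reads[sim$reads$read_id == rid, ]
    win <- substr(refseq, r$mapped_start + 1, r$mapped_start + cfg$read_length)
    sites <- gregexpr("CG", win, fixed = TRUE)[[1]]
    sites <- if (sites[1] == -1) integer(0) else as.integer(sites - 1)
    tt <- sim$truth[sim$truth$read_id == rid, ]
    expect_identical(sort(tt$cpg_position),
                     sort(sites + r$mapped_start))
  }
})
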