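Package: nanomethr
Title: Nanopore CpG Methylation Calling with a Block-Parallel Profile HMM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-level 5-methylcytosine calling from nanopore-style signal
    data. Raw current traces are segmented into events, events are aligned to
    a k-mer pore model with a banded dynamic program, per-read scaling is
    recalibrated, and each CpG group is scored with a three-state-per-k-mer
    profile hidden Markov model that compares the methylated and unmethylated
    haplotypes by log-likelihood ratio. The HMM matrix fill is provided both
    in classic row-major serial form and as a two-phase block-parallel fill
    (independent MATCH/BAD_EVENT updates per block, then a serial KMER_SKIP
    scan) that is bit-identical to the serial fill. Batches of reads flow
    through the four stages under a pipelined executor with a bounded window
    of in-flight batches. A synthetic-data module simulates references,
    reads, signals and per-CpG methylation truth so the whole pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    Biostrings,
    Rsamtools,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
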