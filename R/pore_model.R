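#' Pore model tables
#'
#' A pore model maps every k-mer over the alphabet `{A,C,G,T}` — plus the
#' methylated variants over `{A,C,G,T,M}`, where `M` stands for
#' 5-methylcytosine in CpG context — to the mean and standard deviation of
#' the ionic current (picoamps) observed while that k-mer occupies the pore.
#'
#' @param table A data frame with columns `kmer`, `level_mean`, `level_stdv`.
#' @param k K-mer length. Defaults to the length of the first k-mer.
#'
#' @return A tibble of class `pore_model` with attribute `k`.
#' @export
pore_model <- function(table, k = nchar(table$kmer[1])) {
  table <- as_tibble(table)
  stopifnot(all(c("kmer", "level_mean", "level_stdv") %in% names(table)))
  if (nrow(table) == 0) abort("pore model table is empty")
  if (any(nchar(table$kmer) != k)) abort("all k-mers must have length k")
  if (any(table$level_stdv <= 0)) abort("all level_stdv must be > 0")
  if (anyDuplicated(table$kmer)) abort("duplicate k-mers in pore model")
  plain <- table$kmer[!str_detect(table$kmer, "M")]
  if (length(plain) < 4^k) {
    abort(sprintf("pore model must contain all %d ACGT %d-mers", 4^k, k))
  }
  structure(table, k = k, class = c("pore_model", class(table)))
}

#' K-mer length of a pore model
#' @param model A [pore_model()].
#' @return Integer k-mer length.
#' @export
model_k <- function(model) attr(model, "k")

# All k-mers over {A,C,G,T,M} in which every M is a plausible CpG-context
# 5mC: followed by G, or sitting at the final position (its G lies beyond
# the window). These are exactly the windows of methylated haplotypes.
valid_methyl_kmers <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T", "M")), k),
                      stringsAsFactors = FALSE)
  kmers <- do.call(paste0, rev(grid))
  has_m <- str_detect(kmers, "M")
  kmers <- kmers[has_m]
  ok <- map_lgl(kmers, function(x) {
    pos <- which(strsplit(x, "")[[1]] == "M")
    all(pos == k | str_sub(x, pos + 1, pos + 1) == "G")
  })
  kmers[ok]
}

#' Synthetic pore model
#'
#' Builds a complete deterministic k-mer model for simulation and testing.
#' Each ACGT k-mer gets a level mean derived from its base composition
#' (weights decay along the k-mer, mimicking the position-dependent influence
#' of bases on the pore current), spread over roughly 100--150 pA. Every
#' valid CpG-context M variant is included with its mean offset by `m_shift`
#' from the unmethylated version — a constant offset chosen for controllable
#' effect size rather than realism.
#'
#' @param k K-mer length.
#' @param m_shift Offset (pA) added to the level mean of M-containing k-mers.
#' @param level_stdv Constant per-k-mer current standard deviation (pA).
#' @return A [pore_model()].
#' @export
synthetic_pore_model <- function(k = 6, m_shift = 4, level_stdv = 1.0) {
  stopifnot(k >= 2)
  base_val <- c(A = 0, C = 1, G = 2, T = 3)
  wt <- c(6.1, 4.3, 2.9, 1.7, 0.8, 0.3, 0.15, 0.07)[seq_len(k)]
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  kmers <- do.call(paste0, rev(grid))
  kmer_mean <- function(km) {
    b <- strsplit(km, "")[[1]]
    100 + sum(base_val[b] * wt)
  }
  means <- map_dbl(kmers, kmer_mean)
  mk <- valid_methyl_kmers(k)
  m_means <- map_dbl(str_replace_all(mk, "M", "C"), kmer_mean) + m_shift
  pore_model(
    tibble(
      kmer = c(kmers, mk),
      level_mean = c(means, m_means),
      level_stdv = level_stdv
    ),
    k = k
  )
}

#' Look up k-mers in a pore model
#'
#' @param model A [pore_model()].
#' @param kmers Character vector of k-mers.
#' @return A tibble with columns `kmer`, `level_mean`, `level_stdv` in the
#'   order of `kmers`.
#' @export
model_lookup <- function(model, kmers) {
  idx <- match(kmers, model$kmer)
  if (anyNA(idx)) {
    missing <- unique(kmers[is.na(idx)])
    abort(sprintf("k-mer(s) not in pore model: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  tibble(kmer = kmers,
         level_mean = model$level_mean[idx],
         level_stdv = model$level_stdv[idx])
}

#' Decompose a sequence into its overlapping k-mers
#'
#' @param sequence A character scalar.
#' @param k K-mer length.
#' @return Character vector of `nchar(sequence) - k + 1` k-mers.
#' @export
seq_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) abort("sequence shorter than k")
  str_sub(sequence, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

#' Read / write a pore model file
#'
#' Plain whitespace-delimited text with a header line and columns
#' `kmer`, `level_mean`, `level_stdv`.
#'
#' @param path File path.
#' @return `read_pore_model()` returns a [pore_model()];
#'   `write_pore_model()` returns `path` invisibly.
#' @export
read_pore_model <- function(path) {
  tab <- read.delim(path, sep = "", header = TRUE,
                    colClasses = c("character", "numeric", "numeric"))
  pore_model(tab)
}

#' @rdname read_pore_model
#' @param model A [pore_model()].
#' @export
write_pore_model <- function(model, path) {
  lines <- c(
    "kmer\tlevel_mean\tlevel_stdv",
    sprintf("%s\t%.6f\t%.6f", model$kmer, model$level_mean, model$level_stdv)
  )
  writeLines(lines, path)
  invisible(path)
}
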