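# Small shared fixtures built in code at test time.

test_model_k6 <- local({
  cache <- NULL
  function(m_shift = 4) {
    if (is.null(cache)) cache <<- synthetic_pore_model(k = 6, m_shift = m_shift)
    cache
  }
})

test_model_k3 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_pore_model(k = 3, m_shift = 4)
    cache
  }
})

# A scaled-down end-to-end simulation: few short reads, same generative
# structure as the default conditions.
small_sim_config <- function(seed = 7, n_reads = 6, read_length = 400,
                             ref_length = 2000, ...) {
  sim_config(seed = seed, n_reads = n_reads, read_length = read_length,
             ref_length = ref_length, ...)
}
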