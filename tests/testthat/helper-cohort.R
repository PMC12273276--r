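## Small cohort configuration for fast unit tests.  Scaled-down sizes,
## identical structure to the defaults.
tiny_config <- function(...) {
  cohort_config(n_samples = 40, n_sites = 2000, n_informative = 400,
                n_marker = 20, n_genes = 300, n_coupled = 100,
                n_immune = 30, ...)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
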