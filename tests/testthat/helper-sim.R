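# Shared fixtures: a small background catalog and down-scaled simulation
# parameters so unit tests stay fast. Problem sizes are reduced relative to
# whole-genome scale; the statistical structure (depth, purity, shared
# fractions, Zipf catalog) is unchanged.

small_params <- function(...) {
  sim_params(
    mutations_per_tumor = c(600, 1500),
    hypermutator_prob = 0,
    catalog_n_tumors = 50L,
    catalog_muts_per_tumor = 300L,
    ...
  )
}

test_catalog_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_catalog(50, 300, seed = 4242)
    }
    cache
  }
})

# a tiny hand-built patient case used by harmonization unit tests
toy_case <- function(observations, mutations = NULL, segments = NULL) {
  keys <- unique(observations$key)
  if (is.null(mutations)) {
    mutations <- tibble::tibble(
      key = keys,
      chrom = sub(":.*", "", keys),
      pos = as.integer(sub("^[^:]+:([0-9]+):.*", "\\1", keys)),
      ref = "A", alt = "T", variant_class = "SNV",
      gene = "", effect = "noncoding", context = "TAT"
    )
  }
  samples <- tibble::tibble(
    sample = c("T", "R", "N"),
    role = c("primary", "recurrent", "normal"),
    purity = c(0.7, 0.7, NA), ploidy = c(2, 2, NA)
  )
  patient_case("TP", samples, mutations, observations, segments = segments)
}

obs_row <- function(key, sample, alt, ref, called = alt >= 3) {
  tibble::tibble(key = key, sample = sample, alt_reads = alt, ref_reads = ref,
                 depth = alt + ref,
                 vaf = ifelse(alt + ref > 0, alt / (alt + ref), NA_real_),
                 called = called)
}
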