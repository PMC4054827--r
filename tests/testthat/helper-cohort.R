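# small cohorts used across test files; full-size defaults are exercised in
# test-acceptance.R

small_manifest <- function(n = 2000, seed = 42) {
  generate_manifest(n, seed = seed)
}

small_config <- function(n = 2000, ...) {
  args <- list(...)
  defaults <- list(n_probes = n, n_pairs = 6L, n_planted_dmrs = 3L, seed = 7L)
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}

small_cohort <- function(n = 2000, manifest = small_manifest(n), ...) {
  generate_cohort(small_config(n, ...), manifest)
}

# hand-built sample sheet for matrix-level tests
toy_samples <- function(n_pairs = 2, timepoints = c("birth", "m18")) {
  g <- expand.grid(twin_index = 1:2, pair_id = sprintf("P%02d", seq_len(n_pairs)),
                   timepoint = timepoints, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_T%d_%s", g$pair_id, g$twin_index,
                                 ifelse(g$timepoint == "birth", "B", "18")),
             pair_id = g$pair_id, twin_index = g$twin_index,
             zygosity = "MZ", chorionicity = "MC", sex = "F",
             timepoint = g$timepoint, replicate_id = 1L,
             birth_weight = 2500, stringsAsFactors = FALSE)
}
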