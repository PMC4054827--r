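#' Published twin-pair characteristics table
#'
#' Loads the bundled per-pair study-design table: zygosity, chorionicity,
#' co-twin sexes, gestational age, birth-weight discordance (percent, as
#' defined by [weight_discordance()]) and the arrays removed by quality
#' control (comma-separated `T<twin>_<B|18>` tokens; empty when none).
#'
#' @return a data.frame with one row per twin pair.
#' @export
twin_pair_table <- function() {
  path <- system.file("extdata", "pair_characteristics.tsv",
                      package = "twindrift", mustWork = TRUE)
  utils::read.delim(path, colClasses = c(pair_id = "character",
                                         samples_removed = "character"))
}

#' Median birth-weight discordance of the cohort
#'
#' @param pairs a pair table from [twin_pair_table()].
#' @return the median of the per-pair birth-weight discordance percentages.
#' @export
median_weight_discordance <- function(pairs = twin_pair_table()) {
  stats::median(pairs$birth_weight_discordance_pct)
}

#' Arrays retained after quality control
#'
#' Counts the removed-array tokens in the pair table against the full
#' design (`n_pairs` x 2 co-twins x `timepoints` ages).
#'
#' @param pairs a pair table from [twin_pair_table()].
#' @param timepoints number of profiled ages per individual (default 2).
#' @return list `total`, `removed`, `retained`.
#' @export
retained_array_count <- function(pairs = twin_pair_table(), timepoints = 2L) {
  tokens <- unlist(strsplit(pairs$samples_removed[
    !is.na(pairs$samples_removed) & nzchar(pairs$samples_removed)], ","))
  tokens <- trimws(tokens)
  total <- nrow(pairs) * 2L * timepoints
  list(total = total, removed = length(tokens),
       retained = total - length(tokens))
}
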