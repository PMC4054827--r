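#' Within-pair probe-wise methylation discordance
#'
#' Absolute beta difference between co-twins at one timepoint, after
#' averaging technical replicates. Pairs without both co-twins at the
#' timepoint are dropped (with a message).
#'
#' @param beta probe x sample beta matrix.
#' @param samples sample sheet.
#' @param timepoint `"birth"` or `"m18"`.
#' @return probe x pair matrix of absolute beta differences.
#' @export
pair_discordance <- function(beta, samples, timepoint) {
  samples <- samples[samples$sample_id %in% colnames(beta) &
                     samples$timepoint == timepoint, ]
  if (nrow(samples) == 0L) stop("no samples at timepoint '", timepoint, "'")
  avg <- average_replicates(beta[, samples$sample_id, drop = FALSE], samples)
  m <- avg$mat
  pairs <- sort(unique(samples$pair_id))
  c1 <- match(paste0(pairs, "_T1.", timepoint), colnames(m))
  c2 <- match(paste0(pairs, "_T2.", timepoint), colnames(m))
  ok <- !is.na(c1) & !is.na(c2)
  if (any(!ok))
    message("dropping pair(s) without both co-twins at ", timepoint, ": ",
            paste(pairs[!ok], collapse = ", "))
  if (!any(ok)) stop("no complete pair at timepoint '", timepoint, "'")
  d <- abs(m[, c1[ok], drop = FALSE] - m[, c2[ok], drop = FALSE])
  colnames(d) <- pairs[ok]
  d
}

#' Residual-based co-twin discordance on the M-value scale
#'
#' Fits the linear model with twin-pair group (pair x timepoint) as the
#' predictive factor, probe by probe; the residual (M minus the pair-group
#' mean) is the discordance measurement. For a two-member group the
#' residuals are +/-(M1 - M2)/2; singleton groups get residual 0 with a
#' warning.
#'
#' @param m probe x sample M-value matrix.
#' @param samples sample sheet.
#' @return probe x sample residual matrix.
#' @export
residual_discordance <- function(m, samples) {
  samples <- samples[match(colnames(m), samples$sample_id), ]
  grp <- paste(samples$pair_id, samples$timepoint, sep = ".")
  out <- m
  singleton <- FALSE
  for (g in unique(grp)) {
    j <- which(grp == g)
    if (length(j) == 1L) {
      out[, j] <- 0
      singleton <- TRUE
    } else {
      out[, j] <- m[, j, drop = FALSE] - rowMeans(m[, j, drop = FALSE])
    }
  }
  if (singleton)
    warning("singleton pair group(s): residuals set to 0")
  out
}

#' Count discordant probes
#'
#' Number of probes with discordance strictly greater than `threshold`.
#'
#' @param discordance numeric vector of absolute beta differences.
#' @param threshold discordance cutoff (default 0.2).
#' @return integer count.
#' @export
count_discordant <- function(discordance, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must lie in (0, 1)")
  sum(discordance > threshold, na.rm = TRUE)
}

#' Euclidean distance between co-twin methylation profiles
#'
#' @param beta1,beta2 equal-length beta vectors over the analysis probe set.
#' @return `sqrt(sum((beta1 - beta2)^2))`.
#' @export
euclidean_distance <- function(beta1, beta2) {
  if (length(beta1) != length(beta2)) stop("vectors differ in length")
  sqrt(sum((beta1 - beta2)^2, na.rm = TRUE))
}

#' Change in within-pair discordance with age
#'
#' Per-probe delta discordance (18 months minus birth) with a distribution
#' summary: mean, median and the central mass (fraction with
#' `|delta| < 0.05`). If a `twin_dm` result is supplied, the distribution of
#' |delta discordance| is compared with the |delta beta| distribution of the
#' age effects (median comparison).
#'
#' @param d_birth,d_m18 matched discordance vectors or probe x pair matrices
#'   from [pair_discordance()].
#' @param dm_result optional `twin_dm` table for the magnitude comparison.
#' @return list `delta` (same shape as input), `summary` (mean, median,
#'   central_mass), and `magnitude_comparison` when `dm_result` is given
#'   (median |delta discordance| vs median |delta beta|).
#' @export
delta_discordance <- function(d_birth, d_m18, dm_result = NULL) {
  if (!identical(dim(d_birth), dim(d_m18)) ||
      length(d_birth) != length(d_m18))
    stop("discordance inputs must be matched in shape")
  if (is.matrix(d_birth)) {
    common <- intersect(colnames(d_birth), colnames(d_m18))
    d_birth <- d_birth[, common, drop = FALSE]
    d_m18 <- d_m18[, common, drop = FALSE]
  }
  delta <- d_m18 - d_birth
  summ <- list(mean = mean(delta, na.rm = TRUE),
               median = stats::median(delta, na.rm = TRUE),
               central_mass = mean(abs(delta) < 0.05, na.rm = TRUE))
  out <- list(delta = delta, summary = summ)
  if (!is.null(dm_result)) {
    out$magnitude_comparison <- list(
      median_abs_delta_discordance = stats::median(abs(delta), na.rm = TRUE),
      median_abs_delta_beta = stats::median(abs(dm_result$delta_beta), na.rm = TRUE))
  }
  out
}

#' Classify a pair's discordance dynamics
#'
#' Relative change in the within-pair Euclidean distance from birth to 18
#' months: drift if it grows by more than `rel_threshold`, converge if it
#' shrinks by more than `rel_threshold`, else stable. A zero birth distance
#' yields "stable" with a warning.
#'
#' @param ed_birth,ed_m18 Euclidean distances (>= 0).
#' @param rel_threshold relative-change boundary (default 0.10).
#' @return `"drift"`, `"converge"` or `"stable"`.
#' @export
classify_pair_dynamics <- function(ed_birth, ed_m18, rel_threshold = 0.10) {
  if (ed_birth < 0 || ed_m18 < 0) stop("distances must be >= 0")
  if (ed_birth == 0) {
    warning("birth distance is 0; returning 'stable'")
    return("stable")
  }
  rel <- (ed_m18 - ed_birth) / ed_birth
  if (rel > rel_threshold) "drift"
  else if (rel < -rel_threshold) "converge"
  else "stable"
}

#' Per-pair discordance profiles and dynamics labels
#'
#' Computes, for every pair with both co-twins at both ages: the Euclidean
#' distance and discordant-probe count at each age, the delta discordance
#' distribution and the drift/converge/stable label.
#'
#' @param beta probe x sample beta matrix (QC'd).
#' @param samples sample sheet.
#' @param disc_threshold probe discordance cutoff (default 0.2).
#' @param rel_threshold dynamics boundary for [classify_pair_dynamics()].
#' @return data.frame of class `pair_dynamics`: `pair_id`, `zygosity`,
#'   `chorionicity`, `ed_birth`, `ed_m18`, `n_discordant_birth`,
#'   `n_discordant_m18`, `mean_delta_discordance`, `dynamics`. The
#'   probe x pair discordance matrices are attached as attributes
#'   `d_birth`, `d_m18`.
#' @export
pair_dynamics_profile <- function(beta, samples, disc_threshold = 0.2,
                                  rel_threshold = 0.10) {
  d_b <- pair_discordance(beta, samples, "birth")
  d_18 <- pair_discordance(beta, samples, "m18")
  pairs <- intersect(colnames(d_b), colnames(d_18))
  if (length(pairs) == 0L) stop("no pair complete at both timepoints")
  d_b <- d_b[, pairs, drop = FALSE]
  d_18 <- d_18[, pairs, drop = FALSE]
  meta <- samples[match(pairs, samples$pair_id), ]
  out <- data.frame(
    pair_id = pairs,
    zygosity = meta$zygosity,
    chorionicity = meta$chorionicity,
    ed_birth = apply(d_b, 2, function(v) sqrt(sum(v^2, na.rm = TRUE))),
    ed_m18 = apply(d_18, 2, function(v) sqrt(sum(v^2, na.rm = TRUE))),
    n_discordant_birth = apply(d_b, 2, count_discordant, threshold = disc_threshold),
    n_discordant_m18 = apply(d_18, 2, count_discordant, threshold = disc_threshold),
    mean_delta_discordance = colMeans(d_18 - d_b, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$dynamics <- mapply(classify_pair_dynamics, out$ed_birth, out$ed_m18,
                         MoreArgs = list(rel_threshold = rel_threshold))
  rownames(out) <- NULL
  attr(out, "d_birth") <- d_b
  attr(out, "d_m18") <- d_18
  class(out) <- c("pair_dynamics", "data.frame")
  out
}

#' @export
print.pair_dynamics <- function(x, ...) {
  cat("Within-pair discordance dynamics (", nrow(x), "pairs )\n")
  df <- as.data.frame(x)
  df$ed_birth <- round(df$ed_birth, 1)
  df$ed_m18 <- round(df$ed_m18, 1)
  df$mean_delta_discordance <- signif(df$mean_delta_discordance, 3)
  print(df)
  cat("labels:", paste(sprintf("%s=%d", names(table(x$dynamics)),
                               table(x$dynamics)), collapse = ", "), "\n")
  invisible(x)
}

#' Rank probes and export a gene list for ranked-list ontology
#'
#' Probes are sorted by the metric in decreasing order (ties broken by
#' probe id), mapped to gene symbols, and deduplicated keeping each gene at
#' its best rank — the single-ranked-list dialect expected by ranked-list
#' ontology tools. Probes without a gene (intergenic) are excluded.
#'
#' @param metric named numeric vector (names = probe ids), e.g. mean
#'   within-pair discordance or mean delta discordance.
#' @param gene_map data.frame with `probe_id` and `gene` (the manifest
#'   works).
#' @param path optional file to write (one symbol per line).
#' @return character vector of gene symbols in rank order.
#' @export
rank_probes_for_ontology <- function(metric, gene_map, path = NULL) {
  if (is.null(names(metric))) stop("'metric' must be named by probe id")
  gm <- gene_map[!is.na(gene_map$gene), c("probe_id", "gene")]
  if (nrow(gm) == 0L) stop("empty gene map")
  metric <- metric[is.finite(metric)]
  o <- order(-metric, names(metric))
  ranked_probes <- names(metric)[o]
  genes <- gm$gene[match(ranked_probes, gm$probe_id)]
  genes <- genes[!is.na(genes)]
  genes <- genes[!duplicated(genes)]
  if (!is.null(path)) writeLines(genes, path)
  genes
}

#' Birth weight discordance between co-twins
#'
#' `100 * (heavier - lighter) / heavier`, in percent.
#'
#' @param w1,w2 co-twin weights in grams (> 0); vectorised.
#' @return percent discordance.
#' @export
weight_discordance <- function(w1, w2) {
  if (any(c(w1, w2) <= 0)) stop("weights must be positive")
  hi <- pmax(w1, w2)
  lo <- pmin(w1, w2)
  100 * (hi - lo) / hi
}
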