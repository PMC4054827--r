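#' Convert beta values to M-values and back
#'
#' M-values are the log2 ratio of methylated to unmethylated signal, which
#' for a beta (methylation proportion) equals `log2(beta / (1 - beta))`.
#' Betas are clipped to `[eps, 1 - eps]` before the transform so M stays
#' finite; the inverse recovers the clipped beta.
#'
#' @param beta numeric vector/matrix of proportions in \[0,1\].
#' @param m numeric vector/matrix of M-values (log2 units).
#' @param eps clipping bound (default 1e-6).
#' @return the transformed values, preserving dimensions.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (!is.null(dim(beta))) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  dimnames(out) <- dimnames(m)
  out
}

#' Probe-level detection filter
#'
#' A probe is retained only if its detection p-value is <= `threshold` in
#' every sample; a single sample exceeding the threshold removes the probe
#' (strictly-greater at the boundary).
#'
#' @param detp probe x sample detection p-value matrix.
#' @param threshold detection p-value cutoff (default 0.001).
#' @return logical vector, `TRUE` = probe retained.
#' @export
filter_probes_by_detection <- function(detp, threshold = 0.001) {
  check_detp(detp, threshold)
  apply(detp, 1, function(p) all(p <= threshold, na.rm = TRUE))
}

#' Sample-level detection filter
#'
#' A sample is retained iff its mean detection p-value over probes is
#' <= `threshold` (retained at the boundary).
#'
#' @param detp probe x sample detection p-value matrix.
#' @param threshold mean detection p-value cutoff (default 0.05).
#' @return logical vector over samples, `TRUE` = retained.
#' @export
filter_samples_by_detection <- function(detp, threshold = 0.05) {
  check_detp(detp, threshold)
  colMeans(detp, na.rm = TRUE) <= threshold
}

check_detp <- function(detp, threshold) {
  if (!is.matrix(detp) || nrow(detp) == 0L || ncol(detp) == 0L)
    stop("'detp' must be a non-empty matrix")
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)")
  invisible(TRUE)
}

#' Remove probes on the sex chromosomes
#'
#' @param mat probe x sample matrix with probe ids as rownames.
#' @param manifest probe manifest covering all rows of `mat`.
#' @return the matrix restricted to autosomal probes.
#' @export
drop_sex_chromosomes <- function(mat, manifest) {
  idx <- match(rownames(mat), manifest$probe_id)
  if (anyNA(idx))
    stop("probe(s) missing from manifest: ",
         paste(utils::head(rownames(mat)[is.na(idx)], 5), collapse = ", "))
  keep <- !(manifest$chrom[idx] %in% c("chrX", "chrY"))
  if (!any(keep)) warning("all probes lie on sex chromosomes; empty matrix returned")
  mat[keep, , drop = FALSE]
}

#' Within-array adjustment of Infinium design bias
#'
#' Infinium II probes have compressed beta distributions relative to
#' Infinium I. Within each array, type II beta values are mapped onto the
#' empirical quantiles of the type I probes in the same CpG-island-relation
#' stratum; type I values are unchanged. The map is monotone, so the
#' within-array rank order of type II probes is preserved.
#'
#' @param beta probe x sample beta matrix (rownames = probe ids).
#' @param manifest probe manifest providing `design_type` and
#'   `island_relation` per probe.
#' @return the adjusted beta matrix.
#' @export
adjust_design_bias <- function(beta, manifest) {
  idx <- match(rownames(beta), manifest$probe_id)
  if (anyNA(idx)) stop("probe(s) missing from manifest")
  type <- manifest$design_type[idx]
  strat <- manifest$island_relation[idx]
  if (!any(type == "I") || !any(type == "II")) {
    warning("a design class is absent; returning beta unchanged")
    return(beta)
  }
  out <- beta
  for (st in unique(strat)) {
    i1 <- which(type == "I" & strat == st)
    i2 <- which(type == "II" & strat == st)
    if (length(i1) < 2L || length(i2) == 0L) next
    for (j in seq_len(ncol(beta))) {
      x2 <- beta[i2, j]
      r <- rank(x2, ties.method = "average")
      out[i2, j] <- stats::quantile(beta[i1, j],
                                    probs = (r - 0.5) / length(x2),
                                    names = FALSE, type = 7)
    }
  }
  out
}

#' Between-array quantile normalization
#'
#' Forces every column to the same reference distribution (the mean of the
#' per-column sorted value vectors), preserving ranks within columns. Tied
#' ranks receive the mean of the corresponding reference values.
#'
#' @param m probe x sample matrix (typically M-values).
#' @return the normalized matrix.
#' @export
quantile_normalize_between_arrays <- function(m) {
  if (ncol(m) < 2L) {
    warning("fewer than 2 samples; returning input unchanged")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    v <- ref
    # ties: average the reference values across each tied block
    x <- m[o, j]
    ties <- ave(v, match(x, unique(x)), FUN = mean)
    out[o, j] <- ties
  }
  out
}

#' Run the full quality-control and normalization chain
#'
#' Applies, in order: probe detection filter, sample detection filter,
#' user-supplied sample exclusions, sex-chromosome removal, within-array
#' design-bias adjustment (beta scale), beta-to-M transform, and
#' between-array quantile normalization (M scale).
#'
#' @param cohort a `twin_cohort` (or list with `beta`, `detp`, `samples`,
#'   `manifest`).
#' @param probe_p probe detection threshold (default 0.001).
#' @param sample_p sample mean-detection threshold (default 0.05).
#' @param exclude_samples character vector of sample ids to drop (manual
#'   outlier list).
#' @return a list of class `twin_qc`: `beta` (normalized on the beta scale
#'   via the adjusted values), `m` (quantile-normalized M-values), `samples`
#'   (retained sample sheet), `manifest`, and `report` (counts removed per
#'   rule and per-sample detection means).
#' @export
qc_pipeline <- function(cohort, probe_p = 0.001, sample_p = 0.05,
                        exclude_samples = character()) {
  beta <- cohort$beta
  detp <- cohort$detp
  keep_probe <- filter_probes_by_detection(detp, probe_p)
  keep_sample <- filter_samples_by_detection(detp, sample_p)
  manual <- colnames(beta) %in% exclude_samples
  keep_sample <- keep_sample & !manual

  beta <- beta[keep_probe, keep_sample, drop = FALSE]
  n_before_sex <- nrow(beta)
  beta <- drop_sex_chromosomes(beta, cohort$manifest)
  beta_adj <- adjust_design_bias(beta, cohort$manifest)
  m <- beta_to_m(beta_adj)
  m_norm <- quantile_normalize_between_arrays(m)
  beta_norm <- m_to_beta(m_norm)

  samples <- cohort$samples[match(colnames(beta), cohort$samples$sample_id), ]
  rownames(samples) <- NULL
  report <- list(
    n_probes_in = nrow(cohort$beta),
    n_samples_in = ncol(cohort$beta),
    probes_failed_detection = sum(!keep_probe),
    samples_failed_detection = sum(colMeans(detp, na.rm = TRUE) > sample_p),
    samples_excluded_manually = sum(manual),
    probes_on_sex_chromosomes = n_before_sex - nrow(beta),
    n_probes_out = nrow(beta),
    n_samples_out = ncol(beta),
    sample_mean_detp = colMeans(detp, na.rm = TRUE))
  structure(list(beta = beta_norm, m = m_norm, samples = samples,
                 manifest = cohort$manifest, report = report),
            class = "twin_qc")
}

#' @export
print.twin_qc <- function(x, ...) {
  r <- x$report
  cat("Methylation QC summary\n")
  cat(sprintf("  probes: %d in -> %d out (%d failed detection, %d on chrX/Y)\n",
              r$n_probes_in, r$n_probes_out, r$probes_failed_detection,
              r$probes_on_sex_chromosomes))
  cat(sprintf("  arrays: %d in -> %d out (%d failed detection, %d excluded manually)\n",
              r$n_samples_in, r$n_samples_out, r$samples_failed_detection,
              r$samples_excluded_manually))
  invisible(x)
}
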