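#' Simulation configuration for a synthetic twin methylation cohort
#'
#' Collects the parameters of the generative model used by
#' [generate_cohort()]. Methylation is modelled additively on the log2-odds
#' (M-value) scale and transformed back to beta values, so beta stays in
#' \[0,1\] and M-value analysis is natural:
#'
#' \deqn{logit2(\beta_{gits}) = \mu_g + a_g \cdot 1[t = m18] + G_{gi} +
#'   C_{gp} + \lambda_p^{1[t = m18]} E_{git}}
#'
#' where \eqn{\mu_g} is the probe baseline, \eqn{a_g} the planted age effect
#' (expressed as a target beta shift, converted per probe to the log2-odds
#' offset that produces it), \eqn{G} a genetic component shared exactly by MZ
#' co-twins and with correlation `dz_genetic_correlation` by DZ co-twins,
#' \eqn{C} a shared (common) environment component per pair and \eqn{E} a
#' non-shared stochastic component drawn per individual and timepoint. The
#' pair-specific factor \eqn{\lambda_p} scales only the non-shared component
#' at the second timepoint: \eqn{\lambda > 1} makes a pair drift apart,
#' \eqn{\lambda < 1} converge, \eqn{\lambda = 1} stay stable.
#'
#' Defaults encode the study design being emulated: 15 pairs (2/3 MZ) at two
#' timepoints (birth, 18 months), 20,000 probes, planted age effects of
#' +/-0.25 beta with 87% gains, enrichment of age effects in intergenic /
#' enhancer / open-sea probes, ten planted multi-probe DMRs, and pair
#' dynamics split evenly over drift (1.6), stable (1.0) and converge (0.6).
#'
#' @param n_pairs number of twin pairs.
#' @param mz_fraction fraction of pairs that are monozygotic.
#' @param n_probes number of probes (must match the manifest).
#' @param frac_age_affected fraction of autosomal probes given an isolated
#'   age effect (planted DMR probes are additional).
#' @param age_effect_mean_beta planted age effect size in beta units.
#' @param gain_fraction probability an age effect is a methylation gain.
#' @param region_enrichment_weights named relative odds that a probe carries
#'   an age effect, keyed by `island`, `shore`, `shelf`, `open_sea`,
#'   `intergenic`, `enhancer`; a probe's odds are the product of its
#'   island-relation weight, the intergenic weight if intergenic, and the
#'   enhancer weight if flagged.
#' @param sigma_genetic,sigma_shared_env,sigma_nonshared,sigma_technical
#'   standard deviations of the variance components, log2-odds units.
#' @param dz_genetic_correlation genetic correlation for DZ co-twins.
#' @param pair_dynamics either `NULL` (default: lambda cycles over
#'   1.6 / 1.0 / 0.6 across pairs) or a named numeric vector of positive
#'   drift factors keyed by pair id (`P01`, `P02`, ...).
#' @param n_planted_dmrs number of multi-probe regions with a common planted
#'   age effect.
#' @param dmr_probe_span integer range (length 2) of probes per planted DMR.
#' @param detection_failure_rate fraction of probes given failing detection
#'   p-values (> 0.05) in at least one sample.
#' @param design_bias_compression compression of Infinium II beta values
#'   toward 0.5 (0 disables), exercising the design-bias adjustment.
#' @param seed integer seed for the cohort RNG stream.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_pairs = 15L, mz_fraction = 2 / 3,
                              n_probes = 20000L, frac_age_affected = 0.02,
                              age_effect_mean_beta = 0.25,
                              gain_fraction = 0.87,
                              region_enrichment_weights = c(
                                island = 0.25, shore = 1, shelf = 1,
                                open_sea = 1.7, intergenic = 6, enhancer = 2.5),
                              sigma_genetic = 0.4, sigma_shared_env = 0.3,
                              sigma_nonshared = 0.28, sigma_technical = 0.05,
                              dz_genetic_correlation = 0.5,
                              pair_dynamics = NULL, n_planted_dmrs = 10L,
                              dmr_probe_span = c(5L, 8L),
                              detection_failure_rate = 0.01,
                              design_bias_compression = 0.1, seed = 1L) {
  props <- c(mz_fraction = mz_fraction, frac_age_affected = frac_age_affected,
             gain_fraction = gain_fraction,
             dz_genetic_correlation = dz_genetic_correlation,
             detection_failure_rate = detection_failure_rate)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  sigmas <- c(sigma_genetic, sigma_shared_env, sigma_nonshared, sigma_technical)
  if (any(sigmas < 0)) stop("all sigmas must be >= 0")
  if (n_pairs < 1 || n_probes < 1) stop("counts must be positive")
  if (!is.null(pair_dynamics) && any(pair_dynamics <= 0))
    stop("pair dynamics factors (lambda) must be > 0")
  if (age_effect_mean_beta < 0 || age_effect_mean_beta >= 0.5)
    stop("'age_effect_mean_beta' must lie in [0, 0.5)")
  if (length(dmr_probe_span) != 2L || dmr_probe_span[1] > dmr_probe_span[2] ||
      dmr_probe_span[1] < 4L)
    stop("'dmr_probe_span' must be an increasing range with minimum >= 4")
  cfg <- list(n_pairs = as.integer(n_pairs), mz_fraction = mz_fraction,
              n_probes = as.integer(n_probes),
              frac_age_affected = frac_age_affected,
              age_effect_mean_beta = age_effect_mean_beta,
              gain_fraction = gain_fraction,
              region_enrichment_weights = region_enrichment_weights,
              sigma_genetic = sigma_genetic,
              sigma_shared_env = sigma_shared_env,
              sigma_nonshared = sigma_nonshared,
              sigma_technical = sigma_technical,
              dz_genetic_correlation = dz_genetic_correlation,
              pair_dynamics = pair_dynamics,
              n_planted_dmrs = as.integer(n_planted_dmrs),
              dmr_probe_span = as.integer(dmr_probe_span),
              detection_failure_rate = detection_failure_rate,
              design_bias_compression = design_bias_compression,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

default_pair_dynamics <- function(pair_ids) {
  lam <- rep(c(1.6, 1.0, 0.6), length.out = length(pair_ids))
  names(lam) <- pair_ids
  lam
}

dynamics_label_from_lambda <- function(lambda) {
  ifelse(lambda > 1, "drift", ifelse(lambda < 1, "converge", "stable"))
}

#' Generate a synthetic twin cohort
#'
#' Draws a beta-value matrix, matched detection p-value matrix, sample sheet
#' and ground-truth tables under the variance-component model described in
#' [simulation_config()]. MZ co-twins share the genetic draw exactly; DZ
#' co-twins share it with correlation `dz_genetic_correlation`. Age effects
#' are assigned to autosomal probes with odds proportional to the configured
#' region weights, positive (methylation gain) with probability
#' `gain_fraction`, and realised per probe as the log2-odds offset giving the
#' target beta shift at that probe's baseline. Planted DMRs impose a common
#' beta shift on runs of consecutive probes (inter-probe gap <= 1 kb) on one
#' chromosome. Detection p-values are near zero except for a
#' `detection_failure_rate` fraction of probes that receive values > 0.05 in
#' at least one sample (these are recorded in the truth table as QC
#' failures). Infinium II beta values are compressed toward 0.5 by
#' `design_bias_compression` to emulate design bias.
#'
#' @param config a [simulation_config()] object.
#' @param manifest a probe manifest from [generate_manifest()] with
#'   `config$n_probes` rows.
#' @return an object of class `twin_cohort`: list with `beta`, `detp`
#'   (probe x sample matrices), `samples` (sample sheet), `truth`
#'   (list `probes`, `pairs`), `manifest`, `config`.
#' @export
generate_cohort <- function(config, manifest) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  if (nrow(manifest) != config$n_probes)
    stop("manifest row count (", nrow(manifest),
         ") does not match config$n_probes (", config$n_probes, ")")
  set.seed(config$seed)

  n_probes <- config$n_probes
  n_pairs <- config$n_pairs
  pair_ids <- sprintf("P%02d", seq_len(n_pairs))
  n_mz <- round(config$mz_fraction * n_pairs)
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_pairs - n_mz))
  # monochorionic placentation only occurs in MZ pairs
  chor <- ifelse(zyg == "MZ" & stats::runif(n_pairs) < 0.5, "MC", "DC")
  sex <- sample(c("M", "F"), n_pairs, replace = TRUE)
  lambda <- if (is.null(config$pair_dynamics)) default_pair_dynamics(pair_ids)
            else config$pair_dynamics[pair_ids]
  if (any(is.na(lambda))) stop("pair_dynamics must name every pair id")

  # birth weights: pair mean around 2.5 kg with within-pair discordance
  pair_w <- stats::rnorm(n_pairs, 2500, 350)
  disc <- abs(stats::rnorm(n_pairs, 0, 0.12))
  w1 <- pair_w * (1 + disc / 2)
  w2 <- pair_w * (1 - disc / 2)

  timepoints <- c("birth", "m18")
  samples <- expand.grid(twin_index = 1:2, pair_id = pair_ids,
                         timepoint = timepoints, stringsAsFactors = FALSE)
  samples <- samples[order(samples$pair_id, samples$twin_index,
                           samples$timepoint), ]
  pi <- match(samples$pair_id, pair_ids)
  samples <- data.frame(
    sample_id = sprintf("%s_T%d_%s", samples$pair_id, samples$twin_index,
                        ifelse(samples$timepoint == "birth", "B", "18")),
    pair_id = samples$pair_id, twin_index = samples$twin_index,
    zygosity = zyg[pi], chorionicity = chor[pi], sex = sex[pi],
    timepoint = samples$timepoint, replicate_id = 1L,
    birth_weight = round(ifelse(samples$twin_index == 1, w1[pi], w2[pi])),
    stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  n_samp <- nrow(samples)

  autosomal <- !(manifest$chrom %in% c("chrX", "chrY"))

  # probe baselines: bimodal like real arrays
  comp <- stats::runif(n_probes)
  beta0 <- ifelse(comp < 0.4, stats::rbeta(n_probes, 2, 8),
           ifelse(comp < 0.8, stats::rbeta(n_probes, 8, 2),
                  stats::runif(n_probes, 0.2, 0.8)))

  # ---- planted age effects (isolated aDMPs) -------------------------------
  w <- config$region_enrichment_weights
  probe_w <- w[manifest$island_relation]
  probe_w[manifest$gene_feature == "intergenic"] <-
    probe_w[manifest$gene_feature == "intergenic"] * w[["intergenic"]]
  probe_w[manifest$enhancer] <- probe_w[manifest$enhancer] * w[["enhancer"]]
  probe_w[!autosomal] <- 0

  # ---- planted DMRs on runs of consecutive dense probes -------------------
  # clusters are chosen with the same region odds as isolated age effects,
  # so planted regions share the annotation skew of planted probes
  dmr_id <- rep(NA_integer_, n_probes)
  if (config$n_planted_dmrs > 0) {
    cl <- probe_position_clusters(manifest, maxgap = 1000)
    span_max <- config$dmr_probe_span[2]
    cl_auto <- cl[autosomal]
    cl_sizes <- table(cl_auto)
    eligible <- as.integer(names(cl_sizes)[cl_sizes >= span_max])
    if (length(eligible) < config$n_planted_dmrs)
      stop("manifest too sparse to plant ", config$n_planted_dmrs, " DMRs")
    cl_w <- vapply(eligible, function(cc) mean(probe_w[cl == cc]), numeric(1))
    chosen <- sample(eligible, config$n_planted_dmrs, prob = pmax(cl_w, 1e-9))
    for (d in seq_along(chosen)) {
      idx <- which(cl == chosen[d] & autosomal)
      span <- sample(seq(config$dmr_probe_span[1], config$dmr_probe_span[2]), 1)
      span <- min(span, length(idx))
      start <- sample(seq_len(length(idx) - span + 1L), 1)
      dmr_id[idx[start:(start + span - 1L)]] <- d
    }
  }

  n_aff <- round(config$frac_age_affected * sum(autosomal))
  pool <- which(probe_w > 0 & is.na(dmr_id))
  affected <- sample(pool, min(n_aff, length(pool)), prob = probe_w[pool])

  true_delta <- numeric(n_probes)
  eff <- config$age_effect_mean_beta
  sgn <- function(k) ifelse(stats::runif(k) < config$gain_fraction, 1, -1)
  true_delta[affected] <- eff * sgn(length(affected))
  if (config$n_planted_dmrs > 0) {
    dmr_sign <- sgn(config$n_planted_dmrs)
    in_dmr <- which(!is.na(dmr_id))
    true_delta[in_dmr] <- eff * dmr_sign[dmr_id[in_dmr]]
  }

  # re-draw baselines of affected probes so both endpoints of the shift sit
  # well inside the assay's dynamic range (mid-methylation band)
  up <- true_delta > 0
  dn <- true_delta < 0
  beta0[up] <- stats::runif(sum(up), 0.25, 0.55)
  beta0[dn] <- stats::runif(sum(dn), 0.45, 0.75)

  mu <- beta_to_m(beta0)
  a_g <- numeric(n_probes)
  nz <- true_delta != 0
  a_g[nz] <- beta_to_m(beta0[nz] + true_delta[nz]) - mu[nz]

  # ---- variance components ------------------------------------------------
  rho <- config$dz_genetic_correlation
  G <- matrix(0, n_probes, n_pairs * 2)        # per individual
  Cm <- matrix(stats::rnorm(n_probes * n_pairs, 0, config$sigma_shared_env),
               n_probes, n_pairs)
  for (p in seq_len(n_pairs)) {
    zc <- stats::rnorm(n_probes)
    if (zyg[p] == "MZ") {
      g1 <- g2 <- config$sigma_genetic * zc
    } else {
      g1 <- config$sigma_genetic * (sqrt(rho) * zc + sqrt(1 - rho) * stats::rnorm(n_probes))
      g2 <- config$sigma_genetic * (sqrt(rho) * zc + sqrt(1 - rho) * stats::rnorm(n_probes))
    }
    G[, 2 * p - 1] <- g1
    G[, 2 * p] <- g2
  }

  beta <- matrix(NA_real_, n_probes, n_samp,
                 dimnames = list(manifest$probe_id, samples$sample_id))
  for (s in seq_len(n_samp)) {
    p <- match(samples$pair_id[s], pair_ids)
    ind <- 2 * p - 2 + samples$twin_index[s]
    at18 <- samples$timepoint[s] == "m18"
    lam <- if (at18) lambda[p] else 1
    E <- stats::rnorm(n_probes, 0, config$sigma_nonshared) * lam
    m <- mu + (if (at18) a_g else 0) + G[, ind] + Cm[, p] + E
    b <- m_to_beta(m)
    ii <- manifest$design_type == "II"
    b[ii] <- 0.5 + (b[ii] - 0.5) * (1 - config$design_bias_compression)
    beta[, s] <- b
  }

  # ---- detection p-values -------------------------------------------------
  detp <- matrix(stats::runif(n_probes * n_samp, 0, 1e-4), n_probes, n_samp,
                 dimnames = dimnames(beta))
  n_fail <- round(config$detection_failure_rate * n_probes)
  qc_fail <- rep(FALSE, n_probes)
  if (n_fail > 0) {
    fail_probes <- sample(n_probes, n_fail)
    qc_fail[fail_probes] <- TRUE
    for (g in fail_probes) {
      k <- sample(n_samp, 1 + stats::rbinom(1, 3, 0.3))
      detp[g, k] <- stats::runif(length(k), 0.06, 0.5)
    }
  }

  truth_probes <- data.frame(probe_id = manifest$probe_id,
                             true_delta_beta = true_delta,
                             dmr_id = dmr_id, qc_fail = qc_fail,
                             stringsAsFactors = FALSE)
  truth_pairs <- data.frame(pair_id = pair_ids, zygosity = zyg,
                            lambda = unname(lambda),
                            dynamics = dynamics_label_from_lambda(unname(lambda)),
                            stringsAsFactors = FALSE)

  structure(list(beta = beta, detp = detp, samples = samples,
                 truth = list(probes = truth_probes, pairs = truth_pairs),
                 manifest = manifest, config = config),
            class = "twin_cohort")
}

# cluster ids over probe positions (gap <= maxgap chains), used both to
# plant DMRs and by the bump hunter; manifest assumed position-sorted per chrom
probe_position_clusters <- function(manifest, maxgap = 1000) {
  ids <- integer(nrow(manifest))
  nxt <- 0L
  for (ch in unique(manifest$chrom)) {
    i <- which(manifest$chrom == ch)
    pos <- manifest$pos[i]
    if (is.unsorted(pos)) stop("probe positions must be sorted within ", ch)
    brk <- c(0L, cumsum(diff(pos) > maxgap))
    ids[i] <- nxt + brk + 1L
    nxt <- max(ids[i])
  }
  ids
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("Synthetic twin methylation cohort\n")
  cat("  probes:", nrow(x$beta), " arrays:", ncol(x$beta), "\n")
  cat("  pairs:", length(unique(x$samples$pair_id)),
      sprintf("(%d MZ / %d DZ)\n",
              sum(x$truth$pairs$zygosity == "MZ"),
              sum(x$truth$pairs$zygosity == "DZ")))
  cat("  planted age effects:", sum(x$truth$probes$true_delta_beta != 0),
      "probes;", length(unique(stats::na.omit(x$truth$probes$dmr_id))),
      "planted DMRs\n")
  invisible(x)
}

#' Add technical replicate arrays to a cohort
#'
#' Duplicates every array of the listed pairs (both co-twins at both
#' timepoints) with added noise of scale `sigma_technical` on the log2-odds
#' scale, incrementing `replicate_id`. With `sigma_technical = 0` the new
#' arrays are bit-identical to the originals.
#'
#' @param cohort a `twin_cohort`.
#' @param pair_ids pairs to replicate (default: first three MZ pairs).
#' @param sigma_technical noise sd on the log2-odds scale (default from the
#'   cohort's configuration).
#' @return the augmented `twin_cohort`.
#' @export
inject_technical_replicates <- function(cohort, pair_ids = NULL,
                                        sigma_technical = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (is.null(pair_ids)) {
    mz <- cohort$truth$pairs$pair_id[cohort$truth$pairs$zygosity == "MZ"]
    pair_ids <- utils::head(mz, 3)
  }
  unknown <- setdiff(pair_ids, cohort$samples$pair_id)
  if (length(unknown))
    stop("unknown pair id(s): ", paste(unknown, collapse = ", "))
  if (is.null(sigma_technical)) sigma_technical <- cohort$config$sigma_technical
  if (sigma_technical < 0) stop("'sigma_technical' must be >= 0")

  sel <- which(cohort$samples$pair_id %in% pair_ids &
               cohort$samples$replicate_id == 1L)
  new_samples <- cohort$samples[sel, ]
  new_samples$replicate_id <- 2L
  new_samples$sample_id <- paste0(new_samples$sample_id, "_r2")

  m <- beta_to_m(cohort$beta[, sel, drop = FALSE])
  if (sigma_technical > 0)
    m <- m + stats::rnorm(length(m), 0, sigma_technical)
  new_beta <- m_to_beta(m)
  colnames(new_beta) <- new_samples$sample_id
  new_detp <- cohort$detp[, sel, drop = FALSE]
  colnames(new_detp) <- new_samples$sample_id

  cohort$beta <- cbind(cohort$beta, new_beta)
  cohort$detp <- cbind(cohort$detp, new_detp)
  cohort$samples <- rbind(cohort$samples, new_samples)
  rownames(cohort$samples) <- NULL
  cohort
}

#' Write a cohort to tab-separated files
#'
#' Emits `beta.tsv`, `detp.tsv` (probe_id row key, sample_id columns, `.` for
#' missing), `samples.tsv`, `manifest.tsv`, `truth.tsv` (per-probe ground
#' truth) and `truth_pairs.tsv` (per-pair dynamics truth) into `out_dir`.
#' Beta column order equals the sample-sheet row order. The files round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort a `twin_cohort`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (nrow(cohort$beta) == 0L || ncol(cohort$beta) == 0L)
    stop("refusing to write an empty cohort")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("beta.tsv", "detp.tsv", "samples.tsv",
                                "manifest.tsv", "truth.tsv",
                                "truth_pairs.tsv"))
  write_matrix_tsv(cohort$beta, paths[1])
  write_matrix_tsv(cohort$detp, paths[2])
  data.table::fwrite(cohort$samples, paths[3], sep = "\t", na = ".")
  data.table::fwrite(cohort$manifest, paths[4], sep = "\t", na = ".")
  data.table::fwrite(cohort$truth$probes, paths[5], sep = "\t", na = ".")
  data.table::fwrite(cohort$truth$pairs, paths[6], sep = "\t", na = ".")
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the TSV files.
#' @return a `twin_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("beta.tsv", "detp.tsv", "samples.tsv",
                           "manifest.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing cohort file(s): ", paste(basename(missing), collapse = ", "))
  beta <- read_matrix_tsv(need[1])
  detp <- read_matrix_tsv(need[2])
  samples <- as.data.frame(data.table::fread(need[3], sep = "\t", na.strings = "."))
  manifest <- as.data.frame(data.table::fread(need[4], sep = "\t", na.strings = "."))
  truth <- NULL
  tp <- file.path(dir, "truth.tsv")
  tq <- file.path(dir, "truth_pairs.tsv")
  if (file.exists(tp))
    truth <- list(probes = as.data.frame(data.table::fread(tp, sep = "\t", na.strings = ".")),
                  pairs = if (file.exists(tq))
                    as.data.frame(data.table::fread(tq, sep = "\t", na.strings = ".")) else NULL)
  structure(list(beta = beta, detp = detp, samples = samples,
                 truth = truth, manifest = manifest, config = NULL),
            class = "twin_cohort")
}

write_matrix_tsv <- function(m, path) {
  dt <- data.table::data.table(probe_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t", na = ".")
}

read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = ".")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
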