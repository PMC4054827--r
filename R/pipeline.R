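#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list with per-stage sections and
#' checks every key against the known schema before any computation.
#' Sections (all optional): `simulation` (arguments of
#' [simulation_config()] plus `n_islands`, `replicate_pairs`), `qc`
#' (`probe_p`, `sample_p`, `exclude_samples`), `dm` (`fdr`,
#' `min_delta_beta`), `dmr` (`maxgap`, `cutoff_quantile`, `min_probes`,
#' `window`, `tss_window`), `discordance` (`disc_threshold`,
#' `rel_threshold`), `structure` (`linkage`), plus top-level `out_dir`,
#' `seed`, `verbose`.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  schema <- list(
    simulation = c(names(formals(simulation_config)), "n_islands",
                   "replicate_pairs"),
    qc = c("probe_p", "sample_p", "exclude_samples"),
    dm = c("fdr", "min_delta_beta"),
    dmr = c("maxgap", "cutoff_quantile", "min_probes", "window", "tss_window"),
    discordance = c("disc_threshold", "rel_threshold"),
    structure = c("linkage"))
  top <- c(names(schema), "out_dir", "seed", "verbose")
  bad <- setdiff(names(config), top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(schema)) {
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  config$out_dir <- config$out_dir %||% tempfile("twindrift_run_")
  config$seed <- as.integer(config$seed %||% 1L)
  config$verbose <- isTRUE(config$verbose %||% TRUE)
  class(config) <- "pipeline_config"
  config
}

pipe_log <- function(cfg, stage, ...) {
  if (cfg$verbose) message("[", stage, "] ", ...)
}

write_provenance <- function(cfg, stage, params, inputs = character()) {
  prov <- list(stage = stage, seed = cfg$seed, params = params,
               package_version = as.character(utils::packageVersion("twindrift")),
               input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(prov,
                       file.path(cfg$out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

require_upstream <- function(cfg, files, producer) {
  paths <- file.path(cfg$out_dir, files)
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("missing input file(s) ", paste(basename(miss), collapse = ", "),
         "; run stage '", producer, "' first", call. = FALSE)
  invisible(paths)
}

#' Run pipeline stages
#'
#' Executes the analysis chain on a configuration: `simulate` (synthetic
#' cohort written as TSV), `qc` (filters + normalization), `dm` (moderated
#' paired differential methylation and aDMP calling), `dmr` (bump-hunting
#' regions + BED export), `enrich` (annotation enrichment of the stringent
#' aDMPs), `discordance` (per-pair profiles, dynamics labels, ranked gene
#' lists), `structure` (hierarchical clustering, Newick export, co-twin
#' pairing fractions) and `report` (Markdown summary of all stage JSONs).
#' Each stage reads its inputs from `out_dir`, writes its outputs there
#' along with a provenance JSON (parameters, seed, input checksums,
#' package version), and fails with the name of the producing stage when an
#' upstream output is missing. Rerunning with the same config and seed
#' reproduces every numeric output exactly.
#'
#' @param config a [pipeline_config()] (or list / YAML path coerced to
#'   one).
#' @param stages character vector of stages to run, in order.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "qc", "dm", "dmr", "enrich",
                                    "discordance", "structure", "report")) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  known <- c("simulate", "qc", "dm", "dmr", "enrich", "discordance",
             "structure", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in stages) {
    switch(st,
           simulate = stage_simulate(cfg),
           qc = stage_qc(cfg),
           dm = stage_dm(cfg),
           dmr = stage_dmr(cfg),
           enrich = stage_enrich(cfg),
           discordance = stage_discordance(cfg),
           structure = stage_structure(cfg),
           report = stage_report(cfg))
  }
  invisible(cfg$out_dir)
}

stage_simulate <- function(cfg) {
  sim <- cfg$simulation %||% list()
  n_islands <- sim$n_islands
  rep_pairs <- sim$replicate_pairs
  sim$n_islands <- NULL
  sim$replicate_pairs <- NULL
  if (is.null(sim$seed)) sim$seed <- cfg$seed
  sc <- do.call(simulation_config, sim)
  man_args <- list(n_probes = sc$n_probes, seed = sc$seed + 1L)
  if (!is.null(n_islands)) man_args$n_islands <- n_islands
  manifest <- do.call(generate_manifest, man_args)
  cohort <- generate_cohort(sc, manifest)
  if (!is.null(rep_pairs)) {
    if (isTRUE(rep_pairs)) rep_pairs <- NULL      # default: first 3 MZ pairs
    cohort <- inject_technical_replicates(cohort, pair_ids = rep_pairs)
  }
  pipe_log(cfg, "simulate", "cohort: ", nrow(cohort$beta), " probes x ",
           ncol(cohort$beta), " arrays")
  write_cohort(cohort, cfg$out_dir)
  write_provenance(cfg, "simulate", unclass(sc))
}

stage_qc <- function(cfg) {
  ins <- require_upstream(cfg, c("beta.tsv", "detp.tsv", "samples.tsv",
                                 "manifest.tsv"), "simulate")
  cohort <- read_cohort(cfg$out_dir)
  q <- cfg$qc %||% list()
  qc <- qc_pipeline(cohort, probe_p = q$probe_p %||% 0.001,
                    sample_p = q$sample_p %||% 0.05,
                    exclude_samples = q$exclude_samples %||% character())
  pipe_log(cfg, "qc", qc$report$n_probes_out, " probes, ",
           qc$report$n_samples_out, " arrays retained")
  write_matrix_tsv(qc$m, file.path(cfg$out_dir, "m_norm.tsv"))
  write_matrix_tsv(qc$beta, file.path(cfg$out_dir, "beta_norm.tsv"))
  data.table::fwrite(qc$samples, file.path(cfg$out_dir, "samples_qc.tsv"),
                     sep = "\t", na = ".")
  jsonlite::write_json(qc$report, file.path(cfg$out_dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(cfg, "qc", q, ins)
}

read_qc_outputs <- function(cfg) {
  require_upstream(cfg, c("m_norm.tsv", "beta_norm.tsv", "samples_qc.tsv"),
                   "qc")
  list(m = read_matrix_tsv(file.path(cfg$out_dir, "m_norm.tsv")),
       beta = read_matrix_tsv(file.path(cfg$out_dir, "beta_norm.tsv")),
       samples = as.data.frame(data.table::fread(
         file.path(cfg$out_dir, "samples_qc.tsv"), sep = "\t", na.strings = ".")))
}

stage_dm <- function(cfg) {
  qc <- read_qc_outputs(cfg)
  p <- cfg$dm %||% list()
  fdr <- p$fdr %||% 0.05
  mdb <- p$min_delta_beta %||% 0.2
  res <- dm_test(qc)
  calls <- call_admps(res, fdr = fdr, min_delta_beta = mdb)
  dirs <- if (length(calls$stringent))
    direction_summary(calls$stringent, res) else c(gain = NA_real_, loss = NA_real_)
  data.table::fwrite(
    as.data.frame(res)[, c("probe_id", "delta_beta", "t", "p", "adj_p",
                           "direction")],
    file.path(cfg$out_dir, "differential.tsv"), sep = "\t", na = ".")
  writeLines(calls$stringent, file.path(cfg$out_dir, "admps_stringent.txt"))
  writeLines(calls$relaxed, file.path(cfg$out_dir, "admps_relaxed.txt"))
  summ <- list(n_tested = nrow(res),
               n_significant = length(calls$relaxed),
               n_stringent = length(calls$stringent),
               frac_significant = length(calls$relaxed) / nrow(res),
               gain_fraction = unname(dirs["gain"]),
               loss_fraction = unname(dirs["loss"]),
               mean_abs_delta_beta_significant =
                 mean(abs(res$delta_beta[res$probe_id %in% calls$relaxed])))
  jsonlite::write_json(summ, file.path(cfg$out_dir, "dm_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log(cfg, "dm", summ$n_significant, " significant probes (",
           summ$n_stringent, " stringent aDMPs)")
  write_provenance(cfg, "dm", p,
                   file.path(cfg$out_dir, c("m_norm.tsv", "beta_norm.tsv")))
}

stage_dmr <- function(cfg) {
  require_upstream(cfg, "differential.tsv", "dm")
  res <- as.data.frame(data.table::fread(
    file.path(cfg$out_dir, "differential.tsv"), sep = "\t", na.strings = "."))
  manifest <- as.data.frame(data.table::fread(
    file.path(cfg$out_dir, "manifest.tsv"), sep = "\t", na.strings = "."))
  p <- cfg$dmr %||% list()
  man_tested <- manifest[manifest$probe_id %in% res$probe_id, ]
  clusters <- cluster_probes(man_tested, maxgap = p$maxgap %||% 1000)
  stat <- stats::setNames(res$t, res$probe_id)
  dmrs <- find_dmrs(stat, clusters,
                    cutoff_quantile = p$cutoff_quantile %||% 0.995,
                    min_probes = p$min_probes %||% 4L,
                    window = p$window %||% 3L)
  data.table::fwrite(dmrs$dmrs, file.path(cfg$out_dir, "dmrs.tsv"),
                     sep = "\t", na = ".")
  write_dmrs_bed(dmrs, file.path(cfg$out_dir, "dmrs.bed"))
  tssw <- p$tss_window %||% 5000
  tss_dmr <- annotate_tss_proximity(dmrs, manifest, window = tssw)
  admps <- readLines(file.path(cfg$out_dir, "admps_stringent.txt"))
  tss_admp <- if (length(admps))
    annotate_tss_proximity(admps, manifest, window = tssw)$fraction else NA_real_
  summ <- list(n_dmrs = nrow(dmrs$dmrs), threshold = dmrs$threshold,
               frac_dmrs_near_tss = tss_dmr$fraction,
               frac_admps_near_tss = tss_admp)
  jsonlite::write_json(summ, file.path(cfg$out_dir, "dmr_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log(cfg, "dmr", summ$n_dmrs, " regions")
  write_provenance(cfg, "dmr", p, file.path(cfg$out_dir, "differential.tsv"))
}

stage_enrich <- function(cfg) {
  require_upstream(cfg, c("admps_stringent.txt", "differential.tsv"), "dm")
  manifest <- as.data.frame(data.table::fread(
    file.path(cfg$out_dir, "manifest.tsv"), sep = "\t", na.strings = "."))
  res <- as.data.frame(data.table::fread(
    file.path(cfg$out_dir, "differential.tsv"), sep = "\t", na.strings = "."))
  hits <- readLines(file.path(cfg$out_dir, "admps_stringent.txt"))
  if (length(hits) == 0L)
    hits <- readLines(file.path(cfg$out_dir, "admps_relaxed.txt"))
  universe <- res$probe_id
  prof <- enrichment_profile(hits, manifest, universe)
  data.table::fwrite(as.data.frame(prof),
                     file.path(cfg$out_dir, "enrichment.tsv"),
                     sep = "\t", na = ".")
  pipe_log(cfg, "enrich", "top category: ",
           prof$category[which.max(prof$ratio)])
  write_provenance(cfg, "enrich", list(),
                   file.path(cfg$out_dir, "admps_stringent.txt"))
}

stage_discordance <- function(cfg) {
  qc <- read_qc_outputs(cfg)
  manifest <- as.data.frame(data.table::fread(
    file.path(cfg$out_dir, "manifest.tsv"), sep = "\t", na.strings = "."))
  p <- cfg$discordance %||% list()
  prof <- pair_dynamics_profile(qc$beta, qc$samples,
                                disc_threshold = p$disc_threshold %||% 0.2,
                                rel_threshold = p$rel_threshold %||% 0.10)
  d_b <- attr(prof, "d_birth")
  d_18 <- attr(prof, "d_m18")
  dd <- delta_discordance(d_b, d_18)
  data.table::fwrite(as.data.frame(prof),
                     file.path(cfg$out_dir, "pair_dynamics.tsv"),
                     sep = "\t", na = ".")
  # Fig 5-style scatter/box data: per-probe mean discordance at each age
  data.table::fwrite(
    data.frame(probe_id = rownames(d_b),
               mean_discordance_birth = rowMeans(d_b, na.rm = TRUE),
               mean_discordance_m18 = rowMeans(d_18, na.rm = TRUE),
               mean_delta_discordance = rowMeans(dd$delta, na.rm = TRUE)),
    file.path(cfg$out_dir, "probe_discordance.tsv"), sep = "\t", na = ".")
  for (tp in c("birth", "m18")) {
    metric <- rowMeans(if (tp == "birth") d_b else d_18, na.rm = TRUE)
    rank_probes_for_ontology(metric, manifest,
                             path = file.path(cfg$out_dir,
                                              paste0("ranked_genes_", tp, ".txt")))
  }
  jsonlite::write_json(
    list(labels = as.list(table(prof$dynamics)),
         delta_discordance = dd$summary,
         pairs = as.data.frame(prof)),
    file.path(cfg$out_dir, "discordance_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log(cfg, "discordance",
           paste(sprintf("%s=%d", names(table(prof$dynamics)),
                         table(prof$dynamics)), collapse = ", "))
  write_provenance(cfg, "discordance", p,
                   file.path(cfg$out_dir, "beta_norm.tsv"))
}

stage_structure <- function(cfg) {
  qc <- read_qc_outputs(cfg)
  p <- cfg$structure %||% list()
  hc <- hierarchical_cluster(qc$m, linkage = p$linkage %||% "complete")
  dendrogram_newick(hc, file.path(cfg$out_dir, "dendrogram.nwk"))
  frac <- list()
  for (tp in c("birth", "m18")) for (zy in c("MZ", "DZ")) {
    f <- tryCatch(cotwin_pairing_fraction(qc$m, qc$samples, tp, zygosity = zy),
                  error = function(e) NULL)
    if (!is.null(f))
      frac[[paste(zy, tp, sep = "_")]] <-
        list(fraction = f$fraction, n_pairs = f$n_pairs)
  }
  jsonlite::write_json(frac, file.path(cfg$out_dir, "pairing_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log(cfg, "structure", "co-twin pairing fractions written")
  write_provenance(cfg, "structure", p, file.path(cfg$out_dir, "m_norm.tsv"))
}

stage_report <- function(cfg) {
  jsons <- c(qc = "qc_report.json", dm = "dm_summary.json",
             dmr = "dmr_summary.json", discordance = "discordance_summary.json",
             structure = "pairing_report.json")
  lines <- c("# Twin methylation pipeline report", "")
  for (nm in names(jsons)) {
    path <- file.path(cfg$out_dir, jsons[[nm]])
    if (!file.exists(path)) next
    lines <- c(lines, paste0("## ", nm), "", "```json",
               readLines(path), "```", "")
  }
  enr <- file.path(cfg$out_dir, "enrichment.tsv")
  if (file.exists(enr))
    lines <- c(lines, "## enrichment", "", "```",
               readLines(enr), "```", "")
  writeLines(lines, file.path(cfg$out_dir, "report.md"))
  pipe_log(cfg, "report", "report.md written")
}
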