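#' Build annotation category probe sets
#'
#' One probe set per category in four groups: gene features (TSS1500,
#' TSS200, UTR5, FirstExon, Body, UTR3, intergenic), CpG-island relation
#' (island, also split into intragenic/intergenic islands, shore, shelf,
#' open sea), known DMR classes (CDMR, RDMR) and regulatory regions
#' (promoter = TSS200/TSS1500, enhancer, DHS). Sets may overlap across
#' groups; categories with no members are retained as empty sets.
#'
#' @param manifest probe manifest.
#' @return named list of probe-id vectors with a `group` attribute mapping
#'   category -> group label.
#' @export
build_category_sets <- function(manifest) {
  gene_levels <- c("TSS1500", "TSS200", "UTR5", "FirstExon", "Body", "UTR3",
                   "intergenic")
  island_levels <- c("island", "shore", "shelf", "open_sea")
  bad <- setdiff(unique(manifest$gene_feature), gene_levels)
  if (length(bad)) stop("unknown gene feature label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(manifest$island_relation), island_levels)
  if (length(bad)) stop("unknown island relation label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(manifest$dmr_class), c("none", "CDMR", "RDMR"))
  if (length(bad)) stop("unknown DMR class label(s): ", paste(bad, collapse = ", "))

  id <- manifest$probe_id
  sets <- list()
  grp <- character()
  for (g in gene_levels) {
    sets[[g]] <- id[manifest$gene_feature == g]
    grp[g] <- "gene"
  }
  for (g in island_levels) {
    sets[[g]] <- id[manifest$island_relation == g]
    grp[g] <- "island"
  }
  isl <- manifest$island_relation == "island"
  sets[["island_intragenic"]] <- id[isl & manifest$gene_feature != "intergenic"]
  sets[["island_intergenic"]] <- id[isl & manifest$gene_feature == "intergenic"]
  grp[c("island_intragenic", "island_intergenic")] <- "island"
  for (g in c("CDMR", "RDMR")) {
    sets[[g]] <- id[manifest$dmr_class == g]
    grp[g] <- "dmr"
  }
  sets[["promoter"]] <- id[manifest$gene_feature %in% c("TSS200", "TSS1500")]
  sets[["enhancer"]] <- id[manifest$enhancer]
  sets[["dhs"]] <- id[manifest$dhs]
  grp[c("promoter", "enhancer", "dhs")] <- "regulatory"
  attr(sets, "group") <- grp
  sets
}

#' Hypergeometric enrichment of a hit set in one category
#'
#' Computes observed and expected overlap, the observed/expected ratio, and
#' hypergeometric tail probabilities: `p_enrich = P[X >= observed]` (the
#' reported `p_value`) and `p_deplete = P[X <= observed]`, with
#' `X ~ Hypergeometric(|universe|, |category|, |hits|)`.
#'
#' @param hits probe-id vector (subset of `universe`, non-empty).
#' @param category probe-id vector (subset of `universe`).
#' @param universe background probe-id vector (non-empty).
#' @return one-row data.frame `observed`, `expected`, `ratio`, `log2_ratio`,
#'   `p_value`, `p_enrich`, `p_deplete`.
#' @export
enrichment_test <- function(hits, category, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(hits) == 0L) stop("empty hit set")
  if (length(setdiff(hits, universe))) stop("hits must be a subset of the universe")
  category <- intersect(category, universe)
  N <- length(universe)
  K <- length(category)
  n <- length(hits)
  obs <- length(intersect(hits, category))
  expd <- n * K / N
  ratio <- if (expd > 0) obs / expd else NA_real_
  p_up <- stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
  p_dn <- stats::phyper(obs, K, N - K, n, lower.tail = TRUE)
  data.frame(observed = obs, expected = expd, ratio = ratio,
             log2_ratio = log2(ratio), p_value = p_up,
             p_enrich = p_up, p_deplete = p_dn)
}

#' Enrichment profile over all annotation categories
#'
#' Runs [enrichment_test()] for every category from
#' [build_category_sets()], orders rows by group then descending log2 ratio,
#' and assigns significance tiers on the direction-appropriate tail
#' (enrichment tail when ratio >= 1, depletion tail otherwise):
#' `*` p < 0.05, `**` p < 1e-20, `***` p < 1e-50. No multiple-testing
#' correction is applied across categories (raw tiers are reported; see the
#' `tier` column).
#'
#' @param hits probe-id hit set.
#' @param manifest probe manifest (categories are built from it).
#' @param universe background probe set (e.g. all QC-passing autosomal
#'   probes).
#' @return data.frame of class `enrich_profile` with `category`, `group`,
#'   `size`, the [enrichment_test()] columns and `tier`.
#' @export
enrichment_profile <- function(hits, manifest, universe) {
  sets <- build_category_sets(manifest)
  grp <- attr(sets, "group")
  rows <- lapply(names(sets), function(nm) {
    r <- enrichment_test(hits, sets[[nm]], universe)
    cbind(data.frame(category = nm, group = grp[[nm]],
                     size = length(intersect(sets[[nm]], universe)),
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  p_dir <- ifelse(!is.na(out$ratio) & out$ratio < 1, out$p_deplete, out$p_enrich)
  out$tier <- ifelse(p_dir < 1e-50, "***",
              ifelse(p_dir < 1e-20, "**",
              ifelse(p_dir < 0.05, "*", "")))
  out <- out[order(out$group, -out$log2_ratio), ]
  rownames(out) <- NULL
  class(out) <- c("enrich_profile", "data.frame")
  out
}

#' @export
print.enrich_profile <- function(x, ...) {
  cat("Annotation enrichment profile (", nrow(x), "categories )\n")
  df <- as.data.frame(x)
  df$expected <- round(df$expected, 1)
  df$ratio <- round(df$ratio, 2)
  df$log2_ratio <- round(df$log2_ratio, 2)
  print(df[, c("category", "group", "observed", "expected", "ratio", "tier")])
  invisible(x)
}
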