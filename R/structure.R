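#' Hierarchical clustering of samples
#'
#' Unsupervised agglomerative clustering of arrays with Euclidean distance
#' and, by default, complete linkage. Missing values are imputed by the
#' probe median first (with a message). Deterministic given the input
#' column order.
#'
#' @param m probe x sample matrix (typically M-values).
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"complete"`).
#' @return an `hclust` object over the samples.
#' @export
hierarchical_cluster <- function(m, linkage = "complete") {
  if (ncol(m) < 2L) stop("need at least 2 samples to cluster")
  if (anyNA(m)) {
    message("imputing missing values by probe median")
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      m[na, j] <- med[na]
    }
  }
  stats::hclust(stats::dist(t(m), method = "euclidean"), method = linkage)
}

#' Serialize a dendrogram as Newick
#'
#' @param hc an `hclust` object.
#' @param path optional file to write.
#' @return the Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  s <- ape::write.tree(tr)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Fraction of co-twin pairs that cluster together
#'
#' At one timepoint, a pair "clusters" if its two members are mutual
#' nearest neighbours under Euclidean distance among that timepoint's
#' samples (replicates averaged first); distance ties are broken by
#' lexicographic sample id. The dendrogram-sibling variant (`method =
#' "sibling"`: the pair's two arrays merge directly as leaves under
#' complete linkage) is available as an option.
#'
#' @param m probe x sample matrix restricted (or restrictable) to one
#'   timepoint.
#' @param samples sample sheet.
#' @param timepoint `"birth"` or `"m18"`.
#' @param zygosity optional filter, `"MZ"` or `"DZ"`.
#' @param method `"mnn"` (mutual nearest neighbours, default) or
#'   `"sibling"`.
#' @return list `fraction`, `n_pairs`, and `flags` (named logical per
#'   pair).
#' @export
cotwin_pairing_fraction <- function(m, samples, timepoint,
                                    zygosity = NULL, method = c("mnn", "sibling")) {
  method <- match.arg(method)
  samples <- samples[samples$sample_id %in% colnames(m) &
                     samples$timepoint == timepoint, ]
  if (!is.null(zygosity)) samples <- samples[samples$zygosity == zygosity, ]
  avg <- average_replicates(m[, samples$sample_id, drop = FALSE], samples)
  x <- avg$mat
  colnames(x) <- sub("\\..*$", "", colnames(x))   # individual ids
  ind_pair <- sub("_T[12]$", "", colnames(x))
  pairs <- unique(ind_pair)
  evaluable <- pairs[vapply(pairs, function(p) sum(ind_pair == p) == 2L, logical(1))]
  if (length(evaluable) < 2L) stop("need at least 2 evaluable pairs")
  keep <- ind_pair %in% evaluable
  x <- x[, keep, drop = FALSE]
  ind_pair <- ind_pair[keep]

  if (method == "mnn") {
    D <- as.matrix(stats::dist(t(x)))
    diag(D) <- Inf
    # nearest neighbour with lexicographic tie-break on sample (column) id
    ord <- order(colnames(x))
    nn <- vapply(seq_len(ncol(D)), function(i) {
      cand <- ord[which(D[i, ord] == min(D[i, ]))]
      cand[1]
    }, integer(1))
    flags <- vapply(evaluable, function(p) {
      ij <- which(ind_pair == p)
      nn[ij[1]] == ij[2] && nn[ij[2]] == ij[1]
    }, logical(1))
  } else {
    hc <- hierarchical_cluster(x)
    siblings <- hc$merge[hc$merge[, 1] < 0 & hc$merge[, 2] < 0, , drop = FALSE]
    sib_pairs <- apply(siblings, 1, function(r) {
      paste(sort(colnames(x)[-r]), collapse = "|")
    })
    flags <- vapply(evaluable, function(p) {
      ij <- which(ind_pair == p)
      paste(sort(colnames(x)[ij]), collapse = "|") %in% sib_pairs
    }, logical(1))
  }
  list(fraction = mean(flags), n_pairs = length(evaluable), flags = flags)
}

#' Select probes by SNP annotation class
#'
#' @param manifest probe manifest with `snp_in_probe` and `snp_at_cpg`
#'   flags.
#' @param class `"any_snp"` (any SNP in the probe), `"snp_at_cpg"` (SNP at
#'   the assayed CpG site; a subset of `any_snp`), or `"none"` (the
#'   complement of `any_snp`).
#' @return character vector of probe ids (warns when empty).
#' @export
subset_probes_by_snp_class <- function(manifest, class) {
  if (!class %in% c("any_snp", "snp_at_cpg", "none"))
    stop("unknown SNP class: ", class)
  out <- switch(class,
    any_snp = manifest$probe_id[manifest$snp_in_probe],
    snp_at_cpg = manifest$probe_id[manifest$snp_at_cpg],
    none = manifest$probe_id[!manifest$snp_in_probe])
  if (length(out) == 0L) warning("SNP class '", class, "' selects no probes")
  out
}
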