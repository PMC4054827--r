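#' Cluster probes by genomic proximity
#'
#' Greedy chaining along each chromosome: a new cluster starts whenever the
#' gap to the previous probe exceeds `maxgap`. Positions must be sorted
#' within chromosome (as in a manifest).
#'
#' @param manifest probe manifest with `probe_id`, `chrom`, `pos`.
#' @param maxgap maximum intra-cluster gap in bp (default 1000).
#' @return data.frame `probe_id`, `chrom`, `pos`, `cluster_id`.
#' @export
cluster_probes <- function(manifest, maxgap = 1000) {
  ids <- probe_position_clusters(manifest, maxgap = maxgap)
  data.frame(probe_id = manifest$probe_id, chrom = manifest$chrom,
             pos = manifest$pos, cluster_id = ids, stringsAsFactors = FALSE)
}

#' Smooth a statistic within a cluster
#'
#' Centered running mean with edge truncation: near cluster edges the window
#' shrinks to the available probes. Clusters shorter than the window are
#' returned unchanged (the full-cluster mean never spans less than the
#' cluster itself).
#'
#' @param x numeric statistic vector, in cluster probe order.
#' @param window odd window width in probes (default 3); `window = 1` is the
#'   identity.
#' @return the smoothed vector.
#' @export
smooth_statistic <- function(x, window = 3L) {
  if (window < 1 || window %% 2 == 0) stop("'window' must be odd and >= 1")
  n <- length(x)
  if (window == 1L || n < window) return(x)
  h <- (window - 1L) / 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Bump-hunting detection of differentially methylated regions
#'
#' Smooths the probe-level statistic within each positional cluster, sets
#' the detection threshold at the `cutoff_quantile` of the absolute smoothed
#' statistic over all probes, and reports maximal runs of consecutive
#' same-sign probes exceeding the threshold with at least `min_probes`
#' members. Regions are ranked by area (sum of |smoothed statistic| over the
#' run). Coordinates are 0-based half-open spanning the first to last probe
#' plus one CpG-site width.
#'
#' @param stat per-probe statistic (e.g. moderated t), named or ordered as
#'   `clusters`.
#' @param clusters output of [cluster_probes()] covering the same probes.
#' @param cutoff_quantile quantile of |smoothed statistic| defining the
#'   threshold (default 0.995).
#' @param min_probes minimum probes per region (default 4).
#' @param window smoothing window (default 3).
#' @return list of class `dmr_set`: `dmrs` (data.frame `rank`, `chrom`,
#'   `start`, `end`, `n_probes`, `mean_smoothed_stat`, `direction`, `area`,
#'   `cluster_id`), `probes` (region membership: `rank`, `probe_id`),
#'   `threshold`, `smoothed` (named vector).
#' @export
find_dmrs <- function(stat, clusters, cutoff_quantile = 0.995,
                      min_probes = 4L, window = 3L) {
  if (length(stat) == 0L)
    return(structure(list(dmrs = empty_dmr_frame(), probes = empty_probe_frame(),
                          threshold = NA_real_, smoothed = numeric()),
                     class = "dmr_set"))
  if (!is.null(names(stat))) {
    idx <- match(clusters$probe_id, names(stat))
    if (anyNA(idx)) stop("statistics missing for some clustered probes")
    stat <- stat[idx]
  } else if (length(stat) != nrow(clusters)) {
    stop("'stat' must cover every clustered probe")
  }

  sm <- numeric(length(stat))
  for (cid in unique(clusters$cluster_id)) {
    i <- which(clusters$cluster_id == cid)
    sm[i] <- smooth_statistic(stat[i], window = window)
  }
  names(sm) <- clusters$probe_id
  thr <- stats::quantile(abs(sm), cutoff_quantile, na.rm = TRUE, names = FALSE)

  rows <- list(); members <- list()
  for (cid in unique(clusters$cluster_id)) {
    i <- which(clusters$cluster_id == cid)
    runs <- same_sign_runs(sm[i], thr)
    for (r in runs) {
      if (length(r) < min_probes) next
      j <- i[r]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = clusters$chrom[j[1]],
        start = clusters$pos[j[1]] - 1L,
        end = clusters$pos[j[length(j)]] + 1L,
        n_probes = length(j),
        mean_smoothed_stat = mean(sm[j]),
        direction = if (sm[j[1]] > 0) "gain" else "loss",
        area = sum(abs(sm[j])),
        cluster_id = cid, stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- clusters$probe_id[j]
    }
  }
  if (length(rows) == 0L)
    return(structure(list(dmrs = empty_dmr_frame(), probes = empty_probe_frame(),
                          threshold = thr, smoothed = sm), class = "dmr_set"))
  dmrs <- do.call(rbind, rows)
  o <- order(-dmrs$area)
  dmrs <- dmrs[o, ]
  dmrs$rank <- seq_len(nrow(dmrs))
  dmrs <- dmrs[, c("rank", "chrom", "start", "end", "n_probes",
                   "mean_smoothed_stat", "direction", "area", "cluster_id")]
  rownames(dmrs) <- NULL
  probes <- data.frame(
    rank = rep(dmrs$rank, vapply(members[o], length, integer(1))),
    probe_id = unlist(members[o]), stringsAsFactors = FALSE)
  structure(list(dmrs = dmrs, probes = probes, threshold = thr,
                 smoothed = sm), class = "dmr_set")
}

empty_probe_frame <- function() {
  data.frame(rank = integer(), probe_id = character(), stringsAsFactors = FALSE)
}

empty_dmr_frame <- function() {
  data.frame(rank = integer(), chrom = character(), start = integer(),
             end = integer(), n_probes = integer(),
             mean_smoothed_stat = numeric(), direction = character(),
             area = numeric(), cluster_id = integer(),
             stringsAsFactors = FALSE)
}

# maximal runs of indices whose |value| exceeds thr with constant sign;
# a sign flip inside a run splits it
same_sign_runs <- function(v, thr) {
  state <- ifelse(abs(v) > thr & v != 0, sign(v), 0)
  runs <- list()
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (state[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == state[i]) j <- j + 1L
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("Bump-hunting result:", nrow(x$dmrs), "regions",
      sprintf("(|smoothed stat| threshold %.3f)\n", x$threshold))
  if (nrow(x$dmrs)) print(utils::head(x$dmrs, 5))
  invisible(x)
}

#' Fraction of regions or probes near a transcription start site
#'
#' A region counts as TSS-proximal if any constituent probe lies within
#' `window` bp of a TSS (closed interval: a probe exactly at the window edge
#' counts); a probe set is assessed by each probe's own distance.
#'
#' @param features a `dmr_set` or a character vector of probe ids.
#' @param manifest probe manifest carrying `tss_distance`.
#' @param window proximity window in bp (default 5000).
#' @return list `fraction` and `flags` (logical, per region or per probe).
#' @export
annotate_tss_proximity <- function(features, manifest, window = 5000) {
  if (is.null(manifest$tss_distance)) stop("manifest lacks 'tss_distance'")
  near <- abs(manifest$tss_distance) <= window
  names(near) <- manifest$probe_id
  if (inherits(features, "dmr_set")) {
    if (nrow(features$dmrs) == 0L)
      return(list(fraction = NA_real_, flags = logical()))
    fl <- vapply(split(features$probes$probe_id, features$probes$rank),
                 function(p) any(near[p]), logical(1))
    fl <- fl[order(as.integer(names(fl)))]
  } else {
    miss <- setdiff(features, manifest$probe_id)
    if (length(miss)) stop("probe(s) missing from manifest")
    fl <- near[features]
  }
  list(fraction = mean(fl), flags = fl)
}

#' Write regions as a 6-column BED file
#'
#' 0-based half-open coordinates; name = rank, score = area scaled to
#' 0-1000, strand = ".".
#'
#' @param dmr_set a `dmr_set` from [find_dmrs()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_dmrs_bed <- function(dmr_set, path) {
  d <- dmr_set$dmrs
  score <- if (nrow(d)) as.integer(round(1000 * d$area / max(d$area))) else integer()
  bed <- data.frame(d$chrom, d$start, d$end, paste0("dmr_", d$rank),
                    score, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
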