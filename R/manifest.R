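#' Generate a synthetic array probe manifest
#'
#' Builds a probe annotation table in the style of an Infinium 450K manifest:
#' probes placed along a small set of simulated chromosomes, CpG islands laid
#' down as intervals, and every probe labelled by its distance to the nearest
#' island edge (island / shore 0-2 kb / shelf 2-4 kb / open sea >4 kb).
#' Gene-centric features are derived from simulated transcription start
#' sites: probes within a gene's footprint get TSS1500/TSS200/5'UTR/first
#' exon/body/3'UTR labels, everything else is intergenic. Regulatory flags
#' (enhancer, DNase hypersensitivity), known-DMR classes (CDMR/RDMR), SNP
#' flags (probe body, and the stricter CpG-site subset) and Infinium design
#' type (I/II) are drawn independently at configurable frequencies.
#'
#' A small fraction of probes is placed on chrX/chrY so that the
#' sex-chromosome filter has something to remove; all planted signal in
#' [generate_cohort()] is autosomal.
#'
#' @param n_probes total number of probes (>= 1).
#' @param n_islands number of CpG islands to simulate (default scales with
#'   probe count).
#' @param seed integer seed; the same seed reproduces the table bit for bit.
#' @param n_autosomes number of autosomal chromosome labels to use.
#' @param frac_sex fraction of probes placed on chrX/chrY.
#' @param frac_type1 fraction of probes with Infinium I chemistry.
#' @param frac_enhancer,frac_dhs,frac_cdmr,frac_rdmr,frac_snp_probe,frac_snp_cpg
#'   category frequencies; `frac_snp_cpg` probes are a subset of the
#'   `frac_snp_probe` set.
#' @return a `data.frame` with columns `probe_id`, `chrom`, `pos`,
#'   `island_relation`, `gene_feature`, `gene`, `enhancer`, `dhs`,
#'   `dmr_class`, `snp_in_probe`, `snp_at_cpg`, `design_type`,
#'   `tss_distance`. The simulated island and gene interval tables are
#'   attached as attributes `islands` and `genes` for downstream checks.
#' @export
generate_manifest <- function(n_probes, n_islands = max(1L, round(n_probes / 50)),
                              seed = 1L, n_autosomes = 6L, frac_sex = 0.04,
                              frac_type1 = 0.3, frac_enhancer = 0.10,
                              frac_dhs = 0.08, frac_cdmr = 0.02, frac_rdmr = 0.02,
                              frac_snp_probe = 0.08, frac_snp_cpg = 0.015) {
  if (!is.numeric(n_probes) || length(n_probes) != 1L || n_probes < 1)
    stop("'n_probes' must be a positive count")
  if (!is.numeric(n_islands) || n_islands < 1)
    stop("'n_islands' must be a positive count")
  n_probes <- as.integer(n_probes)
  set.seed(as.integer(seed))

  chroms <- c(paste0("chr", seq_len(n_autosomes)), "chrX", "chrY")
  n_sex <- round(n_probes * frac_sex)
  n_y <- floor(n_sex / 3)
  n_x <- n_sex - n_y
  n_auto <- n_probes - n_sex
  # proportional split of autosomal probes over autosomes
  base <- floor(n_auto / n_autosomes)
  counts <- rep(base, n_autosomes)
  extra <- n_auto - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts <- c(counts, n_x, n_y)

  probe_list <- vector("list", length(chroms))
  island_list <- vector("list", length(chroms))
  gene_list <- vector("list", length(chroms))
  n_isl_per_chr <- pmax(1L, round(n_islands * counts / max(1L, sum(counts))))

  for (k in seq_along(chroms)) {
    nk <- counts[k]
    if (nk == 0L) next
    chr_len <- nk * 2000L + 50000L

    # genes first; islands preferentially placed at promoters, as on the
    # real genome
    ng <- max(1L, round(nk / 12))
    tss <- sort(as.integer(stats::runif(ng, 20000, chr_len - 30000)))
    glen <- as.integer(stats::runif(ng, 5000, 25000))
    gene_list[[k]] <- data.frame(chrom = chroms[k], tss = tss,
                                 end = tss + glen,
                                 gene = sprintf("%s_G%03d", sub("chr", "GENE", chroms[k]), seq_len(ng)))

    ni <- n_isl_per_chr[k]
    at_tss <- stats::runif(ni) < 0.7
    icentre <- ifelse(at_tss,
                      tss[sample.int(ng, ni, replace = TRUE)] +
                        round(stats::rnorm(ni, 0, 500)),
                      round(stats::runif(ni, 10000, chr_len - 10000)))
    iwidth <- as.integer(stats::runif(ni, 300, 2000))
    istart <- pmax(1L, as.integer(icentre - iwidth %/% 2))
    o <- order(istart)
    island_list[[k]] <- data.frame(chrom = chroms[k], start = istart[o],
                                   end = (istart + iwidth)[o])

    # probe placement mirrors the array's design bias: probes come in small
    # local groups (3-5 probes within < 1 kb, like locally clustered CpGs),
    # over half the groups targeting islands and their flanks, most of the
    # rest gene bodies
    sizes <- sample(3:5, max(1L, nk %/% 4L), replace = TRUE)
    sizes <- sizes[cumsum(sizes) <= nk]
    if (length(sizes) == 0L) sizes <- nk
    rem <- nk - sum(sizes)
    if (rem > 0) sizes[length(sizes)] <- sizes[length(sizes)] + rem
    n_cl <- length(sizes)

    isl <- island_list[[k]]
    anchor <- stats::runif(n_cl)
    base <- numeric(n_cl)
    a_isl <- anchor < 0.55
    n_ia <- sum(a_isl)
    if (n_ia > 0) {
      j <- sample.int(nrow(isl), n_ia, replace = TRUE)
      inside <- stats::runif(n_ia) < 0.5
      left <- stats::runif(n_ia) < 0.5
      base[a_isl] <- ifelse(inside,
                            stats::runif(n_ia, isl$start[j], pmax(isl$start[j] + 1, isl$end[j] - 600)),
                            ifelse(left,
                                   isl$start[j] - stats::runif(n_ia, 600, 4000),
                                   isl$end[j] + stats::runif(n_ia, 1, 3400)))
    }
    a_gene <- anchor >= 0.55 & anchor < 0.85
    n_ga <- sum(a_gene)
    if (n_ga > 0) {
      j <- sample.int(ng, n_ga, replace = TRUE)
      base[a_gene] <- stats::runif(n_ga, tss[j] - 1500, tss[j] + glen[j] - 800)
    }
    a_rand <- anchor >= 0.85
    base[a_rand] <- stats::runif(sum(a_rand), 1, chr_len)

    pos <- unlist(lapply(seq_len(n_cl), function(ci) {
      base[ci] + sort(stats::runif(sizes[ci], 0, 800))
    }))
    pos <- sort(as.integer(pmax(1, round(pos))))
    # enforce strictly increasing positions with minimal perturbation
    s <- seq_along(pos)
    pos <- as.integer(cummax(pos - s) + s)
    probe_list[[k]] <- data.frame(chrom = chroms[k], pos = pos)
  }

  probes <- do.call(rbind, probe_list[!vapply(probe_list, is.null, TRUE)])
  islands <- do.call(rbind, island_list[!vapply(island_list, is.null, TRUE)])
  genes <- do.call(rbind, gene_list[!vapply(gene_list, is.null, TRUE)])

  probes$island_dist <- island_edge_distance(probes$chrom, probes$pos, islands)
  probes$island_relation <- island_relation_from_distance(probes$island_dist)

  # nearest TSS (signed: negative = upstream of the TSS, genes on + strand)
  gi <- gene_feature_assign(probes$chrom, probes$pos, genes)
  probes$tss_distance <- gi$tss_distance
  probes$gene_feature <- gi$gene_feature
  probes$gene <- gi$gene

  n <- nrow(probes)
  probes$enhancer <- stats::runif(n) < frac_enhancer
  probes$dhs <- stats::runif(n) < frac_dhs
  u <- stats::runif(n)
  probes$dmr_class <- ifelse(u < frac_cdmr, "CDMR",
                      ifelse(u < frac_cdmr + frac_rdmr, "RDMR", "none"))
  probes$snp_in_probe <- stats::runif(n) < frac_snp_probe
  # SNP-at-CpG probes are a subset of probes with any SNP
  idx_snp <- which(probes$snp_in_probe)
  n_cpg <- min(length(idx_snp), round(n * frac_snp_cpg))
  probes$snp_at_cpg <- FALSE
  if (n_cpg > 0)
    probes$snp_at_cpg[sample(idx_snp, n_cpg)] <- TRUE
  probes$design_type <- ifelse(stats::runif(n) < frac_type1, "I", "II")

  probes$probe_id <- sprintf("cg%08d", seq_len(n))
  out <- probes[, c("probe_id", "chrom", "pos", "island_relation",
                    "gene_feature", "gene", "enhancer", "dhs", "dmr_class",
                    "snp_in_probe", "snp_at_cpg", "design_type",
                    "tss_distance")]
  rownames(out) <- NULL
  attr(out, "islands") <- islands
  attr(out, "genes") <- genes
  out
}

# distance from each position to the nearest island edge on its chromosome
# (0 if inside an island); vectorised per chromosome
island_edge_distance <- function(chrom, pos, islands) {
  d <- rep(Inf, length(pos))
  for (ch in unique(chrom)) {
    ip <- which(chrom == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(isl) == 0L) next
    for (j in seq_len(nrow(isl))) {
      dj <- ifelse(pos[ip] < isl$start[j], isl$start[j] - pos[ip],
            ifelse(pos[ip] > isl$end[j], pos[ip] - isl$end[j], 0))
      d[ip] <- pmin(d[ip], dj)
    }
  }
  d
}

#' Island relation from distance to nearest island edge
#'
#' Applies the standard annotation rule: 0 = island, 0-2 kb = shore,
#' 2-4 kb = shelf, beyond 4 kb = open sea.
#'
#' @param dist non-negative distances in bp (0 for probes inside an island).
#' @return character vector of labels.
#' @export
island_relation_from_distance <- function(dist) {
  if (any(dist < 0)) stop("island distances must be non-negative")
  ifelse(dist == 0, "island",
  ifelse(dist <= 2000, "shore",
  ifelse(dist <= 4000, "shelf", "open_sea")))
}

# assign gene features by position relative to the nearest simulated gene
gene_feature_assign <- function(chrom, pos, genes) {
  n <- length(pos)
  tssd <- integer(n)
  feat <- character(n)
  gname <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    ip <- which(chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) {
      tssd[ip] <- .Machine$integer.max
      feat[ip] <- "intergenic"
      next
    }
    for (i in ip) {
      d <- pos[i] - g$tss
      j <- which.min(abs(d))
      tssd[i] <- d[j]
      within_gene <- pos[i] >= g$tss[j] && pos[i] <= g$end[j]
      glen <- g$end[j] - g$tss[j]
      if (d[j] >= -200 && d[j] < 0) {
        feat[i] <- "TSS200"; gname[i] <- g$gene[j]
      } else if (d[j] >= -1500 && d[j] < -200) {
        feat[i] <- "TSS1500"; gname[i] <- g$gene[j]
      } else if (within_gene) {
        frac <- d[j] / glen
        feat[i] <- if (frac <= 0.05) "UTR5"
                   else if (frac <= 0.15) "FirstExon"
                   else if (frac <= 0.9) "Body" else "UTR3"
        gname[i] <- g$gene[j]
      } else {
        feat[i] <- "intergenic"
      }
    }
  }
  list(tss_distance = tssd, gene_feature = feat, gene = gname)
}
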