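test_that("probe clustering chains gaps up to maxgap", {
  man <- data.frame(probe_id = paste0("p", 1:4), chrom = "chr1",
                    pos = c(100, 600, 1400, 4000))
  cl <- cluster_probes(man, maxgap = 1000)
  expect_equal(cl$cluster_id, c(1, 1, 1, 2))

  single <- cluster_probes(man[1, ])
  expect_equal(single$cluster_id, 1)

  man2 <- data.frame(probe_id = paste0("p", 1:3), chrom = "chr1",
                     pos = c(10, 500, 900))
  expect_equal(unique(cluster_probes(man2)$cluster_id), 1)
  # clusters never span chromosomes
  man3 <- rbind(man2, data.frame(probe_id = "p4", chrom = "chr2", pos = 950))
  expect_equal(cluster_probes(man3)$cluster_id, c(1, 1, 1, 2))

  expect_error(cluster_probes(data.frame(probe_id = c("a", "b"),
                                         chrom = "chr1", pos = c(5, 2))),
               "sorted")
})

test_that("running-mean smoother: edge truncation, short clusters, identity", {
  expect_equal(smooth_statistic(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  expect_equal(smooth_statistic(rep(2, 5), 3), rep(2, 5))
  expect_equal(smooth_statistic(c(4, 7, 1), 1), c(4, 7, 1))
  # clusters shorter than the window are returned unchanged
  expect_equal(smooth_statistic(c(5, 9), 3), c(5, 9))
  expect_equal(smooth_statistic(c(1, 2, 3, 4, 5), 5), c(2, 2.5, 3, 3.5, 4))
  expect_error(smooth_statistic(1:4, 2), "odd")
})

test_that("bump finder matches brute-force run enumeration on random clusters", {
  set.seed(21)
  for (rep in 1:20) {
    n_cl <- 10
    sizes <- sample(1:12, n_cl, replace = TRUE)
    pos <- unlist(lapply(sizes, function(s) sort(sample(1e6, s))))
    clusters <- data.frame(
      probe_id = sprintf("r%d_p%03d", rep, seq_len(sum(sizes))),
      chrom = "chr1", pos = pos,
      cluster_id = rep(seq_len(n_cl), sizes))
    stat <- stats::setNames(rnorm(sum(sizes), 0, 3), clusters$probe_id)
    res <- find_dmrs(stat, clusters, cutoff_quantile = 0.8, min_probes = 3)
    oracle <- brute_force_dmrs(res$smoothed, clusters, res$threshold, 3)
    got <- unname(split(res$probes$probe_id, res$probes$rank))
    expect_setequal(vapply(got, paste, collapse = ",", ""),
                    vapply(oracle, paste, collapse = ",", ""))
  }
})

test_that("bump finder recovers a planted run and applies the rules", {
  # one hot run of 6 probes in a flat background (window 1 keeps the
  # smoothed statistic hand-computable)
  clusters <- data.frame(probe_id = sprintf("p%02d", 1:40), chrom = "chr1",
                         pos = seq(100, by = 200, length.out = 40),
                         cluster_id = rep(1:4, each = 10))
  stat <- stats::setNames(rep(0.1, 40), clusters$probe_id)
  stat[11:16] <- 8
  res <- find_dmrs(stat, clusters, cutoff_quantile = 0.8, min_probes = 4,
                   window = 1)
  expect_equal(nrow(res$dmrs), 1)
  expect_setequal(res$probes$probe_id, sprintf("p%02d", 11:16))
  expect_equal(res$dmrs$direction, "gain")
  expect_equal(res$dmrs$start, clusters$pos[11] - 1)
  expect_equal(res$dmrs$end, clusters$pos[16] + 1)
  expect_equal(res$dmrs$n_probes, 6)

  # with the default window the planted run is still the unique region
  res_sm <- find_dmrs(stat, clusters, cutoff_quantile = 0.85, min_probes = 4)
  expect_equal(nrow(res_sm$dmrs), 1)
  expect_true(all(sprintf("p%02d", 12:15) %in% res_sm$probes$probe_id))

  # a qualifying run of 3 probes is below min_probes
  stat2 <- stats::setNames(rep(0.1, 40), clusters$probe_id)
  stat2[21:23] <- 8
  expect_equal(nrow(find_dmrs(stat2, clusters, 0.8, min_probes = 4,
                              window = 1)$dmrs), 0)

  # a sign flip splits a run
  stat3 <- stats::setNames(rep(0.01, 40), clusters$probe_id)
  stat3[11:20] <- c(8, 8, 8, 8, 8, -8, -8, -8, -8, -8)
  res3 <- find_dmrs(stat3, clusters, cutoff_quantile = 0.7, min_probes = 4,
                    window = 1)
  expect_equal(nrow(res3$dmrs), 2)
  expect_setequal(res3$dmrs$direction, c("gain", "loss"))

  # empty input
  expect_equal(nrow(find_dmrs(numeric(), clusters[0, ], 0.995)$dmrs), 0)
})

test_that("null DMR count decreases as the cutoff quantile rises", {
  set.seed(22)
  man <- small_manifest(4000)
  auto <- man[!(man$chrom %in% c("chrX", "chrY")), ]
  clusters <- cluster_probes(auto)
  counts <- vapply(c(0.95, 0.99, 0.995), function(q) {
    stat <- stats::setNames(rnorm(nrow(auto)), auto$probe_id)
    nrow(find_dmrs(stat, clusters, cutoff_quantile = q)$dmrs)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[3], 10)
})

test_that("TSS proximity: closed boundary and truth recovery", {
  man <- data.frame(probe_id = paste0("p", 1:5), chrom = "chr1",
                    pos = 1:5, tss_distance = c(0, 5000, -5000, 5001, -8000))
  pr <- annotate_tss_proximity(paste0("p", 1:5), man)
  expect_equal(unname(pr$flags), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(pr$fraction, 0.6)
  expect_error(annotate_tss_proximity("p9", man), "missing")
  expect_error(annotate_tss_proximity(paste0("p", 1:2),
                                      man[, c("probe_id", "chrom")]),
               "tss_distance")

  # a region counts as proximal if any member probe is
  man2 <- small_manifest(1500)
  clusters <- cluster_probes(man2)
  stat <- stats::setNames(rep(0.1, nrow(man2)), man2$probe_id)
  i <- which(clusters$cluster_id == clusters$cluster_id[10])
  stat[clusters$probe_id[i]] <- 9
  res <- find_dmrs(stat, clusters, cutoff_quantile = 0.9, min_probes = 3)
  tp <- annotate_tss_proximity(res, man2)
  expect_equal(tp$flags[[1]],
               any(abs(man2$tss_distance[i]) <= 5000))

  # manifest-wide fraction recovered from probe-level flags
  frac <- mean(abs(man2$tss_distance) <= 5000)
  expect_equal(annotate_tss_proximity(man2$probe_id, man2)$fraction, frac)
})

test_that("BED export is 0-based half-open with scaled scores", {
  clusters <- data.frame(probe_id = sprintf("p%02d", 1:10), chrom = "chr2",
                         pos = seq(1000, by = 100, length.out = 10),
                         cluster_id = 1)
  stat <- stats::setNames(c(rep(6, 5), rep(0.1, 5)), clusters$probe_id)
  res <- find_dmrs(stat, clusters, cutoff_quantile = 0.5, min_probes = 4)
  path <- withr::local_tempfile(fileext = ".bed")
  write_dmrs_bed(res, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(ncol(bed), 6)
  expect_equal(bed$V2, res$dmrs$start)
  expect_equal(bed$V3, res$dmrs$end)
  expect_true(all(bed$V3 > bed$V2))
  expect_equal(bed$V5[1], 1000)
})
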