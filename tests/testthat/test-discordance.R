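test_that("pair discordance is the absolute co-twin beta difference", {
  s <- toy_samples(2)
  b <- matrix(0.5, 4, 8, dimnames = list(paste0("p", 1:4), s$sample_id))
  b["p1", "P01_T1_B"] <- 0.30
  b["p1", "P01_T2_B"] <- 0.55
  d <- pair_discordance(b, s, "birth")
  expect_equal(d["p1", "P01"], 0.25)
  expect_equal(d["p2", "P01"], 0)
  # symmetric in twin order
  s_swapped <- s
  s_swapped$twin_index <- 3L - s_swapped$twin_index
  expect_equal(pair_discordance(b, s_swapped, "birth"), d)

  # an incomplete pair is dropped with a message
  expect_message(d2 <- pair_discordance(b[, -1], s, "birth"), "dropping pair")
  expect_equal(colnames(d2), "P02")
})

test_that("residual discordance equals +/- half the co-twin difference", {
  s <- toy_samples(1)
  m <- matrix(0, 3, 4, dimnames = list(paste0("p", 1:3), s$sample_id))
  m["p1", c("P01_T1_B", "P01_T2_B")] <- c(1, 0)
  r <- residual_discordance(m, s)
  expect_equal(r["p1", "P01_T1_B"], 0.5)
  expect_equal(r["p1", "P01_T2_B"], -0.5)
  expect_equal(r["p2", "P01_T1_B"], 0)
  # residuals sum to zero within every pair group
  set.seed(41)
  m2 <- matrix(rnorm(12), 3, 4, dimnames = dimnames(m))
  r2 <- residual_discordance(m2, s)
  expect_equal(r2[, "P01_T1_B"] + r2[, "P01_T2_B"], rep(0, 3),
               ignore_attr = TRUE)

  expect_warning(residual_discordance(m[, 1, drop = FALSE], s[1, ]),
                 "singleton")
})

test_that("discordant-probe counting uses a strict threshold", {
  expect_equal(count_discordant(c(0.25, 0.10, 0.21)), 2)
  expect_equal(count_discordant(rep(0, 5)), 0)
  expect_equal(count_discordant(c(0.2, 0.2001)), 1)
  expect_error(count_discordant(0.1, threshold = 0), "threshold")
})

test_that("Euclidean distance: 3-4-5 triangle, identity, monotonicity", {
  expect_equal(euclidean_distance(c(0.3, 0.4), c(0, 0)), 0.5)
  expect_equal(euclidean_distance(c(0.2, 0.9), c(0.2, 0.9)), 0)
  d1 <- euclidean_distance(c(0.1, 0.2), c(0.3, 0.3))
  d2 <- euclidean_distance(c(0.1, 0.2, 0.5), c(0.3, 0.3, 0.6))
  expect_gt(d2, d1)
  expect_error(euclidean_distance(1:3 / 10, 1:4 / 10), "length")
})

test_that("squared distance decomposes as the sum of squared discordances", {
  coh <- small_cohort(800)
  d <- pair_discordance(coh$beta, coh$samples, "birth")
  s <- coh$samples
  for (p in colnames(d)[1:3]) {
    b1 <- coh$beta[, s$sample_id[s$pair_id == p & s$twin_index == 1 &
                                   s$timepoint == "birth"]]
    b2 <- coh$beta[, s$sample_id[s$pair_id == p & s$twin_index == 2 &
                                   s$timepoint == "birth"]]
    expect_equal(euclidean_distance(b1, b2)^2, sum(d[, p]^2))
  }
})

test_that("delta discordance arithmetic and null centring", {
  expect_equal(delta_discordance(c(a = 0.1), c(a = 0.3))$delta, c(a = 0.2))
  dd <- delta_discordance(c(0.2, 0.4), c(0.2, 0.4))
  expect_true(all(dd$delta == 0))
  expect_equal(dd$summary$central_mass, 1)
  expect_error(delta_discordance(1:3 / 10, 1:4 / 10), "matched")

  # stable pairs leave the delta distribution centred on zero
  means <- vapply(1:5, function(r) {
    man <- small_manifest(600, seed = 50)
    cfg <- small_config(600, n_pairs = 4L,
                        pair_dynamics = c(P01 = 1, P02 = 1, P03 = 1, P04 = 1),
                        frac_age_affected = 0, n_planted_dmrs = 0L,
                        seed = 200 + r)
    coh <- generate_cohort(cfg, man)
    d_b <- pair_discordance(coh$beta, coh$samples, "birth")
    d_18 <- pair_discordance(coh$beta, coh$samples, "m18")
    delta_discordance(d_b, d_18)$summary$mean
  }, numeric(1))
  expect_true(all(abs(means) < 0.005))
})

test_that("drift/converge/stable classification thresholds", {
  expect_equal(classify_pair_dynamics(300, 400), "drift")
  expect_equal(classify_pair_dynamics(400, 300), "converge")
  expect_equal(classify_pair_dynamics(300, 310), "stable")
  expect_warning(out <- classify_pair_dynamics(0, 5), "stable")
  expect_equal(out, "stable")
  expect_error(classify_pair_dynamics(-1, 5), ">= 0")
})

test_that("age change at changing sites dominates the discordance change", {
  man <- small_manifest(3000)
  coh <- generate_cohort(small_config(3000, frac_age_affected = 0.05), man)
  qc <- qc_pipeline(coh)
  res <- dm_test(qc)
  admps <- call_admps(res)$relaxed
  d_b <- pair_discordance(qc$beta, qc$samples, "birth")
  d_18 <- pair_discordance(qc$beta, qc$samples, "m18")
  dd <- delta_discordance(d_b, d_18,
                          dm_result = res[res$probe_id %in% admps, ])
  cmp <- dd$magnitude_comparison
  expect_lt(cmp$median_abs_delta_discordance, cmp$median_abs_delta_beta)
})

test_that("ranked gene export deduplicates at the best rank with stable ties", {
  gm <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                   gene = c("GENEA", "GENEB", "GENEA", NA))
  metric <- c(p1 = 0.9, p2 = 0.5, p3 = 0.7, p4 = 0.99)
  out <- rank_probes_for_ontology(metric, gm)
  expect_equal(out, c("GENEA", "GENEB"))

  # strictly decreasing metric keeps input order; ties break by probe id
  metric2 <- c(p2 = 0.5, p1 = 0.5, p3 = 0.9)
  out2 <- rank_probes_for_ontology(metric2, gm)
  expect_equal(out2, c("GENEA", "GENEB"))

  path <- withr::local_tempfile()
  rank_probes_for_ontology(metric, gm, path = path)
  expect_equal(readLines(path), c("GENEA", "GENEB"))
  expect_error(rank_probes_for_ontology(metric, gm[0, ]), "empty gene map")
})

test_that("weight discordance formula and the cohort median", {
  expect_equal(weight_discordance(3000, 3000), 0)
  expect_equal(weight_discordance(4000, 2000), 50)
  expect_equal(weight_discordance(2000, 4000), 50)
  expect_error(weight_discordance(-1, 10), "positive")

  pairs <- twin_pair_table()
  expect_equal(nrow(pairs), 15)
  expect_equal(median_weight_discordance(pairs), 13.3)
})

test_that("retained-array accounting reproduces the published design", {
  counts <- retained_array_count()
  expect_equal(counts$total, 60)
  expect_equal(counts$removed, 7)
  expect_equal(counts$retained, 53)
})
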