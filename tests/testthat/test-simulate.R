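test_that("cohort betas and detection p-values stay in [0,1]; determinism", {
  man <- small_manifest(1000)
  coh1 <- generate_cohort(small_config(1000), man)
  coh2 <- generate_cohort(small_config(1000), man)
  expect_true(all(coh1$beta >= 0 & coh1$beta <= 1))
  expect_true(all(coh1$detp >= 0 & coh1$detp <= 1))
  expect_identical(coh1$beta, coh2$beta)
  expect_identical(coh1$truth, coh2$truth)
  expect_identical(colnames(coh1$beta), coh1$samples$sample_id)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(mz_fraction = 1.2), "proportions")
  expect_error(simulation_config(sigma_nonshared = -1), "sigmas")
  expect_error(simulation_config(pair_dynamics = c(P01 = -0.5)), "lambda")
  expect_error(simulation_config(dmr_probe_span = c(3, 5)), "minimum >= 4")
  expect_error(generate_cohort(small_config(500), small_manifest(400)),
               "does not match")
})

test_that("MZ co-twins are identical without non-shared variance", {
  man <- small_manifest(500)
  cfg <- small_config(500, n_pairs = 4L, mz_fraction = 1,
                      sigma_nonshared = 0,
                      pair_dynamics = c(P01 = 1, P02 = 1, P03 = 1, P04 = 1))
  coh <- generate_cohort(cfg, man)
  s <- coh$samples
  for (p in unique(s$pair_id)) for (tp in c("birth", "m18")) {
    i1 <- s$sample_id[s$pair_id == p & s$twin_index == 1 & s$timepoint == tp]
    i2 <- s$sample_id[s$pair_id == p & s$twin_index == 2 & s$timepoint == tp]
    expect_identical(coh$beta[, i1], coh$beta[, i2])
  }
})

test_that("null configuration centres per-probe age change on zero", {
  man <- small_manifest(2000)
  coh <- generate_cohort(small_config(2000, frac_age_affected = 0,
                                      n_planted_dmrs = 0L), man)
  expect_true(all(coh$truth$probes$true_delta_beta == 0))
  d <- paired_differences(coh$beta, coh$samples)
  expect_lt(abs(mean(rowMeans(d))), 0.005)
})

test_that("planted effect signs follow the configured gain fraction", {
  man <- small_manifest(5000)
  coh <- generate_cohort(small_config(5000, frac_age_affected = 0.1,
                                      gain_fraction = 0.87), man)
  td <- coh$truth$probes$true_delta_beta
  td <- td[td != 0]
  phat <- mean(td > 0)
  se <- sqrt(0.87 * 0.13 / length(td))
  expect_lt(abs(phat - 0.87), 4 * se)
})

test_that("planted DMRs are runs of >= 4 consecutive probes on one chromosome", {
  man <- small_manifest(3000)
  coh <- generate_cohort(small_config(3000, n_planted_dmrs = 5L), man)
  tp <- coh$truth$probes
  for (d in unique(na.omit(tp$dmr_id))) {
    idx <- which(!is.na(tp$dmr_id) & tp$dmr_id == d)
    expect_gte(length(idx), 4)
    expect_true(all(diff(idx) == 1))
    expect_equal(length(unique(man$chrom[idx])), 1L)
    expect_equal(length(unique(sign(tp$true_delta_beta[idx]))), 1L)
  }
})

test_that("technical replicates: counting, zero-noise identity, noise ordering", {
  man <- small_manifest(1500)
  coh <- small_cohort(1500, man)
  pairs3 <- coh$truth$pairs$pair_id[1:3]

  aug0 <- inject_technical_replicates(coh, pairs3, sigma_technical = 0)
  expect_equal(ncol(aug0$beta), ncol(coh$beta) + 12L)
  orig <- coh$samples$sample_id[coh$samples$pair_id %in% pairs3]
  expect_equal(unname(aug0$beta[, paste0(orig, "_r2")]),
               unname(aug0$beta[, orig]))

  expect_error(inject_technical_replicates(coh, "NOPE"), "unknown pair")

  # replicate noise < co-twin (biological) difference, as in the study's
  # replicate hybridizations
  aug <- inject_technical_replicates(coh, pairs3)
  s <- aug$samples
  rep_diff <- cotwin_diff <- c()
  for (p in pairs3) for (tp in c("birth", "m18")) {
    a1 <- s$sample_id[s$pair_id == p & s$twin_index == 1 & s$timepoint == tp]
    rep_diff <- c(rep_diff, mean(abs(aug$beta[, a1[1]] - aug$beta[, a1[2]])))
    b1 <- s$sample_id[s$pair_id == p & s$twin_index == 2 & s$timepoint == tp &
                        s$replicate_id == 1]
    cotwin_diff <- c(cotwin_diff, mean(abs(aug$beta[, a1[1]] - aug$beta[, b1])))
  }
  expect_lt(mean(rep_diff), mean(cotwin_diff))
})

test_that("pair dynamics scale within-pair distance at 18 months only", {
  # strong drift/convergence factors must move the m18 Euclidean distance in
  # the right direction relative to birth (Monte-Carlo over replicates)
  man <- small_manifest(1200)
  ok_drift <- ok_conv <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    cfg <- small_config(1200, n_pairs = 2L, mz_fraction = 1,
                        pair_dynamics = c(P01 = 1.6, P02 = 0.6),
                        frac_age_affected = 0, n_planted_dmrs = 0L,
                        seed = 100 + r)
    coh <- generate_cohort(cfg, man)
    prof <- pair_dynamics_profile(coh$beta, coh$samples)
    ok_drift <- ok_drift + (prof$ed_m18[prof$pair_id == "P01"] >
                              prof$ed_birth[prof$pair_id == "P01"])
    ok_conv <- ok_conv + (prof$ed_m18[prof$pair_id == "P02"] <
                            prof$ed_birth[prof$pair_id == "P02"])
  }
  expect_gte(ok_drift, n_rep - 1)
  expect_gte(ok_conv, n_rep - 1)
})

test_that("cohort TSV round trip is lossless and ordered like the sample sheet", {
  coh <- small_cohort(600)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_lt(max(abs(back$beta - coh$beta)), 1e-12)
  expect_lt(max(abs(back$detp - coh$detp)), 1e-12)
  expect_identical(colnames(back$beta), back$samples$sample_id)
  expect_equal(back$truth$probes$true_delta_beta,
               coh$truth$probes$true_delta_beta)

  empty <- coh
  empty$beta <- coh$beta[0, , drop = FALSE]
  expect_error(write_cohort(empty, dir), "empty")
})
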