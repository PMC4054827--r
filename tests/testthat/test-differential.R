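test_that("paired differences: zero case, replicate averaging, counting bound", {
  s <- toy_samples(2)
  m <- matrix(rnorm(40), 10, 8, dimnames = list(paste0("p", 1:10), s$sample_id))
  m[, s$timepoint == "m18"] <- m[, s$timepoint == "birth"]
  d <- paired_differences(m, s)
  expect_true(all(d == 0))
  expect_equal(ncol(d), 4)

  # replicate arrays are averaged before differencing
  s2 <- rbind(s, within(s[1, ], {
    replicate_id <- 2L
    sample_id <- paste0(sample_id, "_r2")
  }))
  m2 <- cbind(m, setNames(data.frame(m[, 1] + 1), s2$sample_id[9]))
  m2 <- as.matrix(m2)
  d2 <- paired_differences(m2, s2)
  expect_equal(d2[, "P01_T1"], d[, "P01_T1"] - 0.5)

  # individuals missing a timepoint are dropped
  m3 <- m[, -1]
  d3 <- paired_differences(m3, s)
  expect_equal(ncol(d3), 3)
  expect_equal(attr(d3, "dropped"), "P01_T1")
  expect_error(paired_differences(m[, 1:4], s), "both timepoints")
})

test_that("prior estimator recovers a known inverse-chi-squared prior", {
  set.seed(11)
  d0 <- 4; s0 <- 1; df <- 12
  s2 <- s0 * stats::rf(50000, df, d0)   # s^2 ~ s0^2 F(df, d0)
  pr <- estimate_prior(s2, df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.2)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.1)

  expect_equal(estimate_prior(rep(2, 100), df = 5)$d0, Inf)
  expect_error(estimate_prior(rnorm(5)^2, 5), "at least 10")
})

test_that("prior moment estimator matches limma and a marginal-likelihood grid", {
  skip_if_not_installed("limma")
  set.seed(12)
  df <- 10
  s2 <- 1.3 * stats::rf(5000, df, 6)
  pr <- estimate_prior(s2, df)
  lf <- limma::fitFDist(s2, df1 = df)
  expect_equal(pr$d0, lf$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, lf$scale, tolerance = 1e-6)

  # independent oracle: grid maximization of the exact marginal likelihood
  # (s^2/s0^2 ~ F(df, d0))
  set.seed(13)
  s2b <- stats::rf(1000, df, 4)
  prb <- estimate_prior(s2b, df)
  grid_d0 <- exp(seq(log(0.5), log(50), length.out = 120))
  grid_s0 <- exp(seq(log(0.3), log(3), length.out = 120))
  ll <- function(d0, s0sq)
    sum(stats::df(s2b / s0sq, df, d0, log = TRUE) - log(s0sq))
  lls <- outer(grid_d0, grid_s0, Vectorize(ll))
  best <- which(lls == max(lls), arr.ind = TRUE)
  ml_d0 <- grid_d0[best[1]]; ml_s0 <- grid_s0[best[2]]
  expect_lt(abs(log(prb$d0 / ml_d0)), log(1.5))
  expect_lt(abs(log(prb$s0_sq / ml_s0)), log(1.25))
})

test_that("moderated test reduces to the classic paired t-test at d0 = 0", {
  d <- matrix(c(0.1, 0.2, 0.3), 1, 3)
  res <- moderated_one_sample_test(d, prior = list(d0 = 0, s0_sq = 1),
                                   min_n = 2)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df_total, 2)

  # oracle equivalence on random probes against t.test
  set.seed(3)
  dm <- matrix(rnorm(1000 * 8, sd = 0.5), 1000, 8)
  res2 <- moderated_one_sample_test(dm, prior = list(d0 = 0, s0_sq = 1))
  tt <- apply(dm, 1, function(x) stats::t.test(x)$statistic)
  expect_lt(max(abs(res2$t - tt)), 1e-9)
  pp <- apply(dm, 1, function(x) stats::t.test(x)$p.value)
  expect_lt(max(abs(res2$p - pp)), 1e-9)
})

test_that("moderated test limits and degenerate inputs", {
  dm <- matrix(0, 5, 4)
  res <- moderated_one_sample_test(dm, prior = list(d0 = 0, s0_sq = 1))
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))

  # d0 -> Inf: every probe tested against the prior variance
  set.seed(4)
  dm2 <- matrix(rnorm(50 * 6), 50, 6)
  resI <- moderated_one_sample_test(dm2, prior = list(d0 = Inf, s0_sq = 0.25))
  expect_equal(resI$t, rowMeans(dm2) / (0.5 / sqrt(6)), tolerance = 1e-12)

  expect_error(moderated_one_sample_test(dm2[, 1, drop = FALSE]),
               "at least 2")
})

test_that("moderated pipeline agrees with limma's squeezeVar shrinkage", {
  skip_if_not_installed("limma")
  set.seed(5)
  dm <- matrix(rnorm(2000 * 10, sd = rep(sqrt(0.5 * rf(2000, 9, 4)), 10)),
               2000, 10)
  res <- moderated_one_sample_test(dm)
  pr <- attr(res, "prior")
  sq <- limma::squeezeVar(res$s_sq, df = 9)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(res$s_tilde_sq, sq$var.post, tolerance = 1e-8)
})

test_that("BH adjustment matches the hand computation and bounds", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))
  expect_error(adjust_bh(c(0.1, 1.5)), "\\[0, 1\\]")
  p <- runif(100)
  expect_true(all(adjust_bh(p) >= p))
})

test_that("aDMP calling applies both thresholds; direction summary sums to 1", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    adj_p = c(0.04, 0.04, 0.2, 0.001),
                    delta_beta = c(0.25, 0.15, 0.5, -0.3))
  res$direction <- ifelse(res$delta_beta > 0, "gain", "loss")
  calls <- call_admps(res)
  expect_setequal(calls$stringent, c("a", "d"))
  expect_setequal(calls$relaxed, c("a", "b", "d"))

  ds <- direction_summary(calls$stringent, res)
  expect_equal(sum(ds), 1)
  expect_equal(unname(ds["gain"]), 0.5)
  expect_equal(unname(direction_summary("a", res)), c(1, 0))
  expect_error(direction_summary(character(), res), "empty")
})

test_that("technical contrast is silent when replicates are exact copies", {
  man <- small_manifest(800)
  coh <- small_cohort(800, man)
  coh0 <- inject_technical_replicates(coh, coh$truth$pairs$pair_id[1:3],
                                      sigma_technical = 0)
  qc <- qc_pipeline(coh0)
  tb <- technical_vs_biological(qc$m, qc$samples)
  expect_equal(tb$technical$n_significant, 0)
  expect_gt(tb$biological$n_significant, 0)
  expect_error(technical_vs_biological(qc$m, coh$samples), "no replicate")
})
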