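test_that("relative L1 distance is reference-anchored arithmetic", {
  expect_equal(rel_l1(0.50, 0.48), 4.0)
  expect_equal(rel_l1(0.7, 0.7), 0)
  expect_equal(rel_l1(2e-4, 2.1e-4), 5.0)
  expect_true(is.na(rel_l1(0, 1)))
  # scaling both arms leaves it unchanged
  set.seed(1)
  a <- runif(20, 0.2, 0.9); b <- a + rnorm(20, 0, 0.05)
  expect_equal(rel_l1(a, b), rel_l1(3 * a, 3 * b), tolerance = 1e-12)
})

test_that("distribution summary uses the interpolated percentile rule", {
  expect_equal(summarize_distribution(c(1, 2, 3))$median, 2)
  s <- summarize_distribution(rep(4.2, 10))
  expect_equal(c(s$lo, s$hi), c(4.2, 4.2))
  # independent type-7 formula: q_p at index (n-1)p + 1 with linear interp
  x <- as.numeric(1:100)
  q7 <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
  }
  s2 <- summarize_distribution(x)
  expect_equal(s2$lo, q7(0.025))
  expect_equal(s2$hi, q7(0.975))
  expect_error(summarize_distribution(NA_real_), "no non-missing")
})

test_that("KS statistic equals the brute-force ECDF gap on small samples", {
  set.seed(11)
  for (k in 1:25) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), 0.5)
    res <- ks_profile_test(matrix(x, ncol = 1), matrix(y, ncol = 1))
    # brute-force maximal ECDF gap over the pooled sample points
    pool <- sort(c(x, y))
    gap <- max(vapply(pool, function(t)
      abs(mean(x <= t) - mean(y <= t)), numeric(1)))
    expect_equal(res$statistic[1], gap, tolerance = 1e-12)
  }
})

test_that("a strongly shifted segment is flagged and only that one", {
  set.seed(21)
  n <- 20; n_seg <- 30
  ref <- matrix(rnorm(n * n_seg, 0.5, 0.01), n, n_seg)
  ds <- matrix(rnorm(n * n_seg, 0.5, 0.01), n, n_seg)
  ds[, 17] <- ds[, 17] + 0.1   # 10 SD shift on one segment
  res <- ks_profile_test(ref, ds)
  expect_true(res$significant[17])
  expect_equal(sum(res$significant), 1L)
  # identical arms: statistic 0, no flags
  same <- ks_profile_test(ref, ref)
  expect_true(all(same$statistic == 0))
  expect_true(all(!same$significant))
  expect_error(ks_profile_test(ref[1, , drop = FALSE],
                               ds[1, , drop = FALSE]), "2 subjects")
})

test_that("BH-corrected flags are a subset of uncorrected flags", {
  set.seed(31)
  ref <- matrix(rnorm(200), 10, 20)
  ds <- matrix(rnorm(200, 0.8), 10, 20)
  res <- ks_profile_test(ref, ds)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all(which(res$significant) %in% which(res$p < 0.05)))
})

test_that("Bland-Altman reproduces the hand-worked example", {
  ba <- bland_altman(c(0.9, 1.0, 1.1), c(1.0, 1.0, 1.0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 0.1)
  expect_equal(ba$loa_low, -0.196)
  expect_equal(ba$loa_high, 0.196)
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman limits behave as 95% bands and swap antisymmetrically", {
  set.seed(41)
  a <- rnorm(1000, 10, 1); b <- a + rnorm(1000, 0.3, 0.5)
  ba <- bland_altman(a, b)
  expect_gte(ba$frac_within, 0.93)
  ba_sw <- bland_altman(b, a)
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(ba_sw$loa_high - ba_sw$loa_low,
               ba$loa_high - ba$loa_low, tolerance = 1e-12)
})

test_that("volume loss sums per-bundle voxel counts", {
  m1 <- array(FALSE, c(5, 5, 4)); m1[1:5, 1:5, 1] <- TRUE   # 25
  m2 <- array(FALSE, c(5, 5, 4)); m2[1:5, 1:5, 2:4] <- TRUE # 75
  m2b <- m2; m2b[1, 1, 2:4] <- FALSE                        # 72
  expect_equal(volume_loss(list(m1, m2), list(m1, m2)), 0)
  expect_equal(volume_loss(list(m1, m2), list(m1, m2b)), 3)
  # matches an independent per-bundle accumulation
  v_ref <- sum(m1) + sum(m2); v_ds <- sum(m1) + sum(m2b)
  expect_equal(volume_loss(list(m1, m2), list(m1, m2b)),
               100 * (v_ref - v_ds) / v_ref)
  expect_error(volume_loss(list(array(FALSE, c(2, 2, 2))),
                           list(array(FALSE, c(2, 2, 2)))), "zero")
})

test_that("report writing emits the CSV/JSON contract", {
  cfg <- study_config(
    phantom = phantom_spec(grid_dim = c(8, 8, 8), n_subjects = 2,
                           n_sessions = 1, seed = 17, snr = 30,
                           n_streamlines = 4),
    rates = 0.5, metrics = c("FA", "ICvf"))
  rep <- run_study(cfg)
  tmp <- withr::local_tempdir()
  write_report(rep, tmp)
  for (f in c("bundle_average.csv", "profiles_ks.csv",
              "bland_altman.csv", "volume_loss.csv", "manifest.json"))
    expect_true(file.exists(file.path(tmp, f)))
  man <- jsonlite::read_json(file.path(tmp, "manifest.json"))
  expect_equal(man$seed, 17L)
  # rate-0 arm: exact zeros by construction
  ref_rows <- rep$bundle_average[rep$bundle_average$rate_pct == 0, ]
  expect_true(all(ref_rows$median_rel_l1 == 0))
  expect_true(all(rep$volume_loss$loss_pct[
    rep$volume_loss$rate_pct == 0] == 0))
  # determinism of the full pipeline
  rep2 <- run_study(cfg)
  expect_identical(rep$bundle_average, rep2$bundle_average)
})
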