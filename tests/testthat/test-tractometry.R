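test_that("resampling spaces points equally in arc length", {
  s <- line_streamline(c(0, 0, 0), c(0, 0, 97), n = 5)
  r <- resample_streamline(s, 98)
  expect_equal(nrow(r), 98L)
  expect_equal(r[, 3], 0:97)
  expect_equal(r[1, ], c(0, 0, 0)); expect_equal(r[98, ], c(0, 0, 97))
  # idempotent on an already-uniform 98-point line
  r2 <- resample_streamline(r, 98)
  expect_lt(max(abs(r2 - r)), 1e-9)
  # density invariance: resampled profile identical for denser input
  dense <- line_streamline(c(0, 0, 0), c(0, 0, 97), n = 400)
  expect_lt(max(abs(resample_streamline(dense, 98) - r)), 1e-9)
  expect_error(resample_streamline(rbind(c(1, 1, 1), c(1, 1, 1)), 5),
               "zero-length")
})

test_that("centroid averages flip-aligned streamlines", {
  a <- line_streamline(c(2, 2, 2), c(2, 2, 10))
  b_ <- line_streamline(c(4, 2, 2), c(4, 2, 10))
  bun <- toy_bundle(list(a, b_))
  ctr <- bundle_centroid(bun)
  expect_equal(ctr[, 1], rep(3, 98))
  # identical streamlines -> centroid equals them
  bun2 <- toy_bundle(list(a, a))
  expect_equal(bundle_centroid(bun2), resample_streamline(a, 98))
  # a reversed copy is flipped back before averaging
  bun3 <- toy_bundle(list(a, a[nrow(a):1, ]))
  expect_lt(max(abs(bundle_centroid(bun3) - resample_streamline(a, 98))),
            1e-9)
})

test_that("profiles match a brute-force assignment oracle", {
  # linear-gradient map over a 12^3 grid at 1 mm
  dims <- c(12, 12, 12)
  map <- array(0, dims)
  for (k in 1:12) map[, , k] <- k - 1      # value = z coordinate (mm)
  # irregular offsets so no streamline point is equidistant between two
  # centroid points (exact ties would depend on float rounding order)
  a <- line_streamline(c(5, 5, 1.1), c(5, 5, 9.7))
  b_ <- line_streamline(c(6.3, 5.2, 1.7), c(6.3, 5.2, 9.2))
  bun <- toy_bundle(list(a, b_))
  pr <- profile_bundle(bun, map)
  # independent brute force: same resampling, explicit nearest search
  rs <- lapply(list(a, b_), resample_streamline, n = 98)
  ctr <- (rs[[1]] + rs[[2]]) / 2
  vals <- rep(0, 98); cnt <- rep(0, 98)
  for (m in rs) for (i in 1:98) {
    dd <- colSums((t(ctr) - m[i, ])^2)
    j <- which.min(dd)
    vals[j] <- vals[j] + m[i, 3]   # trilinear sample of this map = z
    cnt[j] <- cnt[j] + 1
  }
  oracle <- ifelse(cnt > 0, vals / pmax(cnt, 1), NA)
  expect_equal(pr$values, oracle, tolerance = 1e-9)
  # constant map -> constant profile
  prc <- profile_bundle(bun, array(2.5, dims))
  expect_true(all(abs(prc$values[!is.na(prc$values)] - 2.5) < 1e-12))
  # single streamline: profile is the map along it
  pr1 <- profile_bundle(toy_bundle(list(a)), map)
  expect_equal(pr1$values, resample_streamline(a, 98)[, 3],
               tolerance = 1e-9)
})

test_that("profiles are invariant to streamline order", {
  set.seed(3)
  sls <- lapply(1:5, function(i)
    line_streamline(c(4 + i * 0.3, 5, 1), c(4 + i * 0.3, 5, 10)) +
      matrix(rnorm(60, 0, 0.05), 20, 3))
  map <- array(runif(12^3), c(12, 12, 12))
  p1 <- profile_bundle(toy_bundle(sls), map)
  p2 <- profile_bundle(toy_bundle(rev(sls)), map)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
  expect_equal(bundle_centroid(toy_bundle(sls)),
               bundle_centroid(toy_bundle(rev(sls))), tolerance = 1e-12)
})

test_that("joining concatenates left then right into 196 segments", {
  a <- line_streamline(c(2, 2, 2), c(2, 2, 10))
  pl <- profile_bundle(toy_bundle(list(a), name = "cst_left",
                                  side = "left"), array(1, c(12, 12, 12)))
  pr <- profile_bundle(toy_bundle(list(a), name = "cst_right",
                                  side = "right"), array(2, c(12, 12, 12)))
  j <- join_profiles(pl, pr)
  expect_equal(length(j$values), 196L)
  expect_equal(j$values, c(rep(1, 98), rep(2, 98)))
  expect_equal(j$bundle, "cst")
  short <- pl; short$values <- pl$values[1:50]
  expect_error(join_profiles(pl, short), "lengths differ")
})

test_that("bundle averages skip missing segments", {
  p <- structure(list(bundle = "x", side = "unpaired",
                      values = as.numeric(1:196)),
                 class = "bundle_profile")
  expect_equal(bundle_average(p), 98.5)
  p$values[5] <- NA
  expect_equal(bundle_average(p), mean(c(1:4, 6:196)))
  p$values[] <- NA
  expect_error(bundle_average(p), "missing")
})

test_that("bundle volume counts voxels and converts to mm^3", {
  m <- array(FALSE, c(10, 10, 3)); m[, , 2] <- TRUE
  expect_equal(bundle_volume(m, voxdim = c(2, 2, 2)),
               list(voxels = 100, mm3 = 800))
  expect_equal(bundle_volume(array(FALSE, c(4, 4, 4)),
                             voxdim = c(1, 1, 1))$voxels, 0)
})

test_that("streamline files round-trip in both formats", {
  sls <- list(line_streamline(c(0, 0, 0), c(1, 2, 3), 5),
              line_streamline(c(5, 5, 5), c(2, 1, 0), 8))
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "t.tck")
  write_tck(sls, f1)
  back <- read_tck(f1)
  expect_equal(length(back), 2L)
  for (i in 1:2) expect_equal(back[[i]], sls[[i]], tolerance = 1e-6)
  f2 <- file.path(tmp, "t.txt")
  write_polylines(sls, f2)
  back2 <- read_polylines(f2)
  for (i in 1:2) expect_equal(back2[[i]], sls[[i]], tolerance = 1e-6)
})

test_that("the packaged bundle grouping maps 40 labels to 22 groups", {
  g <- read_bundle_groups()
  expect_equal(nrow(g), 40L)
  expect_equal(length(unique(g$group)), 22L)
  cc <- c("Rostrum_and_Genu", "Anterior_Body", "Posterior_Body",
          "Isthmus", "Splenium")
  expect_true(all(cc %in% g$group))
})
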