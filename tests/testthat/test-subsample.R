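test_that("pair energy matches the antipodal Coulomb kernel", {
  expect_equal(pair_energy(c(1, 0, 0), c(0, 1, 0)), 2 / sqrt(2),
               tolerance = 1e-9)
  expect_identical(pair_energy(c(1, 0, 0), c(-1, 0, 0)), Inf)
  expect_identical(pair_energy(c(0, 1, 0), c(0, 1, 0)), Inf)
  set.seed(42)
  for (k in 1:10) {
    u <- random_dirs(1, seed = k); v <- random_dirs(1, seed = k + 100)
    expect_equal(pair_energy(u[1, ], v[1, ]), pair_energy(u[1, ], -v[1, ]))
  }
})

test_that("scheme energy combines per-shell and global terms", {
  s <- multishell_scheme(list(list(
    bvalue = 1000, directions = rbind(c(1, 0, 0), c(0, 1, 0)))))
  e <- scheme_energy(s, energy_config(0.5))
  expect_equal(e$V1, sqrt(2), tolerance = 1e-6)
  expect_equal(e$V2, sqrt(2), tolerance = 1e-6)
  expect_equal(e$V, sqrt(2), tolerance = 1e-6)
  # limiting cases of the alpha weight
  s2 <- toy_scheme(c(4, 5), seed = 3)
  e1 <- scheme_energy(s2, energy_config(1))
  e0 <- scheme_energy(s2, energy_config(0))
  expect_equal(e1$V, e1$V1)
  expect_equal(e0$V, e0$V2)
  # rotation invariance: energy depends on pairwise angles only
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- multishell_scheme(lapply(s2$shells, function(sh)
    list(bvalue = sh$bvalue, directions = sh$directions %*% t(R))))
  expect_equal(scheme_energy(rot)$V, scheme_energy(s2)$V,
               tolerance = 1e-9)
})

test_that("retained-count rule reproduces all nine reference triples", {
  expect_equal(unname(target_counts(c(6, 48, 60), 0.10)), c(5, 43, 54))
  expect_equal(unname(target_counts(c(6, 48, 60), 0.30)), c(4, 34, 42))
  expect_equal(unname(target_counts(c(6, 48, 60), 0.50)), c(3, 24, 30))
  expect_equal(unname(target_counts(c(8, 32, 60), 0.10)), c(7, 29, 54))
  expect_equal(unname(target_counts(c(8, 32, 60), 0.30)), c(6, 22, 42))
  expect_equal(unname(target_counts(c(8, 32, 60), 0.50)), c(4, 16, 30))
  expect_equal(unname(target_counts(c(6, 20, 45), 0.10)), c(5, 18, 41))
  expect_equal(unname(target_counts(c(6, 20, 45), 0.30)), c(4, 14, 32))
  expect_equal(unname(target_counts(c(6, 20, 45), 0.50)), c(3, 10, 23))
  expect_equal(unname(target_counts(c(5, 9), 0)), c(5, 9))
  expect_equal(unname(target_counts(c(2), 0.9)), 1)  # floored at 1
  expect_error(target_counts(c(6, 20), 1))
  expect_error(target_counts(c(6, 20), -0.1))
})

test_that("greedy+swap matches exhaustive enumeration on a 4-choose-3 shell", {
  s <- toy_scheme(c(4), seed = 1)
  sub <- subsample_scheme(s, subsample_plan(0, target_counts = 3L))
  ex <- exhaustive_min_subset(s, 3L)
  expect_equal(attr(sub, "energy_after")$V, ex$V, tolerance = 1e-12)
  # cross-check the oracle's V against the public energy function
  kept <- s$shells[[1]]$directions[ex$keep, , drop = FALSE]
  s_ex <- multishell_scheme(list(list(bvalue = 1000, directions = kept)))
  expect_equal(scheme_energy(s_ex)$V, ex$V, tolerance = 1e-12)
})

test_that("subset, quota, and determinism properties hold", {
  s <- toy_scheme(c(5, 6), seed = 7)
  plan <- subsample_plan(0, target_counts = c(3L, 4L))
  sub <- subsample_scheme(s, plan)
  expect_equal(unname(shell_counts(sub)), c(3L, 4L))
  for (k in 1:2) {
    ref_rows <- apply(s$shells[[k]]$directions, 1, paste, collapse = ",")
    sub_rows <- apply(sub$shells[[k]]$directions, 1, paste, collapse = ",")
    expect_true(all(sub_rows %in% ref_rows))  # bit-identical subset
  }
  sub2 <- subsample_scheme(s, plan)
  expect_identical(scheme_dirs(sub2), scheme_dirs(sub))
  # energy no worse than 200 random valid subsets
  V <- attr(sub, "energy_after")$V
  set.seed(123)
  for (r in 1:200) {
    k1 <- sort(sample(5, 3)); k2 <- sort(sample(6, 4))
    rs <- multishell_scheme(list(
      list(bvalue = 1000,
           directions = s$shells[[1]]$directions[k1, , drop = FALSE]),
      list(bvalue = 2000,
           directions = s$shells[[2]]$directions[k2, , drop = FALSE])))
    expect_lte(V, scheme_energy(rs)$V + 1e-12)
  }
})

test_that("rate 0 returns the scheme unchanged with identity indices", {
  s <- toy_scheme(c(4, 6), n_b0 = 2, seed = 5)
  sub <- subsample_scheme(s, subsample_plan(0))
  expect_identical(scheme_dirs(sub), scheme_dirs(s))
  expect_equal(attr(sub, "retained_volumes"), seq_len(n_volumes(s)))
})

test_that("greedy elimination picks the locally optimal removal at each step", {
  s <- toy_scheme(c(7), seed = 11)
  sub <- subsample_scheme(s, subsample_plan(0, target_counts = 6L))
  # removing any single direction: the chosen one must give minimal V
  V_choice <- attr(sub, "energy_after")$V
  for (i in 1:7) {
    alt <- multishell_scheme(list(list(
      bvalue = 1000,
      directions = s$shells[[1]]$directions[-i, , drop = FALSE])))
    expect_lte(V_choice, scheme_energy(alt)$V + 1e-12)
  }
})

test_that("impossible quotas and bad plans error", {
  s <- toy_scheme(c(4), seed = 1)
  expect_error(subsample_scheme(s, subsample_plan(0, target_counts = 5L)),
               "exceeds")
  expect_error(subsample_plan(1.2))
  expect_error(energy_config(1.5))
})

test_that("file-level downsampling writes scheme and sidecar", {
  tmp <- withr::local_tempdir()
  s <- make_scheme("adni3", seed = 2)
  write_scheme(s, file.path(tmp, "ref"), "fsl")
  out <- downsample_files(file.path(tmp, "ref.bval"),
                          file.path(tmp, "ref.bvec"),
                          rate = 0.3, out_prefix = file.path(tmp, "ds"))
  expect_equal(unname(shell_counts(out)), c(4L, 34L, 42L))
  side <- jsonlite::read_json(file.path(tmp, "ds.json"),
                              simplifyVector = TRUE)
  expect_equal(side$retained_counts, c(4L, 34L, 42L))
  expect_lt(side$energy_after$V, side$energy_before$V)
  expect_equal(length(side$retained_volumes), 13 + 80)
})
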