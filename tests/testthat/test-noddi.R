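test_that("orientation dispersion index maps kappa correctly", {
  expect_equal(od_from_kappa(1), 0.5)
  expect_equal(od_from_kappa(0), 1)
  expect_lt(od_from_kappa(1e8), 1e-7)
  expect_error(od_from_kappa(-1))
})

test_that("Watson-dispersed stick obeys its limits", {
  s <- toy_scheme(c(12, 12), bvalues = c(1000, 2000), n_b0 = 2, seed = 2)
  b <- scheme_bvals(s); G <- scheme_dirs(s)
  # b0 rows are exactly 1
  E <- watson_stick_signal(s, c(0, 0, 1), kappa = 2)
  expect_identical(E[1:2], c(1, 1))
  # coherent limit: no attenuation perpendicular to the stick
  sp <- multishell_scheme(list(list(
    bvalue = 2000, directions = rbind(c(1, 0, 0), c(0, 0, 1)))))
  Ec <- watson_stick_signal(sp, c(0, 0, 1), kappa = 1e6)
  expect_equal(Ec[1], 1, tolerance = 1e-9)                  # g  |  mu
  expect_equal(Ec[2], exp(-2000 * 1.7e-3), tolerance = 1e-9) # g || mu
  # kappa = 0: isotropic dispersion, signal independent of direction
  E0 <- watson_stick_signal(s, c(0, 0, 1), kappa = 0)
  for (bb in unique(b[b > 0]))
    expect_lt(diff(range(E0[b == bb])), 1e-10)
  # dense-quadrature oracle
  Ed <- watson_stick_signal(s, c(0, 0, 1), kappa = 0,
                            quad = watson_quadrature(100, 100))
  expect_lt(max(abs(E0 - Ed)), 1e-4)
})

test_that("NODDI forward signal matches a dense-quadrature oracle", {
  s <- make_scheme("basel", seed = 2)
  p <- noddi_params(0.6, 0.1, 2, mu = c(0, 0, 1))
  E <- noddi_signal(s, p)
  Ed <- noddi_signal(s, p, quad = watson_quadrature(100, 100))
  expect_lt(max(abs(E - Ed)), 1e-4)
  # normalization and pure-CSF limits
  expect_true(all(E[scheme_bvals(s) == 0] == 1))
  csf <- noddi_signal(s, noddi_params(0.3, 1, 2))
  expect_equal(csf, exp(-scheme_bvals(s) * 3e-3), tolerance = 1e-12)
})

test_that("dictionary has the advertised structure", {
  s <- toy_scheme(c(8, 8), bvalues = c(1000, 2000), n_b0 = 2, seed = 3)
  d <- build_dictionary(s, c(0, 0, 1), noddi_grid(12, 12))
  expect_equal(ncol(d$atoms), 144L)
  expect_equal(nrow(d$atoms), n_volumes(s))
  expect_true(all(abs(d$atoms[1:2, ] - 1) < 1e-12))   # b0 rows
  expect_true(all(abs(d$iso_atom[1:2] - 1) < 1e-12))
  expect_error(build_dictionary(s, c(0, 0, 1),
                                structure(list(v_ic = numeric(0),
                                               kappa = numeric(0)),
                                          class = "noddi_grid")))
  # near-coherent atoms approach the parallel stick-zeppelin mixture;
  # the residual Watson dispersion perturbs the signal at relative order
  # b*d_par/kappa (~5% at kappa=64, b=2000), vanishing as kappa grows
  b <- scheme_bvals(s); G <- scheme_dirs(s)
  ct2 <- G[, 3]^2
  for (kap in c(64, 640)) {
    dk <- build_dictionary(s, c(0, 0, 1),
                           noddi_grid(3, 1, vic_range = c(0.3, 0.7),
                                      kappa_range = c(kap, kap)))
    bound <- 1.5 * max(b) * 1.7e-3 / kap
    for (j in 1:3) {
      v <- dk$grid$v_ic[j]
      dpe <- 1.7e-3 * (1 - v)
      closed <- v * exp(-b * 1.7e-3 * ct2) +
        (1 - v) * exp(-b * (dpe + (1.7e-3 - dpe) * ct2))
      expect_lt(max(abs(dk$atoms[, j] - closed) / closed), bound)
    }
  }
})

test_that("dictionary fit recovers known parameters and is deterministic", {
  s <- make_scheme("basel", seed = 4)
  p <- noddi_params(0.6, 0.1, 2, mu = c(0.3, -0.5, 0.8))
  sim <- simulate_voxels(s, params = list(p, p), snr = Inf)
  tf <- fit_tensor(sim$data)
  nm <- fit_noddi(sim$data, tf)
  expect_lt(abs(nm$ICvf[1, 1, 1] - 0.6), 0.03)
  expect_lt(abs(nm$ISOvf[1, 1, 1] - 0.1), 0.03)
  expect_lt(abs(nm$OD[1, 1, 1] - od_from_kappa(2)), 0.05)
  nm2 <- fit_noddi(sim$data, tf)
  expect_identical(nm$ICvf, nm2$ICvf)
  # pure CSF voxel
  csf <- simulate_voxels(s, params = list(noddi_params(0.5, 1, 1),
                                          noddi_params(0.5, 1, 1)),
                         snr = Inf)
  nmc <- fit_noddi(csf$data, fit_tensor(csf$data))
  expect_gte(nmc$ISOvf[1, 1, 1], 0.95)
  # bounds
  for (m in list(nm$ICvf, nm$ISOvf, nm$OD)) {
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("maps are invariant to raw signal scaling (b0 normalization)", {
  s <- make_scheme("sherbrooke", seed = 5)
  sim <- simulate_voxels(s, params = list(noddi_params(0.7, 0.05, 4)),
                         snr = Inf)
  tf <- fit_tensor(sim$data)
  nm1 <- fit_noddi(sim$data, tf)
  ds2 <- sim$data
  ds2$signal <- ds2$signal * 3.7
  nm2 <- fit_noddi(ds2, fit_tensor(ds2))
  expect_equal(nm1$ICvf, nm2$ICvf, tolerance = 1e-8)
  expect_equal(nm1$ISOvf, nm2$ISOvf, tolerance = 1e-8)
})

test_that("ICvf error shrinks from SNR 10 to noise-free", {
  s <- make_scheme("basel", seed = 6)
  err <- sapply(c(10, Inf), function(snr) {
    sim <- simulate_voxels(s, n = 60, snr = snr, seed = 31)
    tf <- fit_tensor(sim$data)
    nm <- fit_noddi(sim$data, tf)
    true_ic <- vapply(sim$params, `[[`, numeric(1), "v_ic")
    mean(abs(nm$ICvf[, 1, 1] - true_ic))
  })
  expect_lt(err[2], err[1])
})

test_that("compiled NNLS agrees with an independent active-set solver", {
  set.seed(8)
  for (k in 1:20) {
    A <- matrix(rnorm(15 * 6), 15, 6)
    y <- rnorm(15)
    x1 <- dwidown:::nnls_solve(A, y)
    x2 <- pracma::lsqnonneg(A, y)$x
    expect_equal(as.vector(x1), x2, tolerance = 1e-7)
  }
})
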