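#' @useDynLib dwidown, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed diffusivities (NODDI convention), mm^2/s
.D_PAR <- 1.7e-3
.D_ISO <- 3.0e-3
# Watson concentration beyond which the coherent (stick) limit is used
.KAPPA_STICK <- 1e4

#' Orientation dispersion index from Watson concentration
#'
#' `OD = (2/pi) * atan(1/kappa)`, with `OD(0) = 1` by continuity
#' (isotropically dispersed) and `OD -> 0` as `kappa -> Inf` (coherent).
#'
#' @param kappa Watson concentration parameter(s), >= 0.
#' @return OD in `[0, 1]`.
#' @export
od_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  ifelse(kappa == 0, 1, (2 / pi) * atan(1 / kappa))
}

#' NODDI tissue parameters
#'
#' Three-compartment model: Watson-dispersed intra-cellular sticks
#' (volume fraction `v_ic` of the tissue), hindered extra-cellular
#' zeppelin with tortuosity `d_perp = d_par * (1 - v_ic)`, and isotropic
#' CSF (`v_iso` of the voxel) with fixed diffusivity.
#'
#' @param v_ic intra-cellular volume fraction in `[0, 1]`.
#' @param v_iso isotropic (CSF) volume fraction in `[0, 1]`.
#' @param kappa Watson concentration, >= 0.
#' @param mu mean orientation unit 3-vector.
#' @param d_par intrinsic parallel diffusivity, mm^2/s.
#' @param d_iso CSF diffusivity, mm^2/s.
#' @return A `noddi_params` list; `OD` is derived from `kappa`.
#' @export
noddi_params <- function(v_ic, v_iso, kappa, mu = c(0, 0, 1),
                         d_par = .D_PAR, d_iso = .D_ISO) {
  stopifnot(v_ic >= 0, v_ic <= 1, v_iso >= 0, v_iso <= 1, kappa >= 0)
  mu <- mu / sqrt(sum(mu^2))
  structure(list(v_ic = v_ic, v_iso = v_iso, kappa = kappa,
                 OD = od_from_kappa(kappa), mu = mu,
                 d_par = d_par, d_iso = d_iso),
            class = "noddi_params")
}

#' Antipodally symmetric spherical quadrature grid
#'
#' Gauss-Legendre nodes in cos(theta) crossed with a uniform periodic
#' azimuth grid; exact for smooth integrands to high order. The grid is
#' closed under the antipodal map (even `n_phi`), as required by the
#' axially symmetric Watson kernels.
#'
#' @param n_t number of Gauss-Legendre nodes in cos(theta).
#' @param n_phi number of (even) azimuth nodes.
#' @return list with `points` (n x 3 unit rows) and `weights`
#'   (normalized to sum 1).
#' @export
watson_quadrature <- function(n_t = 64, n_phi = 48) {
  gl <- pracma::gaussLegendre(n_t, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  t <- rep(gl$x, each = n_phi)
  p <- rep(phi, n_t)
  st <- sqrt(pmax(1 - t^2, 0))
  pts <- cbind(st * cos(p), st * sin(p), t)
  w <- rep(gl$w, each = n_phi) / n_phi
  list(points = pts, weights = w / sum(w))
}

# Normalized Watson weights over a quadrature grid; tq = mu . n per node.
# exp(kappa * (t^2 - 1)) avoids overflow; normalization is numeric, from
# the same grid, so model and normalization share one quadrature.
.watson_weights <- function(kappa, tq, base_w) {
  w <- base_w * exp(kappa * (tq^2 - 1))
  w / sum(w)
}

# Watson-weighted mean of exp(-b * d * (g . n)^2) over stick orientations
# n; the shared primitive behind both dispersed compartments.
.watson_attenuation <- function(b, G, mu, kappa, d, quad) {
  if (kappa >= .KAPPA_STICK) {
    ct <- as.vector(G %*% mu)
    return(exp(-b * d * ct^2))
  }
  tq <- as.vector(quad$points %*% mu)
  w <- .watson_weights(kappa, tq, quad$weights)
  M <- (G %*% t(quad$points))^2      # (g_i . n_q)^2
  as.vector(exp(-(b * d) * M) %*% w)
}

#' Watson-dispersed stick signal
#'
#' Intra-cellular signal fraction: the stick attenuation
#' `exp(-b d_par (g . n)^2)` convolved with a Watson orientation
#' distribution about `mu` with concentration `kappa`, evaluated by
#' spherical quadrature. b0 volumes return exactly 1. For
#' `kappa >= 1e4` the coherent-stick limit is returned in closed form.
#'
#' @param scheme a `multishell_scheme`.
#' @param mu mean orientation unit 3-vector.
#' @param kappa Watson concentration, >= 0.
#' @param d_par parallel diffusivity, mm^2/s.
#' @param quad quadrature grid from [watson_quadrature()].
#' @return Signal fraction per canonical volume.
#' @export
watson_stick_signal <- function(scheme, mu, kappa, d_par = .D_PAR,
                                quad = watson_quadrature()) {
  stopifnot(kappa >= 0)
  mu <- mu / sqrt(sum(mu^2))
  b <- scheme_bvals(scheme)
  G <- scheme_dirs(scheme)
  E <- rep(1, length(b))
  dw <- b > 0
  if (any(dw))
    E[dw] <- .watson_attenuation(b[dw], G[dw, , drop = FALSE], mu, kappa,
                                 d_par, quad)
  E
}

#' NODDI forward signal
#'
#' `E = v_iso exp(-b d_iso) + (1 - v_iso) [v_ic E_ic + (1 - v_ic) E_ec]`,
#' with `E_ic` the Watson-dispersed stick and `E_ec` a zeppelin with
#' tortuosity `d_perp = d_par (1 - v_ic)` dispersed by the same Watson
#' distribution (the zeppelin factorizes as
#' `exp(-b d_perp) * exp(-b (d_par - d_perp) (g.n)^2)`, so its dispersed
#' form reuses the stick quadrature at diffusivity `d_par - d_perp`).
#'
#' @param scheme a `multishell_scheme`.
#' @param p a [noddi_params()].
#' @param quad quadrature grid from [watson_quadrature()].
#' @return Signal fraction per canonical volume (1 at b0).
#' @export
noddi_signal <- function(scheme, p, quad = watson_quadrature()) {
  stopifnot(inherits(p, "noddi_params"))
  b <- scheme_bvals(scheme)
  G <- scheme_dirs(scheme)
  E_iso <- exp(-b * p$d_iso)
  d_perp <- p$d_par * (1 - p$v_ic)
  E <- rep(1, length(b))
  dw <- b > 0
  if (any(dw)) {
    Gd <- G[dw, , drop = FALSE]; bd <- b[dw]
    E_ic <- .watson_attenuation(bd, Gd, p$mu, p$kappa, p$d_par, quad)
    E_ec <- exp(-bd * d_perp) *
      .watson_attenuation(bd, Gd, p$mu, p$kappa, p$d_par - d_perp, quad)
    E[dw] <- p$v_iso * E_iso[dw] +
      (1 - p$v_iso) * (p$v_ic * E_ic + (1 - p$v_ic) * E_ec)
  }
  E
}

#' Dictionary grid specification
#'
#' @param n_vic number of `v_ic` grid points (default 12 in
#'   `[0.05, 0.95]`).
#' @param n_kappa number of `kappa` grid points (default 12, log-spaced in
#'   `[0.05, 64]`).
#' @param vic_range,kappa_range grid ranges.
#' @return A `noddi_grid` list with `v_ic` and `kappa` vectors.
#' @export
noddi_grid <- function(n_vic = 12, n_kappa = 12,
                       vic_range = c(0.05, 0.95),
                       kappa_range = c(0.05, 64)) {
  stopifnot(n_vic >= 1, n_kappa >= 1)
  structure(list(
    v_ic = seq(vic_range[1], vic_range[2], length.out = n_vic),
    kappa = exp(seq(log(kappa_range[1]), log(kappa_range[2]),
                    length.out = n_kappa))),
    class = "noddi_grid")
}

#' Build a NODDI signal dictionary for one orientation
#'
#' One atom per `(v_ic, kappa)` grid pair, computed by [noddi_signal()]
#' with `v_iso = 0`, plus the isotropic CSF atom `exp(-b d_iso)`. Every
#' atom equals 1 on b0 rows.
#'
#' @param scheme a `multishell_scheme`.
#' @param mu mean orientation unit 3-vector.
#' @param grid a [noddi_grid()].
#' @param quad quadrature grid.
#' @return A `noddi_dictionary`: list with `atoms` (n_volumes x n_pairs),
#'   `grid` (data.frame of the v_ic/kappa pairs, v_ic varying fastest),
#'   and `iso_atom`.
#' @export
build_dictionary <- function(scheme, mu, grid = noddi_grid(),
                             quad = watson_quadrature()) {
  if (length(grid$v_ic) == 0 || length(grid$kappa) == 0)
    stop("empty dictionary grid")
  pairs <- expand.grid(v_ic = grid$v_ic, kappa = grid$kappa)
  atoms <- vapply(seq_len(nrow(pairs)), function(j)
    noddi_signal(scheme,
                 noddi_params(pairs$v_ic[j], 0, pairs$kappa[j], mu = mu),
                 quad),
    numeric(n_volumes(scheme)))
  structure(list(atoms = atoms, grid = pairs,
                 iso_atom = exp(-scheme_bvals(scheme) * .D_ISO)),
            class = "noddi_dictionary")
}

# Precomputed per-shell atom tables over t = |g . mu| for fast per-voxel
# dictionary assembly (the signal depends on g and mu only through t).
.noddi_shell_tables <- function(scheme, grid, quad, n_t_grid = 65) {
  tt <- seq(0, 1, length.out = n_t_grid)
  ut <- cbind(sqrt(pmax(1 - tt^2, 0)), 0, tt)   # probe directions, mu = z
  tq <- quad$points[, 3]
  nk <- length(grid$kappa)
  Wk <- vapply(grid$kappa, function(k) .watson_weights(k, tq, quad$weights),
               numeric(length(tq)))
  M <- (ut %*% t(quad$points))^2
  bvals <- shell_bvalues(scheme)
  tabs <- vector("list", length(bvals))
  for (s in seq_along(bvals)) {
    b <- bvals[s]
    Fic <- exp(-(b * .D_PAR) * M) %*% Wk          # n_t x n_kappa
    Ts <- matrix(0, n_t_grid, length(grid$v_ic) * nk)
    for (vi in seq_along(grid$v_ic)) {
      v <- grid$v_ic[vi]
      d_perp <- .D_PAR * (1 - v)
      Fec <- exp(-(b * (.D_PAR - d_perp)) * M) %*% Wk
      # columns laid out as expand.grid(v_ic, kappa): v_ic fastest
      idx <- vi + (seq_len(nk) - 1) * length(grid$v_ic)
      Ts[, idx] <- v * Fic + (1 - v) * exp(-b * d_perp) * Fec
    }
    tabs[[s]] <- Ts
  }
  list(t_grid = tt, tables = tabs)
}

#' AMICO-style linearized NODDI fit
#'
#' Per masked voxel: the orientation `mu` is taken from the tensor fit's
#' principal eigenvector (two-step design, as in dictionary-based NODDI
#' solvers); the b0-normalized signal is decomposed by non-negative least
#' squares onto the tissue dictionary plus the isotropic atom, with a
#' small ridge penalty. ISOvf is the isotropic weight fraction; ICvf and
#' kappa are weight-averaged over the tissue atoms, and OD is derived
#' from the averaged kappa. Atoms are tabulated per shell as functions of
#' `t = |g . mu|` and interpolated per voxel, so the dictionary is built
#' once per scheme rather than per voxel.
#'
#' @param data a `dwi_dataset`.
#' @param tensor a `tensor_fit` sharing the dataset's scheme and mask.
#' @param grid a [noddi_grid()].
#' @param lambda ridge penalty on the atom weights (default 1e-3).
#' @param quad quadrature grid.
#' @return A `noddi_maps` list with 3-D arrays `ICvf`, `ISOvf`, `OD` (all
#'   in `[0, 1]`), `kappa`, and logical `flagged` (zero total weight).
#' @export
fit_noddi <- function(data, tensor, grid = noddi_grid(), lambda = 1e-3,
                      quad = watson_quadrature()) {
  stopifnot(inherits(data, "dwi_dataset"), inherits(tensor, "tensor_fit"))
  scheme <- data$scheme
  if (n_volumes(tensor$scheme) != n_volumes(scheme))
    stop("tensor fit and dataset schemes differ")
  b <- scheme_bvals(scheme)
  G <- scheme_dirs(scheme)
  sidx <- scheme_shell_index(scheme)
  dims <- dim(data$signal)[1:3]
  vox <- which(data$mask)
  S <- matrix(data$signal, prod(dims), length(b))[vox, , drop = FALSE]
  MU <- matrix(tensor$evec1, prod(dims), 3)[vox, , drop = FALSE]
  S0 <- rowMeans(S[, b == 0, drop = FALSE])

  tab <- .cached_shell_tables(scheme, grid, quad)
  dt <- tab$t_grid[2] - tab$t_grid[1]
  n_atoms <- nrow(expand.grid(grid$v_ic, grid$kappa))
  vic_of <- rep(grid$v_ic, times = length(grid$kappa))
  kap_of <- rep(grid$kappa, each = length(grid$v_ic))
  iso_col <- exp(-b * .D_ISO)
  ridge <- sqrt(lambda) * diag(n_atoms + 1)

  nvox <- length(vox)
  icvf <- isovf <- odv <- kapv <- numeric(nvox)
  flag <- logical(nvox)
  A <- matrix(1, length(b), n_atoms + 1)
  A[, n_atoms + 1] <- iso_col
  for (i in seq_len(nvox)) {
    if (!is.finite(S0[i]) || S0[i] <= 0 || !all(is.finite(MU[i, ]))) {
      flag[i] <- TRUE; next
    }
    mu <- MU[i, ]
    for (s in seq_along(scheme$shells)) {
      rows <- which(sidx == s)
      tv <- abs(G[rows, , drop = FALSE] %*% mu)
      pos <- pmin(pmax(as.vector(tv), 0), 1) / dt
      i0 <- pmin(floor(pos), length(tab$t_grid) - 2)
      w1 <- pos - i0
      Ts <- tab$tables[[s]]
      A[rows, seq_len(n_atoms)] <-
        Ts[i0 + 1, , drop = FALSE] * (1 - w1) +
        Ts[i0 + 2, , drop = FALSE] * w1
    }
    y <- S[i, ] / S0[i]
    w <- nnls_solve(rbind(A, ridge), c(y, numeric(n_atoms + 1)))
    tot <- sum(w)
    if (tot <= 1e-12) { flag[i] <- TRUE; next }
    wt <- w[seq_len(n_atoms)]
    st <- sum(wt)
    isovf[i] <- w[n_atoms + 1] / tot
    if (st > 1e-12) {
      icvf[i] <- sum(wt * vic_of) / st
      kapv[i] <- sum(wt * kap_of) / st
      odv[i] <- od_from_kappa(kapv[i])
    }
  }
  to3d <- function(v) { a <- array(NA_real_, dims); a[vox] <- v; a }
  structure(list(ICvf = to3d(icvf), ISOvf = to3d(isovf), OD = to3d(odv),
                 kappa = to3d(kapv),
                 flagged = {a <- array(FALSE, dims); a[vox] <- flag; a},
                 voxdim = data$voxdim),
            class = "noddi_maps")
}
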