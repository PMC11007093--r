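#' Diffusion-weighted dataset
#'
#' Bundles a 4-D signal array with its gradient scheme and a brain mask.
#' The 4th dimension follows the scheme's canonical volume order (b0
#' volumes first, then shells in ascending b-value).
#'
#' @param signal 4-D numeric array (x, y, z, volume), arbitrary units.
#' @param scheme a `multishell_scheme` with `n_volumes(scheme)` equal to
#'   the 4th dimension.
#' @param mask 3-D logical array matching the spatial dimensions.
#' @param voxdim voxel size in mm (length-3).
#' @return A `dwi_dataset` list.
#' @export
dwi_dataset <- function(signal, scheme, mask, voxdim = c(2, 2, 2)) {
  stopifnot(length(dim(signal)) == 4, inherits(scheme, "multishell_scheme"))
  if (dim(signal)[4] != n_volumes(scheme))
    stop("4th dimension (", dim(signal)[4], ") != n_b0 + total directions (",
         n_volumes(scheme), ")")
  if (!all(dim(mask) == dim(signal)[1:3]))
    stop("mask shape does not match signal spatial dimensions")
  structure(list(signal = signal, scheme = scheme,
                 mask = array(as.logical(mask), dim(mask)),
                 voxdim = voxdim),
            class = "dwi_dataset")
}

#' Restrict a dataset to a retained subset of volumes
#'
#' Applies the `retained_volumes` index set produced by
#' [subsample_scheme()] (b0 volumes always included) to the 4-D signal,
#' rebuilding the scheme consistently.
#'
#' @param data a `dwi_dataset`.
#' @param retained integer vector of canonical volume indices to keep.
#' @return A `dwi_dataset` with the reduced scheme and signal.
#' @export
slice_dataset <- function(data, retained) {
  stopifnot(inherits(data, "dwi_dataset"))
  nv <- n_volumes(data$scheme)
  if (any(retained < 1 | retained > nv)) stop("volume index out of range")
  retained <- sort(unique(as.integer(retained)))
  b <- scheme_bvals(data$scheme)
  b0_idx <- seq_len(data$scheme$n_b0)
  retained <- sort(unique(c(b0_idx, retained)))  # b0 always retained
  if (identical(retained, seq_len(nv))) return(data)
  d <- scheme_dirs(data$scheme)
  scheme <- scheme_from_volumes(b[retained], d[retained, , drop = FALSE],
                                metadata = data$scheme$metadata)
  dwi_dataset(data$signal[, , , retained, drop = FALSE], scheme, data$mask,
              data$voxdim)
}

#' Weighted linear least-squares diffusion tensor fit
#'
#' Per masked voxel, fits `log(S/S0)` against the 6 unique tensor elements
#' with design rows `(-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz,
#' -2b gy gz)`. An ordinary LLS pass provides predicted signals whose
#' squares serve as weights for one reweighted pass. S0 is the mean of the
#' b0 volumes. Non-positive signals are clipped to a small epsilon before
#' the log and their weight set to ~0, so a single clipped measurement is
#' effectively excluded while the fit still returns. All shells enter the
#' fit.
#'
#' @param data a `dwi_dataset` with >= 6 diffusion-weighted volumes
#'   spanning non-coplanar directions and >= 1 b0 volume.
#' @return A `tensor_fit`: list with 4-D array `D` (x,y,z,6; order Dxx,
#'   Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), 3-D `S0`, 4-D `evals`
#'   (descending), 4-D `evec1` (principal eigenvector), logical 3-D
#'   `clamped` (negative eigenvalues clamped to 0 for metrics), plus the
#'   scheme and mask.
#' @export
fit_tensor <- function(data) {
  stopifnot(inherits(data, "dwi_dataset"))
  scheme <- data$scheme
  if (scheme$n_b0 < 1) stop("at least one b0 volume is required")
  b <- scheme_bvals(scheme)
  g <- scheme_dirs(scheme)
  dwi <- which(b > 0)
  if (length(dwi) < 6) stop("fewer than 6 diffusion-weighted volumes")
  X <- cbind(-b[dwi] * g[dwi, 1]^2, -b[dwi] * g[dwi, 2]^2,
             -b[dwi] * g[dwi, 3]^2, -2 * b[dwi] * g[dwi, 1] * g[dwi, 2],
             -2 * b[dwi] * g[dwi, 1] * g[dwi, 3],
             -2 * b[dwi] * g[dwi, 2] * g[dwi, 3])
  if (qr(X)$rank < 6) stop("directions do not span 6 non-coplanar axes")

  dims <- dim(data$signal)[1:3]
  vox <- which(data$mask)
  nvox <- length(vox)
  S <- matrix(data$signal, prod(dims), dim(data$signal)[4])[vox, ,
                                                            drop = FALSE]
  S0 <- rowMeans(S[, seq_len(scheme$n_b0), drop = FALSE])
  Sd <- S[, dwi, drop = FALSE]

  Dmat <- matrix(NA_real_, nvox, 6)
  ok <- S0 > 0 & apply(Sd, 1, function(r) any(r > 0))
  eps <- 1e-8
  XtX_inv_Xt <- solve(crossprod(X), t(X))
  for (i in which(ok)) {
    s <- Sd[i, ]
    clip <- s <= 0
    s[clip] <- eps * S0[i]
    y <- log(s / S0[i])
    beta <- XtX_inv_Xt %*% y
    w <- (S0[i] * exp(X %*% beta))^2
    w[clip] <- 1e-12 * max(w)
    XW <- X * as.vector(w)
    beta <- tryCatch(solve(crossprod(X, XW), crossprod(XW, y)),
                     error = function(e) beta)
    Dmat[i, ] <- beta
  }

  evals <- matrix(NA_real_, nvox, 3)
  evec1 <- matrix(NA_real_, nvox, 3)
  clamped <- rep(FALSE, nvox)
  for (i in which(ok)) {
    d <- Dmat[i, ]
    M <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3)
    e <- eigen(M, symmetric = TRUE)
    evals[i, ] <- e$values
    evec1[i, ] <- e$vectors[, 1]
    if (any(e$values < 0)) clamped[i] <- TRUE
  }

  to3d <- function(v) { a <- array(NA_real_, dims); a[vox] <- v; a }
  to4d <- function(m) {
    a <- array(NA_real_, c(dims, ncol(m)))
    for (k in seq_len(ncol(m))) a[vox + (k - 1) * prod(dims)] <- m[, k]
    a
  }
  structure(list(D = to4d(Dmat), S0 = to3d(S0), evals = to4d(evals),
                 evec1 = to4d(evec1),
                 clamped = {a <- array(FALSE, dims); a[vox] <- clamped; a},
                 flagged = {a <- array(FALSE, dims); a[vox] <- !ok; a},
                 scheme = scheme, mask = data$mask, voxdim = data$voxdim),
            class = "tensor_fit")
}

#' Scalar maps from a tensor fit
#'
#' MD is the eigenvalue mean, RD the mean of the two smaller eigenvalues,
#' and FA the normalized eigenvalue dispersion
#' `sqrt(3/2) * sqrt(sum((l_i - MD)^2)) / sqrt(sum(l_i^2))`. Negative
#' eigenvalues are clamped to 0 before the metric computation (the voxels
#' are flagged in the fit); an all-zero voxel yields FA = 0.
#'
#' @param fit a `tensor_fit`.
#' @return A `tensor_maps` list with 3-D arrays `FA` (dimensionless, in
#'   `[0, 1]`), `MD` and `RD` (mm^2/s).
#' @export
tensor_metrics <- function(fit) {
  stopifnot(inherits(fit, "tensor_fit"))
  d3 <- dim(fit$evals)[1:3]
  l1 <- array(pmax(fit$evals[, , , 1], 0), d3)
  l2 <- array(pmax(fit$evals[, , , 2], 0), d3)
  l3 <- array(pmax(fit$evals[, , , 3], 0), d3)
  MD <- (l1 + l2 + l3) / 3
  RD <- (l2 + l3) / 2
  num <- sqrt((l1 - MD)^2 + (l2 - MD)^2 + (l3 - MD)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  FA <- sqrt(3 / 2) * ifelse(den > 0, num / den, 0)
  FA[!is.na(FA)] <- pmin(pmax(FA[!is.na(FA)], 0), 1)
  structure(list(FA = FA, MD = MD, RD = RD, voxdim = fit$voxdim),
            class = "tensor_maps")
}
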