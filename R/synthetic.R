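.PROTOCOLS <- list(
  adni3 = list(bvalues = c(500, 1000, 2000), counts = c(6, 48, 60),
               n_b0 = 13,
               metadata = list(delta_ms = 13.6, Delta_ms = 35,
                               TR_ms = 3300, TE_ms = 71,
                               voxel_mm = c(2, 2, 2))),
  sherbrooke = list(bvalues = c(300, 1000, 2000), counts = c(8, 32, 60),
                    n_b0 = 7,
                    metadata = list(delta_ms = 21.9, Delta_ms = 46.5,
                                    TR_ms = 4800, TE_ms = 92,
                                    voxel_mm = c(2, 2, 2))),
  basel = list(bvalues = c(700, 1000, 2000, 3000),
               counts = c(6, 20, 45, 66), n_b0 = 12,
               metadata = list(delta_ms = 19, Delta_ms = 36,
                               TR_ms = 4500, TE_ms = 75,
                               voxel_mm = c(1.8, 1.8, 1.8)))
)

#' Named acquisition protocols
#'
#' Shell structure of the three reference sequences the study conditions
#' emulate: `adni3` (6/48/60 directions at b = 500/1000/2000 s/mm^2 plus
#' 13 b0), `sherbrooke` (8/32/60 at 300/1000/2000, 7 b0) and `basel`
#' (6/20/45/66 at 700/1000/2000/3000, 12 b0). Timing and voxel-size
#' descriptors are carried as metadata only.
#'
#' @param name one of `"adni3"`, `"sherbrooke"`, `"basel"`.
#' @return list with `bvalues`, `counts`, `n_b0`, `metadata`.
#' @export
protocol_spec <- function(name) {
  if (!name %in% names(.PROTOCOLS)) stop("unknown protocol: ", name)
  .PROTOCOLS[[name]]
}

# run code with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

.random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Generate a multi-shell gradient scheme
#'
#' Directions start from a seeded random placement and are refined by
#' projected gradient descent on the combined per-shell/global repulsion
#' energy (the same energy used by [subsample_scheme()]), with
#' backtracking step control. Named protocols reproduce the reference
#' shell counts exactly.
#'
#' @param protocol protocol name, or a list with `bvalues`, `counts`,
#'   `n_b0` (and optionally `metadata`).
#' @param seed integer seed; the same seed yields an identical scheme.
#' @param alpha energy weight, see [energy_config()].
#' @param n_iter maximum descent iterations.
#' @return A `multishell_scheme`.
#' @export
make_scheme <- function(protocol, seed = 1, alpha = 0.5, n_iter = 200) {
  if (is.character(protocol)) protocol <- protocol_spec(protocol)
  counts <- protocol$counts
  stopifnot(length(counts) == length(protocol$bvalues), all(counts >= 1))
  sid <- rep(seq_along(counts), counts)
  N <- sum(counts)
  D <- .with_seed(seed, .random_unit_vectors(N))
  same <- outer(sid, sid, "==")
  W <- alpha * same + (1 - alpha)
  diag(W) <- 0
  energy <- function(D) {
    E <- .pair_energy_matrix(D)
    E[!is.finite(E)] <- 1e30
    sum(W * E) / 2
  }
  grad <- function(D) {
    C <- pmin(pmax(tcrossprod(D), -1), 1)
    dm <- pmax(2 - 2 * C, 1e-12); dp <- pmax(2 + 2 * C, 1e-12)
    M <- W * (dm^-1.5 - dp^-1.5)
    diag(M) <- 0
    G <- M %*% D
    G - D * rowSums(G * D)   # project onto sphere tangent
  }
  V <- energy(D); step <- 0.01
  for (it in seq_len(n_iter)) {
    G <- grad(D)
    Dn <- D - step * G
    Dn <- Dn / sqrt(rowSums(Dn^2))
    Vn <- energy(Dn)
    if (Vn < V) {
      D <- Dn; V <- Vn; step <- step * 1.2
    } else {
      step <- step / 2
      if (step < 1e-10) break
    }
  }
  shells <- lapply(seq_along(counts), function(s)
    list(bvalue = protocol$bvalues[s],
         directions = D[sid == s, , drop = FALSE]))
  multishell_scheme(shells, n_b0 = protocol$n_b0,
                    metadata = if (is.null(protocol$metadata)) list()
                               else protocol$metadata)
}

#' Add Rician noise to a signal array
#'
#' Magnitude-MRI noise: `sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ Normal(0, sigma)`. For pure-noise voxels the expected
#' magnitude is `sigma * sqrt(pi/2)` (the Rician floor).
#'
#' @param S numeric array of noise-free signals.
#' @param sigma noise SD (same units as S); 0 or `Inf` SNR leaves S
#'   untouched.
#' @param seed integer seed.
#' @return Array of noisy magnitudes, same shape as `S`.
#' @export
rician_noise <- function(S, sigma, seed = 1) {
  if (sigma <= 0) return(S)
  .with_seed(seed, {
    n1 <- stats::rnorm(length(S), 0, sigma)
    n2 <- stats::rnorm(length(S), 0, sigma)
    array(sqrt((S + n1)^2 + n2^2), dim(S))
  })
}

#' Tube specification for the synthetic phantom
#'
#' @param name bundle name.
#' @param control n x 3 matrix of centerline control points (mm).
#' @param radius tube radius (mm).
#' @param v_ic,v_iso,kappa NODDI parameters inside the tube.
#' @param side `"left"`, `"right"` or `"unpaired"`.
#' @return A `tube_spec` list.
#' @export
tube_spec <- function(name, control, radius, v_ic, v_iso, kappa,
                      side = "unpaired") {
  structure(list(name = name, control = control, radius = radius,
                 v_ic = v_ic, v_iso = v_iso, kappa = kappa, side = side),
            class = "tube_spec")
}

.default_tubes <- function() {
  arc_t <- seq(pi, 0, length.out = 9)
  list(
    tube_spec("cst_left", cbind(6, 11, seq(2, 20, length.out = 7)),
              radius = 3, v_ic = 0.70, v_iso = 0.02, kappa = 4,
              side = "left"),
    tube_spec("cst_right", cbind(16, 11, seq(2, 20, length.out = 7)),
              radius = 3, v_ic = 0.70, v_iso = 0.02, kappa = 4,
              side = "right"),
    tube_spec("arc", cbind(11 + 7 * cos(arc_t), 6, 8 + 7 * sin(arc_t)),
              radius = 2.5, v_ic = 0.60, v_iso = 0.05, kappa = 3)
  )
}

#' Phantom study specification
#'
#' Defines the synthetic multi-shell phantom: an acquisition protocol, a
#' small voxel grid carrying a few tube-shaped "bundles" with known NODDI
#' parameters over a more dispersed background, Rician noise at a given
#' b0 SNR, and a multi-subject / multi-session sampling structure
#' (subjects differ by a small parameter jitter, sessions only by the
#' noise draw).
#'
#' @param protocol protocol name or explicit spec (see [make_scheme()]).
#' @param grid_dim voxel grid dimensions (default 12 x 12 x 12).
#' @param voxdim voxel size in mm (default 2 mm isotropic).
#' @param tubes list of [tube_spec()]s; defaults to two straight
#'   "cst"-like tubes (left/right pair) and one curved unpaired arc.
#' @param background NODDI parameter list for non-tube voxels.
#' @param snr b0 signal-to-noise ratio S0/sigma (`Inf` for noise-free).
#' @param S0 b0 signal level (arbitrary units).
#' @param n_subjects,n_sessions replication structure.
#' @param jitter_sd SD of the per-subject jitter on the volume fractions.
#' @param n_streamlines streamlines generated per tube.
#' @param seed master seed; every output is a deterministic function of
#'   the spec and this seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(protocol = "basel", grid_dim = c(12, 12, 12),
                         voxdim = c(2, 2, 2), tubes = .default_tubes(),
                         background = list(v_ic = 0.30, v_iso = 0.10,
                                           kappa = 0.5),
                         snr = 20, S0 = 1000, n_subjects = 1,
                         n_sessions = 1, jitter_sd = 0.02,
                         n_streamlines = 10, seed = 1) {
  structure(list(protocol = protocol, grid_dim = grid_dim,
                 voxdim = voxdim, tubes = tubes, background = background,
                 snr = snr, S0 = S0, n_subjects = n_subjects,
                 n_sessions = n_sessions, jitter_sd = jitter_sd,
                 n_streamlines = n_streamlines, seed = seed),
            class = "phantom_spec")
}

# dilate a logical mask by one 6-connected step, n times
.dilate_mask <- function(mask, n = 1) {
  d <- dim(mask)
  for (k in seq_len(n)) {
    out <- mask
    out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
    out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
    out[, , -1] <- out[, , -1] | mask[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
    mask <- out
  }
  mask
}

# dense centerline + unit tangents for a tube
.tube_centerline <- function(tube, n = 60) {
  cl <- resample_streamline(tube$control, n)
  tg <- rbind(cl[2, ] - cl[1, ], cl[-1, , drop = FALSE] -
                cl[-n, , drop = FALSE])
  tg / sqrt(rowSums(tg^2))
}

#' Generate a synthetic multi-shell phantom
#'
#' Builds ground-truth NODDI parameter maps on a voxel grid (tube
#' parameters inside each tube with per-subject jitter on the volume
#' fractions, background parameters elsewhere; fibre orientation follows
#' the local tube tangent), simulates the diffusion signal with
#' [noddi_signal()], and adds Rician noise at the requested SNR. Sessions
#' of a subject share the noise-free signal and differ only in the noise
#' draw. Streamlines are jittered copies of each tube's centerline,
#' clipped to the tube. Overlapping tubes resolve by first-listed
#' precedence.
#'
#' @param spec a [phantom_spec()].
#' @param quad quadrature grid for the forward model.
#' @return list with `scheme`, `truth` (list per subject: `maps` with
#'   v_ic/v_iso/kappa/OD arrays, `mu` 4-D array), `bundles` (list of
#'   [bundle()]s with masks and streamlines), `mask` (analysis mask:
#'   tubes dilated by 2 voxels), and `data[[subject]][[session]]`
#'   (`dwi_dataset`s).
#' @export
make_phantom <- function(spec = phantom_spec(),
                         quad = watson_quadrature()) {
  stopifnot(inherits(spec, "phantom_spec"))
  scheme <- make_scheme(spec$protocol, seed = spec$seed %% 100000 + 7)
  d <- spec$grid_dim
  nvox <- prod(d)
  centers <- cbind(
    (rep(seq_len(d[1]), times = d[2] * d[3]) - 1) * spec$voxdim[1],
    (rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - 1) *
      spec$voxdim[2],
    (rep(seq_len(d[3]), each = d[1] * d[2]) - 1) * spec$voxdim[3])

  tube_id <- integer(nvox)           # 0 = background
  mu_all <- matrix(rep(c(0, 0, 1), each = nvox), nvox, 3)
  for (ti in seq_along(spec$tubes)) {
    tb <- spec$tubes[[ti]]
    pts <- resample_streamline(tb$control, 60)
    tgs <- .tube_centerline(tb)
    d2 <- outer(rowSums(centers^2), rowSums(pts^2), "+") -
      2 * tcrossprod(centers, pts)
    nearest <- max.col(-d2, ties.method = "first")
    dist <- sqrt(pmax(d2[cbind(seq_len(nvox), nearest)], 0))
    inside <- dist <= tb$radius & tube_id == 0L
    tube_id[inside] <- ti
    mu_all[inside, ] <- tgs[nearest[inside], , drop = FALSE]
  }

  tube_mask <- array(tube_id > 0, d)
  mask <- .dilate_mask(tube_mask, 2)

  # per-tube masks and streamlines (geometry shared by all subjects)
  bundles <- list()
  for (ti in seq_along(spec$tubes)) {
    tb <- spec$tubes[[ti]]
    pts <- resample_streamline(tb$control, 60)
    sl <- .with_seed(spec$seed * 13 + ti, {
      lapply(seq_len(spec$n_streamlines), function(k) {
        o <- stats::rnorm(3); o <- o / sqrt(sum(o^2)) *
          stats::runif(1, 0, 0.6 * tb$radius)
        p <- sweep(pts, 2, o, "+") +
          matrix(stats::rnorm(length(pts), 0, 0.2), nrow(pts), 3)
        # clip back inside the tube
        d2 <- outer(rowSums(p^2), rowSums(pts^2), "+") -
          2 * tcrossprod(p, pts)
        nn <- max.col(-d2, ties.method = "first")
        dd <- sqrt(pmax(d2[cbind(seq_len(nrow(p)), nn)], 0))
        out <- dd > tb$radius
        if (any(out)) {
          ctr <- pts[nn[out], , drop = FALSE]
          p[out, ] <- ctr + (p[out, , drop = FALSE] - ctr) *
            (0.95 * tb$radius / dd[out])
        }
        p
      })
    })
    bundles[[tb$name]] <- bundle(tb$name, sl, array(tube_id == ti, d),
                                 side = tb$side, voxdim = spec$voxdim)
  }

  sigma <- if (is.finite(spec$snr)) spec$S0 / spec$snr else 0
  truth <- vector("list", spec$n_subjects)
  data <- vector("list", spec$n_subjects)
  for (sj in seq_len(spec$n_subjects)) {
    # per-subject parameter jitter, one draw per region
    regions <- c(list(spec$background),
                 lapply(spec$tubes, function(t)
                   list(v_ic = t$v_ic, v_iso = t$v_iso, kappa = t$kappa)))
    jit <- .with_seed(spec$seed * 101 + sj, {
      lapply(regions, function(r) {
        list(v_ic = min(max(r$v_ic + stats::rnorm(1, 0, spec$jitter_sd),
                            0.01), 0.99),
             v_iso = min(max(r$v_iso + stats::rnorm(1, 0, spec$jitter_sd),
                             0), 0.99),
             kappa = r$kappa)
      })
    })
    vic <- visof <- kap <- numeric(nvox)
    for (ri in seq_along(regions)) {
      sel <- tube_id == (ri - 1L)
      vic[sel] <- jit[[ri]]$v_ic
      visof[sel] <- jit[[ri]]$v_iso
      kap[sel] <- jit[[ri]]$kappa
    }
    # noise-free signal, cached over identical (params, mu) combinations
    Svol <- matrix(0, nvox, n_volumes(scheme))
    keys <- paste(tube_id, round(mu_all[, 1], 3), round(mu_all[, 2], 3),
                  round(mu_all[, 3], 3))
    in_mask <- which(mask)
    for (key in unique(keys[in_mask])) {
      idx <- in_mask[keys[in_mask] == key]
      i1 <- idx[1]
      p <- noddi_params(vic[i1], visof[i1], kap[i1], mu = mu_all[i1, ])
      E <- noddi_signal(scheme, p, quad)
      Svol[idx, ] <- matrix(spec$S0 * E, length(idx), length(E),
                            byrow = TRUE)
    }
    truth[[sj]] <- list(
      maps = list(v_ic = array(vic, d), v_iso = array(visof, d),
                  kappa = array(kap, d),
                  OD = array(od_from_kappa(kap), d)),
      mu = array(mu_all, c(nvox, 3)))
    data[[sj]] <- lapply(seq_len(spec$n_sessions), function(ss) {
      noisy <- rician_noise(array(Svol, c(d, n_volumes(scheme))), sigma,
                            seed = (spec$seed * 7919 + sj * 131 + ss) %%
                              .Machine$integer.max)
      dwi_dataset(noisy, scheme, mask, spec$voxdim)
    })
  }

  list(scheme = scheme, truth = truth, bundles = bundles, mask = mask,
       data = data, spec = spec)
}

#' Simulate single voxels from known NODDI parameters
#'
#' Convenience generator for parameter-recovery experiments: arranges `n`
#' voxels with seeded random NODDI parameters (or a supplied list) on an
#' n x 1 x 1 grid and simulates their signal at the given SNR.
#'
#' @param scheme a `multishell_scheme`.
#' @param n number of voxels.
#' @param snr b0 SNR (`Inf` = noise-free).
#' @param seed integer seed.
#' @param params optional list of [noddi_params()] (length `n`).
#' @param S0 b0 signal level.
#' @param quad quadrature grid.
#' @return list with `data` (a `dwi_dataset`) and `params`.
#' @export
simulate_voxels <- function(scheme, n = 500, snr = Inf, seed = 1,
                            params = NULL, S0 = 1000,
                            quad = watson_quadrature()) {
  if (is.null(params)) {
    params <- .with_seed(seed, {
      lapply(seq_len(n), function(i) {
        mu <- stats::rnorm(3); mu <- mu / sqrt(sum(mu^2))
        noddi_params(stats::runif(1, 0.2, 0.9),
                     stats::runif(1, 0, 0.3),
                     exp(stats::runif(1, log(0.5), log(16))), mu = mu)
      })
    })
  }
  n <- length(params)
  S <- t(vapply(params, function(p) S0 * noddi_signal(scheme, p, quad),
                numeric(n_volumes(scheme))))
  sigma <- if (is.finite(snr)) S0 / snr else 0
  arr <- rician_noise(array(S, c(n, 1, 1, ncol(S))), sigma,
                      seed = seed + 17)
  list(data = dwi_dataset(arr, scheme, array(TRUE, c(n, 1, 1)),
                          voxdim = c(2, 2, 2)),
       params = params)
}
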