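#' Antipodally symmetric electrostatic pair energy
#'
#' The repulsion kernel between two gradient directions treats each
#' direction and its antipode as the same physical measurement:
#' `1/|u - v| + 1/|u + v|`. Coincident or antipodal pairs have infinite
#' energy, so such subsets are never selected when alternatives exist.
#'
#' @param u,v unit 3-vectors.
#' @return Dimensionless energy; `Inf` for coincident/antipodal pairs.
#' @export
pair_energy <- function(u, v) {
  dm <- sqrt(sum((u - v)^2)); dp <- sqrt(sum((u + v)^2))
  if (dm < 1e-12 || dp < 1e-12) return(Inf)
  1 / dm + 1 / dp
}

# Pairwise energy matrix for unit row-vector matrix D (diag = 0).
.pair_energy_matrix <- function(D) {
  C <- tcrossprod(D)
  C <- pmin(pmax(C, -1), 1)
  dm2 <- 2 - 2 * C; dp2 <- 2 + 2 * C
  E <- ifelse(dm2 < 1e-20, Inf, 1 / sqrt(dm2)) +
       ifelse(dp2 < 1e-20, Inf, 1 / sqrt(dp2))
  diag(E) <- 0
  E
}

#' Energy configuration for scheme subsampling
#'
#' `alpha` weighs per-shell angular coverage (V1, the sum of pair energies
#' within each shell) against whole-set coverage (V2, the sum over all
#' pairs of directions projected onto a single unit sphere):
#' `V = alpha * V1 + (1 - alpha) * V2`.
#'
#' @param alpha weight in `[0, 1]`; default 0.5 balances the two terms.
#' @return An `energy_config` list.
#' @export
energy_config <- function(alpha = 0.5) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha), class = "energy_config")
}

# Pair weight matrix combining per-shell (V1) and global (V2) terms:
# w_ij = alpha * [same shell] + (1 - alpha). V = sum_{i<j} w_ij E_ij.
.weighted_energy_matrix <- function(D, shell_id, alpha) {
  E <- .pair_energy_matrix(D)
  same <- outer(shell_id, shell_id, "==")
  W <- alpha * same + (1 - alpha)
  WE <- W * E
  diag(WE) <- 0
  # large finite penalty instead of Inf keeps the selection arithmetic
  # NaN-free while still making coincident/antipodal pairs never selected
  WE[!is.finite(WE)] <- 1e30
  WE
}

#' Combined per-shell and global repulsion energy of a scheme
#'
#' Computes `V = alpha * V1 + (1 - alpha) * V2` where V1 sums the pair
#' energy over all unordered pairs within each shell and V2 sums it over
#' all unordered pairs of the full direction set projected onto one unit
#' sphere. Unordered pairs are counted once; no normalization by pair
#' count is applied (it cancels in any argmin over equal-count subsets).
#'
#' @param scheme a `multishell_scheme` (b0 volumes are ignored).
#' @param cfg an [energy_config()].
#' @return A list with `V`, `V1`, `V2`.
#' @export
scheme_energy <- function(scheme, cfg = energy_config()) {
  stopifnot(inherits(scheme, "multishell_scheme"))
  D <- do.call(rbind, lapply(scheme$shells, function(s) s$directions))
  if (is.null(D) || nrow(D) < 2) stop("scheme has fewer than 2 directions")
  sid <- rep(seq_along(scheme$shells), shell_counts(scheme))
  E <- .pair_energy_matrix(D)
  same <- outer(sid, sid, "==")
  up <- upper.tri(E)
  V1 <- sum(E[up & same])
  V2 <- sum(E[up])
  list(V = cfg$alpha * V1 + (1 - cfg$alpha) * V2, V1 = V1, V2 = V2)
}

#' Per-shell retained direction counts for a down-sampling rate
#'
#' Each reference count `c` maps to `round_half_up(c * (1 - rate))`,
#' floored at 1. Half values round up: 40.5 -> 41, 22.5 -> 23. This rule
#' reproduces the retained-direction triples of all three study protocols
#' at 10/30/50% down-sampling.
#'
#' @param reference_counts integer vector of per-shell direction counts.
#' @param rate fraction of directions to remove, in `[0, 1)`.
#' @return Integer vector of retained counts, same length and names.
#' @export
target_counts <- function(reference_counts, rate) {
  stopifnot(all(reference_counts >= 1))
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1)
    stop("rate must be a single value in [0, 1)")
  # round half up; the epsilon guards against binary representation of
  # the rate pushing an exact half (e.g. 45 * 0.7 = 31.5) just below it
  kept <- floor(reference_counts * (1 - rate) + 0.5 + 1e-9)
  as.integer(pmax(kept, 1))
}

#' Subsampling plan
#'
#' @param rate fraction of directions removed, in `[0, 1)`.
#' @param target_counts optional explicit per-shell retained counts;
#'   computed from `rate` via [target_counts()] when a scheme is supplied
#'   to [subsample_scheme()].
#' @return A `subsample_plan` list.
#' @export
subsample_plan <- function(rate, target_counts = NULL) {
  stopifnot(rate >= 0, rate < 1)
  structure(list(rate = rate, target_counts = target_counts),
            class = "subsample_plan")
}

#' Electrostatic-repulsion subset selection of gradient directions
#'
#' Retains exactly the planned number of directions per shell, chosen as a
#' deterministic local minimizer of [scheme_energy()]: greedy backward
#' elimination (repeatedly drop the direction whose removal lowers V the
#' most, respecting per-shell quotas) followed by pairwise swap refinement
#' (replace a retained direction by a removed one from the same shell
#' whenever that lowers V) until no improving swap exists. Ties are broken
#' by lowest original index, so identical inputs give identical outputs.
#' b0 volumes are never removed.
#'
#' @param scheme a `multishell_scheme`.
#' @param plan a [subsample_plan()]; if `plan$target_counts` is `NULL` it
#'   is computed from `plan$rate` via [target_counts()].
#' @param cfg an [energy_config()].
#' @return A `multishell_scheme` whose directions are a subset of the
#'   input's, with attributes `retained_volumes` (canonical volume indices
#'   into the input scheme, b0 included), `energy_before` and
#'   `energy_after` (lists with V, V1, V2).
#' @export
subsample_scheme <- function(scheme, plan, cfg = energy_config()) {
  stopifnot(inherits(scheme, "multishell_scheme"),
            inherits(plan, "subsample_plan"))
  ref <- shell_counts(scheme)
  quota <- plan$target_counts
  if (is.null(quota)) quota <- target_counts(ref, plan$rate)
  if (length(quota) != length(ref))
    stop("target_counts length does not match number of shells")
  if (any(quota > ref))
    stop("a target count exceeds its shell's size")
  if (any(quota < 1)) stop("target counts must be >= 1")

  D <- do.call(rbind, lapply(scheme$shells, function(s) s$directions))
  sid <- rep(seq_along(scheme$shells), ref)
  N <- nrow(D)
  keep <- rep(TRUE, N)
  if (all(quota == ref)) {
    out <- scheme
    attr(out, "retained_volumes") <- seq_len(n_volumes(scheme))
    e <- scheme_energy(scheme, cfg)
    attr(out, "energy_before") <- e
    attr(out, "energy_after") <- e
    return(out)
  }

  WE <- .weighted_energy_matrix(D, sid, cfg$alpha)
  # contribution of i to V given the retained set (V = sum(contrib)/2)
  contrib <- rowSums(WE)

  counts <- ref
  while (any(counts > quota)) {
    cand <- which(keep & (counts[sid] > quota[sid]))
    # removing the largest contributor yields the lowest remaining V
    best <- cand[which.max(contrib[cand])]
    keep[best] <- FALSE
    counts[sid[best]] <- counts[sid[best]] - 1L
    contrib <- contrib - WE[, best]
    contrib[best] <- 0
  }
  # swap refinement to a 1-exchange-stable state, then a deterministic
  # one-move lookahead: provisionally apply each of the least-worsening
  # swaps and re-refine, keeping the result when it beats the incumbent
  # (this follows 2-exchange escape paths out of shallow local minima)
  keep <- .swap_refine(keep, WE, sid)
  keep <- .swap_lookahead(keep, WE, sid, k_try = 10L)

  shells <- lapply(seq_along(scheme$shells), function(s) {
    list(bvalue = scheme$shells[[s]]$bvalue,
         directions = D[keep & sid == s, , drop = FALSE])
  })
  out <- multishell_scheme(shells, n_b0 = scheme$n_b0,
                           metadata = scheme$metadata)
  attr(out, "retained_volumes") <-
    c(seq_len(scheme$n_b0), scheme$n_b0 + which(keep))
  attr(out, "energy_before") <- scheme_energy(scheme, cfg)
  attr(out, "energy_after") <- scheme_energy(out, cfg)
  out
}

# Run best-improvement single swaps (retained <-> removed, same shell)
# until 1-exchange stable. Ties broken by lowest (removed, retained) index.
.swap_refine <- function(keep, WE, sid) {
  contrib <- as.vector(WE %*% keep)
  repeat {
    best_dv <- -1e-12; best_r <- 0L; best_m <- 0L
    for (s in unique(sid)) {
      rs <- which(keep & sid == s); ms <- which(!keep & sid == s)
      if (!length(ms)) next
      for (r in rs) {
        dv <- (contrib[ms] - WE[ms, r]) - contrib[r]
        dv[!is.finite(dv)] <- Inf
        j <- which.min(dv)
        if (dv[j] < best_dv) {
          best_dv <- dv[j]; best_r <- r; best_m <- ms[j]
        }
      }
    }
    if (best_r == 0L) break
    keep[best_r] <- FALSE; keep[best_m] <- TRUE
    contrib <- contrib + WE[, best_m] - WE[, best_r]
  }
  keep
}

.subset_V <- function(keep, WE) sum(WE[keep, keep]) / 2

.swap_lookahead <- function(keep, WE, sid, k_try = 10L) {
  repeat {
    V0 <- .subset_V(keep, WE)
    contrib <- as.vector(WE %*% keep)
    # enumerate all single swaps with their immediate V change
    cand <- NULL
    for (s in unique(sid)) {
      rs <- which(keep & sid == s); ms <- which(!keep & sid == s)
      if (!length(ms)) next
      for (r in rs) {
        dv <- (contrib[ms] - WE[ms, r]) - contrib[r]
        cand <- rbind(cand, cbind(r = r, m = ms, dv = dv))
      }
    }
    if (is.null(cand)) return(keep)
    cand <- cand[is.finite(cand[, "dv"]), , drop = FALSE]
    cand <- cand[order(cand[, "dv"], cand[, "r"], cand[, "m"]),
                 , drop = FALSE]
    improved <- FALSE
    for (i in seq_len(min(k_try, nrow(cand)))) {
      k2 <- keep
      k2[cand[i, "r"]] <- FALSE; k2[cand[i, "m"]] <- TRUE
      k2 <- .swap_refine(k2, WE, sid)
      if (.subset_V(k2, WE) < V0 - 1e-12) {
        keep <- k2; improved <- TRUE; break
      }
    }
    if (!improved) return(keep)
  }
}

#' Exhaustive minimum-energy subset (oracle for small schemes)
#'
#' Enumerates every per-shell combination meeting the quotas and returns
#' the global minimizer of [scheme_energy()]. Exponential cost; intended
#' for validation on schemes with few directions.
#'
#' @param scheme a `multishell_scheme`.
#' @param quota integer vector of retained counts per shell.
#' @param cfg an [energy_config()].
#' @return list with `V` (minimum energy) and `keep` (logical vector over
#'   the scheme's directions in canonical order).
#' @export
exhaustive_min_subset <- function(scheme, quota, cfg = energy_config()) {
  ref <- shell_counts(scheme)
  stopifnot(length(quota) == length(ref), all(quota >= 1), all(quota <= ref))
  D <- do.call(rbind, lapply(scheme$shells, function(s) s$directions))
  sid <- rep(seq_along(ref), ref)
  WE <- .weighted_energy_matrix(D, sid, cfg$alpha)
  per_shell <- lapply(seq_along(ref), function(s)
    utils::combn(which(sid == s), quota[s], simplify = FALSE))
  bestV <- Inf; bestK <- NULL
  grid <- expand.grid(lapply(per_shell, seq_along))
  for (g in seq_len(nrow(grid))) {
    idx <- unlist(lapply(seq_along(per_shell),
                         function(s) per_shell[[s]][[grid[g, s]]]))
    V <- sum(WE[idx, idx]) / 2
    if (V < bestV) { bestV <- V; bestK <- idx }
  }
  keep <- rep(FALSE, nrow(D)); keep[bestK] <- TRUE
  list(V = bestV, keep = keep)
}

#' Down-sample a gradient scheme on disk
#'
#' Thin file-level wrapper: reads a scheme, subsamples it at `rate`, writes
#' the reduced scheme with [write_scheme()] and a JSON sidecar holding the
#' energies before/after and the retained canonical volume indices (for
#' slicing the matching 4-D volume).
#'
#' @param path_bval,path_bvec input FSL gradient files.
#' @param rate fraction of directions to remove.
#' @param alpha energy weight, see [energy_config()].
#' @param out_prefix output path prefix.
#' @param dialect output dialect, `"fsl"` or `"mrtrix"`.
#' @return Invisibly, the subsampled scheme.
#' @export
downsample_files <- function(path_bval, path_bvec, rate, alpha = 0.5,
                             out_prefix, dialect = "fsl") {
  scheme <- read_scheme(path_bval, path_bvec)
  out <- subsample_scheme(scheme, subsample_plan(rate),
                          energy_config(alpha))
  write_scheme(out, out_prefix, dialect)
  side <- list(
    rate = rate, alpha = alpha,
    reference_counts = as.integer(shell_counts(scheme)),
    retained_counts = as.integer(shell_counts(out)),
    bvalues = shell_bvalues(scheme),
    energy_before = attr(out, "energy_before"),
    energy_after = attr(out, "energy_after"),
    retained_volumes = as.integer(attr(out, "retained_volumes")))
  jsonlite::write_json(side, paste0(out_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
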