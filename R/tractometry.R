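#' Bundle of streamlines with its voxel mask
#'
#' @param name bundle name.
#' @param streamlines list of n x 3 matrices of ordered 3-D points (mm).
#' @param mask 3-D logical array (bundle segmentation).
#' @param side `"left"`, `"right"` or `"unpaired"`.
#' @param voxdim voxel size in mm.
#' @param origin world coordinate (mm) of the center of voxel (1,1,1).
#' @return A `bundle` list.
#' @export
bundle <- function(name, streamlines, mask, side = "unpaired",
                   voxdim = c(2, 2, 2), origin = c(0, 0, 0)) {
  stopifnot(is.list(streamlines), length(streamlines) >= 1)
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2 || !all(is.finite(s)))
      stop("each streamline must be a finite n x 3 matrix with >= 2 points")
  }
  if (!any(mask)) stop("bundle mask is empty")
  side <- match.arg(side, c("left", "right", "unpaired"))
  structure(list(name = name, streamlines = streamlines,
                 mask = array(as.logical(mask), dim(mask)), side = side,
                 voxdim = voxdim, origin = origin),
            class = "bundle")
}

#' Resample a streamline to equally spaced points
#'
#' Returns `n` points equally spaced in arc length along the polyline;
#' the endpoints are preserved. Along-tract profiling uses `n = 98`
#' segments per side.
#'
#' @param s an m x 3 matrix of ordered points.
#' @param n number of output points (>= 2), default 98.
#' @return An n x 3 matrix.
#' @export
resample_streamline <- function(s, n = 98) {
  stopifnot(is.matrix(s), ncol(s) == 3, nrow(s) >= 2, n >= 2)
  seg <- sqrt(rowSums(diff(s)^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  if (L <= 0) stop("zero-length streamline")
  tgt <- seq(0, L, length.out = n)
  cbind(stats::approx(cs, s[, 1], xout = tgt, ties = "ordered")$y,
        stats::approx(cs, s[, 2], xout = tgt, ties = "ordered")$y,
        stats::approx(cs, s[, 3], xout = tgt, ties = "ordered")$y)
}

# Resample all streamlines to n points and flip-align them to a canonical
# anchor: the streamline whose start point is lexicographically smallest
# (after orienting each individual streamline so its own start <= end
# lexicographically is NOT done -- instead each streamline is reversed
# when that lowers its summed pointwise distance to the anchor). Using a
# lexicographic anchor rather than list order makes the result invariant
# to streamline permutation.
.aligned_streamlines <- function(streamlines, n = 98) {
  rs <- lapply(streamlines, resample_streamline, n = n)
  starts <- t(vapply(rs, function(m) m[1, ], numeric(3)))
  ends <- t(vapply(rs, function(m) m[n, ], numeric(3)))
  key <- function(p) do.call(order, as.data.frame(p))[1]
  # candidate anchor endpoints: lexicographically smallest endpoint of
  # each streamline, then the smallest across streamlines
  lex_lt <- function(a, b) {
    for (k in 1:3) {
      if (a[k] < b[k]) return(TRUE)
      if (a[k] > b[k]) return(FALSE)
    }
    FALSE
  }
  ep <- t(vapply(seq_along(rs), function(i) {
    if (lex_lt(ends[i, ], starts[i, ])) ends[i, ] else starts[i, ]
  }, numeric(3)))
  a <- key(ep)
  anchor <- rs[[a]]
  if (lex_lt(ends[a, ], starts[a, ])) anchor <- anchor[n:1, ]
  lapply(rs, function(m) {
    d_fwd <- sum(sqrt(rowSums((m - anchor)^2)))
    d_rev <- sum(sqrt(rowSums((m[n:1, ] - anchor)^2)))
    if (d_rev < d_fwd) m[n:1, ] else m
  })
}

#' Bundle centroid streamline
#'
#' All streamlines are resampled to `n` points, flip-aligned to a
#' canonical anchor (reversing a streamline when that lowers its summed
#' pointwise distance), and averaged pointwise.
#'
#' @param b a `bundle`.
#' @param n points per streamline, default 98.
#' @return An n x 3 matrix.
#' @export
bundle_centroid <- function(b, n = 98) {
  stopifnot(inherits(b, "bundle"))
  al <- .aligned_streamlines(b$streamlines, n)
  Reduce(`+`, al) / length(al)
}

# Trilinear interpolation of a 3-D array at world points (mm). Voxel
# centers sit at origin + (index - 1) * voxdim. Points are clamped to the
# grid; NA map values propagate.
.trilinear <- function(map, pts, voxdim, origin = c(0, 0, 0)) {
  dims <- dim(map)
  ix <- (pts[, 1] - origin[1]) / voxdim[1]
  iy <- (pts[, 2] - origin[2]) / voxdim[2]
  iz <- (pts[, 3] - origin[3]) / voxdim[3]
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  ix <- cl(ix, dims[1]); iy <- cl(iy, dims[2]); iz <- cl(iz, dims[3])
  x0 <- pmin(floor(ix), dims[1] - 2); y0 <- pmin(floor(iy), dims[2] - 2)
  z0 <- pmin(floor(iz), dims[3] - 2)
  if (dims[1] < 2) x0 <- ix * 0
  if (dims[2] < 2) y0 <- iy * 0
  if (dims[3] < 2) z0 <- iz * 0
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  g <- function(dx, dy, dz)
    map[cbind(pmin(x0 + dx, dims[1] - 1) + 1,
              pmin(y0 + dy, dims[2] - 1) + 1,
              pmin(z0 + dz, dims[3] - 1) + 1)]
  g(0,0,0) * (1-fx)*(1-fy)*(1-fz) + g(1,0,0) * fx*(1-fy)*(1-fz) +
  g(0,1,0) * (1-fx)*fy*(1-fz)     + g(0,0,1) * (1-fx)*(1-fy)*fz +
  g(1,1,0) * fx*fy*(1-fz)         + g(1,0,1) * fx*(1-fy)*fz +
  g(0,1,1) * (1-fx)*fy*fz         + g(1,1,1) * fx*fy*fz
}

#' Sample a 3-D map at world coordinates
#'
#' @param map 3-D numeric array.
#' @param pts n x 3 matrix of world points (mm).
#' @param voxdim voxel size (mm); voxel centers at
#'   `origin + (index - 1) * voxdim`.
#' @param origin world position of voxel (1,1,1).
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return Numeric vector of sampled values.
#' @export
sample_map <- function(map, pts, voxdim, origin = c(0, 0, 0),
                       method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (method == "trilinear")
    return(.trilinear(map, pts, voxdim, origin))
  dims <- dim(map)
  idx <- sapply(1:3, function(k)
    pmin(pmax(round((pts[, k] - origin[k]) / voxdim[k]) + 1, 1), dims[k]))
  map[matrix(idx, ncol = 3)]
}

#' Along-tract profile of a metric over a bundle
#'
#' Streamlines are resampled to `n` points and flip-aligned; each point of
#' each streamline is assigned to the nearest centroid point (Euclidean);
#' the metric map is sampled at each streamline point (trilinear by
#' default) and averaged per centroid segment. Segments with no assigned
#' points yield `NA`.
#'
#' @param b a `bundle`.
#' @param metric_map 3-D numeric array covering the bundle extent.
#' @param n segments per side, default 98.
#' @param method interpolation method, see [sample_map()].
#' @return A `bundle_profile`: list with `bundle`, `side`, and `values`
#'   (length `n`).
#' @export
profile_bundle <- function(b, metric_map, n = 98,
                           method = c("trilinear", "nearest")) {
  stopifnot(inherits(b, "bundle"))
  method <- match.arg(method)
  al <- .aligned_streamlines(b$streamlines, n)
  centroid <- Reduce(`+`, al) / length(al)
  vals <- rep(0, n); cnt <- rep(0L, n)
  for (m in al) {
    d2 <- outer(rowSums(m^2), rowSums(centroid^2), "+") -
      2 * tcrossprod(m, centroid)
    assign <- max.col(-d2, ties.method = "first")
    sm <- sample_map(metric_map, m, b$voxdim, b$origin, method)
    if (anyNA(sm))
      stop("bundle '", b$name, "' extends outside the metric map")
    for (k in seq_len(n)) {
      vals[assign[k]] <- vals[assign[k]] + sm[k]
      cnt[assign[k]] <- cnt[assign[k]] + 1L
    }
  }
  out <- ifelse(cnt > 0, vals / pmax(cnt, 1), NA_real_)
  structure(list(bundle = b$name, side = b$side, values = out),
            class = "bundle_profile")
}

#' Join left and right bundle profiles
#'
#' Concatenates the left profile then the right; two 98-segment sides
#' give the 196-segment joined profile used for per-segment statistics.
#'
#' @param left,right `bundle_profile`s of equal length.
#' @return A `bundle_profile` of length `length(left) + length(right)`.
#' @export
join_profiles <- function(left, right) {
  stopifnot(inherits(left, "bundle_profile"),
            inherits(right, "bundle_profile"))
  if (length(left$values) != length(right$values))
    stop("profile lengths differ (", length(left$values), " vs ",
         length(right$values), ")")
  structure(list(bundle = sub("_(left|right)$", "", left$bundle),
                 side = "joined",
                 values = c(left$values, right$values)),
            class = "bundle_profile")
}

#' Average metric value of a bundle profile
#'
#' Mean over non-missing segments.
#'
#' @param p a `bundle_profile`.
#' @return Scalar mean.
#' @export
bundle_average <- function(p) {
  stopifnot(inherits(p, "bundle_profile"))
  v <- p$values[!is.na(p$values)]
  if (!length(v)) stop("all segments of '", p$bundle, "' are missing")
  mean(v)
}

#' Bundle mask volume
#'
#' @param b a `bundle` (or a 3-D logical mask).
#' @param voxdim voxel size in mm (taken from the bundle if omitted).
#' @return list with `voxels` (count of TRUE voxels) and `mm3`.
#' @export
bundle_volume <- function(b, voxdim = NULL) {
  if (inherits(b, "bundle")) {
    mask <- b$mask
    if (is.null(voxdim)) voxdim <- b$voxdim
  } else {
    mask <- b
    if (is.null(voxdim)) stop("voxdim required for a bare mask")
  }
  n <- sum(mask)
  list(voxels = n, mm3 = n * prod(voxdim))
}

#' Read a bundle-grouping table
#'
#' Maps segmentation labels (e.g. the 40 TractSeg outputs) to grouped
#' bundle names (e.g. 22 groups with the corpus callosum in five parts).
#' The packaged table (`system.file("extdata", "bundle_groups.csv",
#' package = "dwidown")`) is illustrative and fully user-overridable.
#'
#' @param path CSV with columns `label`, `group`, `side`.
#' @return data.frame.
#' @export
read_bundle_groups <- function(path = system.file("extdata",
                                                  "bundle_groups.csv",
                                                  package = "dwidown")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
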