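#' Relative L1 distance, in percent
#'
#' `100 * |ref - ds| / |ref|`: the absolute difference between a
#' reference-derived and a down-sampled-derived value, expressed relative
#' to the reference. A zero reference yields `NA` (flagged missing), not
#' infinity.
#'
#' @param ref reference value(s).
#' @param ds down-sampled value(s), same length.
#' @return Percent difference(s), >= 0 or `NA`.
#' @export
rel_l1 <- function(ref, ds) {
  stopifnot(length(ref) == length(ds))
  ifelse(ref == 0, NA_real_, 100 * abs(ref - ds) / abs(ref))
}

#' Median and 2.5-97.5 percentile interval of a distribution
#'
#' Summarizes a subject/session distribution by its median and central
#' 95% percentile interval (linear-interpolation percentile rule,
#' `quantile type 7`). This is an interval of the distribution, not a
#' confidence interval of the median.
#'
#' @param values numeric vector (NAs dropped).
#' @return list with `median`, `lo` (2.5th), `hi` (97.5th percentile).
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to summarize")
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), names = FALSE,
                       type = 7)
  list(median = q[2], lo = q[1], hi = q[3])
}

#' Per-segment two-sample KS tests between profile arms with BH-FDR
#'
#' For each segment, compares the across-subject sample of metric values
#' from the reference arm against the down-sampled arm with a two-sample
#' Kolmogorov-Smirnov test (exact p-value when both arms have <= 25
#' observations, asymptotic otherwise), then applies Benjamini-Hochberg
#' FDR correction across the segments of the bundle.
#'
#' @param ref_profiles matrix (subjects x segments) of reference-arm
#'   values, or a list of `bundle_profile`s.
#' @param ds_profiles same shape, down-sampled arm.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with `segment`, `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
ks_profile_test <- function(ref_profiles, ds_profiles, alpha = 0.05) {
  as_mat <- function(x) {
    if (is.list(x) && !is.data.frame(x) && !is.matrix(x))
      x <- do.call(rbind, lapply(x, function(p)
        if (inherits(p, "bundle_profile")) p$values else p))
    as.matrix(x)
  }
  R <- as_mat(ref_profiles); D <- as_mat(ds_profiles)
  if (ncol(R) != ncol(D)) stop("segment counts differ between arms")
  if (nrow(R) < 2 || nrow(D) < 2)
    stop("at least 2 subjects per arm are required")
  n_seg <- ncol(R)
  stat <- p <- numeric(n_seg)
  for (k in seq_len(n_seg)) {
    x <- R[, k][!is.na(R[, k])]; y <- D[, k][!is.na(D[, k])]
    if (length(x) < 2 || length(y) < 2) { stat[k] <- NA; p[k] <- NA; next }
    if (isTRUE(all.equal(sort(x), sort(y)))) {         # identical arms
      stat[k] <- 0; p[k] <- 1; next
    }
    kt <- suppressWarnings(
      stats::ks.test(x, y, exact = length(x) <= 25 && length(y) <= 25))
    stat[k] <- unname(kt$statistic); p[k] <- kt$p.value
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(segment = seq_len(n_seg), statistic = stat, p = p,
             p_adj = p_adj, significant = !is.na(p_adj) & p_adj < alpha)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b` between paired measurements from method A
#' (reference) and method B (down-sampled); bias is the mean difference
#' and the limits of agreement are `bias +/- 1.96 * sd(d)` with the
#' sample (n-1) standard deviation. Under normality about 95% of
#' differences fall inside the limits.
#'
#' @param a,b paired numeric vectors, length >= 2.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`,
#'   `frac_within` (fraction of differences inside the limits), `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  lo <- bias - 1.96 * s; hi <- bias + 1.96 * s
  list(bias = bias, loa_low = lo, loa_high = hi, sd = s,
       frac_within = mean(d >= lo & d <= hi), n = length(d))
}

#' White-matter volume loss between arms, in percent
#'
#' `100 * (V_ref - V_ds) / V_ref`, where each V is the per-bundle
#' voxel-count sum over the grouped bundle set (overlapping voxels are
#' counted once per bundle, matching a per-bundle volume sum rather than
#' a voxel union).
#'
#' @param ref_bundles,ds_bundles lists of `bundle`s (or of 3-D logical
#'   masks), same bundle set in both arms.
#' @return Percent volume loss (negative = volume gain).
#' @export
volume_loss <- function(ref_bundles, ds_bundles) {
  count <- function(bs) sum(vapply(bs, function(b) {
    if (inherits(b, "bundle")) sum(b$mask) else sum(b)
  }, numeric(1)))
  v_ref <- count(ref_bundles); v_ds <- count(ds_bundles)
  if (v_ref == 0) stop("reference volume is zero")
  100 * (v_ref - v_ds) / v_ref
}
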