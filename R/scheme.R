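#' Multi-shell gradient scheme
#'
#' A `multishell_scheme` groups diffusion-gradient directions into b-value
#' shells and records the number of b0 (non-diffusion-weighted) volumes.
#' Directions are unit vectors stored exactly as given; antipodal symmetry
#' is handled inside the repulsion energy, never by mutating coordinates.
#'
#' The canonical volume order of a scheme is: all b0 volumes first, then the
#' shells in ascending b-value, each shell's directions in their original
#' order. A scheme read from files additionally carries a `source_index`
#' attribute mapping canonical volumes back to the original column order,
#' so a 4-D volume read alongside the gradient table can be reordered.
#'
#' @param shells named list; each element a list with `bvalue` (s/mm^2) and
#'   `directions` (n x 3 matrix of unit row vectors).
#' @param n_b0 number of b0 volumes (b below the b0 threshold).
#' @param metadata optional list of acquisition descriptors (delta, Delta,
#'   TR, TE in ms; voxel size in mm). Carried through, never computed on.
#' @return An object of class `multishell_scheme`.
#' @export
multishell_scheme <- function(shells, n_b0 = 0L, metadata = list()) {
  stopifnot(is.list(shells), n_b0 >= 0)
  bvals <- vapply(shells, function(s) s$bvalue, numeric(1))
  shells <- shells[order(bvals)]
  for (s in shells) {
    d <- s$directions
    if (!is.matrix(d) || ncol(d) != 3 || nrow(d) < 1)
      stop("each shell needs a non-empty n x 3 direction matrix")
    nrm <- sqrt(rowSums(d^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("directions in shell b=", s$bvalue, " are not unit vectors")
    if (anyDuplicated(d))
      stop("exact duplicate directions in shell b=", s$bvalue)
    if (s$bvalue <= .B0_THRESHOLD)
      stop("shell b-value ", s$bvalue, " is below the b0 threshold")
  }
  structure(list(shells = shells, n_b0 = as.integer(n_b0),
                 metadata = metadata),
            class = "multishell_scheme")
}

# b-values below this (s/mm^2) count as b0; |b - center| <= this groups a
# measurement into an existing shell.
.B0_THRESHOLD <- 50
.SHELL_TOL <- 50

#' @export
print.multishell_scheme <- function(x, ...) {
  cat("Multi-shell gradient scheme\n")
  cat(sprintf("  b0 volumes: %d\n", x$n_b0))
  for (s in x$shells)
    cat(sprintf("  b=%g s/mm^2: %d directions\n", s$bvalue,
                nrow(s$directions)))
  invisible(x)
}

#' Per-shell direction counts
#'
#' @param scheme a `multishell_scheme`.
#' @return Integer vector of direction counts, one per shell in ascending
#'   b-value order, named by b-value.
#' @export
shell_counts <- function(scheme) {
  stopifnot(inherits(scheme, "multishell_scheme"))
  n <- vapply(scheme$shells, function(s) nrow(s$directions), integer(1))
  names(n) <- vapply(scheme$shells, function(s) as.character(s$bvalue),
                     character(1))
  n
}

#' Shell b-values
#' @param scheme a `multishell_scheme`.
#' @return Numeric vector of shell b-values, ascending.
#' @export
shell_bvalues <- function(scheme)
  vapply(scheme$shells, function(s) s$bvalue, numeric(1))

#' Total number of volumes (b0 + all directions)
#' @param scheme a `multishell_scheme`.
#' @return Integer count.
#' @export
n_volumes <- function(scheme) scheme$n_b0 + sum(shell_counts(scheme))

#' Per-volume b-values and directions in canonical order
#'
#' Canonical order is b0 volumes first, then shells ascending in b.
#' b0 volumes get a zero direction vector.
#'
#' @param scheme a `multishell_scheme`.
#' @return `scheme_bvals`: numeric vector, one b per volume.
#' @export
scheme_bvals <- function(scheme) {
  c(rep(0, scheme$n_b0),
    unlist(lapply(scheme$shells,
                  function(s) rep(s$bvalue, nrow(s$directions)))))
}

#' @rdname scheme_bvals
#' @return `scheme_dirs`: numeric matrix (n_volumes x 3).
#' @export
scheme_dirs <- function(scheme) {
  rbind(matrix(0, scheme$n_b0, 3),
        do.call(rbind, lapply(scheme$shells, function(s) s$directions)))
}

#' Shell index per volume (0 for b0)
#' @param scheme a `multishell_scheme`.
#' @return Integer vector, 0 for b0 volumes, 1..n_shells otherwise.
#' @export
scheme_shell_index <- function(scheme) {
  c(rep(0L, scheme$n_b0),
    unlist(lapply(seq_along(scheme$shells),
                  function(i) rep(i, nrow(scheme$shells[[i]]$directions)))))
}

.cluster_shells <- function(b, dirs) {
  # greedy clustering of b-values into shells within .SHELL_TOL of a center
  is_b0 <- b < .B0_THRESHOLD
  if (any(!is_b0)) {
    zn <- sqrt(rowSums(dirs[!is_b0, , drop = FALSE]^2))
    if (any(zn < 1e-12))
      stop("diffusion-weighted entry with zero-norm gradient vector")
  }
  centers <- numeric(0)
  assign <- integer(length(b))
  for (i in which(!is_b0)) {
    if (length(centers)) {
      d <- abs(centers - b[i])
      k <- which.min(d)
    }
    if (length(centers) && d[k] <= .SHELL_TOL) {
      assign[i] <- k
    } else {
      centers <- c(centers, b[i])
      assign[i] <- length(centers)
    }
  }
  list(is_b0 = is_b0, centers = centers, assign = assign)
}

#' Read a gradient scheme from FSL bvals/bvecs files
#'
#' Entries with b below 50 s/mm^2 are counted as b0 volumes; the remaining
#' entries are clustered into shells (tolerance 50 s/mm^2 around the first
#' b seen for each shell) with a representative b-value equal to the median
#' b of the shell's members, rounded to the nearest integer. Direction
#' order within each shell follows file order. Non-unit b>0 vectors are
#' normalized to unit length (FSL convention tolerates scaling).
#'
#' @param path_bval path to the bvals file (one whitespace-separated row).
#' @param path_bvec path to the bvecs file (three rows: x, y, z).
#' @return A `multishell_scheme` with a `source_index` attribute giving,
#'   for each canonical volume, its 1-based column in the input files.
#' @export
read_scheme <- function(path_bval, path_bvec) {
  b <- scan(path_bval, what = numeric(), quiet = TRUE)
  v <- as.matrix(utils::read.table(path_bvec))
  if (nrow(v) != 3)
    stop("bvecs file must have exactly 3 rows (x, y, z)")
  if (ncol(v) != length(b))
    stop("bvals has ", length(b), " entries but bvecs has ", ncol(v),
         " columns")
  .scheme_from_table(b, t(v))
}

#' Read a gradient scheme from an MRtrix gradient table
#'
#' One row per volume: "x y z b". Comment lines starting with '#' are
#' skipped.
#'
#' @param path path to the gradient file.
#' @return A `multishell_scheme` with a `source_index` attribute.
#' @export
read_scheme_mrtrix <- function(path) {
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  if (ncol(m) != 4) stop("MRtrix gradient table must have 4 columns")
  .scheme_from_table(m[, 4], m[, 1:3, drop = FALSE])
}

.scheme_from_table <- function(b, dirs) {
  if (anyNA(b) || anyNA(dirs)) stop("non-numeric content in gradient table")
  cl <- .cluster_shells(b, dirs)
  shells <- list()
  src <- which(cl$is_b0)
  for (k in order(cl$centers)) {
    idx <- which(cl$assign == k)
    d <- unname(dirs[idx, , drop = FALSE])
    d <- d / sqrt(rowSums(d^2))
    shells[[length(shells) + 1]] <-
      list(bvalue = round(stats::median(b[idx])), directions = d)
    src <- c(src, idx)
  }
  s <- multishell_scheme(shells, n_b0 = sum(cl$is_b0))
  attr(s, "source_index") <- src
  s
}

#' Write a gradient scheme to disk
#'
#' Volumes are written in canonical order (b0 first, shells ascending).
#' The FSL dialect produces `<prefix>.bval` (one row of b-values) and
#' `<prefix>.bvec` (three rows x, y, z); the MRtrix dialect produces
#' `<prefix>.b` with one "x y z b" row per volume.
#'
#' @param scheme a `multishell_scheme`.
#' @param prefix output path prefix.
#' @param dialect `"fsl"` or `"mrtrix"`.
#' @return Invisibly, the written file path(s). Round-tripping through
#'   [read_scheme()] / [read_scheme_mrtrix()] reproduces shell counts,
#'   b-values, and coordinates to 1e-6.
#' @export
write_scheme <- function(scheme, prefix, dialect = c("fsl", "mrtrix")) {
  stopifnot(inherits(scheme, "multishell_scheme"))
  dialect <- match.arg(dialect)
  b <- scheme_bvals(scheme)
  d <- scheme_dirs(scheme)
  if (dialect == "fsl") {
    fb <- paste0(prefix, ".bval"); fv <- paste0(prefix, ".bvec")
    writeLines(paste(format(b, trim = TRUE), collapse = " "), fb)
    writeLines(apply(t(d), 1, function(r)
      paste(formatC(r, format = "g", digits = 10), collapse = " ")), fv)
    invisible(c(fb, fv))
  } else {
    f <- paste0(prefix, ".b")
    writeLines(apply(cbind(d, b), 1, function(r)
      paste(formatC(r, format = "g", digits = 10), collapse = " ")), f)
    invisible(f)
  }
}

#' Build a scheme from explicit per-volume b-values and directions
#'
#' @param b numeric vector of per-volume b-values.
#' @param dirs matrix (length(b) x 3) of gradient vectors (zero rows for b0).
#' @param metadata optional metadata list.
#' @return A `multishell_scheme`.
#' @export
scheme_from_volumes <- function(b, dirs, metadata = list()) {
  s <- .scheme_from_table(b, dirs)
  s$metadata <- metadata
  s
}
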