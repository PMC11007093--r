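# Shared fixture builders; everything is generated in code.

# n seeded random unit vectors
random_dirs <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# single- or multi-shell scheme from direction counts
toy_scheme <- function(counts, bvalues = NULL, n_b0 = 0, seed = 1) {
  if (is.null(bvalues)) bvalues <- 1000 * seq_along(counts)
  D <- random_dirs(sum(counts), seed)
  sid <- rep(seq_along(counts), counts)
  shells <- lapply(seq_along(counts), function(i)
    list(bvalue = bvalues[i], directions = D[sid == i, , drop = FALSE]))
  multishell_scheme(shells, n_b0 = n_b0)
}

# noise-free single-tensor DWI dataset on a scheme
tensor_dataset <- function(scheme, D, S0 = 1000) {
  b <- scheme_bvals(scheme)
  G <- scheme_dirs(scheme)
  S <- vapply(seq_along(b), function(i)
    S0 * exp(-b[i] * drop(G[i, ] %*% D %*% G[i, ])), numeric(1))
  dwi_dataset(array(S, c(1, 1, 1, length(b))), scheme,
              array(TRUE, c(1, 1, 1)))
}

# straight-line streamline from a to b with n points
line_streamline <- function(a, b, n = 20) {
  t <- seq(0, 1, length.out = n)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
        a[3] + t * (b[3] - a[3]))
}

# small bundle living in a dim^3 grid at 1 mm voxels
toy_bundle <- function(streamlines, dim = c(12, 12, 12), name = "toy",
                       side = "unpaired") {
  mask <- array(FALSE, dim); mask[5:8, 5:8, 5:8] <- TRUE
  bundle(name, streamlines, mask, side = side, voxdim = c(1, 1, 1))
}
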