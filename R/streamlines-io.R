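#' Read streamlines from an MRtrix TCK file
#'
#' Minimal reader for the MRtrix track format: ASCII header terminated by
#' `END`, then IEEE float triplets with `NaN` triplets separating
#' streamlines and an `Inf` triplet terminating the stream. Only
#' `Float32LE` data (the MRtrix default) is supported.
#'
#' @param path TCK file path.
#' @return List of n x 3 point matrices (mm, scanner/world space).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^mrtrix tracks", magic)) stop("not an MRtrix track file")
  dtype <- "Float32LE"; offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || ln == "END") break
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) >= 2) {
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
      if (key == "datatype") dtype <- val
      if (key == "file") offset <- as.integer(sub("^\\. ", "", val))
    }
  }
  if (dtype != "Float32LE") stop("unsupported TCK datatype: ", dtype)
  if (is.na(offset)) stop("TCK header lacks a file offset")
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4,
                 endian = "little")
  m <- matrix(raw[seq_len(3 * (length(raw) %/% 3))], ncol = 3,
              byrow = TRUE)
  out <- list(); cur <- NULL
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    if (all(is.infinite(r))) break
    if (all(is.nan(r))) {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- NULL
    } else cur <- rbind(cur, r)
  }
  if (!is.null(cur) && nrow(cur)) out[[length(out) + 1]] <- cur
  lapply(out, function(x) { dimnames(x) <- NULL; x })
}

#' Write streamlines to an MRtrix TCK file
#'
#' @param streamlines list of n x 3 matrices (mm).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tck <- function(streamlines, path) {
  # the offset counts the full header including the offset field itself,
  # so write it fixed-width and resolve in one pass
  mk <- function(off) paste0(
    "mrtrix tracks\n", "datatype: Float32LE\n",
    "count: ", length(streamlines), "\n",
    sprintf("file: . %06d", off), "\nEND\n")
  txt <- mk(nchar(mk(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4,
             endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read streamlines from the plain-text polyline format
#'
#' One "x y z" line per point; blank lines separate streamlines; lines
#' starting with `#` are comments. This text format is the fixture
#' counterpart of TCK.
#'
#' @param path file path.
#' @return List of n x 3 matrices.
#' @export
read_polylines <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  out <- list(); cur <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- NULL
    } else {
      cur <- rbind(cur, as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  lapply(out, function(x) { dimnames(x) <- NULL; x })
}

#' Write streamlines in the plain-text polyline format
#'
#' @param streamlines list of n x 3 matrices.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_polylines <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(streamlines)) {
    if (i > 1) writeLines("", con)
    writeLines(apply(streamlines[[i]], 1, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
  }
  invisible(path)
}

#' Write a 3-D or 4-D array as NIfTI
#'
#' @param x numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxdim voxel size in mm.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path, voxdim = c(2, 2, 2)) {
  img <- RNifti::asNifti(x, pixdim = voxdim)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array with a `voxdim` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attr(a, "voxdim") <- RNifti::pixdim(img)
  a
}
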