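#' Construct a streamline set
#'
#' Streamlines are 3-D polylines in world coordinates (mm). The optional
#' affine records the voxel-to-world mapping of the reference image grid the
#' polylines were tracked in; it is used only for consistency checks against
#' parcellations and masks.
#'
#' @param streamlines list of n_i x 3 numeric matrices (n_i >= 2) of world
#'   coordinates in mm.
#' @param affine optional 4 x 4 voxel-to-world matrix of the reference grid.
#' @return an object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, affine = NULL) {
  if (!is.list(streamlines)) stopf("streamlines must be a list of matrices")
  streamlines <- lapply(streamlines, function(m) {
    m <- to_point_matrix(m)
    if (nrow(m) < 2L) stopf("every streamline needs at least 2 points")
    if (any(!is.finite(m))) stopf("streamline coordinates must be finite")
    m
  })
  if (!is.null(affine)) check_affine(affine)
  structure(list(streamlines = streamlines, affine = affine),
            class = "streamline_set")
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' @export
print.streamline_set <- function(x, ...) {
  np <- if (length(x)) sum(vapply(x$streamlines, nrow, 0L)) else 0L
  cat(sprintf("Streamline set: %d polylines, %d points\n", length(x), np))
  invisible(x)
}

#' Read streamlines from a TRK- or TCK-dialect file
#'
#' The format is chosen from the file extension, falling back to the magic
#' bytes. All polylines are returned in world mm. A zero-length file yields
#' an empty streamline set.
#'
#' @param path path to a `.tck` or `.trk` file.
#' @param affine optional reference-grid affine to attach (TCK files carry
#'   none; TRK files carry their own, which takes precedence).
#' @return a [streamline_set()].
#' @export
read_streamlines <- function(path, affine = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L) {
    return(structure(list(streamlines = list(), affine = affine),
                     class = "streamline_set"))
  }
  magic <- readBin(path, "raw", n = 13L)
  if (grepl("\\.tck$", path, ignore.case = TRUE) ||
      identical(rawToChar(magic), "mrtrix tracks")) {
    read_tck(path, affine)
  } else if (grepl("\\.trk$", path, ignore.case = TRUE) ||
             identical(rawToChar(magic[1:5]), "TRACK")) {
    read_trk(path)
  } else {
    stopf("unknown streamline format: %s", path)
  }
}

#' Write streamlines to a TCK or TRK file
#'
#' @param x a [streamline_set()].
#' @param path destination path ending in `.tck` or `.trk`; TRK additionally
#'   requires the set to carry a reference affine.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(x, path) {
  if (!inherits(x, "streamline_set")) stopf("x must be a streamline_set")
  if (grepl("\\.tck$", path, ignore.case = TRUE)) {
    write_tck(x, path)
  } else if (grepl("\\.trk$", path, ignore.case = TRUE)) {
    write_trk(x, path)
  } else {
    stopf("unsupported streamline extension (use .tck or .trk): %s", path)
  }
  invisible(path)
}

## ---- TCK (text header + Float32LE triplets, NaN/Inf sentinels) ----

read_tck <- function(path, affine = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(first, "mrtrix tracks")) stopf("corrupt TCK header: %s", path)
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stopf("corrupt TCK header (no END): %s", path)
    if (identical(line, "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "file") offset <- as.integer(sub("^\\.\\s+", "", val))
      if (key == "datatype") datatype <- val
    }
  }
  if (is.na(offset)) stopf("corrupt TCK header (no file offset): %s", path)
  if (!identical(datatype, "Float32LE")) {
    stopf("unsupported TCK datatype %s (only Float32LE)", datatype)
  }
  seek(con, offset)
  nfloat <- (file.size(path) - offset) %/% 4L
  vals <- readBin(con, "numeric", n = nfloat, size = 4L, endian = "little")
  pts <- matrix(vals[seq_len((length(vals) %/% 3L) * 3L)],
                ncol = 3L, byrow = TRUE)
  split_sentinel_points(pts, affine)
}

split_sentinel_points <- function(pts, affine) {
  is_nan <- rowSums(is.na(pts)) == 3L
  is_inf <- is.infinite(pts[, 1])
  keepto <- which(is_inf)
  if (length(keepto)) pts <- pts[seq_len(keepto[1] - 1L), , drop = FALSE]
  is_nan <- rowSums(is.na(pts)) == 3L
  grp <- cumsum(c(TRUE, is_nan[-length(is_nan)]))
  streamlines <- list()
  if (nrow(pts)) {
    keep <- !is_nan
    streamlines <- unname(split.data.frame(pts[keep, , drop = FALSE],
                                           grp[keep]))
    streamlines <- Filter(function(m) nrow(m) > 0L, streamlines)
  }
  streamline_set(streamlines, affine)
}

write_tck <- function(x, path) {
  n <- length(x)
  body_head <- sprintf("mrtrix tracks\ndatatype: Float32LE\ncount: %d\n", n)
  tail_txt <- "\nEND\n"
  offset <- 0L
  for (i in 1:3) { # fixed point for the self-referential offset field
    file_line <- sprintf("file: . %d", offset)
    offset <- nchar(body_head) + nchar(file_line) + nchar(tail_txt)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(body_head, file_line, tail_txt), con, eos = NULL)
  for (m in x$streamlines) {
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3L)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3L)), con, size = 4L, endian = "little")
  invisible(path)
}

## ---- TRK (1000-byte binary header, voxmm corner-convention points) ----

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (!identical(id, "TRACK")) stopf("corrupt TRK header: %s", path)
  dims <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  invisible(readBin(con, "numeric", 3L, size = 4L, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  n_properties <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  vox2ras <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                    4L, 4L, byrow = TRUE)
  invisible(readBin(con, "raw", 444L + 4L + 4L + 24L + 6L + 2L))
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stopf("corrupt TRK header (hdr_size %d)", hdr_size)
  if (version >= 2L && any(vox2ras[4, ] != c(0, 0, 0, 1))) {
    stopf("corrupt TRK vox_to_ras matrix")
  }
  if (all(vox2ras == 0)) vox2ras <- diag(c(voxel_size, 1))
  if (any(voxel_size <= 0)) stopf("corrupt TRK header (voxel size)")
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(npts)) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_properties > 0L) {
      invisible(readBin(con, "numeric", n_properties, size = 4L,
                        endian = "little"))
    }
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm corner convention -> voxel centres -> world
    vox <- sweep(m, 2L, voxel_size, "/") - 0.5
    i <- i + 1L
    streamlines[[i]] <- voxel_to_world(vox, vox2ras)
  }
  streamline_set(streamlines[seq_len(i)], vox2ras)
}

write_trk <- function(x, path) {
  if (is.null(x$affine)) {
    stopf("TRK output needs a reference affine on the streamline set")
  }
  aff <- x$affine
  voxel_size <- sqrt(colSums(aff[1:3, 1:3]^2))
  inv <- solve(aff)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(c(0L, 0L, 0L)), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 2L, endian = "little")           # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")           # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(aff)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)
  writeChar("RAS", con, nchars = 3L, eos = NULL); writeBin(as.raw(0L), con)
  writeBin(raw(4L), con)
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  writeBin(raw(2L + 6L), con)
  writeBin(length(x), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")           # version
  writeBin(1000L, con, size = 4L, endian = "little")        # hdr_size
  for (m in x$streamlines) {
    h <- cbind(m, 1) %*% t(inv)
    voxmm <- sweep(h[, 1:3, drop = FALSE] + 0.5, 2L, voxel_size, "*")
    writeBin(nrow(m), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
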