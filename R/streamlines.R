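# Streamline sets and TRK/TCK file I/O.
#
# Streamlines are stored in world millimetre coordinates regardless of the
# on-disk convention: TCK files already hold world mm; TRK files hold
# "voxmm" coordinates (voxel indices scaled by voxel size, measured from the
# corner of the first voxel) which are converted through the header affine
# on load. No installed R package reads these formats, so the binary layout
# is implemented here with readBin/writeBin.

#' Set of streamlines in world coordinates
#'
#' @param streamlines list of n_i x 3 numeric matrices, one polyline each;
#'   every polyline must have at least 2 points with finite coordinates.
#' @param tract_label optional character vector, one tract name per
#'   streamline.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, tract_label = NULL) {
  if (!length(streamlines)) stop("streamline_set: empty streamline list")
  streamlines <- lapply(streamlines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("streamline_set: polylines must be n x 3")
    if (nrow(p) < 2L) stop("streamline_set: polyline with fewer than 2 points")
    if (!all(is.finite(p))) stop("streamline_set: non-finite coordinates")
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  if (!is.null(tract_label)) {
    if (length(tract_label) != length(streamlines))
      stop("streamline_set: tract_label length mismatch")
    tract_label <- as.character(tract_label)
  }
  structure(list(streamlines = streamlines, tract_label = tract_label),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("<streamline_set> ", length(x$streamlines), " streamlines",
      if (!is.null(x$tract_label))
        paste0(" (", length(unique(x$tract_label)), " tracts)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Read streamlines from a TRK or TCK file
#'
#' @param path file path; format is chosen by extension (`.trk` / `.tck`).
#' @return A [streamline_set()] in world mm coordinates. Tract labels are
#'   not stored by either format; attach them separately.
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop("read_streamlines: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = read_trk(path),
         tck = read_tck(path),
         stop("read_streamlines: unsupported format '.", ext,
              "' (TRK and TCK are supported)"))
}

#' Write streamlines to a TRK or TCK file
#'
#' @param sset a [streamline_set()] (world mm coordinates).
#' @param path output path ending in `.trk` or `.tck`.
#' @param affine voxel-to-world affine of the reference grid (TRK only; the
#'   default identity stores world coordinates directly as voxel mm).
#' @param dim grid extents for the TRK header.
#' @param voxel_size voxel size (mm) for the TRK header.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(sset, path, affine = diag(4),
                              dim = c(0L, 0L, 0L), voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(sset, "streamline_set"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = write_trk(sset, path, affine, dim, voxel_size),
         tck = write_tck(sset, path),
         stop("write_streamlines: unsupported format '.", ext, "'"))
  invisible(path)
}

# ---- TCK (MRtrix) ----------------------------------------------------------
# ASCII header terminated by "END", then little-endian float32 triplets;
# (NaN,NaN,NaN) separates streamlines, (Inf,Inf,Inf) terminates the stream.

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  first <- readLines(con, n = 1L)
  if (!grepl("^mrtrix tracks", first))
    stop("read_tck: not an MRtrix track file: ", path)
  offset <- NA_real_
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("read_tck: header not terminated")
    if (identical(line, "END")) break
    header <- c(header, line)
    if (grepl("^file:", line))
      offset <- as.numeric(sub("^file:\\s*\\.\\s*", "", line))
  }
  dt <- grep("^datatype:", header, value = TRUE)
  if (length(dt) && !grepl("Float32LE", dt))
    stop("read_tck: only Float32LE data supported, got: ", dt)
  if (!is.finite(offset)) stop("read_tck: missing 'file:' offset")
  seek(con, offset)
  sz <- file.size(path)
  n_float <- (sz - offset) / 4
  raw <- readBin(con, "numeric", n = n_float, size = 4, endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  is_sep <- !is.finite(m[, 1])
  ends <- which(is_sep)
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- ends > starts            # drop zero-length records
  lines <- mapply(function(s, e) m[s:(e - 1L), , drop = FALSE],
                  starts[keep], ends[keep], SIMPLIFY = FALSE)
  if (!length(lines)) stop("read_tck: file contains no streamlines")
  streamline_set(lines)
}

write_tck <- function(sset, path) {
  body_floats <- sum(vapply(sset$streamlines, nrow, 1L) + 1L) * 3L + 3L
  make_header <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           "count: ", length(sset$streamlines), "\n",
           "file: . ", offset, "\n",
           "END\n")
  }
  # header length depends on the printed offset; iterate to a fixed point
  offset <- nchar(make_header(1000), type = "bytes")
  repeat {
    h <- make_header(offset)
    if (nchar(h, type = "bytes") == offset) break
    offset <- nchar(h, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(h, con, eos = NULL)
  nanrow <- c(NaN, NaN, NaN)
  for (p in sset$streamlines) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    writeBin(nanrow, con, size = 4, endian = "little")
  }
  writeBin(c(Inf, Inf, Inf), con, size = 4, endian = "little")
}

# ---- TRK (TrackVis) --------------------------------------------------------
# 1000-byte header; per-streamline int32 point count then float32 points.
# Points are voxmm; world = M %*% (voxmm / voxel_size - 0.5) with M the
# header's vox_to_ras affine (the nibabel convention, voxel corners at the
# origin of each voxel's mm box).

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6)
  if (rawToChar(id[1:5]) != "TRACK")
    stop("read_trk: not a TrackVis file: ", path)
  readBin(con, "integer", n = 3, size = 2)          # dim
  voxel_size <- readBin(con, "numeric", n = 3, size = 4)
  readBin(con, "numeric", n = 3, size = 4)          # origin (unused)
  n_scalars <- readBin(con, "integer", n = 1, size = 2)
  readBin(con, "raw", n = 200)                      # scalar names
  n_props <- readBin(con, "integer", n = 1, size = 2)
  readBin(con, "raw", n = 200)                      # property names
  vox_to_ras <- matrix(readBin(con, "numeric", n = 16, size = 4),
                       4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444 + 4 + 4 + 24 + 2 + 6) # reserved..inverts
  n_count <- readBin(con, "integer", n = 1, size = 4)
  readBin(con, "integer", n = 1, size = 4)          # version
  hdr_size <- readBin(con, "integer", n = 1, size = 4)
  if (hdr_size != 1000L)
    stop("read_trk: unexpected header size ", hdr_size,
         " (byte order not supported)")
  if (any(voxel_size <= 0)) voxel_size <- c(1, 1, 1)
  if (all(vox_to_ras == 0)) {                       # legacy header: assume id
    vox_to_ras <- diag(4)
    vox_to_ras[cbind(1:3, 1:3)] <- voxel_size
  }
  lines <- list()
  repeat {
    n_pts <- readBin(con, "integer", n = 1, size = 4)
    if (!length(n_pts)) break
    vals <- readBin(con, "numeric",
                    n = n_pts * (3 + n_scalars) + n_props,
                    size = 4, endian = "little")
    pts <- matrix(vals[seq_len(n_pts * (3 + n_scalars))],
                  ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pts, 2, voxel_size, "/") - 0.5
    world <- cbind(vox, 1) %*% t(vox_to_ras)
    lines[[length(lines) + 1L]] <- world[, 1:3, drop = FALSE]
    if (n_count > 0 && length(lines) == n_count) break
  }
  if (!length(lines)) stop("read_trk: file contains no streamlines")
  streamline_set(lines)
}

write_trk <- function(sset, path, affine = diag(4),
                      dim = c(0L, 0L, 0L), voxel_size = c(1, 1, 1)) {
  affine <- check_affine(affine)
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dim), con, size = 2)
  writeBin(as.numeric(voxel_size), con, size = 4)
  writeBin(numeric(3), con, size = 4)               # origin
  writeBin(0L, con, size = 2)                       # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                       # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4)    # vox_to_ras, row-major
  writeBin(raw(444), con)
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(as.raw(0), con)
  writeBin(raw(4), con)                             # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)
  writeBin(raw(2), con)                             # pad1
  writeBin(raw(6), con)                             # invert/swap flags
  writeBin(length(sset$streamlines), con, size = 4) # n_count
  writeBin(2L, con, size = 4)                       # version
  writeBin(1000L, con, size = 4)                    # hdr_size
  for (p in sset$streamlines) {
    vox <- cbind(p, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, voxel_size, "*")
    writeBin(nrow(p), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
}

# ---- Polyline geometry -----------------------------------------------------

#' Resample a polyline at a maximum arc-length step
#'
#' Inserts evenly spaced points along every segment so that consecutive
#' samples are at most `step_mm` apart; original vertices are always kept.
#'
#' @param line n x 3 matrix of polyline points (mm).
#' @param step_mm maximum spacing between samples (mm), > 0.
#' @return m x 3 matrix of sampled points (m >= n).
#' @export
resample_polyline <- function(line, step_mm) {
  line <- rbind3(line)
  if (nrow(line) < 2L) stop("resample_polyline: polyline needs >= 2 points")
  if (!is.numeric(step_mm) || step_mm <= 0)
    stop("resample_polyline: step_mm must be > 0")
  seg <- diff(line)
  len <- sqrt(rowSums(seg^2))
  n_sub <- pmax(1L, ceiling(len / step_mm))
  total <- sum(n_sub) + 1L
  out <- matrix(0, total, 3)
  pos <- 1L
  for (i in seq_len(nrow(seg))) {
    t <- seq(0, 1, length.out = n_sub[i] + 1L)[-(n_sub[i] + 1L)]
    out[pos:(pos + n_sub[i] - 1L), ] <-
      cbind(line[i, 1] + t * seg[i, 1],
            line[i, 2] + t * seg[i, 2],
            line[i, 3] + t * seg[i, 3])
    pos <- pos + n_sub[i]
  }
  out[total, ] <- line[nrow(line), ]
  out
}
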