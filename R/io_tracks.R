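# Tractogram file formats. TCK (MRtrix) stores points verbatim in world
# RAS mm. TRK (TrackVis) stores points in "voxmm" with the origin at the
# corner of voxel (0,0,0): world = vox_to_ras %*% (voxmm / voxel_size - 0.5),
# so conversion needs the grid geometry.

#' Write a tractogram as TCK (MRtrix format)
#'
#' @param tractogram a `tractogram`.
#' @param path output path (`.tck`).
#' @return invisibly, the path.
#' @export
write_tck <- function(tractogram, path) {
  sl <- tractogram$streamlines
  header_for <- function(offset) paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    sprintf("count: %d\n", length(sl)),
    sprintf("file: . %d\n", offset),
    "END\n")
  # fixed-point iteration on the offset (its digits change the length)
  off <- nchar(header_for(0), type = "bytes")
  off <- nchar(header_for(off), type = "bytes")
  hdr <- header_for(off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  nan3 <- rep(NaN, 3)
  for (s in sl) {
    writeBin(as.numeric(t(s$points)), con, size = 4, endian = "little")
    writeBin(nan3, con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' Only Float32LE data are supported. Per-fiber length is recomputed from
#' the points; mean FA is not stored by the format and is set to NA unless
#' a `field` is given, in which case it is resampled.
#'
#' @param path input path.
#' @param field optional [diffusion_field()] used to resample per-point FA.
#' @return a `tractogram`.
#' @export
read_tck <- function(path, field = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  end_pat <- charToRaw("END\n")
  hdr_end <- NULL
  limit <- min(length(raw), 4096L)
  for (i in seq_len(limit - 3L))
    if (identical(raw[i:(i + 3L)], end_pat)) { hdr_end <- i + 3L; break }
  if (is.null(hdr_end)) stop("malformed TCK header: no END marker")
  hdr <- strsplit(rawToChar(raw[1:hdr_end]), "\n")[[1]]
  if (hdr[1] != "mrtrix tracks")
    stop("malformed TCK header at offset 0: bad magic line")
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop(sprintf("malformed TCK header: missing '%s'", key))
    sub(paste0("^", key, ": "), "", ln[1])
  }
  if (get_field("datatype") != "Float32LE")
    stop("only Float32LE TCK files are supported")
  off <- as.integer(strsplit(get_field("file"), " ")[[1]][2])
  vals <- readBin(raw[(off + 1L):length(raw)], "numeric",
                  (length(raw) - off) / 4L, size = 4, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- is.nan(m[, 1])
  is_end <- is.infinite(m[, 1])
  fiber <- cumsum(is_sep) + 1L
  keep <- !is_sep & !is_end
  sl <- lapply(split(seq_len(nrow(m))[keep], fiber[keep]), function(ix) {
    pts <- m[ix, , drop = FALSE]
    fa <- if (is.null(field)) NA_real_ else field_fa_at(field, pts)
    new_streamline(pts, fa)
  })
  new_tractogram(unname(sl), NULL, provenance = path)
}

trk_header_skeleton <- function(n_count, dim, voxel_size, vox_to_ras) {
  con <- rawConnection(raw(0), "w")
  writeBin(charToRaw("TRACK"), con); writeBin(raw(1), con)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")  # origin (unused)
  writeBin(0L, con, size = 2, endian = "little")          # n_scalars
  writeBin(raw(200), con)                                 # scalar names
  writeBin(0L, con, size = 2, endian = "little")          # n_properties
  writeBin(raw(200), con)                                 # property names
  writeBin(as.numeric(t(vox_to_ras)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                 # reserved
  writeBin(charToRaw("RAS"), con); writeBin(raw(1), con)  # voxel_order
  writeBin(raw(4), con)                                   # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4,
           endian = "little")                             # img orientation
  writeBin(raw(2), con)                                   # pad1
  writeBin(raw(6), con)                                   # invert/swap flags
  writeBin(as.integer(n_count), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")          # version
  writeBin(1000L, con, size = 4, endian = "little")       # hdr_size
  out <- rawConnectionValue(con)
  close(con)
  stopifnot(length(out) == 1000L)
  out
}

#' Write a tractogram as TRK (TrackVis format)
#'
#' Points are converted from world RAS mm to the TRK voxmm convention
#' using the grid geometry of `field`.
#'
#' @param tractogram a `tractogram`.
#' @param path output path (`.trk`).
#' @param field a [diffusion_field()] defining the voxel grid.
#' @return invisibly, the path.
#' @export
write_trk <- function(tractogram, path, field) {
  sl <- tractogram$streamlines
  vs <- field_voxel_size(field)
  hdr <- trk_header_skeleton(length(sl), dim(field$fa), vs, field$affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (s in sl) {
    vox <- world_to_voxel(field, s$points)
    voxmm <- sweep(vox + 0.5, 2, vs, `*`)
    writeBin(nrow(voxmm), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TRK tractogram
#'
#' Points are converted back to world RAS mm via the header's vox_to_ras
#' and voxel size. Files with per-point scalars or per-track properties
#' are read, with scalars/properties discarded.
#'
#' @param path input path.
#' @param field optional [diffusion_field()] used to resample per-point FA.
#' @return a `tractogram`.
#' @export
read_trk <- function(path, field = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5))
  if (magic != "TRACK") stop("malformed TRK header at offset 0: bad magic")
  readBin(con, "raw", 1)
  invisible(readBin(con, "integer", 3, size = 2, endian = "little"))
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  vox_to_ras <- matrix(readBin(con, "numeric", 16, size = 4,
                               endian = "little"), 4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4)          # reserved, voxel_order, pad2
  readBin(con, "raw", 24 + 2 + 6)           # orientation, pad1, flags
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L)
    stop(sprintf("malformed TRK header at offset 996: hdr_size %d", hdr_size))
  if (all(vox_to_ras == 0))
    stop("TRK header has no vox_to_ras; world coordinates undefined")
  sl <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(np) == 0L) break
    vals <- readBin(con, "numeric", np * (3L + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0)
      readBin(con, "numeric", n_props, size = 4, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    voxmm <- m[, 1:3, drop = FALSE]
    vox <- sweep(voxmm, 2, voxel_size, `/`) - 0.5
    pts <- t(vox_to_ras %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    fa <- if (is.null(field)) NA_real_ else field_fa_at(field, pts)
    sl[[length(sl) + 1L]] <- new_streamline(pts, fa)
  }
  new_tractogram(sl, NULL, provenance = path)
}
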