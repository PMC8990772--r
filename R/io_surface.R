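# FreeSurfer binary triangle-surface dialect (big-endian: a 3-byte magic
# 0xFFFFFE, a creator comment ended by "\n\n", vertex/face counts, float32
# coordinates, int32 0-based faces).

#' Read a FreeSurfer binary surface
#'
#' @param path input path (e.g. `lh.white`).
#' @return a [cortical_mesh()].
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  if (!identical(magic, c(255L, 255L, 254L)))
    stop("not a FreeSurfer binary triangle surface")
  # comment terminated by "\n\n"
  prev <- 0L
  repeat {
    b <- readBin(con, "integer", 1, size = 1, signed = FALSE)
    if (length(b) == 0L) stop("unexpected end of file in surface header")
    if (b == 10L && prev == 10L) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  v <- readBin(con, "numeric", nv * 3L, size = 4, endian = "big")
  f <- readBin(con, "integer", nf * 3L, size = 4, endian = "big")
  cortical_mesh(matrix(v, ncol = 3, byrow = TRUE),
                matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

#' Write a FreeSurfer binary surface
#'
#' @param mesh a [cortical_mesh()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(255L, 255L, 254L)), con, size = 1)
  writeBin(charToRaw("created by sficd\n\n"), con)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}
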