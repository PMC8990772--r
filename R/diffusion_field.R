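#' Per-voxel FA and principal diffusion direction field
#'
#' Container for the two volumes the tracker consumes: a scalar fractional
#' anisotropy (FA) volume and a unit principal-direction vector volume on
#' the same grid, plus the affine mapping 0-based voxel indices to world
#' RAS millimetres.
#'
#' @param fa 3D numeric array, FA in \[0, 1\].
#' @param dirs 4D numeric array `dim = c(dim(fa), 3)`, unit vectors. Sign
#'   is not meaningful (diffusion is axial).
#' @param affine 4x4 matrix, 0-based voxel index -> world RAS mm.
#' @return an object of class `diffusion_field`.
#' @export
diffusion_field <- function(fa, dirs, affine) {
  fa <- as.array(fa)
  if (length(dim(fa)) != 3L) stop("fa must be a 3D array")
  if (!identical(dim(dirs)[1:3], dim(fa)) || dim(dirs)[4] != 3L)
    stop("dims of fa and dirs grids mismatch")
  if (any(fa < 0 | fa > 1)) stop("FA values must lie in [0, 1]")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is not invertible")
  n <- sqrt(dirs[, , , 1]^2 + dirs[, , , 2]^2 + dirs[, , , 3]^2)
  if (max(abs(n - 1)) > 1e-6)
    stop("direction vectors must be unit norm (within 1e-6)")
  structure(list(fa = fa, dirs = dirs, affine = affine,
                 inv_affine = solve(affine)),
            class = "diffusion_field")
}

#' @export
print.diffusion_field <- function(x, ...) {
  d <- dim(x$fa)
  cat(sprintf("diffusion_field: %d x %d x %d voxels, voxel size %s mm\n",
              d[1], d[2], d[3],
              paste(signif(field_voxel_size(x), 4), collapse = " x ")))
  invisible(x)
}

#' Voxel edge lengths (mm) of a field's grid
#' @param field a [diffusion_field()].
#' @export
field_voxel_size <- function(field) {
  vnorm(t(field$affine[1:3, 1:3]))
}

# world mm -> continuous 0-based voxel coordinates (n x 3)
world_to_voxel <- function(field, pts) {
  pts <- rbind_pts(pts)
  t(field$inv_affine %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel coordinates -> world mm
voxel_to_world <- function(field, ijk) {
  ijk <- rbind_pts(ijk)
  t(field$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

rbind_pts <- function(p) {
  if (is.matrix(p)) p else matrix(p, nrow = 1)
}

# nearest-voxel 1-based index of world points; NA rows when outside grid
nearest_voxel_index <- function(field, pts) {
  vc <- round(world_to_voxel(field, pts))
  d <- dim(field$fa)
  bad <- vc[, 1] < 0 | vc[, 1] >= d[1] |
         vc[, 2] < 0 | vc[, 2] >= d[2] |
         vc[, 3] < 0 | vc[, 3] >= d[3]
  vc <- vc + 1
  vc[bad, ] <- NA_real_
  vc
}

#' Sample FA at world points
#'
#' @param field a [diffusion_field()].
#' @param pts n x 3 world coordinates (mm).
#' @param interp `"nearest"` (default, matches discrete FACT-style
#'   tracking) or `"trilinear"`.
#' @return numeric vector; NA outside the grid.
#' @export
field_fa_at <- function(field, pts, interp = c("nearest", "trilinear")) {
  interp <- match.arg(interp)
  pts <- rbind_pts(pts)
  if (interp == "nearest") {
    idx <- nearest_voxel_index(field, pts)
    out <- rep(NA_real_, nrow(pts))
    ok <- !is.na(idx[, 1])
    out[ok] <- field$fa[idx[ok, , drop = FALSE]]
    out
  } else {
    trilinear_sample(field$fa, world_to_voxel(field, pts))
  }
}

trilinear_sample <- function(arr, vc) {
  d <- dim(arr)
  out <- rep(NA_real_, nrow(vc))
  v0 <- floor(vc)
  fr <- vc - v0
  ok <- v0[, 1] >= 0 & v0[, 1] <= d[1] - 2 &
        v0[, 2] >= 0 & v0[, 2] <= d[2] - 2 &
        v0[, 3] >= 0 & v0[, 3] <= d[3] - 2
  if (!any(ok)) return(out)
  v0 <- v0[ok, , drop = FALSE] + 1
  f <- fr[ok, , drop = FALSE]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    acc <- acc + w * arr[cbind(v0[, 1] + dx, v0[, 2] + dy, v0[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

# principal direction at world points (nearest voxel); NA rows outside
field_dir_at <- function(field, pts) {
  pts <- rbind_pts(pts)
  idx <- nearest_voxel_index(field, pts)
  out <- matrix(NA_real_, nrow(pts), 3)
  ok <- !is.na(idx[, 1])
  if (any(ok)) {
    i <- idx[ok, , drop = FALSE]
    out[ok, ] <- cbind(field$dirs[cbind(i, 1)],
                       field$dirs[cbind(i, 2)],
                       field$dirs[cbind(i, 3)])
  }
  out
}

# world coordinates of all voxel centers, in array order
all_voxel_centers <- function(field) {
  d <- dim(field$fa)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  voxel_to_world(field, ijk)
}
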