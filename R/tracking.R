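#' Deterministic tracking parameters
#'
#' Defaults follow common deterministic (FACT-style) practice for
#' short-range fiber extraction: FA threshold 0.14, turning angle 35
#' degrees, step 0.5 mm, direction momentum 0.5, one seed per voxel, and
#' a final length constraint of 10-65 mm.
#'
#' @param fa_threshold FA below which propagation stops.
#' @param angle_threshold maximum turning angle per step (degrees),
#'   checked on the raw (unblended) voxel direction.
#' @param step_size step length (mm).
#' @param smoothing fraction of the previous step direction blended into
#'   the next step (momentum), in \[0, 1\].
#' @param seeds_per_voxel seeds per supra-threshold voxel.
#' @param min_length,max_length length filter bounds (mm), inclusive.
#' @param max_points safety cap on points per half-track.
#' @param interp FA sampling: `"nearest"` or `"trilinear"`.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(fa_threshold = 0.14, angle_threshold = 35,
                            step_size = 0.5, smoothing = 0.5,
                            seeds_per_voxel = 1L, min_length = 10,
                            max_length = 65, max_points = 2000L,
                            interp = c("nearest", "trilinear")) {
  if (step_size <= 0) stop("step_size must be > 0")
  if (smoothing < 0 || smoothing > 1) stop("smoothing must be in [0, 1]")
  if (!(min_length > 0 && min_length < max_length))
    stop("need 0 < min_length < max_length")
  structure(list(fa_threshold = fa_threshold,
                 angle_threshold = angle_threshold,
                 step_size = step_size, smoothing = smoothing,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 min_length = min_length, max_length = max_length,
                 max_points = as.integer(max_points),
                 interp = match.arg(interp)),
            class = "tracking_params")
}

new_streamline <- function(points, fa_values) {
  points <- rbind_pts(points)
  segs <- if (nrow(points) > 1)
    vnorm(points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])
  else numeric(0)
  structure(list(points = points, length = sum(segs),
                 mean_fa = mean(fa_values)),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("streamline: %d points, length %.2f mm, mean FA %.3f\n",
              nrow(x$points), x$length, x$mean_fa))
  invisible(x)
}

# one-directional propagation; returns points beyond the seed (possibly none)
propagate <- function(field, p0, dir0, params) {
  pts <- matrix(NA_real_, params$max_points, 3)
  fas <- numeric(params$max_points)
  n <- 0L
  p <- p0
  prev <- dir0
  cos_thresh <- cos(params$angle_threshold * pi / 180)
  repeat {
    if (n >= params$max_points) break
    d <- field_dir_at(field, p)[1, ]
    if (any(is.na(d))) break
    if (sum(d * prev) < 0) d <- -d          # antipodal sign alignment
    if (sum(d * prev) < cos_thresh) break   # raw turning-angle stop
    step_dir <- unitize(params$smoothing * prev + (1 - params$smoothing) * d)
    pn <- p + params$step_size * step_dir
    fa <- field_fa_at(field, pn, interp = params$interp)
    if (is.na(fa) || fa < params$fa_threshold) break
    n <- n + 1L
    pts[n, ] <- pn
    fas[n] <- fa
    p <- pn
    prev <- step_dir
  }
  list(points = pts[seq_len(n), , drop = FALSE], fa = fas[seq_len(n)])
}

#' Track a single streamline from a seed point
#'
#' Bidirectional deterministic propagation. From the seed, the voxel
#' principal direction is followed in both (antipodal) orientations; at
#' each step the voxel direction is sign-aligned to the previous step
#' direction, checked against the turning-angle threshold, blended with
#' the previous direction by the momentum weight, and the position is
#' advanced by `step_size`. Propagation halts when FA at the new point
#' falls below `fa_threshold`, the raw turn exceeds `angle_threshold`,
#' the track exits the grid, or `max_points` is reached. The two
#' half-tracks are concatenated, sharing the seed point once.
#'
#' @param field a [diffusion_field()].
#' @param seed length-3 world coordinates (mm).
#' @param params a [tracking_params()].
#' @return a `streamline`, or `NULL` when the seed FA is below threshold
#'   or the track has fewer than 2 points.
#' @export
track_from_seed <- function(field, seed, params = tracking_params()) {
  seed <- as.numeric(seed)
  fa0 <- field_fa_at(field, seed, interp = params$interp)
  if (is.na(fa0) || fa0 < params$fa_threshold) return(NULL)
  d0 <- field_dir_at(field, seed)[1, ]
  if (any(is.na(d0))) return(NULL)
  fwd <- propagate(field, seed, d0, params)
  bwd <- propagate(field, seed, -d0, params)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(seed, 1), fwd$points)
  if (nrow(pts) < 2L) return(NULL)
  new_streamline(pts, c(rev(bwd$fa), fa0, fwd$fa))
}

new_tractogram <- function(streamlines, params, provenance = "") {
  structure(list(streamlines = streamlines, space = "RAS mm",
                 params = params, provenance = provenance),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  if (n) {
    len <- vapply(x$streamlines, `[[`, 0, "length")
    cat(sprintf("tractogram: %d streamlines, length %.1f-%.1f mm (median %.1f)\n",
                n, min(len), max(len), median(len)))
  } else cat("tractogram: 0 streamlines\n")
  invisible(x)
}

#' Track the whole volume, one seed per supra-threshold voxel
#'
#' Seeds are placed at the center of every voxel with FA at or above the
#' tracking threshold (deterministic; `rng_seed` is reserved for optional
#' sub-voxel jitter, which is off by default). The resulting streamlines
#' are length-filtered to `[min_length, max_length]`.
#'
#' @param field a [diffusion_field()].
#' @param params a [tracking_params()].
#' @param rng_seed integer; used only when `jitter = TRUE`.
#' @param jitter add uniform sub-voxel jitter to seed positions.
#' @param length_filter apply the length constraint (default TRUE).
#' @return a `tractogram`.
#' @export
track_volume <- function(field, params = tracking_params(), rng_seed = 1L,
                         jitter = FALSE, length_filter = TRUE) {
  d <- dim(field$fa)
  idx <- which(field$fa >= params$fa_threshold)
  if (!length(idx)) return(new_tractogram(list(), params))
  ijk <- arrayInd(idx, d) - 1
  seeds <- voxel_to_world(field, ijk)
  if (params$seeds_per_voxel > 1L)
    seeds <- seeds[rep(seq_len(nrow(seeds)), params$seeds_per_voxel), ,
                   drop = FALSE]
  if (jitter) {
    set.seed(rng_seed)
    vs <- field_voxel_size(field)
    seeds <- seeds + matrix(runif(length(seeds), -0.5, 0.5), ncol = 3) %*%
      diag(vs)
  }
  sl <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds)))
    sl[[i]] <- track_from_seed(field, seeds[i, ], params)
  sl <- sl[!vapply(sl, is.null, TRUE)]
  tg <- new_tractogram(sl, params)
  if (length_filter) filter_by_length(tg, params$min_length, params$max_length)
  else tg
}

#' Keep streamlines within a length range
#'
#' Bounds are inclusive; order is preserved.
#'
#' @param tractogram a `tractogram`.
#' @param min_mm,max_mm length bounds (mm).
#' @return the filtered `tractogram`.
#' @export
filter_by_length <- function(tractogram, min_mm = 10, max_mm = 65) {
  len <- vapply(tractogram$streamlines, `[[`, 0, "length")
  keep <- len >= min_mm & len <= max_mm
  tractogram$streamlines <- tractogram$streamlines[keep]
  tractogram
}

#' Per-fiber summary table
#'
#' @param tractogram a `tractogram`.
#' @return data.frame with fiber index, point count, length (mm), mean FA.
#' @export
tractogram_table <- function(tractogram) {
  sl <- tractogram$streamlines
  data.frame(
    fiber = seq_along(sl),
    n_points = vapply(sl, function(s) nrow(s$points), 0L),
    length_mm = vapply(sl, `[[`, 0, "length"),
    mean_fa = vapply(sl, `[[`, 0, "mean_fa"))
}
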