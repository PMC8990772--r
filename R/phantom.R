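#' Specify a synthetic U-fiber bundle
#'
#' A bundle is a tube of radius `tube_radius` around a circular arc joining
#' two endpoints. The arc is defined by its chord (the endpoints) and its
#' sagitta (`arc_depth`, the perpendicular bulge at the midpoint along
#' `bulge`); `arc_depth = 0` gives a straight segment. The circular-arc
#' parameterization gives the bundle a closed-form length, so tracking can
#' be validated against analytic ground truth.
#'
#' @param endpoint_a,endpoint_b length-3 world coordinates (mm).
#' @param arc_depth sagitta of the arc (mm), >= 0.
#' @param tube_radius tube radius (mm), > 0. The tube has flat caps: a
#'   point belongs to the tube only if its projection falls on the arc,
#'   so every line through a straight bundle has in-tube extent equal to
#'   the chord.
#' @param fa_inside FA value inside the tube, in (0, 1].
#' @param id bundle label.
#' @param bulge length-3 direction of the sagitta (need not be unit; it is
#'   orthogonalized against the chord). Default bulges toward -z, i.e.
#'   beneath a surface sitting above the volume.
#' @return an object of class `bundle_spec`.
#' @export
bundle_spec <- function(endpoint_a, endpoint_b, arc_depth = 0,
                        tube_radius = 1, fa_inside = 0.6,
                        id = "bundle", bulge = c(0, 0, -1)) {
  if (tube_radius <= 0) stop("tube_radius must be > 0")
  if (arc_depth < 0) stop("arc_depth must be >= 0")
  if (fa_inside <= 0 || fa_inside > 1) stop("fa_inside must be in (0, 1]")
  chord <- vnorm(endpoint_b - endpoint_a)
  if (chord <= 0) stop("endpoints must be distinct")
  structure(list(endpoint_a = as.numeric(endpoint_a),
                 endpoint_b = as.numeric(endpoint_b),
                 arc_depth = arc_depth, tube_radius = tube_radius,
                 fa_inside = fa_inside, id = id,
                 bulge = as.numeric(bulge)),
            class = "bundle_spec")
}

#' Closed-form length of a bundle's arc
#'
#' For chord c and sagitta s the circle radius is R = (c^2/4 + s^2)/(2s)
#' and the arc subtends a half-angle alpha = atan2(c/2, R - s), giving
#' length 2 R alpha. A zero sagitta returns the chord.
#'
#' @param bundle a [bundle_spec()].
#' @return arc length (mm).
#' @export
arc_length <- function(bundle) {
  c_ <- vnorm(bundle$endpoint_b - bundle$endpoint_a)
  s <- bundle$arc_depth
  if (s == 0) return(c_)
  R <- (c_^2 / 4 + s^2) / (2 * s)
  alpha <- atan2(c_ / 2, R - s)
  2 * R * alpha
}

# sample n points (and unit tangents) along the arc, endpoint to endpoint
arc_points <- function(bundle, n = 200) {
  a <- bundle$endpoint_a; b <- bundle$endpoint_b
  u <- unitize(b - a)
  s <- bundle$arc_depth
  if (s == 0) {
    t <- seq(0, 1, length.out = n)
    pts <- outer(rep(1, n), a) + outer(t, b - a)
    return(list(points = pts, tangents = outer(rep(1, n), u)))
  }
  w <- bundle$bulge - sum(bundle$bulge * u) * u
  if (vnorm(w) < 1e-12)
    stop(sprintf("bundle '%s': bulge direction parallel to chord", bundle$id))
  w <- unitize(w)
  c_ <- vnorm(b - a)
  R <- (c_^2 / 4 + s^2) / (2 * s)
  alpha <- atan2(c_ / 2, R - s)
  m <- (a + b) / 2
  center <- m + s * w - R * w
  t <- seq(-alpha, alpha, length.out = n)
  pts <- outer(rep(1, n), center) +
    R * (outer(cos(t), w) + outer(sin(t), u))
  tan_ <- -outer(sin(t), w) + outer(cos(t), u)
  list(points = pts, tangents = tan_)
}

#' Specify a synthetic diffusion phantom
#'
#' @param grid_shape length-3 integer, voxels per axis.
#' @param voxel_size length-3 numeric, mm per axis.
#' @param bundles list of [bundle_spec()].
#' @param fa_background background FA; must stay below the tracking FA
#'   threshold so background voxels do not track.
#' @param noise_sd_fa SD of additive Gaussian FA noise (clipped to \[0,1\]).
#' @param noise_sd_dir_deg angular SD (degrees) of a random rotation
#'   applied to in-tube directions.
#' @param origin world position (mm) of the center of voxel (0,0,0).
#' @param rng_seed integer seed; the generator is fully reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size = c(0.5, 0.5, 0.5),
                         bundles = list(), fa_background = 0.05,
                         noise_sd_fa = 0, noise_sd_dir_deg = 0,
                         origin = c(0, 0, 0), rng_seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("grid_shape must be 3 positive integers")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (fa_background < 0 || fa_background > 1) stop("fa_background in [0,1]")
  if (noise_sd_fa < 0 || noise_sd_dir_deg < 0) stop("noise SDs must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 bundles = bundles, fa_background = fa_background,
                 noise_sd_fa = noise_sd_fa,
                 noise_sd_dir_deg = noise_sd_dir_deg,
                 origin = as.numeric(origin),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

phantom_affine <- function(spec) {
  A <- diag(4)
  A[1, 1] <- spec$voxel_size[1]
  A[2, 2] <- spec$voxel_size[2]
  A[3, 3] <- spec$voxel_size[3]
  A[1:3, 4] <- spec$origin
  A
}

#' Generate a synthetic diffusion field with ground truth
#'
#' Rasterizes each bundle into the grid: every voxel whose center lies
#' within `tube_radius` of the bundle's arc (with flat end caps) receives
#' FA `fa_inside` and the local arc tangent as its principal direction;
#' all other voxels receive the background FA and a random unit direction.
#' FA noise is additive Gaussian clipped to \[0, 1\]; direction noise is a
#' random small rotation (so vectors stay exactly unit norm); every
#' direction's sign is then randomized, since diffusion directions are
#' axial and the tracker must handle antipodal symmetry.
#'
#' @param spec a [phantom_spec()].
#' @return list with `field` (a [diffusion_field()]) and `ground_truth`,
#'   a data.frame with one row per bundle: id, analytic arc length (mm),
#'   fa_inside, endpoint coordinates, and in-tube voxel count.
#' @export
generate_diffusion_field <- function(spec) {
  set.seed(spec$rng_seed)
  d <- spec$grid_shape
  nvox <- prod(d)
  A <- phantom_affine(spec)

  # background: FA + random unit directions
  fa <- array(spec$fa_background, dim = d)
  theta <- acos(runif(nvox, -1, 1)); phi <- runif(nvox, 0, 2 * pi)
  dirs <- array(0, dim = c(d, 3))
  dirs[, , , 1] <- sin(theta) * cos(phi)
  dirs[, , , 2] <- sin(theta) * sin(phi)
  dirs[, , , 3] <- cos(theta)

  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  centers <- t(A %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  lo <- centers[1, ] - spec$voxel_size / 2
  hi <- centers[nvox, ] + spec$voxel_size / 2

  gt <- list()
  nvox_in <- integer(length(spec$bundles))
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    n_samp <- max(50L, ceiling(arc_length(b) / (min(spec$voxel_size) / 4)))
    arc <- arc_points(b, n_samp)
    if (any(t(arc$points) - b$tube_radius < lo) ||
        any(t(arc$points) + b$tube_radius > hi))
      stop(sprintf("bundle '%s' extends outside the grid", b$id))

    # candidate voxels: bounding box of the tube
    bb_lo <- apply(arc$points, 2, min) - b$tube_radius
    bb_hi <- apply(arc$points, 2, max) + b$tube_radius
    cand <- which(centers[, 1] >= bb_lo[1] & centers[, 1] <= bb_hi[1] &
                  centers[, 2] >= bb_lo[2] & centers[, 2] <= bb_hi[2] &
                  centers[, 3] >= bb_lo[3] & centers[, 3] <= bb_hi[3])
    if (length(cand)) {
      cc <- centers[cand, , drop = FALSE]
      # nearest arc sample per candidate voxel
      d2 <- matrix(Inf, length(cand), 1)
      nearest <- integer(length(cand))
      # chunk over arc samples to bound memory
      dist2 <- outer(rowSums(cc^2), rep(1, n_samp)) -
        2 * cc %*% t(arc$points) +
        outer(rep(1, length(cand)), rowSums(arc$points^2))
      nearest <- max.col(-dist2, ties.method = "first")
      mind2 <- dist2[cbind(seq_along(cand), nearest)]
      inside <- mind2 <= b$tube_radius^2
      # flat caps: drop points whose nearest sample is an arc end and
      # which project beyond that end along the end tangent
      at_start <- inside & nearest == 1L
      if (any(at_start)) {
        proj <- (cc[at_start, , drop = FALSE] -
                   outer(rep(1, sum(at_start)), arc$points[1, ])) %*%
          arc$tangents[1, ]
        inside[at_start][proj < 0] <- FALSE
      }
      at_end <- inside & nearest == n_samp
      if (any(at_end)) {
        proj <- (cc[at_end, , drop = FALSE] -
                   outer(rep(1, sum(at_end)), arc$points[n_samp, ])) %*%
          arc$tangents[n_samp, ]
        inside[at_end][proj > 0] <- FALSE
      }
      vin <- cand[inside]
      nvox_in[bi] <- length(vin)
      fa[vin] <- b$fa_inside
      tang <- arc$tangents[nearest[inside], , drop = FALSE]
      dirs[vin] <- tang[, 1]
      dirs[vin + nvox] <- tang[, 2]
      dirs[vin + 2 * nvox] <- tang[, 3]
    }
    gt[[bi]] <- data.frame(
      id = b$id, length_mm = arc_length(b), fa_inside = b$fa_inside,
      ax = b$endpoint_a[1], ay = b$endpoint_a[2], az = b$endpoint_a[3],
      bx = b$endpoint_b[1], by = b$endpoint_b[2], bz = b$endpoint_b[3])
  }

  if (spec$noise_sd_fa > 0)
    fa <- clamp(fa + rnorm(nvox, 0, spec$noise_sd_fa), 0, 1)

  dm <- matrix(c(dirs[, , , 1], dirs[, , , 2], dirs[, , , 3]), ncol = 3)
  if (spec$noise_sd_dir_deg > 0)
    dm <- rotate_randomly(dm, spec$noise_sd_dir_deg)
  # randomize axial sign
  flip <- sample(c(-1, 1), nvox, replace = TRUE)
  dm <- dm * flip
  dirs <- array(dm, dim = c(d, 3))

  field <- diffusion_field(fa, dirs, A)
  gt <- do.call(rbind, gt)
  if (!is.null(gt)) gt$n_voxels <- nvox_in
  list(field = field, ground_truth = gt)
}

# rotate each row of v by an angle ~ |N(0, sd_deg)| about a random axis
# perpendicular to v (keeps unit norm exactly)
rotate_randomly <- function(v, sd_deg) {
  n <- nrow(v)
  ang <- rnorm(n, 0, sd_deg * pi / 180)
  # random perpendicular direction
  r <- matrix(rnorm(3 * n), n, 3)
  perp <- r - rowSums(r * v) * v
  bad <- vnorm(perp) < 1e-12
  if (any(bad)) perp[bad, ] <- matrix(rnorm(3 * sum(bad)), ncol = 3)
  perp <- perp / vnorm(perp)
  cos(ang) * v + sin(ang) * perp
}
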