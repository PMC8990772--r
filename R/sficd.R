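#' Assign fibers to cortical units by endpoint membership
#'
#' A fiber connects to a CU iff either of its two terminal points falls in
#' a voxel of that CU's mask. A fiber whose endpoints land in two
#' different CUs is listed under both; a fiber with both endpoints in the
#' same CU is listed once; fibers touching no mask are unassigned.
#'
#' @param tractogram a `tractogram`.
#' @param masks a `cu_masks` from [cu_voxel_layer()].
#' @param field the [diffusion_field()] supplying the grid geometry.
#' @return list of integer vectors (fiber indices), one per CU.
#' @export
assign_fibers <- function(tractogram, masks, field) {
  sl <- tractogram$streamlines
  K <- length(masks$masks)
  out <- rep(list(integer(0)), K)
  if (!length(sl)) return(out)
  ends <- do.call(rbind, lapply(sl, function(s)
    s$points[c(1L, nrow(s$points)), , drop = FALSE]))
  idx <- nearest_voxel_index(field, ends)
  d <- masks$grid_dim
  lin <- idx[, 1] + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2]
  # voxel -> CU lookup
  vox_all <- unlist(masks$masks, use.names = FALSE)
  cu_all <- rep(seq_len(K), times = lengths(masks$masks))
  m <- match(lin, vox_all)
  cu_hit <- cu_all[m]                         # NA when endpoint in no mask
  fiber <- rep(seq_along(sl), each = 2L)
  ok <- !is.na(cu_hit)
  df <- unique(data.frame(fiber = fiber[ok], cu = cu_hit[ok]))
  for (k in unique(df$cu)) out[[k]] <- df$fiber[df$cu == k]
  out
}

#' Short-range fiber connectivity density of one cortical unit
#'
#' SFiCD = sum over connecting fibers f of mean FA_f, divided by the CU's
#' subcortical volume V_CU (mm^-3).
#'
#' @param fiber_fas mean FA of each connecting fiber.
#' @param volume_mm3 CU volume (mm^3), > 0.
#' @return SFiCD in mm^-3.
#' @export
compute_sficd <- function(fiber_fas, volume_mm3) {
  stopifnot_scalar(volume_mm3, "volume_mm3")
  if (volume_mm3 <= 0) stop("CU volume must be > 0 (flagged CU)")
  sum(fiber_fas) / volume_mm3
}

#' Per-CU SFiCD table for a subject
#'
#' Runs [assign_fibers()] and [compute_sficd()] over all CUs. Flagged
#' (zero-volume) CUs get `NA`, never zero: zero would conflate "no data"
#' with "no connectivity".
#'
#' @inheritParams assign_fibers
#' @return data.frame: cu_id (0-based), n_fibers, sum_fa, volume_mm3,
#'   sficd.
#' @export
sficd_per_cu <- function(tractogram, masks, field) {
  assigned <- assign_fibers(tractogram, masks, field)
  mean_fas <- vapply(tractogram$streamlines, `[[`, 0, "mean_fa")
  K <- length(masks$masks)
  sum_fa <- vapply(assigned, function(ix) sum(mean_fas[ix]), 0)
  n_fib <- lengths(assigned)
  sficd <- ifelse(masks$flagged, NA_real_, sum_fa / masks$volumes_mm3)
  data.frame(cu_id = 0:(K - 1L), n_fibers = n_fib, sum_fa = sum_fa,
             volume_mm3 = masks$volumes_mm3, sficd = sficd)
}

#' Project per-CU values to a per-vertex surface map
#'
#' Each vertex receives its CU's value; vertices of flagged CUs carry
#' `NA`, which smoothing and statistics treat as missing.
#'
#' @param parc a [parcellation()].
#' @param cu_values numeric vector, one value per CU (NA for flagged CUs).
#' @return numeric per-vertex map.
#' @export
project_to_vertices <- function(parc, cu_values) {
  if (length(cu_values) != parc$K) stop("need one value per CU")
  as.numeric(cu_values[parc$labels + 1L])
}

#' Carry a subject map onto a template surface
#'
#' Values are transported through a supplied subject-to-template vertex
#' correspondence (nearest-correspondent assignment). Spherical
#' registration of real brains is out of scope and must be provided
#' externally; for synthetic cohorts sharing one template mesh the
#' correspondence is the identity.
#'
#' @param map per-vertex values on the subject mesh.
#' @param correspondence integer vector, one entry per template vertex,
#'   giving the corresponding subject vertex index.
#' @return per-vertex values on the template mesh; missing values
#'   propagate.
#' @export
normalize_to_template <- function(map, correspondence) {
  if (missing(correspondence) || is.null(correspondence))
    stop("a subject-to-template vertex correspondence is required")
  if (any(correspondence < 1 | correspondence > length(map)))
    stop("correspondence indexes outside the subject map")
  map[correspondence]
}

#' Geodesic Gaussian smoothing operator for a mesh
#'
#' Builds a sparse row-stochastic matrix W with
#' `W[v, u] ~ exp(-d(v,u)^2 / (2 sigma^2))` for graph-geodesic distances
#' `d <= 2.5 sigma` (under 1% of kernel mass lost before renormalization),
#' `sigma = fwhm / sqrt(8 log 2)`. Rows are normalized to sum to 1, so
#' constant maps are fixed points. Precompute once per mesh and reuse via
#' the `operator` argument of [smooth_surface()] when smoothing many maps.
#'
#' @param mesh a [cortical_mesh()].
#' @param fwhm_mm kernel full width at half maximum (mm), > 0.
#' @return a `dgCMatrix` of dimension n x n.
#' @export
smoothing_operator <- function(mesh, fwhm_mm) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  sigma <- fwhm_to_sigma(fwhm_mm)
  cutoff <- 2.5 * sigma
  g <- mesh_graph(mesh)
  n <- nrow(mesh$vertices)
  D <- igraph::distances(g, mode = "all")
  D[D > cutoff] <- Inf
  W <- exp(-D^2 / (2 * sigma^2))
  W[!is.finite(W)] <- 0
  W <- Matrix::Matrix(W, sparse = TRUE)
  rs <- Matrix::rowSums(W)
  Matrix::Diagonal(x = 1 / rs) %*% W
}

#' Smooth a surface map with a geodesic Gaussian kernel
#'
#' Missing vertices are excluded from every kernel and the remaining
#' weights renormalized; vertices that are themselves missing stay
#' missing. `fwhm_mm = 0` is the identity.
#'
#' @param map per-vertex values (may contain NA).
#' @param mesh a [cortical_mesh()].
#' @param fwhm_mm kernel FWHM in mm (default 15).
#' @param operator optional precomputed [smoothing_operator()]; when
#'   given, `mesh`/`fwhm_mm` are not used to rebuild it.
#' @return smoothed per-vertex map.
#' @export
smooth_surface <- function(map, mesh, fwhm_mm = 15, operator = NULL) {
  if (is.null(operator)) {
    if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
    if (fwhm_mm == 0) return(map)
    operator <- smoothing_operator(mesh, fwhm_mm)
  }
  miss <- is.na(map)
  if (!any(miss)) return(as.numeric(operator %*% map))
  x <- ifelse(miss, 0, map)
  num <- as.numeric(operator %*% x)
  den <- as.numeric(operator %*% as.numeric(!miss))
  out <- num / den
  out[miss | den == 0] <- NA_real_
  out
}
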