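#' Parcellate a mesh into contiguous near-equal-area cortical units
#'
#' Farthest-point sampling of K seed vertices on the mesh's edge graph
#' (graph-geodesic distances, Euclidean edge weights) followed by geodesic
#' Voronoi labeling and a contiguity repair pass. The first seed is drawn
#' from `rng_seed`; everything after is deterministic, so the same seed
#' always yields the same parcellation. On a disconnected mesh the K units
#' are allocated to components proportionally to vertex count (at least
#' one each).
#'
#' @param mesh a [cortical_mesh()].
#' @param K number of cortical units (CUs); default 1000, must not exceed
#'   the vertex count.
#' @param rng_seed integer; picks the first seed vertex.
#' @return An object of class `parcellation`: `labels` (per-vertex CU id
#'   in 0..K-1), `K`, `seeds` (per-CU seed vertex index), and `cu_areas`
#'   (mm^2, from the per-vertex areas).
#' @export
parcellate <- function(mesh, K = 1000L, rng_seed = 1L) {
  nv <- nrow(mesh$vertices)
  K <- as.integer(K)
  if (K > nv) stop("K exceeds the number of mesh vertices")
  if (K < 1L) stop("K must be >= 1")
  g <- mesh_graph(mesh)
  comp <- igraph::components(g)
  set.seed(rng_seed)

  labels <- integer(nv)
  seeds <- integer(K)
  # allocate CUs to components proportionally (>= 1 each)
  nc <- comp$no
  if (nc > K) stop("mesh has more components than K")
  alloc <- pmax(1L, floor(K * comp$csize / nv))
  while (sum(alloc) < K) {
    i <- which.max(comp$csize / alloc)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > K) {
    i <- which(alloc > 1L)[which.max(alloc[alloc > 1L] / comp$csize[alloc > 1L])]
    alloc[i] <- alloc[i] - 1L
  }

  next_id <- 0L
  for (ci in seq_len(nc)) {
    vids <- which(comp$membership == ci)
    k_c <- alloc[ci]
    sub <- igraph::induced_subgraph(g, vids)
    n_c <- length(vids)
    s1 <- sample.int(n_c, 1L)
    sds <- integer(k_c)
    sds[1] <- s1
    dmin <- as.vector(igraph::distances(sub, v = s1))
    if (k_c > 1L) for (j in 2:k_c) {
      s <- which.max(dmin)
      sds[j] <- s
      dmin <- pmin(dmin, as.vector(igraph::distances(sub, v = s)))
    }
    D <- igraph::distances(sub, v = sds)      # k_c x n_c
    lab_local <- max.col(-t(D), ties.method = "first")
    lab_local <- repair_contiguity(sub, lab_local, sds)
    labels[vids] <- next_id + lab_local - 1L
    seeds[next_id + seq_len(k_c)] <- vids[sds]
    next_id <- next_id + k_c
  }

  cu_areas <- as.vector(tapply(mesh$vertex_areas,
                               factor(labels, levels = 0:(K - 1L)),
                               sum, default = 0))
  structure(list(labels = labels, K = K, seeds = seeds,
                 cu_areas = cu_areas),
            class = "parcellation")
}

# reassign vertices of label fragments not containing their seed to the
# majority neighboring label, iterating until all labels are connected
repair_contiguity <- function(g, labels, seeds) {
  adj <- igraph::as_adj_list(g, mode = "all")
  for (iter in 1:100) {
    moved <- FALSE
    for (lab in sort(unique(labels))) {
      vs <- which(labels == lab)
      sub <- igraph::induced_subgraph(g, vs)
      cc <- igraph::components(sub)
      if (cc$no <= 1L) next
      seed_comp <- cc$membership[match(seeds[lab], vs)]
      if (is.na(seed_comp)) seed_comp <- which.max(cc$csize)
      for (frag in setdiff(seq_len(cc$no), seed_comp)) {
        fv <- vs[cc$membership == frag]
        for (v in fv) {
          nb_labs <- labels[unlist(adj[[v]])]
          nb_labs <- nb_labs[nb_labs != lab]
          if (length(nb_labs)) {
            tab <- table(nb_labs)
            labels[v] <- as.integer(names(tab)[which.max(tab)])
            moved <- TRUE
          }
        }
      }
    }
    if (!moved) break
  }
  labels
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d CUs over %d vertices, CU area %.2f-%.2f mm^2\n",
              x$K, length(x$labels), min(x$cu_areas), max(x$cu_areas)))
  invisible(x)
}

#' Subcortical voxel-layer masks for each cortical unit
#'
#' For every CU, collects the voxels whose centers lie within `depth_mm`
#' beneath the CU's surface, by sampling along the inward vertex normals
#' at sub-voxel spacing. A voxel reached from several CUs is assigned to
#' the CU whose claiming surface vertex is nearest (ties to the lower CU
#' id), so masks are disjoint and fibers at CU borders are never counted
#' twice. CUs that capture no voxel are flagged and must be excluded from
#' statistics.
#'
#' @param parc a [parcellation()].
#' @param mesh the parcellated [cortical_mesh()] (same world space as the
#'   grid).
#' @param field a [diffusion_field()] supplying the grid geometry.
#' @param depth_mm sampling depth beneath the surface (mm); the default 2
#'   is one voxel along a typical 2 mm slice pitch.
#' @return An object of class `cu_masks`: list with `masks` (per CU: 1-based
#'   linear voxel indices into the grid), `volumes_mm3`, `flagged`
#'   (logical, CUs with empty masks), and `voxel_cu` (named map from
#'   voxel index to CU id).
#' @export
cu_voxel_layer <- function(parc, mesh, field, depth_mm = 2) {
  if (depth_mm < 0) stop("depth_mm must be >= 0")
  d <- dim(field$fa)
  nvert <- nrow(mesh$vertices)
  vs <- field_voxel_size(field)
  voxvol <- prod(vs)
  step <- min(vs) / 2
  offs <- if (depth_mm > 0) seq(0, depth_mm, by = step) else numeric(0)
  # include the exact depth endpoint
  if (depth_mm > 0 && offs[length(offs)] < depth_mm) offs <- c(offs, depth_mm)

  if (length(offs)) {
    inward <- -mesh$vertex_normals
    # sample points: nvert * length(offs) rows
    pts <- do.call(rbind, lapply(offs, function(o) mesh$vertices + o * inward))
    src_vert <- rep(seq_len(nvert), times = length(offs))
    idx <- nearest_voxel_index(field, pts)
    ok <- !is.na(idx[, 1])
    lin <- idx[ok, 1] + (idx[ok, 2] - 1) * d[1] + (idx[ok, 3] - 1) * d[1] * d[2]
    src_vert <- src_vert[ok]
    pts <- pts[ok, , drop = FALSE]
    # distance from the voxel center to the claiming surface vertex
    centers <- voxel_to_world(field, idx[ok, , drop = FALSE] - 1)
    dist2 <- rowSums((centers - mesh$vertices[src_vert, , drop = FALSE])^2)
    cu <- parc$labels[src_vert]
    o <- order(lin, dist2, cu)   # per voxel: nearest vertex, then lower CU id
    lin_o <- lin[o]
    first <- !duplicated(lin_o)
    vox <- lin_o[first]
    vox_cu <- cu[o][first]
  } else {
    vox <- integer(0); vox_cu <- integer(0)
  }

  masks <- split(vox, factor(vox_cu, levels = 0:(parc$K - 1L)))
  volumes <- vapply(masks, length, 0L) * voxvol
  flagged <- vapply(masks, length, 0L) == 0L
  if (any(flagged))
    warning(sprintf("%d CU(s) captured no voxels and were flagged: %s",
                    sum(flagged),
                    paste(utils::head(which(flagged) - 1L, 10), collapse = ", ")))
  structure(list(masks = masks, volumes_mm3 = unname(volumes),
                 flagged = unname(flagged),
                 grid_dim = d, voxel_volume_mm3 = voxvol),
            class = "cu_masks")
}

#' @export
print.cu_masks <- function(x, ...) {
  cat(sprintf("cu_masks: %d CUs, %d flagged empty, median volume %.2f mm^3\n",
              length(x$masks), sum(x$flagged), median(x$volumes_mm3)))
  invisible(x)
}
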