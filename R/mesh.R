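#' Triangulated cortical surface mesh
#'
#' Container for a triangulated gray-white interface mesh: vertex
#' coordinates in world millimetres, triangular faces, per-vertex areas
#' (one third of the area of each incident face) and the vertex adjacency
#' implied by the edges. All geodesic operations in the package use
#' shortest paths on the edge graph weighted by Euclidean edge length.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return An object of class `cortical_mesh` with elements `vertices`,
#'   `faces`, `vertex_areas` (mm^2), `face_areas`, `vertex_normals`
#'   (unit, area-weighted), `edges` (2-column index matrix) and
#'   `edge_lengths` (mm).
#' @export
cortical_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(faces) != 3L) stop("faces must be m x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("faces index vertices outside 1..n")

  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(p2 - p1, p3 - p1)
  face_areas <- 0.5 * vnorm(cr)
  face_normals <- cr / pmax(vnorm(cr), .Machine$double.eps)

  n <- nrow(vertices)
  vertex_areas <- numeric(n)
  w <- rep(face_areas / 3, 3L)
  idx <- as.vector(faces)
  vertex_areas <- as.vector(tapply(w, factor(idx, levels = seq_len(n)), sum,
                                   default = 0))

  # area-weighted vertex normals
  vn <- matrix(0, n, 3)
  for (j in 1:3) {
    contrib <- face_normals * face_areas
    vn[, 1] <- vn[, 1] + as.vector(tapply(contrib[, 1],
      factor(faces[, j], levels = seq_len(n)), sum, default = 0))
    vn[, 2] <- vn[, 2] + as.vector(tapply(contrib[, 2],
      factor(faces[, j], levels = seq_len(n)), sum, default = 0))
    vn[, 3] <- vn[, 3] + as.vector(tapply(contrib[, 3],
      factor(faces[, j], levels = seq_len(n)), sum, default = 0))
  }
  nz <- vnorm(vn) > 0
  vn[nz, ] <- vn[nz, ] / vnorm(vn[nz, , drop = FALSE])

  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  el <- vnorm(vertices[e[, 1], , drop = FALSE] - vertices[e[, 2], , drop = FALSE])

  structure(list(
    vertices = vertices, faces = faces,
    vertex_areas = vertex_areas, face_areas = face_areas,
    vertex_normals = vn, edges = e, edge_lengths = el
  ), class = "cortical_mesh")
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [cortical_mesh()].
#' @export
mesh_area <- function(mesh) sum(mesh$face_areas)

#' Edge graph of a mesh, weighted by Euclidean edge length
#'
#' @param mesh a [cortical_mesh()].
#' @return An igraph graph with `weight` edge attribute (mm).
#' @export
mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = mesh$edge_lengths)
}

#' Generate a synthetic cortical sheet mesh
#'
#' Builds a regular triangulated sheet in the xy plane, optionally with a
#' sinusoidal undulation along x to mimic gyral folding. Normals point
#' toward +z for the flat sheet (the "pial" side); the subcortical voxel
#' layer therefore lies at negative z offsets along the inward normal.
#'
#' @param extent_mm length-2 numeric, sheet size along x and y (mm).
#' @param vertex_spacing_mm grid spacing (mm), > 0.
#' @param undulation_amplitude_mm amplitude of the sinusoidal height field
#'   (mm); 0 gives a flat sheet.
#' @param undulation_wavelength_mm wavelength of the undulation (mm).
#' @param origin length-3 numeric, world position of the sheet corner.
#' @return a [cortical_mesh()].
#' @export
generate_sheet_mesh <- function(extent_mm, vertex_spacing_mm,
                                undulation_amplitude_mm = 0,
                                undulation_wavelength_mm = 10,
                                origin = c(0, 0, 0)) {
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 2L)
  if (vertex_spacing_mm <= 0) stop("vertex_spacing_mm must be > 0")
  if (any(extent_mm <= 0)) stop("degenerate extent")
  xs <- seq(0, extent_mm[1], by = vertex_spacing_mm)
  ys <- seq(0, extent_mm[2], by = vertex_spacing_mm)
  nx <- length(xs); ny <- length(ys)
  if (nx < 2L || ny < 2L) stop("degenerate extent")
  g <- expand.grid(x = xs, y = ys)
  z <- undulation_amplitude_mm *
    sin(2 * pi * g$x / undulation_wavelength_mm)
  v <- cbind(g$x + origin[1], g$y + origin[2], z + origin[3])

  # two CCW (viewed from +z) triangles per grid quad
  ii <- rep(seq_len(nx - 1L), ny - 1L)
  jj <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (jj - 1L) * nx + ii
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v01), cbind(v10, v11, v01))
  cortical_mesh(v, faces)
}

#' Combine meshes into one (possibly disconnected) mesh
#'
#' Concatenates vertex and face lists; the components stay disconnected.
#' Useful for modelling separate patches (or hemispheres) as one surface.
#'
#' @param ... [cortical_mesh()] objects.
#' @return a [cortical_mesh()].
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  off <- 0L
  v <- NULL; f <- NULL
  for (m in ms) {
    v <- rbind(v, m$vertices)
    f <- rbind(f, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  cortical_mesh(v, f)
}

#' Generate an icosphere mesh
#'
#' Repeated 4-way subdivision of an icosahedron projected to a sphere.
#' Used as a closed-surface test bed for parcellation (2562 vertices at
#' 4 subdivisions).
#'
#' @param subdivisions number of subdivision rounds (0 = icosahedron).
#' @param radius sphere radius (mm).
#' @return a [cortical_mesh()].
#' @export
generate_icosphere <- function(subdivisions = 4, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / vnorm(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- unitize((v[a, ] + v[b, ]) / 2)
      newv[[length(newv) + 1L]] <<- p
      m <- nv + length(newv)
      edge_mid[[key]] <- m
      m
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  cortical_mesh(v * radius, f)
}
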