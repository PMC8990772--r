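# Shared fixtures, built in code. Expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# straight 12 mm bundle in a thin (sub-voxel) tube: tracking recovers the
# chord exactly under nearest-voxel sampling
straight_bundle_phantom <- function(noise_sd_fa = 0, rng_seed = 3) {
  b <- bundle_spec(c(4, 5, 5), c(16, 5, 5), arc_depth = 0,
                   tube_radius = 0.45, fa_inside = 0.6, id = "straight12")
  generate_diffusion_field(phantom_spec(
    grid_shape = c(40, 20, 20), voxel_size = c(0.5, 0.5, 0.5),
    bundles = list(b), noise_sd_fa = noise_sd_fa, rng_seed = rng_seed))
}

# semicircular bundle (chord 10, sagitta 5 -> length 5*pi) in a thick,
# well-resolved tube; its apex voxel center sits on the arc
semicircle_phantom <- function(tube_radius = 2, rng_seed = 4) {
  b <- bundle_spec(c(10, 6, 9), c(20, 6, 9), arc_depth = 5,
                   tube_radius = tube_radius, fa_inside = 0.6, id = "semi")
  list(phantom = generate_diffusion_field(phantom_spec(
         grid_shape = c(60, 24, 26), bundles = list(b), rng_seed = rng_seed)),
       bundle = b, apex = c(15, 6, 4))
}

# uniform +x direction field in a 20 mm box (no phantom machinery)
uniform_x_field <- function(fa = 0.8, n = c(40, 20, 20), voxel = 0.5) {
  fa_arr <- array(fa, n)
  dirs <- array(0, c(n, 3))
  dirs[, , , 1] <- 1
  diffusion_field(fa_arr, dirs, diag(c(rep(voxel, 3), 1)))
}

# in-plane circular direction field around the grid center
circular_field <- function(voxel, nxy, fa = 0.8) {
  ctr <- (nxy - 1) / 2 * voxel
  d <- c(nxy, nxy, 3)
  fa_arr <- array(fa, d)
  dirs <- array(0, c(d, 3))
  for (i in seq_len(nxy)) for (j in seq_len(nxy)) {
    x <- (i - 1) * voxel - ctr
    y <- (j - 1) * voxel - ctr
    r <- sqrt(x^2 + y^2)
    if (r < voxel / 2) {
      fa_arr[i, j, ] <- 0
      dirs[i, j, , 1] <- 1
    } else {
      dirs[i, j, , 1] <- -y / r
      dirs[i, j, , 2] <- x / r
    }
  }
  list(field = diffusion_field(fa_arr, dirs, diag(c(voxel, voxel, voxel, 1))),
       center = c(ctr, ctr))
}

# two identical sheets over two mirrored U-bundles of FA 0.6 and 0.4;
# K = 2 gives one CU per sheet with exactly equal geometry
two_bundle_setup <- function() {
  cached("two_bundle_setup", {
    mesh <- merge_meshes(
      generate_sheet_mesh(c(20, 8), 0.5, origin = c(8, 11, 13)),
      generate_sheet_mesh(c(20, 8), 0.5, origin = c(8, 21, 13)))
    b1 <- bundle_spec(c(12, 15, 12), c(24, 15, 12), arc_depth = 4,
                      tube_radius = 0.8, fa_inside = 0.6, id = "u_strong")
    b2 <- bundle_spec(c(12, 25, 12), c(24, 25, 12), arc_depth = 4,
                      tube_radius = 0.8, fa_inside = 0.4, id = "u_weak")
    ph <- generate_diffusion_field(phantom_spec(
      c(80, 80, 30), bundles = list(b1, b2), rng_seed = 11))
    tg <- track_volume(ph$field, tracking_params())
    parc <- parcellate(mesh, K = 2, rng_seed = 7)
    masks <- cu_voxel_layer(parc, mesh, ph$field, depth_mm = 2)
    list(mesh = mesh, phantom = ph, tractogram = tg, parc = parc,
         masks = masks)
  })
}

# coarse flat sheet used for cohort statistics (961 vertices, 2 mm spacing)
stats_mesh <- function() {
  cached("stats_mesh",
         generate_sheet_mesh(c(60, 60), 2, origin = c(-30, -30, 0)))
}

# fine flat sheet for smoothing calibration (3721 vertices, 1 mm spacing)
fine_sheet <- function() {
  cached("fine_sheet",
         generate_sheet_mesh(c(60, 60), 1, origin = c(-30, -30, 0)))
}

fine_sheet_operator <- function() {
  cached("fine_sheet_operator", smoothing_operator(fine_sheet(), 15))
}

stats_mesh_null_areas <- function() {
  cached("stats_mesh_null_areas",
         null_max_cluster_areas(stats_mesh(), fwhm_mm = 15, vertex_p = 0.01,
                                n_iter = 1000, rng_seed = 99))
}

expect_points_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}
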