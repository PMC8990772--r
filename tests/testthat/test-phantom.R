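test_that("arc length closed form: chord, semicircle, and polyline agreement", {
  straight <- bundle_spec(c(0, 0, 0), c(12, 0, 0), arc_depth = 0)
  expect_equal(arc_length(straight), 12)

  semi <- bundle_spec(c(0, 0, 0), c(10, 0, 0), arc_depth = 5)
  expect_equal(arc_length(semi), 5 * pi, tolerance = 1e-12)

  # polyline integration agrees with the closed form within 0.1 %
  for (s in c(0.5, 2, 5, 8)) {
    b <- bundle_spec(c(0, 0, 0), c(10, 0, 0), arc_depth = s)
    pts <- sficd:::arc_points(b, 2000)$points
    poly <- sum(sqrt(rowSums(diff(pts)^2)))
    expect_equal(poly, arc_length(b), tolerance = 1e-3)
  }
})

test_that("zero-noise phantom rasterizes exact FA and tangent directions", {
  ph <- straight_bundle_phantom(noise_sd_fa = 0)
  field <- ph$field
  expect_equal(ph$ground_truth$length_mm, 12)
  in_tube <- which(field$fa == 0.6)
  expect_equal(length(in_tube), ph$ground_truth$n_voxels)
  expect_gt(length(in_tube), 0)
  # all other voxels at background
  expect_true(all(field$fa[-in_tube] == 0.05))
  # in-tube directions are +-x (the chord tangent)
  d <- dim(field$fa)
  nvox <- prod(d)
  dx <- abs(field$dirs[in_tube])
  expect_equal(max(abs(dx - 1)), 0, tolerance = 1e-12)
})

test_that("FA stays in [0,1] and directions unit under noise", {
  b <- bundle_spec(c(4, 5, 5), c(16, 5, 5), tube_radius = 1, fa_inside = 0.9)
  ph <- generate_diffusion_field(phantom_spec(
    c(40, 20, 20), bundles = list(b), noise_sd_fa = 0.3,
    noise_sd_dir_deg = 20, rng_seed = 8))
  expect_true(all(ph$field$fa >= 0 & ph$field$fa <= 1))
  n <- sqrt(ph$field$dirs[, , , 1]^2 + ph$field$dirs[, , , 2]^2 +
              ph$field$dirs[, , , 3]^2)
  expect_lt(max(abs(n - 1)), 1e-6)
})

test_that("same seed gives bit-identical phantoms; bundle outside grid rejected", {
  a <- straight_bundle_phantom(noise_sd_fa = 0.05, rng_seed = 21)
  b <- straight_bundle_phantom(noise_sd_fa = 0.05, rng_seed = 21)
  expect_identical(a$field$fa, b$field$fa)
  expect_identical(a$field$dirs, b$field$dirs)

  off <- bundle_spec(c(-5, 5, 5), c(16, 5, 5), id = "runaway")
  expect_error(
    generate_diffusion_field(phantom_spec(c(40, 20, 20),
                                          bundles = list(off))),
    "runaway")
})

test_that("sheet mesh: flat area exact, undulation increases area, normals", {
  flat <- generate_sheet_mesh(c(20, 20), 1)
  expect_equal(mesh_area(flat), 400, tolerance = 1e-6)
  expect_equal(sum(flat$vertex_areas), 400, tolerance = 1e-6)
  # amplitude 0: all normals identical (+z)
  expect_lt(max(abs(flat$vertex_normals[, 3] - 1)), 1e-12)

  bumpy <- generate_sheet_mesh(c(20, 20), 1, undulation_amplitude_mm = 2)
  expect_gt(mesh_area(bumpy), mesh_area(flat))
  expect_error(generate_sheet_mesh(c(0, 20), 1), "degenerate")
  expect_error(generate_sheet_mesh(c(20, 20), 0), "> 0")
})

test_that("icosphere approximates sphere area and is edge-connected", {
  sph <- generate_icosphere(3, radius = 10)
  expect_equal(nrow(sph$vertices), 642)
  expect_equal(mesh_area(sph), 4 * pi * 100, tolerance = 0.01)
  expect_equal(igraph::components(mesh_graph(sph))$no, 1)
})

test_that("cohort generator: zero-noise identities and exact effect injection", {
  mesh <- generate_sheet_mesh(c(10, 10), 2)
  nv <- nrow(mesh$vertices)
  base <- seq(1, 2, length.out = nv)

  cs <- cohort_spec(mesh, n_per_group = 3, baseline_mean_map = base,
                    effect_map = 0, rate_map = 0, noise_sd = 0, rng_seed = 1)
  coh <- generate_cohort_maps(cs)
  expect_equal(nrow(coh$maps_t0), 6)
  for (i in 1:6) expect_equal(unname(coh$maps_t0[i, ]), base)
  expect_equal(coh$maps_t0, coh$maps_t1)

  delta <- rep(0, nv); delta[5] <- 0.25
  cs2 <- cohort_spec(mesh, n_per_group = 3, baseline_mean_map = base,
                     effect_map = delta, noise_sd = 0, rng_seed = 1)
  coh2 <- generate_cohort_maps(cs2)
  g2 <- coh2$design$group == "high"
  expect_equal(mean(coh2$maps_t0[g2, 5]) - mean(coh2$maps_t0[!g2, 5]), 0.25)
  expect_equal(mean(coh2$maps_t0[g2, 1]) - mean(coh2$maps_t0[!g2, 1]), 0)

  # rate map applied per month
  cs3 <- cohort_spec(mesh, n_per_group = 3, baseline_mean_map = base,
                     rate_map = 0.01, noise_sd = 0, months = 27, rng_seed = 1)
  coh3 <- generate_cohort_maps(cs3)
  expect_equal(coh3$maps_t1 - coh3$maps_t0,
               matrix(0.27, 6, nv), tolerance = 1e-12)

  # reproducible under a seed
  csn <- cohort_spec(mesh, n_per_group = 3, noise_sd = 0.1,
                     noise_fwhm_mm = 6, rng_seed = 42)
  expect_identical(generate_cohort_maps(csn), generate_cohort_maps(csn))
})

test_that("cohort generator effect is recovered within its 95% CI", {
  # small template; moderate noise; the GLM CI should cover the injected
  # offset in ~95% of seeds (checked >= 90% over 100 seeds)
  mesh <- generate_sheet_mesh(c(16, 16), 2)
  nv <- nrow(mesh$vertices)
  v <- 41L
  delta <- rep(0, nv); delta[v] <- 0.1
  covered <- 0L
  for (s in 1:100) {
    cs <- cohort_spec(mesh, n_per_group = 20, baseline_mean_map = 1,
                      effect_map = delta, noise_sd = 0.05,
                      noise_fwhm_mm = 6, rng_seed = s)
    coh <- generate_cohort_maps(cs)
    dods <- build_dods_design(coh$design, "group")
    res <- fit_glm_vertexwise(coh$maps_t0[, v, drop = FALSE], dods, "offset")
    se <- abs(res$effect / res$t)
    ci <- res$effect + c(-1, 1) * qt(0.975, res$df) * se
    # offset contrast is high - low with levels sorted: high first
    if (ci[1] <= 0.1 && 0.1 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})
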