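test_that("SFiCD formula: direct arithmetic, empty sum, and guards", {
  expect_equal(compute_sficd(c(0.5, 0.3, 0.2), 2), 0.5)
  expect_equal(compute_sficd(numeric(0), 4), 0)
  expect_equal(compute_sficd(0.14, 1), 0.14)
  expect_error(compute_sficd(c(0.5), 0), "> 0")
  expect_error(compute_sficd(c(0.5), -1), "> 0")
})

test_that("fiber-to-CU assignment follows the endpoint-membership contract", {
  st <- two_bundle_setup()
  assigned <- assign_fibers(st$tractogram, st$masks, st$phantom$field)
  expect_length(assigned, 2)
  # both bundles have both endpoints under their own sheet: each fiber
  # appears exactly once, in its own CU
  expect_equal(lengths(assigned), c(70, 70))
  expect_equal(anyDuplicated(c(assigned[[1]], assigned[[2]])), 0)
  mean_fas <- vapply(st$tractogram$streamlines, `[[`, 0, "mean_fa")
  expect_true(all(mean_fas[assigned[[1]]] > 0.5))
  expect_true(all(mean_fas[assigned[[2]]] < 0.5))

  # a fiber bridging the two CUs is listed under both; one outside all
  # masks is unassigned
  bridge <- sficd:::new_streamline(rbind(c(12, 15, 12.4), c(12, 20, 12.4),
                                         c(12, 25, 12.4)), c(0.5, 0.5, 0.5))
  outside <- sficd:::new_streamline(rbind(c(2, 2, 2), c(2, 2, 4)),
                                    c(0.5, 0.5))
  tg2 <- sficd:::new_tractogram(list(bridge, outside), tracking_params())
  a2 <- assign_fibers(tg2, st$masks, st$phantom$field)
  expect_equal(a2[[1]], 1L)
  expect_equal(a2[[2]], 1L)

  # both endpoints in the same CU: listed once
  loop <- sficd:::new_streamline(rbind(c(10, 14, 12.4), c(12, 14, 9),
                                       c(14, 14, 12.4)), rep(0.5, 3))
  a3 <- assign_fibers(sficd:::new_tractogram(list(loop), tracking_params()),
                      st$masks, st$phantom$field)
  expect_equal(a3[[1]], 1L)
  expect_length(a3[[2]], 0)
})

test_that("per-CU table: homogeneity in FA and inverse scaling in volume", {
  st <- two_bundle_setup()
  percu <- sficd_per_cu(st$tractogram, st$masks, st$phantom$field)
  expect_equal(percu$sficd, percu$sum_fa / percu$volume_mm3)

  # scaling every fiber's FA by c scales SFiCD by c
  tg_scaled <- st$tractogram
  tg_scaled$streamlines <- lapply(tg_scaled$streamlines, function(s) {
    s$mean_fa <- 3 * s$mean_fa
    s
  })
  percu3 <- sficd_per_cu(tg_scaled, st$masks, st$phantom$field)
  expect_equal(percu3$sficd, 3 * percu$sficd, tolerance = 1e-12)

  # doubling V_CU analytically halves SFiCD for fixed fibers
  masks2 <- st$masks
  masks2$volumes_mm3 <- 2 * masks2$volumes_mm3
  percu_half <- sficd_per_cu(st$tractogram, masks2, st$phantom$field)
  expect_equal(percu_half$sficd, percu$sficd / 2, tolerance = 1e-12)
})

test_that("two equal bundles with FA 0.6 vs 0.4 give SFiCD ratio 1.5", {
  st <- two_bundle_setup()
  percu <- sficd_per_cu(st$tractogram, st$masks, st$phantom$field)
  expect_equal(percu$volume_mm3[1], percu$volume_mm3[2])
  ratio <- max(percu$sficd) / min(percu$sficd)
  expect_lt(abs(ratio - 1.5), 0.15)
})

test_that("projection to vertices: piecewise constant, flagged CUs missing", {
  mesh <- generate_sheet_mesh(c(10, 10), 1)
  p1 <- parcellate(mesh, K = 1, rng_seed = 1)
  expect_equal(project_to_vertices(p1, 0.7),
               rep(0.7, nrow(mesh$vertices)))

  p4 <- parcellate(mesh, K = 4, rng_seed = 1)
  vals <- c(1, 2, NA, 4)
  m <- project_to_vertices(p4, vals)
  for (k in 0:3) {
    got <- m[p4$labels == k]
    if (is.na(vals[k + 1])) expect_true(all(is.na(got)))
    else expect_true(all(got == vals[k + 1]))
  }
  expect_error(project_to_vertices(p4, 1:3), "one value per CU")
})

test_that("template normalization carries values through the correspondence", {
  m <- c(1, 2, 3, NA, 5)
  expect_equal(normalize_to_template(m, 1:5), m)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  expect_equal(normalize_to_template(m, perm), m[perm])
  expect_true(is.na(normalize_to_template(m, perm)[which(perm == 4)]))
  expect_error(normalize_to_template(m, NULL), "correspondence")
  expect_error(normalize_to_template(m, c(1L, 9L)), "outside")
})

test_that("smoothing: constant fixed point, identity at 0, linear, bounded", {
  mesh <- generate_sheet_mesh(c(20, 20), 1)
  n <- nrow(mesh$vertices)
  W <- smoothing_operator(mesh, 8)
  expect_equal(smooth_surface(rep(2.5, n), operator = W), rep(2.5, n),
               tolerance = 1e-12)
  set.seed(7)
  x <- runif(n); y <- runif(n)
  expect_equal(smooth_surface(x, mesh, fwhm_mm = 0), x)
  sx <- smooth_surface(x, operator = W)
  sy <- smooth_surface(y, operator = W)
  expect_equal(smooth_surface(2 * x + 3 * y, operator = W),
               2 * sx + 3 * sy, tolerance = 1e-10)
  expect_true(all(sx >= 0))
  expect_lte(max(sx), max(x))

  # missing vertices are excluded and renormalized, never imputed to 0
  xm <- x; xm[100] <- NA
  sm <- smooth_surface(xm, operator = W)
  expect_true(is.na(sm[100]))
  expect_true(all(!is.na(sm[-100])))
  const <- rep(1, n); const[100] <- NA
  sc <- smooth_surface(const, operator = W)
  expect_equal(sc[-100], rep(1, n - 1), tolerance = 1e-12)
})

test_that("impulse response of the 15 mm kernel measures 15 mm FWHM", {
  mesh <- fine_sheet()
  W <- fine_sheet_operator()
  n <- nrow(mesh$vertices)
  ctr <- which.min(rowSums(mesh$vertices[, 1:2]^2))
  imp <- rep(0, n); imp[ctr] <- 1
  sm <- smooth_surface(imp, operator = W)
  row <- which(mesh$vertices[, 2] == mesh$vertices[ctr, 2])
  x <- mesh$vertices[row, 1]; y <- sm[row]
  o <- order(x); x <- x[o]; y <- y[o]
  half <- max(y) / 2
  i1 <- min(which(y >= half)); i2 <- max(which(y >= half))
  left <- approx(y[c(i1 - 1, i1)], x[c(i1 - 1, i1)], half)$y
  right <- approx(y[c(i2, i2 + 1)], x[c(i2, i2 + 1)], half)$y
  expect_lt(abs((right - left) - 15), 1.5)
})
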