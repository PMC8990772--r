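make_design <- function(n_per_group = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    group = rep(c("high", "low"), each = n_per_group),
    age = round(runif(2 * n_per_group, 69, 83)),
    sex = sample(0:1, 2 * n_per_group, replace = TRUE),
    education = round(runif(2 * n_per_group, 0, 16)),
    tiv = rnorm(2 * n_per_group, 1.45e6, 1e5),
    homocysteine = exp(rnorm(2 * n_per_group, log(17), 0.3)))
}

test_that("DODS structure: column counts, contrasts, median split", {
  d <- make_design(6)
  d0 <- build_dods_design(d, "group")
  expect_equal(ncol(d0$X), 2)
  expect_equal(unname(d0$contrasts$offset), c(1, -1))

  d1 <- build_dods_design(d, "group", "age")
  expect_equal(ncol(d1$X), 4)

  d4 <- build_dods_design(d, "group", c("age", "sex", "education", "tiv"),
                          moderator = "homocysteine")
  expect_equal(ncol(d4$X), 12)  # 2 intercepts + 5 per-group slopes
  expect_equal(sum(d4$contrasts$interaction != 0), 2)

  dm <- data.frame(group = rep(c("a", "b"), 2), m = c(10, 12, 18, 30))
  dd <- build_dods_design(dm, "group", moderator = "m")
  expect_equal(dd$moderator_binary, c(0, 0, 1, 1))

  d$age2 <- d$age  # collinear with age within each group
  expect_error(build_dods_design(d, "group", c("age", "age2")),
               "rank deficient")
})

test_that("vertexwise GLM equals the pooled two-sample t without covariates", {
  set.seed(3)
  n <- 12
  maps <- matrix(rnorm(2 * n * 30), 2 * n, 30)
  d <- data.frame(group = rep(c("high", "low"), each = n))
  dods <- build_dods_design(d, "group")
  res <- fit_glm_vertexwise(maps, dods, "offset")
  for (v in 1:30) {
    tt <- t.test(maps[1:n, v], maps[(n + 1):(2 * n), v], var.equal = TRUE)
    expect_equal(res$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[v], tt$p.value, tolerance = 1e-10)
  }
  expect_true(all(res$df == 2 * n - 2))
})

test_that("vertexwise GLM matches the lm() oracle with covariates", {
  d <- make_design(6, seed = 9)
  dods <- build_dods_design(d, "group", c("age", "sex", "education", "tiv"))
  set.seed(10)
  maps <- matrix(rnorm(12 * 5), 12, 5)
  res <- fit_glm_vertexwise(maps, dods, "offset")
  for (v in 1:5) {
    fit <- lm(maps[, v] ~ 0 + dods$X)
    co <- summary(fit)$coefficients
    cvec <- dods$contrasts$offset
    eff <- sum(cvec * coef(fit))
    se <- sqrt(drop(t(cvec) %*% vcov(fit) %*% cvec))
    expect_equal(res$effect[v], eff, tolerance = 1e-8)
    expect_equal(res$t[v], eff / se, tolerance = 1e-8)
  }
})

test_that("GLM t is invariant to affine rescaling of covariates", {
  d <- make_design(8, seed = 4)
  set.seed(5)
  maps <- matrix(rnorm(16 * 8), 16, 8)
  r1 <- fit_glm_vertexwise(maps,
    build_dods_design(d, "group", c("age", "tiv")), "offset")
  d2 <- d
  d2$age <- (d2$age - 50) / 7
  d2$tiv <- d2$tiv / 1e6 + 3
  r2 <- fit_glm_vertexwise(maps,
    build_dods_design(d2, "group", c("age", "tiv")), "offset")
  expect_equal(r1$t, r2$t, tolerance = 1e-8)
})

test_that("null p values are uniform across vertices", {
  set.seed(11)
  d <- make_design(10, seed = 11)
  dods <- build_dods_design(d, "group", "age")
  maps <- matrix(rnorm(20 * 500), 20, 500)
  res <- fit_glm_vertexwise(maps, dods, "offset")
  ks <- ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("missing subject values are dropped per vertex with adjusted df", {
  d <- make_design(8, seed = 2)
  set.seed(2)
  maps <- matrix(rnorm(16 * 3), 16, 3)
  maps[c(2, 5), 2] <- NA
  dods <- build_dods_design(d, "group", "age")
  res <- fit_glm_vertexwise(maps, dods, "offset")
  expect_equal(res$df[1], 16 - 4)
  expect_equal(res$df[2], 14 - 4)
  ok <- !is.na(maps[, 2])
  dods_sub <- build_dods_design(d[ok, ], "group", "age")
  # same rows, but covariate demeaning differs on the subset; refit on
  # the identical design columns instead
  Xs <- dods$X[ok, ]
  fit <- lm(maps[ok, 2] ~ 0 + Xs)
  eff <- sum(dods$contrasts$offset * coef(fit))
  expect_equal(res$effect[2], eff, tolerance = 1e-8)
})

test_that("smoothness estimator: clamps for white noise, errors on constants", {
  mesh <- stats_mesh()
  n <- nrow(mesh$vertices)
  set.seed(1)
  wn <- matrix(rnorm(3 * n), 3, n)
  expect_equal(estimate_smoothness(wn, mesh), min(mesh$edge_lengths))
  expect_error(estimate_smoothness(matrix(1, 2, n), mesh), "variance")
  expect_error(estimate_smoothness(wn[1, , drop = FALSE], mesh),
               "at least 2")
})

test_that("smoothness estimator is consistent with the surface smoother", {
  mesh <- stats_mesh()
  n <- nrow(mesh$vertices)
  W <- smoothing_operator(mesh, 15)
  sdv <- sqrt(Matrix::rowSums(W^2))
  set.seed(6)
  R <- t(sapply(1:6, function(i) as.numeric(W %*% rnorm(n)) / sdv))
  est <- estimate_smoothness(R, mesh)
  expect_lt(abs(est - 15) / 15, 0.15)
})

test_that("cluster correction: trivial maps, estimator bound, monotonicity", {
  mesh <- stats_mesh()
  n <- nrow(mesh$vertices)
  null_areas <- stats_mesh_null_areas()

  zero <- structure(list(t = rep(0, n), p = rep(1, n), df = rep(30, n),
                         effect = rep(0, n),
                         residuals = matrix(rnorm(2 * n), 2, n),
                         contrast = 1), class = "vertex_stat")
  rep0 <- cluster_correct_montecarlo(zero, mesh, null_areas = null_areas)
  expect_equal(nrow(rep0$clusters), 0)

  # a cluster larger than every null max gets p = 1 / (1 + n_iter)
  big <- zero
  big$t[1:400] <- 10
  big$p[1:400] <- 1e-12
  repb <- cluster_correct_montecarlo(big, mesh, null_areas = null_areas)
  expect_equal(max(repb$clusters$area_mm2) > max(null_areas), TRUE)
  expect_equal(min(repb$clusters$p), 1 / (1 + length(null_areas)))

  # p is monotone non-increasing in area for a fixed null
  areas <- sort(runif(20, 0, max(null_areas) * 1.2))
  ps <- vapply(areas, function(a)
    (1 + sum(null_areas >= a)) / (1 + length(null_areas)), 0)
  expect_true(all(diff(ps) <= 0))

  expect_error(cluster_correct_montecarlo(zero, mesh, vertex_p = 0),
               "thresholds")
  expect_warning(
    cluster_correct_montecarlo(big, mesh, n_iter = 50, fwhm_mm = 15,
                               rng_seed = 1),
    "coarse")
})

test_that("longitudinal rate: arithmetic, zero change, missing propagation", {
  expect_equal(longitudinal_rate(1, 2, 27), 1 / 27)
  expect_equal(longitudinal_rate(c(1, 2, NA), c(1, 2.54, 3), 27),
               c(0, 0.02, NA))
  expect_equal(longitudinal_rate(c(3, 4), c(3, 4), 12), c(0, 0))
  expect_error(longitudinal_rate(1, 2, 0), "months")
  expect_error(longitudinal_rate(1, 2, -3), "months")
})

test_that("within-group rate test matches the one-sample t oracle", {
  set.seed(12)
  rates <- matrix(rnorm(10 * 20, 0, 0.01), 10, 20)
  res <- within_group_rate_test(rates)
  for (v in 1:20) {
    tt <- t.test(rates[, v])
    expect_equal(res$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[v], tt$p.value, tolerance = 1e-10)
  }
  # zero-variance vertices are flagged as degenerate
  rates[, 3] <- 0.02
  res2 <- within_group_rate_test(rates)
  expect_true(is.na(res2$t[3]))
  expect_error(within_group_rate_test(rates[1:2, ]), "at least 3")
})

test_that("rate effect injected by the cohort generator is detected", {
  mesh <- stats_mesh()
  n <- nrow(mesh$vertices)
  dist <- sqrt(rowSums(mesh$vertices^2))
  region <- dist <= 10
  rate_map <- ifelse(region, 0.004, 0)   # 0.1 over 27 months, d = 2
  null_areas <- stats_mesh_null_areas()
  hits <- 0L
  for (s in 1:10) {
    cs <- cohort_spec(mesh, n_per_group = 10, baseline_mean_map = 1,
                      rate_map = rate_map, noise_sd = 0.05,
                      noise_fwhm_mm = 15, months = 27, rng_seed = 300 + s)
    coh <- generate_cohort_maps(cs)
    rates <- (coh$maps_t1 - coh$maps_t0) / 27
    res <- within_group_rate_test(rates)
    rep_ <- cluster_correct_montecarlo(res, mesh, null_areas = null_areas)
    sig <- rep_$clusters[rep_$clusters$significant, ]
    ok <- FALSE
    if (nrow(sig)) for (cid in sig$cluster)
      if (any(region[which(rep_$membership == cid)])) ok <- TRUE
    hits <- hits + ok
  }
  expect_gte(hits, 9L)
})

test_that("partial correlation: Pearson reduction, perfect fit, oracle", {
  set.seed(13)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  p0 <- partial_correlation(x, y)
  expect_equal(p0$r, cor(x, y), tolerance = 1e-12)
  expect_equal(p0$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  expect_equal(partial_correlation(x, x)$r, 1, tolerance = 1e-12)

  Z <- matrix(rnorm(30 * 4), 30, 4)
  x2 <- rnorm(30) + Z %*% c(1, -1, 0.5, 0)
  y2 <- rnorm(30) + Z %*% c(0.3, 0.3, -0.2, 1)
  pc <- partial_correlation(as.numeric(x2), as.numeric(y2), Z)
  rx <- resid(lm(x2 ~ Z)); ry <- resid(lm(y2 ~ Z))
  r_or <- cor(rx, ry)
  expect_equal(pc$r, r_or, tolerance = 1e-10)
  t_or <- r_or * sqrt((30 - 2 - 4) / (1 - r_or^2))
  expect_equal(pc$p, 2 * pt(-abs(t_or), 30 - 2 - 4), tolerance = 1e-10)

  expect_error(partial_correlation(x[1:5], y[1:5], Z[1:5, ]), "n > k")
  expect_error(partial_correlation(x, rep(1, 30)), "constant")
})

test_that("composite cognitive Z-scores standardize and average correctly", {
  tests <- c("COWAT", "CFT", "SRT", "CRT", "CPAL", "ISLT")
  mns <- setNames(c(30, 18, 250, 300, 40, 25), tests)
  sds <- setNames(c(5, 4, 30, 40, 8, 6), tests)
  raw <- as.data.frame(as.list(mns))
  z <- composite_zscores(raw, mns, sds)
  expect_true(all(abs(as.matrix(z)) < 1e-12))

  raw2 <- raw
  raw2$COWAT <- mns[["COWAT"]] + sds[["COWAT"]]
  z2 <- composite_zscores(raw2, mns, sds)
  expect_equal(z2$Z_COWAT, 1)
  expect_equal(z2$executive, 0.5)
  expect_equal(z2$psychomotor, 0)
  expect_equal(z2$memory, 0)

  sds_bad <- sds; sds_bad[["SRT"]] <- 0
  expect_error(composite_zscores(raw, mns, sds_bad), "> 0")
  expect_error(composite_zscores(raw[, 1:3], mns, sds), "missing test")
})
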