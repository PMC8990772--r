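#' Specify a synthetic multi-subject SFiCD cohort
#'
#' Describes a two-group, two-timepoint cohort of vertexwise SFiCD maps on
#' a shared template mesh, with injectable group offset, group-by-moderator
#' interaction, and longitudinal rate effects plus spatially smooth noise.
#' Covariate distributions default to the scale of an older diabetic
#' trial population: age ~ 74 y, education ~ 5 y, total intracranial
#' volume ~ 1.45e6 mm^3, serum homocysteine ~ 17 umol/L (lognormal, hence
#' right-skewed), balanced sex, and a 27-month follow-up.
#'
#' @param template_mesh the shared [cortical_mesh()].
#' @param n_per_group subjects per group (default 20).
#' @param baseline_mean_map per-vertex baseline SFiCD mean; a scalar is
#'   recycled.
#' @param effect_map per-vertex group offset added to group 2.
#' @param interaction_map per-vertex extra offset added to group 2
#'   subjects whose moderator exceeds the cohort median (a DODS
#'   slope-difference signal).
#' @param rate_map per-vertex change per month applied to every subject.
#' @param noise_sd per-vertex SD of the spatially smooth noise (map
#'   units); 0 disables noise.
#' @param noise_fwhm_mm geodesic FWHM of the noise (mm).
#' @param months follow-up interval (months).
#' @param rng_seed integer seed; generation is fully reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(template_mesh, n_per_group = 20L,
                        baseline_mean_map = 1, effect_map = 0,
                        interaction_map = 0, rate_map = 0,
                        noise_sd = 0.05, noise_fwhm_mm = 15,
                        months = 27, rng_seed = 1L) {
  nv <- nrow(template_mesh$vertices)
  expand <- function(m, nm) {
    if (length(m) == 1L) m <- rep(m, nv)
    if (length(m) != nv) stop(sprintf("'%s' must match the template vertex count", nm))
    as.numeric(m)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_per_group < 2L) stop("need at least 2 subjects per group")
  structure(list(template_mesh = template_mesh,
                 n_per_group = as.integer(n_per_group),
                 baseline_mean_map = expand(baseline_mean_map, "baseline_mean_map"),
                 effect_map = expand(effect_map, "effect_map"),
                 interaction_map = expand(interaction_map, "interaction_map"),
                 rate_map = expand(rate_map, "rate_map"),
                 noise_sd = noise_sd, noise_fwhm_mm = noise_fwhm_mm,
                 months = months, rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of vertexwise SFiCD maps
#'
#' Each subject's map at time t (months) is
#' `baseline + group2 * effect + group2 * moderator_high * interaction +
#'  t * rate + noise`, where the noise is unit Gaussian white noise
#' smoothed to `noise_fwhm_mm` with the package's geodesic operator,
#' restandardized to unit per-vertex SD, and scaled by `noise_sd`
#' (independent across subjects and timepoints). The design table records
#' the true group, moderator, covariates and timepoints.
#'
#' @param spec a [cohort_spec()].
#' @return list with `maps_t0`, `maps_t1` (subjects x vertices matrices)
#'   and `design` (data.frame: subject, group, sex, age, education, tiv,
#'   homocysteine, moderator_high, months).
#' @export
generate_cohort_maps <- function(spec) {
  set.seed(spec$rng_seed)
  n <- 2L * spec$n_per_group
  nv <- length(spec$baseline_mean_map)
  group <- rep(c("low", "high"), each = spec$n_per_group)
  age <- round(runif(n, 69, 83))
  sex <- sample(c(0L, 1L), n, replace = TRUE)
  education <- pmax(0, round(rnorm(n, 5, 3)))
  tiv <- rnorm(n, 1.45e6, 1.2e5)
  homocysteine <- exp(rnorm(n, log(17), 0.3))
  moderator_high <- as.numeric(homocysteine > median(homocysteine))
  g2 <- as.numeric(group == "high")

  smooth_noise <- NULL
  if (spec$noise_sd > 0) {
    W <- smoothing_operator(spec$template_mesh, spec$noise_fwhm_mm)
    sdv <- sqrt(Matrix::rowSums(W^2))
    smooth_noise <- function(k) {
      Z <- matrix(rnorm(nv * k), nv, k)
      t(as.matrix(W %*% Z) / sdv) * spec$noise_sd
    }
  }

  fixed <- outer(rep(1, n), spec$baseline_mean_map) +
    outer(g2, spec$effect_map) +
    outer(g2 * moderator_high, spec$interaction_map)
  maps_t0 <- fixed
  maps_t1 <- fixed + outer(rep(spec$months, n), spec$rate_map)
  if (!is.null(smooth_noise)) {
    maps_t0 <- maps_t0 + smooth_noise(n)
    maps_t1 <- maps_t1 + smooth_noise(n)
  }
  design <- data.frame(
    subject = sprintf("sub-%03d", seq_len(n)), group = group,
    sex = sex, age = age, education = education, tiv = tiv,
    homocysteine = homocysteine, moderator_high = moderator_high,
    months = spec$months)
  list(maps_t0 = maps_t0, maps_t1 = maps_t1, design = design)
}
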