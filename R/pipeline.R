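#' Read and validate a run configuration
#'
#' A run config is a YAML file with blocks `mesh`, `phantom`, `tracking`,
#' `parcellation`, `sficd`, `cohort` and `stats`. Every random operation
#' must carry an explicit seed (`phantom.rng_seed`, `parcellation.rng_seed`,
#' `cohort.rng_seed`, `stats.rng_seed`); a missing seed is a validation
#' error so runs are reproducible by construction.
#'
#' @param path YAML config path.
#' @return the validated config (list) with a `config_hash` attribute
#'   (md5 of the file).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  cfg
}

validate_run_config <- function(cfg) {
  for (blk in c("mesh", "phantom", "tracking", "parcellation", "sficd",
                "cohort", "stats"))
    if (is.null(cfg[[blk]])) stop(sprintf("config block '%s' missing", blk))
  for (sd in list(c("phantom", "rng_seed"), c("parcellation", "rng_seed"),
                  c("cohort", "rng_seed"), c("stats", "rng_seed")))
    if (is.null(cfg[[sd[1]]][[sd[2]]]))
      stop(sprintf("config validation: '%s.%s' (a seed) is required",
                   sd[1], sd[2]))
  invisible(cfg)
}

config_to_phantom_spec <- function(cfg) {
  bundles <- lapply(cfg$phantom$bundles, function(b)
    bundle_spec(endpoint_a = as.numeric(b$endpoint_a),
                endpoint_b = as.numeric(b$endpoint_b),
                arc_depth = b$arc_depth %||% 0,
                tube_radius = b$tube_radius %||% 1,
                fa_inside = b$fa_inside %||% 0.6,
                id = b$id %||% "bundle",
                bulge = as.numeric(b$bulge %||% c(0, 0, -1))))
  phantom_spec(grid_shape = as.integer(cfg$phantom$grid_shape),
               voxel_size = as.numeric(cfg$phantom$voxel_size %||% c(0.5, 0.5, 0.5)),
               bundles = bundles,
               fa_background = cfg$phantom$fa_background %||% 0.05,
               noise_sd_fa = cfg$phantom$noise_sd_fa %||% 0,
               noise_sd_dir_deg = cfg$phantom$noise_sd_dir_deg %||% 0,
               origin = as.numeric(cfg$phantom$origin %||% c(0, 0, 0)),
               rng_seed = cfg$phantom$rng_seed)
}

config_to_tracking_params <- function(cfg) {
  tp <- cfg$tracking
  tracking_params(fa_threshold = tp$fa_threshold %||% 0.14,
                  angle_threshold = tp$angle_threshold %||% 35,
                  step_size = tp$step_size %||% 0.5,
                  smoothing = tp$smoothing %||% 0.5,
                  min_length = tp$min_length %||% 10,
                  max_length = tp$max_length %||% 65)
}

write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Executes phantom generation, whole-volume tracking with the short-range
#' length constraint, mesh parcellation and voxel-layer extraction, SFiCD
#' mapping with geodesic smoothing, synthetic-cohort generation on the same
#' mesh, and the vertexwise GLM with Monte Carlo cluster correction.
#' Per-stage counts (seeds, streamlines kept/filtered, flagged CUs,
#' clusters) are logged to a manifest, and all CSV outputs are stamped
#' with the config hash. Identical config and seeds give identical
#' outputs.
#'
#' @param config a config list from [read_run_config()], or a path to one.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest (list).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  hash <- attr(config, "config_hash") %||% "unhashed"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config_hash = hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- phantom ---
  mesh <- stage("phantom", {
    mc <- config$mesh
    generate_sheet_mesh(extent_mm = as.numeric(mc$extent_mm),
                        vertex_spacing_mm = mc$vertex_spacing_mm,
                        undulation_amplitude_mm = mc$undulation_amplitude_mm %||% 0,
                        undulation_wavelength_mm = mc$undulation_wavelength_mm %||% 10,
                        origin = as.numeric(mc$origin %||% c(0, 0, 0)))
  })
  ph <- stage("phantom", generate_diffusion_field(config_to_phantom_spec(config)))
  write_diffusion_field(ph$field, file.path(out_dir, "fa.nii.gz"),
                        file.path(out_dir, "dirs.nii.gz"))
  write_gifti_surface(mesh, file.path(out_dir, "mesh.surf.gii"))
  write_csv_stamped(ph$ground_truth, file.path(out_dir, "ground_truth.csv"), hash)
  log$phantom <- list(n_bundles = length(config$phantom$bundles),
                      n_voxels = prod(dim(ph$field$fa)))

  # --- tracking ---
  params <- config_to_tracking_params(config)
  tg_all <- stage("tracking", track_volume(ph$field, params,
                                           length_filter = FALSE))
  tg <- filter_by_length(tg_all, params$min_length, params$max_length)
  write_tck(tg, file.path(out_dir, "tracks.tck"))
  write_csv_stamped(tractogram_table(tg), file.path(out_dir, "fibers.csv"), hash)
  log$tracking <- list(n_seeds = sum(ph$field$fa >= params$fa_threshold),
                       n_streamlines = length(tg_all$streamlines),
                       n_kept_10_65 = length(tg$streamlines))

  # --- parcellation ---
  parc <- stage("parcellation",
                parcellate(mesh, K = config$parcellation$K,
                           rng_seed = config$parcellation$rng_seed))
  masks <- stage("parcellation",
                 cu_voxel_layer(parc, mesh, ph$field,
                                depth_mm = config$parcellation$depth_mm %||% 2))
  write_gifti_map(parc$labels, file.path(out_dir, "cu_labels.label.gii"),
                  intent = "NIFTI_INTENT_LABEL")
  labvol <- array(NA_integer_, dim = dim(ph$field$fa))
  for (k in seq_along(masks$masks)) labvol[masks$masks[[k]]] <- k - 1L
  labvol[is.na(labvol)] <- -1L
  write_volume(labvol, ph$field$affine, file.path(out_dir, "cu_masks.nii.gz"))
  log$parcellation <- list(K = parc$K, n_flagged = sum(masks$flagged))

  # --- sficd ---
  percu <- stage("sficd", sficd_per_cu(tg, masks, ph$field))
  vmap <- project_to_vertices(parc, percu$sficd)
  fwhm <- config$sficd$fwhm_mm %||% 15
  smap <- smooth_surface(vmap, mesh, fwhm_mm = fwhm)
  write_csv_stamped(percu, file.path(out_dir, "sficd_per_cu.csv"), hash)
  write_gifti_map(smap, file.path(out_dir, "sficd_smoothed.func.gii"))
  log$sficd <- list(fwhm_mm = fwhm,
                    n_cu_with_fibers = sum(percu$n_fibers > 0))

  # --- cohort + stats ---
  cc <- config$cohort
  effect_map <- rep(0, nrow(mesh$vertices))
  if (!is.null(cc$effect_region)) {
    er <- cc$effect_region
    ctr <- as.numeric(er$center)
    dist <- vnorm(mesh$vertices - outer(rep(1, nrow(mesh$vertices)), ctr))
    effect_map[dist <= er$radius_mm] <- er$delta
  }
  cs <- stage("stats", cohort_spec(
    template_mesh = mesh, n_per_group = cc$n_per_group %||% 20L,
    baseline_mean_map = cc$baseline_mean %||% 1,
    effect_map = effect_map, noise_sd = cc$noise_sd %||% 0.05,
    noise_fwhm_mm = cc$noise_fwhm_mm %||% 15,
    months = cc$months %||% 27, rng_seed = cc$rng_seed))
  coh <- generate_cohort_maps(cs)
  dods <- build_dods_design(coh$design, group = "group",
                            covariates = c("age", "sex", "education", "tiv"))
  res <- fit_glm_vertexwise(coh$maps_t0, dods, contrast = "offset")
  st <- config$stats
  rep_ <- stage("stats", cluster_correct_montecarlo(
    res, mesh, vertex_p = st$vertex_p %||% 0.01,
    cluster_p = st$cluster_p %||% 0.01, n_iter = st$n_iter %||% 10000L,
    fwhm_mm = st$fwhm_mm, rng_seed = st$rng_seed))
  write_csv_stamped(rep_$clusters, file.path(out_dir, "clusters.csv"), hash)
  write_gifti_map(res$t, file.path(out_dir, "group_tmap.func.gii"))
  log$stats <- list(n_subjects = nrow(coh$design),
                    fwhm_mm = rep_$fwhm_mm, n_iter = rep_$n_iter,
                    n_clusters = nrow(rep_$clusters),
                    n_significant = sum(rep_$clusters$significant))

  jsonlite::write_json(log, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(log)
}
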