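# Orchestration of the E1-E8 experiment suite. Each experiment is a thin,
# deterministic composition of module operations; every random draw is
# seeded from the config's master_seed through .derive_seed so any
# sub-result can be re-run in isolation.

# deterministic sub-seed derivation, kept inside 32-bit integer range
.derive_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 48271 + as.double(tag)) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Experiment configuration
#'
#' Bundles every tunable of the E1-E8 experiment suite.
#'
#' @param experiment one of "E1".."E8".
#' @param n_participants cohort size.
#' @param params shared [fold_params()] for the synthetic cohort.
#' @param fwhm smoothing FWHM in mm.
#' @param T timepoints per scan.
#' @param K number of parcels.
#' @param thresholds distance thresholds (mm) for the E7 sweep.
#' @param n_perm permutations for shift tests.
#' @param n_seeds number of mesh seeds for the mechanism experiments
#'   (E3-E5).
#' @param n_replicates replicates for the E7 parcel-level accuracy.
#' @param master_seed master RNG seed.
#' @return list of class `fb_config`.
#' @export
experiment_config <- function(experiment, n_participants = 20L,
                              params = fold_params(), fwhm = 2, T = 500L,
                              K = 50L, thresholds = c(0, 1, 2, 3, 4, 6),
                              n_perm = 1000L, n_seeds = 5L,
                              n_replicates = 10L, master_seed = 0L) {
  experiment <- match.arg(experiment, paste0("E", 1:8))
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 params = params, fwhm = fwhm, T = as.integer(T),
                 K = as.integer(K), thresholds = thresholds,
                 n_perm = as.integer(n_perm), n_seeds = as.integer(n_seeds),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "fb_config")
}

# smoothed-noise normalised local correlation map for one participant
.e1_map <- function(p, fwhm, T, seed) {
  kern <- build_kernel(p$mesh, fwhm = fwhm)
  x <- smooth_surface(surface_noise(p$mesh, T, seed = seed), kern)
  normalise_local(local_correlation(x, p$mesh), p$mesh, radius = 15)
}

.run_e1 <- function(cfg) {
  cohort <- make_cohort(cfg$n_participants, cfg$params, cfg$master_seed)
  i <- 0L
  mm <- matched_mismatched(
    cohort,
    map_fn = function(p) {
      i <<- i + 1L
      .e1_map(p, cfg$fwhm, cfg$T, .derive_seed(cfg$master_seed, 100 + i))
    },
    assoc_fn = function(map, depth, p)
      weighted_pearson(map, depth, vertex_areas(p$mesh)))
  list(matched_r = mm$matched, mismatched_r = mm$mismatched,
       paired_t = mm$test$t, paired_df = mm$test$df, paired_p = mm$test$p,
       all_matched_stronger = all(abs(mm$matched) > abs(mm$mismatched)))
}

.run_e2 <- function(cfg) {
  cohort <- make_cohort(cfg$n_participants, cfg$params, cfg$master_seed)
  r <- vapply(cohort$participants, function(p)
    weighted_pearson(inter_vertex_distance(p$mesh), p$depth,
                     vertex_areas(p$mesh)), 0)
  t1 <- group_tests(r, type = "one_sample")
  list(r = r, mean_r = mean(r), t = t1$t, df = t1$df, p = t1$p)
}

.run_e3 <- function(cfg) {
  res <- lapply(seq_len(cfg$n_seeds), function(s) {
    p0 <- cfg$params
    p0$seed <- .derive_seed(cfg$master_seed, 300 + s)
    p <- make_folded_sheet(p0)
    grid <- make_voxel_grid(p$mesh, voxel_size = 2, pad = 2)
    grid <- volume_noise(grid, cfg$T, seed = .derive_seed(cfg$master_seed,
                                                          350 + s))
    spacing <- inter_vertex_distance(p$mesh)
    areas <- vertex_areas(p$mesh)
    vapply(c("trilinear", "nearest"), function(m) {
      x <- project_volume_to_surface(grid, p$mesh, method = m)
      weighted_pearson(spacing, local_correlation(x, p$mesh), areas)
    }, 0)
  })
  r <- do.call(rbind, res)
  list(r_trilinear = r[, "trilinear"], r_nearest = r[, "nearest"],
       mean_trilinear = mean(r[, "trilinear"]),
       mean_nearest = mean(r[, "nearest"]))
}

.run_e4 <- function(cfg) {
  one <- function(builder, s) {
    p0 <- cfg$params
    p0$seed <- .derive_seed(cfg$master_seed, 400 + s)
    p <- builder(p0)
    kern <- build_kernel(p$mesh, fwhm = cfg$fwhm)
    x <- smooth_surface(surface_noise(p$mesh, cfg$T,
                                      seed = .derive_seed(cfg$master_seed,
                                                          450 + s)), kern)
    weighted_pearson(inter_vertex_distance(p$mesh),
                     local_correlation(x, p$mesh), vertex_areas(p$mesh))
  }
  rf <- vapply(seq_len(cfg$n_seeds), function(s) one(make_folded_sheet, s), 0)
  ru <- vapply(seq_len(cfg$n_seeds), function(s) one(make_uniform_mesh, s), 0)
  list(r_folded = rf, r_uniform = ru,
       mean_folded = mean(rf), mean_uniform = mean(ru))
}

.run_e5 <- function(cfg) {
  res <- vapply(seq_len(cfg$n_seeds), function(s) {
    p0 <- cfg$params
    p0$seed <- .derive_seed(cfg$master_seed, 500 + s)
    p <- make_folded_sheet(p0)
    grid <- make_voxel_grid(p$mesh, voxel_size = 2, pad = 2)
    grid <- volume_noise(grid, cfg$T, seed = .derive_seed(cfg$master_seed,
                                                          550 + s))
    vol_lc <- volumetric_local_correlation(grid)
    map_grid <- grid
    map_grid$values <- array(vol_lc, dim = c(dim(vol_lc), 1))
    surf_lc <- project_volume_to_surface(map_grid, p$mesh,
                                         method = "trilinear")[, 1]
    weighted_pearson(surf_lc, p$depth, vertex_areas(p$mesh))
  }, 0)
  # distance-resolved autocorrelation of smoothed vs raw surface noise
  p0 <- cfg$params
  p0$seed <- .derive_seed(cfg$master_seed, 501)
  p <- make_folded_sheet(p0)
  noise <- surface_noise(p$mesh, cfg$T,
                         seed = .derive_seed(cfg$master_seed, 560))
  kern <- build_kernel(p$mesh, fwhm = cfg$fwhm)
  edges <- seq(0, 8, by = 2)
  prof_raw <- autocorr_profile(noise, p$mesh, edges)
  prof_sm <- autocorr_profile(smooth_surface(noise, kern), p$mesh, edges)
  list(r_depth = res, mean_r_depth = mean(res),
       autocorr_raw = prof_raw, autocorr_smoothed = prof_sm)
}

.e6_cohort_stats <- function(cohort, cfg, tag) {
  i <- 0L
  matched_mismatched(
    cohort,
    map_fn = function(p) {
      i <<- i + 1L
      kern <- build_kernel(p$mesh, fwhm = cfg$fwhm)
      x <- smooth_surface(
        surface_noise(p$mesh, cfg$T, seed = .derive_seed(cfg$master_seed,
                                                         tag + i)), kern)
      list(labels = ward_parcellate(x, p$mesh, cfg$K), mesh = p$mesh)
    },
    assoc_fn = function(map, depth, p)
      border_depth_test(map$labels, depth, map$mesh)$t)
}

.run_e6 <- function(cfg) {
  cohort <- make_cohort(cfg$n_participants, cfg$params, cfg$master_seed)
  mm <- .e6_cohort_stats(cohort, cfg, 600)
  second <- group_tests(mm$matched, type = "one_sample")
  uni <- make_cohort(cfg$n_participants, cfg$params, cfg$master_seed,
                     uniform = TRUE)
  mmu <- .e6_cohort_stats(uni, cfg, 650)
  list(matched_t = mm$matched, mismatched_t = mm$mismatched,
       n_positive = sum(mm$matched > 0),
       second_level_t = second$t, second_level_p = second$p,
       paired_t = mm$test$t, paired_p = mm$test$p,
       uniform_matched_t = mmu$matched,
       mean_t_folded = mean(mm$matched),
       mean_t_uniform = mean(mmu$matched))
}

.run_e7 <- function(cfg) {
  cohort <- make_cohort(cfg$n_participants, cfg$params, cfg$master_seed)
  labels <- make_contiguous_parcellation(cohort$participants[[1]]$mesh,
                                         cfg$K,
                                         seed = .derive_seed(cfg$master_seed,
                                                             700))
  kernels <- cohort_kernels(cohort, cfg$fwhm)
  acc <- vapply(seq_len(cfg$n_replicates), function(r)
    parcel_fingerprint(cohort, labels, cfg$fwhm, cfg$T,
                       scan_seed = .derive_seed(cfg$master_seed, 710 + r),
                       kernels = kernels)$accuracy, 0)
  sweep <- threshold_sweep(cohort, labels, cfg$thresholds, cfg$fwhm, cfg$T,
                           scan_seed = .derive_seed(cfg$master_seed, 790))
  list(parcel_accuracy = acc, parcel_accuracy_mean = mean(acc),
       parcel_accuracy_sem = sd(acc) / sqrt(length(acc)),
       chance = 1 / cfg$n_participants,
       sweep_thresholds = sweep$thresholds, sweep_mean = sweep$mean,
       sweep_sem = sweep$sem)
}

.run_e8 <- function(cfg) {
  p0 <- cfg$params
  p0$seed <- .derive_seed(cfg$master_seed, 800)
  run_one <- function(p) {
    kern <- build_kernel(p$mesh, fwhm = cfg$fwhm)
    x <- smooth_surface(surface_noise(p$mesh, cfg$T,
                                      seed = .derive_seed(cfg$master_seed,
                                                          810)), kern)
    labels <- make_contiguous_parcellation(p$mesh, cfg$K,
                                           seed = .derive_seed(
                                             cfg$master_seed, 820))
    parcel_mean_bias(x, labels, p$depth, vertex_areas(p$mesh), p$mesh,
                     weighted = "both", n_perm = cfg$n_perm,
                     seed = .derive_seed(cfg$master_seed, 830))
  }
  folded <- run_one(make_folded_sheet(p0))
  uniform <- run_one(make_uniform_mesh(p0))
  list(folded = folded, uniform = uniform,
       weighting_reduces_bias =
         abs(folded$weighted$r) < abs(folded$unweighted$r))
}

#' Run an experiment
#'
#' Dispatches one of the eight experiments on synthetic cohorts:
#' E1 depth vs normalised local correlation (matched/mismatched);
#' E2 spacing-depth association; E3 volume-to-surface projection null;
#' E4 smoothing null on folded vs uniform meshes; E5 volumetric control and
#' autocorrelation-vs-distance; E6 Ward parcellation border bias;
#' E7 fingerprinting and the distance-threshold sweep; E8 parcel-mean bias.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory; when given, a JSON summary is
#'   written to `<out_dir>/<experiment>_summary.json`.
#' @return the experiment summary (list), invisibly carrying the config.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "fb_config"))
  runner <- switch(config$experiment,
                   E1 = .run_e1, E2 = .run_e2, E3 = .run_e3, E4 = .run_e4,
                   E5 = .run_e5, E6 = .run_e6, E7 = .run_e7, E8 = .run_e8)
  res <- runner(config)
  res$config <- unclass(config)
  res$config$params <- unclass(config$params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res,
                         file.path(out_dir,
                                   paste0(config$experiment,
                                          "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(res)
}

#' Diagnose gyral bias on real surface data
#'
#' Computes the package's bias diagnostics on GIFTI files: inter-vertex
#' distance and vertex-area maps, local correlation of the supplied series,
#' its 15 mm-normalised version, and area-weighted associations with the
#' supplied depth map. On arbitrary (non-toroidal) meshes no exact
#' autocorrelation-preserving permutation group exists, so the permutation p
#' uses the naive random-vertex scheme and is flagged as such.
#'
#' @param surface path to a `.surf.gii` surface.
#' @param depth path to a depth metric file (`.shape.gii`/`.func.gii`).
#' @param series path to a time-series metric file (vertices x T).
#' @param n_perm permutations for the fallback test (0 to skip).
#' @param seed RNG seed.
#' @return list with the computed maps and association statistics.
#' @export
diagnose_real_surface <- function(surface, depth, series, n_perm = 1000L,
                                  seed = 1L) {
  mesh <- read_gifti_surface(surface)
  d <- read_gifti_metric(depth)[, 1]
  x <- read_gifti_metric(series)
  if (length(d) != n_vertices(mesh) || nrow(x) != n_vertices(mesh))
    stop("vertex counts of surface, depth and series files differ")
  spacing <- inter_vertex_distance(mesh)
  areas <- vertex_areas(mesh)
  lc <- local_correlation(x, mesh)
  nlc <- normalise_local(lc, mesh, radius = 15)
  out <- list(n_vertices = n_vertices(mesh),
              spacing = spacing, areas = areas,
              local_correlation = lc, normalised_local_correlation = nlc,
              r_spacing_depth = weighted_pearson(spacing, d, areas),
              r_nlc_depth = weighted_pearson(nlc, d, areas))
  if (n_perm > 0) {
    pt <- shift_permutation_test(nlc, d, mesh, w = areas, n_perm = n_perm,
                                 seed = seed, fallback = TRUE)
    out$p_nlc_depth <- pt$p
    out$p_scheme <- pt$scheme
    out$p_autocorrelation_naive <- pt$scheme == "random_permutation"
  }
  out
}
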