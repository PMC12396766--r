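# End-to-end orchestration: phantom -> segmentation -> centerline geometry
# -> boundary conditions -> flow solution -> hemodynamic metrics, with
# provenance-logged artifacts and a two-timepoint comparison workflow.

#' Build a pipeline run configuration
#'
#' @param preset `"day7"`, `"day21"`, or `"custom"` (then supply `spec`).
#' @param spec an [avf_geometry()] for custom runs.
#' @param spacing_um phantom voxel spacing.
#' @param hu_window segmentation HU window `c(lo, hi)`.
#' @param noise_sd phantom noise (HU).
#' @param pulsatility inlet waveform pulsatility (NULL = study default).
#' @param level solver refinement level.
#' @param n_cycles cardiac cycles.
#' @param out_dir output directory for artifacts.
#' @param seed global RNG seed, threaded through every stochastic stage and
#'   recorded in every artifact.
#' @return a validated `run_config`.
#' @export
run_config <- function(preset = "day7", spec = NULL, spacing_um = 72,
                       hu_window = c(300, 1000), noise_sd = 0,
                       pulsatility = NULL, level = "coarse", n_cycles = 3,
                       out_dir = tempfile("avfcfd_run_"), seed = 0) {
  if (is.null(spec)) {
    if (!preset %in% c("day7", "day21"))
      stop("custom preset requires an explicit geometry spec")
    spec <- avf_geometry(preset)
  } else {
    validate_avf_geometry(spec)
  }
  if (!level %in% c("coarse", "medium", "fine")) stop("invalid level")
  if (hu_window[1] >= hu_window[2]) stop("invalid HU window")
  cfg <- list(preset = preset, spec = spec, spacing_um = spacing_um,
              hu_window = hu_window, noise_sd = noise_sd,
              pulsatility = pulsatility, level = level, n_cycles = n_cycles,
              out_dir = out_dir, seed = seed)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "run_config"
  cfg
}

# endpoint voxels of the three vessel ends, from the known phantom frame
.phantom_endpoints <- function(spec, mask) {
  h <- um_to_mm(mask$spacing_um)
  ext <- spec$inlet_extension
  theta <- spec$anastomosis_angle * pi / 180
  Lf <- spec$fistula$length + spec$vein$length - 0.3
  to_idx <- function(p) {
    idx <- round((p - mask$origin_mm) / h) + 1
    pmin(pmax(idx, 1), dim(mask$values))
  }
  list(PA = to_idx(c(-(spec$proximal_artery$length + ext) + 0.3, 0, 0)),
       DA = to_idx(c(spec$distal_artery$length + ext - 0.3, 0, 0)),
       vein = to_idx(c(Lf * cos(theta), Lf * sin(theta), 0)))
}

#' Run the full single-timepoint pipeline
#'
#' Executes every stage in order and writes all artifacts (NIfTI phantom
#' and mask, STL surface, CSV profiles, VTK fields, JSON report) with
#' provenance (config hash, seed) into `config$out_dir`. Stages are cached
#' by config hash so that re-running with unchanged inputs skips the solve.
#'
#' @param config a [run_config()].
#' @param cache reuse cached stage results when present (default TRUE).
#' @return invisible list with `report` (a `hemodynamic_report`), measured
#'   `profile`, `stats` (2 mm / 4 mm window statistics), `field`, and paths.
#' @export
run_single <- function(config, cache = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- run_logger(file.path(config$out_dir, "run_log.jsonl"))
  stamp <- function(stage, expr) {
    t0 <- Sys.time()
    out <- expr
    logf(stage, wall_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
         hash = config$hash, seed = config$seed)
    out
  }
  spec <- config$spec

  vol <- stamp("phantom", voxelize_phantom(
    spec, spacing_um = config$spacing_um, noise_sd = config$noise_sd,
    seed = config$seed))
  write_volume_nifti(vol, file.path(config$out_dir, "phantom.nii.gz"))

  mask <- stamp("segment", {
    m <- threshold_segment(vol, config$hu_window[1], config$hu_window[2])
    ep <- .phantom_endpoints(spec, m)
    region_grow(m, list(ep$PA), connectivity = 26)
  })
  write_volume_nifti(list(values = mask$values * 1L,
                          spacing_um = mask$spacing_um,
                          origin_mm = mask$origin_mm),
                     file.path(config$out_dir, "mask.nii.gz"))

  surf <- stamp("surface", smooth_surface(extract_surface(mask), 10))
  write_stl(surf, file.path(config$out_dir, "lumen.stl"))

  geo <- stamp("geometry", {
    ep <- .phantom_endpoints(spec, mask)
    cl <- extract_centerline(mask, ep)
    prof <- suppressWarnings(cross_section_profile(cl, mask))
    list(centerline = cl, profile = prof)
  })
  utils::write.csv(as.data.frame(geo$profile),
                   file.path(config$out_dir, "diameter_profile.csv"),
                   row.names = FALSE)
  write_centerline_vtk(geo$centerline,
                       file.path(config$out_dir, "centerline.vtk"))
  stats <- list(avf2 = segment_stats(geo$profile, c(0, 2)),
                avf4 = segment_stats(geo$profile, c(0, 4)))

  bc <- stamp("flowbc", avf_boundary_conditions(
    spec, if (config$preset %in% c("day7", "day21")) config$preset else "day7",
    pulsatility = config$pulsatility, seed = config$seed))

  cache_file <- file.path(config$out_dir, paste0("field-", config$hash, ".rds"))
  field <- if (cache && file.exists(cache_file)) {
    logf("solve", cached = TRUE, hash = config$hash)
    readRDS(cache_file)
  } else {
    ff <- stamp("solve", {
      grid <- build_grid(spec, config$level)
      solve_unsteady(grid, fluid_properties(), bc$inlet,
                     n_cycles = config$n_cycles)
    })
    saveRDS(ff, cache_file)
    ff
  }
  write_flow_vtk(field, file.path(config$out_dir, "field_peak_systole.vtk"))

  report <- stamp("metrics", hemodynamic_report(field, profile = geo$profile))
  rec <- wall_shear_stress(field)
  tw <- metric_profile(field, "tawss", record = rec)
  os <- metric_profile(field, "osi", record = rec)
  utils::write.csv(data.frame(s_mm = tw$s_mm, tawss_pa = tw$avg,
                              osi = os$avg),
                   file.path(config$out_dir, "wall_metrics.csv"),
                   row.names = FALSE)
  out_report <- c(report, list(config_hash = config$hash, seed = config$seed,
                               avf2_mean_mm = stats$avf2$mean_mm,
                               avf4_mean_mm = stats$avf4$mean_mm))
  jsonlite::write_json(out_report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(report = report, profile = geo$profile, stats = stats,
                 centerline = geo$centerline, field = field,
                 out_dir = config$out_dir))
}

#' Two-timepoint comparison workflow
#'
#' Runs the pipeline at two timepoints (typically the day-7 and day-21
#' presets) and reports the temporal deltas: percent diameter changes of
#' the 2 mm and 4 mm fistula windows and of the stenosis minimum,
#' Poiseuille resistance ratio, flow-split shift, and windowed TAWSS/OSI
#' ratios. A longitudinal diameter-profile comparison figure is written to
#' the first run's output directory.
#'
#' @param config_a,config_b [run_config()]s for the two timepoints.
#' @param cache passed to [run_single()].
#' @return a `comparison_report`.
#' @export
run_comparison <- function(config_a, config_b, cache = TRUE) {
  ra <- run_single(config_a, cache = cache)
  rb <- run_single(config_b, cache = cache)
  mu <- fluid_properties()$viscosity
  res_a <- poiseuille_resistance(ra$profile, mu, s_range = c(0, 4))
  res_b <- poiseuille_resistance(rb$profile, mu, s_range = c(0, 4))
  rep <- list(
    a = ra$report, b = rb$report,
    diameter_change_2mm_pct = percent_change(ra$stats$avf2$mean_mm,
                                             rb$stats$avf2$mean_mm),
    diameter_change_4mm_pct = percent_change(ra$stats$avf4$mean_mm,
                                             rb$stats$avf4$mean_mm),
    min_diameter_change_pct = percent_change(ra$stats$avf2$min_mm,
                                             rb$stats$avf2$min_mm),
    resistance_ratio = res_b / res_a,
    split_shift = rb$report$split[1] - ra$report$split[1],
    tawss_ratio = rb$report$tawss_window_pa / ra$report$tawss_window_pa,
    osi_ratio = rb$report$osi_window / max(ra$report$osi_window, 1e-12)
  )
  fig <- file.path(config_a$out_dir, "diameter_comparison.pdf")
  grDevices::pdf(fig, width = 7, height = 4.5)
  plot_diameter_comparison(ra$profile, rb$profile)
  grDevices::dev.off()
  rep$figure <- fig
  class(rep) <- "comparison_report"
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("two-timepoint comparison\n")
  cat(sprintf("  AVF 2 mm mean diameter change: %+.1f%%\n",
              x$diameter_change_2mm_pct))
  cat(sprintf("  AVF 4 mm mean diameter change: %+.1f%%\n",
              x$diameter_change_4mm_pct))
  cat(sprintf("  minimum (stenosis) change: %+.1f%%\n",
              x$min_diameter_change_pct))
  cat(sprintf("  Poiseuille resistance ratio (b/a): %.2f\n",
              x$resistance_ratio))
  cat(sprintf("  TAWSS windowed ratio: %.2f, OSI windowed ratio: %.2f\n",
              x$tawss_ratio, x$osi_ratio))
  invisible(x)
}

#' Longitudinal diameter-profile comparison plot
#'
#' Plots two measured lumen diameter profiles against distance from the
#' anastomosis (negative = artery side), the standard longitudinal view of
#' AVF remodeling.
#'
#' @param profile_a,profile_b `diameter_profile`s.
#' @param labels legend labels.
#' @export
plot_diameter_comparison <- function(profile_a, profile_b,
                                     labels = c("timepoint A", "timepoint B")) {
  pa <- as.data.frame(profile_a); pb <- as.data.frame(profile_b)
  rng_x <- range(pa$s_mm, pb$s_mm)
  rng_y <- range(0, pa$diameter_mm, pb$diameter_mm)
  graphics::plot(pa$s_mm, pa$diameter_mm, type = "l", lwd = 2, col = "#2166ac",
                 xlim = rng_x, ylim = rng_y,
                 xlab = "distance from anastomosis (mm)",
                 ylab = "lumen diameter (mm)")
  graphics::lines(pb$s_mm, pb$diameter_mm, lwd = 2, col = "#b2182b")
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topleft", legend = labels, col = c("#2166ac", "#b2182b"),
                   lwd = 2, bty = "n")
  invisible(NULL)
}
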