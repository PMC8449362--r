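# Configuration and the staged pipeline surface. Stages communicate through
# plain files (MRC volumes + TSV/STAR tables) in an output directory, so
# each is independently runnable and inspectable; every run writes a frozen
# copy of the resolved configuration and a log that reconciles the
# (in, kept, rejected) counts of every filter.

#' Default pipeline configuration
#'
#' Physical parameters mirror the working values of the method: 8-nm
#' segment spacing, 11-nm slab, +/-60 degree tilt, 50-70-nm height band;
#' class counts and volume sizes are the desk-scale defaults.
#' @param ... overrides of named entries
#' @return list of class `pipeline_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    # scene
    n_scenes = 1, volume_shape = c(256, 256, 128), pixel_size = 1.1,
    n_filaments = 20, tip_fraction = 0.74, noise_sigma = 0.3,
    tilt_range = 60, receptor_count = 0, receptor_height = 12,
    receptor_band = c(50, 70), tube_radius = 50, support_z = 8,
    tube_length = NULL, length_range = c(80, 200), seed = 1,
    # segments / polarity
    spacing = 8, box_edge = 32, slab_thickness = 11, mask_radius = 6,
    k = 20, n_iter = 12, shift_max = 3, margin = 0.05, min_members = 10,
    helical = helical_params(),
    # filament calls
    alpha = 0.05, alpha_stringent = 0.01, n_min = 5,
    # receptors
    attach_band = c(2, 12), tilt_max = 20, min_sep = 8, k3d = 2,
    receptor_box = 32, center_offset = 6, height_level = 0.5)
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; entries override [default_config()]
#' @return `pipeline_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$helical)) y$helical <- do.call(helical_params, y$helical)
  do.call(default_config, y)
}

# scene_spec from a config (one scene; seed explicit)
config_scene_spec <- function(cfg, seed) {
  scene_spec(volume_shape = cfg$volume_shape, pixel_size = cfg$pixel_size,
             n_filaments = cfg$n_filaments, tip_fraction = cfg$tip_fraction,
             noise_sigma = cfg$noise_sigma, tilt_range = cfg$tilt_range,
             receptor_count = cfg$receptor_count,
             receptor_height = cfg$receptor_height,
             receptor_band = cfg$receptor_band,
             tube_radius = cfg$tube_radius, support_z = cfg$support_z,
             tube_length = cfg$tube_length,
             length_range = cfg$length_range, seed = seed,
             helical = cfg$helical)
}

.log_line <- function(con, ...) {
  msg <- sprintf(...)
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run a pipeline stage
#'
#' Stages: `simulate` writes per-scene volumes (MRC) and ground-truth trace
#' tables; `polarity` reads them, runs the polarity pipeline per scene and
#' appends votes to the segment tables; `report` aggregates filament calls
#' into the per-tomogram fraction summary and the stacked-column CSV;
#' `receptors` runs picking/averaging/height measurement on receptor
#' scenes; `fsc` computes the half-set FSC of the polarity segments.
#' Missing upstream artifacts raise a dependency error.
#' @param config a `pipeline_config`, or path to a YAML file
#' @param stage one of "simulate", "polarity", "receptors", "fsc", "report"
#' @param out_dir artifact directory (created if needed)
#' @param seed overrides `config$seed`
#' @return stage result, invisibly (artifacts are on disk)
#' @export
run_pipeline <- function(config, stage, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stage <- match.arg(stage, c("simulate", "polarity", "receptors", "fsc",
                              "report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) config$seed <- seed
  cfg_out <- config
  cfg_out$helical <- unclass(cfg_out$helical)
  yaml::write_yaml(unclass(cfg_out), file.path(out_dir, "config_used.yaml"))
  log_con <- file(file.path(out_dir, sprintf("%s.log", stage)), "w")
  on.exit(close(log_con))
  .log_line(log_con, "stage=%s seed=%d", stage, config$seed)
  switch(stage,
    simulate = .stage_simulate(config, out_dir, log_con),
    polarity = .stage_polarity(config, out_dir, log_con),
    receptors = .stage_receptors(config, out_dir, log_con),
    fsc = .stage_fsc(config, out_dir, log_con),
    report = .stage_report(config, out_dir, log_con))
}

.scene_paths <- function(out_dir, s) {
  list(mrc = file.path(out_dir, sprintf("scene_%03d.mrc", s)),
       traces = file.path(out_dir, sprintf("scene_%03d_traces.tsv", s)),
       segments = file.path(out_dir, sprintf("scene_%03d_segments.tsv", s)),
       picks = file.path(out_dir, sprintf("scene_%03d_picks.star", s)))
}

.stage_simulate <- function(cfg, out_dir, log_con) {
  seeds <- derive_seeds(cfg$seed, cfg$n_scenes)
  for (s in seq_len(cfg$n_scenes)) {
    sp <- config_scene_spec(cfg, seeds[s])
    sc <- simulate_scene(sp)
    pth <- .scene_paths(out_dir, s)
    write_mrc(sc$volume, pth$mrc)
    tt <- traces_to_table(sc$truth$traces)
    if (!is.null(tt)) write_table(tt, pth$traces, type = "trace")
    if (!is.null(sc$truth$receptor_placements))
      write_table(sc$truth$receptor_placements,
                  file.path(out_dir, sprintf("scene_%03d_receptors.tsv", s)))
    .log_line(log_con, "scene=%d filaments=%d receptors=%d peak=%.3f",
              s, length(sc$truth$traces),
              if (is.null(sc$truth$receptor_placements)) 0L
              else nrow(sc$truth$receptor_placements),
              sc$truth$filament_peak)
  }
  invisible(cfg$n_scenes)
}

.stage_polarity <- function(cfg, out_dir, log_con) {
  templates <- .template_bank(
    actin_templates(cfg$helical, cfg$box_edge, cfg$pixel_size,
                    cfg$slab_thickness, mask_radius = cfg$mask_radius,
                    tilt_range = cfg$tilt_range),
    shift_max = 3)
  # one pooled classification across all scenes: class averages need
  # hundreds of members to rise above the per-segment noise
  prepped <- vector("list", cfg$n_scenes)
  for (s in seq_len(cfg$n_scenes)) {
    pth <- .scene_paths(out_dir, s)
    if (!file.exists(pth$mrc) || !file.exists(pth$traces))
      stop("dependency error: run `simulate` first (missing ", pth$mrc, ")",
           call. = FALSE)
    tomo <- read_mrc(pth$mrc, tilt_range = cfg$tilt_range)
    traces <- table_to_traces(read_table(pth$traces))
    prepped[[s]] <- prepare_polarity_images(tomo, traces, cfg)
    .log_line(log_con, "scene=%d segments=%d rejected=%d usable=%d",
              s, nrow(prepped[[s]]$segments),
              sum(prepped[[s]]$segments$rejected),
              sum(prepped[[s]]$segments$usable))
  }
  res <- run_polarity_pooled(prepped, cfg,
                             seed = derive_seeds(cfg$seed, 1, salt = 7L),
                             templates = templates)
  for (s in seq_len(cfg$n_scenes)) {
    write_table(res$segments[[s]], .scene_paths(out_dir, s)$segments,
                type = "segment")
  }
  .log_line(log_con,
            "pooled: segments=%d classified=%d voted=%d selected_classes=%d",
            res$log["segments"], res$log["classified"], res$log["voted"],
            sum(res$class_info$selected))
  invisible(res)
}

.stage_report <- function(cfg, out_dir, log_con) {
  calls <- NULL; traces <- list()
  for (s in seq_len(cfg$n_scenes)) {
    pth <- .scene_paths(out_dir, s)
    if (!file.exists(pth$segments))
      stop("dependency error: no segment/vote table (run `polarity` first)",
           call. = FALSE)
    segs <- read_table(pth$segments, type = "segment")
    cl <- call_filaments(segs, alpha = cfg$alpha, n_min = cfg$n_min)
    cl$tomogram_id <- s
    calls <- rbind(calls, cl)
    tr <- table_to_traces(read_table(pth$traces))
    for (t_ in tr) { t_$tomogram_id <- s; traces <- c(traces, list(t_)) }
  }
  smry <- summarize_fractions(calls, traces, tip_axis = c(1, 0, 0))
  write_table(smry$calls, file.path(out_dir, "filament_calls.tsv"),
              type = "call")
  utils::write.csv(smry$per_tomogram,
                   file.path(out_dir, "fraction_stacked_columns.csv"),
                   row.names = FALSE)
  .log_line(log_con, "tomograms=%d tip_ward=%.1f%% +/- %.1f%% unresolved=%.1f%%",
            nrow(smry$per_tomogram), smry$aggregate_mean, smry$aggregate_sd,
            100 * smry$unresolved_fraction)
  invisible(smry)
}

.stage_receptors <- function(cfg, out_dir, log_con) {
  seeds <- derive_seeds(cfg$seed, cfg$n_scenes, salt = 9L)
  heights <- numeric(0)
  for (s in seq_len(cfg$n_scenes)) {
    pth <- .scene_paths(out_dir, s)
    if (!file.exists(pth$mrc))
      stop("dependency error: run `simulate` first (missing ", pth$mrc, ")",
           call. = FALSE)
    tomo <- read_mrc(pth$mrc, tilt_range = cfg$tilt_range)
    sp <- config_scene_spec(cfg, seeds[s])
    mm <- estimate_normals(membrane_interior_mask(sp), cfg$pixel_size,
                           support_z = sp$support_z, downsample = 2)
    picks <- pick_densities(tomo, mm, attach_band = cfg$attach_band,
                            height_band = cfg$receptor_band,
                            tilt_max = cfg$tilt_max, min_sep = cfg$min_sep)
    write_table(picks, pth$picks, type = "pick")
    .log_line(log_con, "scene=%d candidates=%d kept=%d rejected=%d",
              s, nrow(picks), sum(picks$kept), sum(!picks$kept))
    if (sum(picks$kept) < cfg$k3d) next
    stack <- extract_picks(tomo, picks, cfg$receptor_box, cfg$center_offset)
    cls <- classify_3d(stack, k = cfg$k3d, seed = seeds[s])
    sel <- refined_class_average(stack, cls$labels, cls$selected)
    membrane_z <- (cfg$receptor_box / 2 - 0.5) * cfg$pixel_size -
      cfg$center_offset + 2.5
    h <- measure_height(sel, membrane_z, level = cfg$height_level,
                        pixel_size = cfg$pixel_size)
    heights <- c(heights, h$height)
    write_mrc(sel, file.path(out_dir, sprintf("scene_%03d_class.mrc", s)),
              pixel_size = cfg$pixel_size)
    .log_line(log_con, "scene=%d selected_class=%d height=%.2f nm",
              s, cls$selected, h$height)
  }
  invisible(heights)
}

.stage_fsc <- function(cfg, out_dir, log_con) {
  pth <- .scene_paths(out_dir, 1)
  if (!file.exists(pth$segments))
    stop("dependency error: run `polarity` first", call. = FALSE)
  segs <- read_table(pth$segments, type = "segment")
  tomo <- read_mrc(pth$mrc, tilt_range = cfg$tilt_range)
  use <- which(segs$polarity_vote != 0)
  ex <- extract_segments(tomo, segs[use, ], cfg$box_edge)
  keep <- !ex$segments$rejected
  ori <- data.frame(inplane = segs$inplane_angle[use][keep],
                    flip = segs$polarity_vote[use][keep] == -1,
                    sx = 0, sy = 0)
  fsc <- split_half_fsc(ex$boxes[keep], ori, seed = cfg$seed,
                        pixel_size = cfg$pixel_size, helical = cfg$helical)
  utils::write.table(
    data.frame(frequency = fsc$shell_frequencies,
               correlation = fsc$correlations),
    file.path(out_dir, "fsc.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  .log_line(log_con, "fsc: res(0.5)=%s A res(0.143)=%s A",
            format(fsc$resolution_at_05), format(fsc$resolution_at_0143))
  invisible(fsc)
}
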