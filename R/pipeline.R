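#' Default experiment configuration
#'
#' Configuration of a full in-silico perfusion experiment mirroring the
#' reference study design: four groups (capillary tube and parallel-plate
#' chamber, each static and under 10 mPa flow), six independent samples per
#' group, one simulated field of view per sample. The perfused-capillary
#' group carries the osteogenic signature — peripheral stress fibres and
#' elevated nuclear marker intensity; the capillary groups are set above the
#' chamber groups, reflecting the curvature effect.
#'
#' Scene defaults here are scaled to a practical field (256 x 256 px,
#' 5 planes, 6 cells) so a whole experiment runs in seconds; pass
#' `scene` overrides (e.g. `image_size = c(1024, 1024), n_planes = 20`)
#' for full-scale acquisition geometry.
#'
#' @param seed Base seed; per-scene seeds are derived from it.
#' @param n_samples Independent samples (devices) per group.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 20200911L, n_samples = 6L) {
  structure(list(
    design = list(
      capillary = list(diameter = 560e-6, flow_ul_min = 10),
      ppfc = list(width = 5e-3, height = 200e-6, flow_ul_min = 20),
      viscosity = 1.0e-3, density = 1000),
    scene = list(image_size = c(256L, 256L), n_planes = 5L,
                 pixel_size = 1.14, n_cells = 6L,
                 cell_radius_range = c(22, 30),
                 nucleus_radius_range = c(8, 12),
                 noise = list(poisson_scale = 0.5, gaussian_sd = 20,
                              background_level = 100)),
    groups = list(
      cap_static = list(runx2_mean = 2200, runx2_sd = 250,
                        phenotype = "homogeneous_filaments"),
      cap_flow = list(runx2_mean = 3200, runx2_sd = 250,
                      phenotype = "peripheral_stress_fibres"),
      ppfc_static = list(runx2_mean = 1500, runx2_sd = 250,
                         phenotype = "homogeneous_filaments"),
      ppfc_flow = list(runx2_mean = 1600, runx2_sd = 250,
                       phenotype = "homogeneous_filaments")),
    n_samples = as.integer(n_samples),
    segmentation = list(sigma = 2, watershed_tolerance = 2,
                        min_area = 80, max_area = 2500,
                        min_solidity = 0.85, r_touch = 3, lambda = 1e-4),
    texture = list(g = 8L, d = 3L, quantization = "region"),
    stats = list(alpha = 0.05, unit = "sample"),
    seed = as.integer(seed)), class = "run_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file.
#' @param config A `run_config` list.
#' @return `read_run_config` returns a `run_config`;
#'   `write_run_config` invisibly returns `path`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  cfg <- utils::modifyList(base, cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(config) {
  missing <- setdiff(PERFUSION_GROUPS, names(config$groups))
  if (length(missing)) {
    stop("config validation error: missing group(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (g in names(config$groups)) {
    gc <- config$groups[[g]]
    if (is.null(gc$runx2_mean) || gc$runx2_mean <= 0) {
      stop("config validation error: group ", g,
           " needs a positive runx2_mean", call. = FALSE)
    }
    if (!gc$phenotype %in% c("homogeneous_filaments",
                             "peripheral_stress_fibres")) {
      stop("config validation error: group ", g, " has unknown phenotype ",
           gc$phenotype, call. = FALSE)
    }
  }
  if (is.null(config$seed)) {
    stop("config validation error: explicit `seed` required", call. = FALSE)
  }
  invisible(TRUE)
}

# Derived per-scene seed, kept within 32-bit integer range.
scene_seed <- function(base_seed, group_index, sample_index) {
  as.integer((as.numeric(base_seed) + 7919 * group_index + sample_index) %%
               2147483647)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Quantify one stack: projection, segmentation, per-cell measurement
#'
#' The single-field pipeline: maximum-intensity projection, channel split,
#' nucleus segmentation from DAPI, automated isolated-cell QC, cytoplasm
#' propagation from phalloidin, then per-cell nuclear marker intensity and
#' actin texture.
#'
#' @param stack An `image_stack`.
#' @param seg A [seg_params()].
#' @param tex A [texture_params()].
#' @return List of class `quantified_stack`: `cells` (per-cell data frame),
#'   `nuclei` and `cytoplasm` label masks, `qc` report, `projection`.
#' @export
quantify_stack <- function(stack, seg = seg_params(),
                           tex = texture_params()) {
  proj <- max_intensity_projection(stack)
  chans <- split_channels(proj)
  nuc <- segment_nuclei(chans$dapi, seg)
  filt <- filter_isolated_cells(nuc$mask, seg)
  cyto <- propagate_cytoplasm(filt$mask, chans$phalloidin, seg)
  cells <- measure_cells(chans, filt$mask, cyto, tex)
  structure(list(cells = cells, nuclei = filt$mask, cytoplasm = cyto,
                 qc = filt$report, projection = proj),
            class = "quantified_stack")
}

scene_spec_for_group <- function(config, group, seed) {
  gc <- config$groups[[group]]
  sc <- config$scene
  ph_args <- gc$phenotype_params
  phenotype <- do.call(phenotype_spec, c(list(kind = gc$phenotype),
                                         ph_args))
  args <- list(phenotype = phenotype, runx2_mean = gc$runx2_mean,
               seed = seed)
  if (!is.null(gc$runx2_sd)) args$runx2_sd <- gc$runx2_sd
  for (f in c("image_size", "n_planes", "pixel_size", "n_cells",
              "cell_radius_range", "nucleus_radius_range", "dapi_mean",
              "actin_mean", "noise", "min_cell_separation",
              "allow_border_cells", "allow_overlaps", "axial_sigma",
              "bit_depth")) {
    if (!is.null(sc[[f]])) args[[f]] <- sc[[f]]
  }
  do.call(scene_spec, args)
}

#' Run a full in-silico perfusion experiment
#'
#' Generates synthetic confocal fields for every group and sample of the
#' configuration, quantifies each field (projection, segmentation, per-cell
#' measurement), compares the groups with one-way ANOVA and Tukey HSD, and
#' reports the shear-stress design of both devices. The run is a pure
#' function of the configuration: per-scene seeds are derived from the base
#' seed, so identical configs give identical per-cell tables.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Optional output directory; when given, writes the per-cell
#'   CSV, per-sample CSV, ANOVA/Tukey tables, design report and a
#'   `manifest.json` with the config hash and file list.
#' @param save_images Also write the simulated stacks and label masks as
#'   TIFF (only with `out_dir`).
#' @return Object of class `perfusion_run`: `cells`, `samples`,
#'   `comparison`, `design`, `manifest`.
#' @export
run_experiment <- function(config = default_run_config(), out_dir = NULL,
                           save_images = FALSE) {
  validate_run_config(config)
  t0 <- Sys.time()
  warnings_log <- character(0)
  seg <- do.call(seg_params, config$segmentation)
  tex <- do.call(texture_params, config$texture)

  design <- rbind(
    design_report(tube_geometry(config$design$capillary$diameter),
                  flow_rate = ul_min_to_m3s(config$design$capillary$flow_ul_min),
                  viscosity = config$design$viscosity,
                  density = config$design$density),
    design_report(chamber_geometry(config$design$ppfc$width,
                                   config$design$ppfc$height),
                  flow_rate = ul_min_to_m3s(config$design$ppfc$flow_ul_min),
                  viscosity = config$design$viscosity,
                  density = config$design$density))

  all_cells <- list()
  files <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  for (gi in seq_along(PERFUSION_GROUPS)) {
    group <- PERFUSION_GROUPS[gi]
    for (si in seq_len(config$n_samples)) {
      seed <- scene_seed(config$seed, gi, si)
      spec <- scene_spec_for_group(config, group, seed)
      stage <- sprintf("%s sample %d", group, si)
      q <- withCallingHandlers(
        {
          scene <- generate_scene(spec)
          if (isTRUE(save_images) && !is.null(out_dir)) {
            files <- c(files, write_stack(scene$stack,
                                          file.path(out_dir, "images"),
                                          prefix = sprintf("%s_s%02d",
                                                           group, si)))
          }
          quantify_stack(scene$stack, seg, tex)
        },
        warning = function(w) {
          warnings_log <<- c(warnings_log,
                             sprintf("[%s] %s", stage, conditionMessage(w)))
          invokeRestart("muffleWarning")
        },
        error = function(e) {
          stop(sprintf("stage failed (%s): %s", stage, conditionMessage(e)),
               call. = FALSE)
        })
      if (nrow(q$cells)) {
        q$cells$group <- group
        q$cells$sample <- sprintf("%s_s%02d", group, si)
        all_cells[[length(all_cells) + 1]] <- q$cells
      }
    }
  }
  cells <- do.call(rbind, all_cells)
  samples <- aggregate_samples(cells)
  comparison <- withCallingHandlers(
    compare_groups(cells, alpha = config$stats$alpha,
                   unit = config$stats$unit),
    warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[compare] %s", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })

  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("perfusim")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   n_cells = nrow(cells),
                   files = files,
                   warnings = warnings_log)
  if (!is.null(out_dir)) {
    f_cells <- file.path(out_dir, "cells.csv")
    write_cells_csv(cells, f_cells, tex)
    f_samples <- file.path(out_dir, "samples.csv")
    utils::write.csv(samples, f_samples, row.names = FALSE)
    f_design <- file.path(out_dir, "design.csv")
    utils::write.csv(design, f_design, row.names = FALSE)
    tk <- do.call(rbind, lapply(names(comparison$measures), function(m) {
      cbind(measure = m, comparison$measures[[m]]$tukey)
    }))
    f_tukey <- file.path(out_dir, "tukey.csv")
    utils::write.csv(tk, f_tukey, row.names = FALSE)
    an <- do.call(rbind, lapply(names(comparison$measures), function(m) {
      a <- comparison$measures[[m]]$anova
      data.frame(measure = m, F = a$F, p = a$p,
                 df_between = a$df[1], df_within = a$df[2])
    }))
    f_anova <- file.path(out_dir, "anova.csv")
    utils::write.csv(an, f_anova, row.names = FALSE)
    manifest$files <- c(manifest$files, f_cells, f_samples, f_design,
                        f_tukey, f_anova)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(cells = cells, samples = samples, comparison = comparison,
                 design = design, manifest = manifest),
            class = "perfusion_run")
}

#' @export
print.perfusion_run <- function(x, ...) {
  cat("In-silico perfusion experiment\n")
  cat(sprintf("  %d cells measured across %d samples\n",
              nrow(x$cells), nrow(x$samples)))
  cat("\nDevice design:\n")
  print(x$design, row.names = FALSE)
  cat("\n")
  print(x$comparison)
  invisible(x)
}
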