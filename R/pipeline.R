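# Orchestration of the inline shim workflow:
#   Calc Shim : register -> average -> segment -> field-map -> solve -> write
#               plain-text shim configuration + JSON report + figures
#   Adjust Shim: read the configuration file back as a shim solution.

#' Default pipeline configuration
#'
#' Units are explicit throughout: echo times in us, geometry in mm,
#' frequencies in Hz. The acquisition defaults follow the lung field-mapping
#' protocol (TE1 570 us, spacing 100 us, 4 echoes, 3 repetitions, 128 x 128
#' over 450 x 450 mm).
#'
#' @param seed integer seed used by every stochastic stage.
#' @param output_dir directory for pipeline outputs.
#' @return nested list of class `pipeline_config` (JSON-serializable).
#' @export
pipeline_config <- function(seed = 1L, output_dir = tempfile("lungshim_")) {
  structure(list(
    acquisition = list(te1_us = 570, delta_t_us = 100, n_echoes = 4L,
                       n_reps = 3L, snr = 20, motion_amplitude_px = 5),
    phantom = unclass(phantom_params()),
    preprocess = unclass(register_settings()),
    segmentation = unclass(segment_settings()),
    fieldmap = list(floor_frac = 0.05, weighted = FALSE),
    shim = list(order = 2L),
    evaluate = c(unclass(bssfp_params()), list(bins = 50L)),
    seed = as.integer(seed),
    output_dir = output_dir
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()] list.
#' @param path JSON file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  for (blk in names(base)) {
    if (blk %in% names(cfg)) {
      if (is.list(base[[blk]])) {
        base[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
      } else {
        base[[blk]] <- cfg[[blk]]
      }
    }
  }
  base
}

log_stage <- function(stage, ..., logfile = NULL) {
  msg <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste0(..., collapse = ""))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Simulate a phantom acquisition from a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return list with `truth`, `geometry`, `series`.
#' @export
simulate_acquisition <- function(config = pipeline_config()) {
  ph <- do.call(phantom_params, config$phantom[names(config$phantom) %in%
                                                 names(formals(phantom_params))])
  acq <- config$acquisition
  phant <- make_phantom(ph, seed = config$seed)
  series <- simulate_echo_series(
    phant$truth, phant$geometry,
    te1 = acq$te1_us, delta_t = acq$delta_t_us,
    n_echoes = acq$n_echoes, n_reps = acq$n_reps, snr = acq$snr,
    motion_amplitude = acq$motion_amplitude_px,
    seed = config$seed + 1L
  )
  list(truth = phant$truth, geometry = phant$geometry, series = series)
}

#' Run the full Calc Shim workflow
#'
#' Registers and averages the echo series, segments the lungs from the
#' first-echo magnitude, fits the field map from the incremental phases,
#' solves the mask-restricted shim problem, predicts the residual field, and
#' writes the plain-text shim configuration, a JSON report and PNG figures to
#' the configured output directory.
#'
#' @param series an `echo_series`, or a directory readable by
#'   [read_echo_series()].
#' @param config a [pipeline_config()].
#' @param mask optional externally supplied lung mask (logical matrix or
#'   `lung_mask`) bypassing the classical segmentation.
#' @param write_outputs set `FALSE` to skip all file output.
#' @return list with `solution`, `field`, `residual`, `mask`, `aligned`,
#'   `report` (the statistics that go into the JSON report), `paths`.
#' @export
calc_shim <- function(series, config = pipeline_config(), mask = NULL,
                      write_outputs = TRUE) {
  if (is.character(series)) series <- read_echo_series(series)
  stopifnot(inherits(series, "echo_series"))
  outdir <- config$output_dir
  logfile <- NULL
  if (write_outputs) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(outdir, "calcshim.log")
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  log_stage("preprocess", sprintf("registering %d echoes x %d repetitions",
                                  series$n_echoes, series$n_reps),
            logfile = logfile)
  reg <- do.call(register_settings,
                 config$preprocess[names(config$preprocess) %in%
                                     names(formals(register_settings))])
  aligned <- run_stage("preprocess", align_and_average(series, reg))

  log_stage("segmentation", "lung mask from first-echo magnitude",
            logfile = logfile)
  first_mag <- Mod(aligned$data[, , 1, 1])
  lmask <- run_stage("segmentation", {
    if (!is.null(mask)) {
      if (inherits(mask, "lung_mask")) mask else
        as_lung_mask(mask, series$geometry)
    } else {
      seg <- do.call(segment_settings,
                     config$segmentation[names(config$segmentation) %in%
                                           names(formals(segment_settings))])
      segment_lungs(first_mag, seg, series$geometry)
    }
  })

  log_stage("fieldmap", "incremental-phase least squares", logfile = logfile)
  field <- run_stage("fieldmap",
                     compute_fieldmap(aligned,
                                      floor_frac = config$fieldmap$floor_frac,
                                      weighted = isTRUE(config$fieldmap$weighted)))

  log_stage("shim", "mask-restricted spherical-harmonic fit", logfile = logfile)
  basis <- build_basis(series$geometry, order = config$shim$order)
  solution <- run_stage("shim", solve_shim(field, lmask, basis))
  residual <- predict_residual(field, solution, basis)

  log_stage("evaluate", "pre/post in-mask statistics", logfile = logfile)
  ev <- config$evaluate
  bssfp <- bssfp_params(ev$tr, ev$te, ev$flip_angle, ev$t1, ev$t2,
                        ev$phase_cycling)
  pre_stats <- mask_stats(field, lmask, bins = ev$bins)
  post_stats <- mask_stats(residual, lmask, bins = ev$bins)
  bssfp_pre <- render_bssfp(field, first_mag, bssfp, lmask, bins = ev$bins)
  bssfp_post <- render_bssfp(residual, first_mag, bssfp, lmask, bins = ev$bins)
  report <- list(
    pre_shim = pre_stats[c("mean_hz", "range_hz", "std_hz", "n_voxels")],
    post_shim = post_stats[c("mean_hz", "range_hz", "std_hz")],
    improvement = list(
      mean_reduction_hz = abs(pre_stats$mean_hz) - abs(post_stats$mean_hz),
      range_reduction_hz = pre_stats$range_hz - post_stats$range_hz
    ),
    bssfp = list(pre_mean = bssfp_pre$stats$mean, pre_std = bssfp_pre$stats$std,
                 post_mean = bssfp_post$stats$mean,
                 post_std = bssfp_post$stats$std),
    coefficients = as.list(solution$coefficients),
    residual_rms_hz = sqrt(solution$residual_ss / solution$n_voxels),
    n_mask_voxels = solution$n_voxels
  )

  paths <- list()
  if (write_outputs) {
    paths$shim_config <- file.path(outdir, "shim_config.txt")
    write_shim_config(solution, paths$shim_config, series$geometry)
    paths$report <- file.path(outdir, "report.json")
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    pd <- c(series$geometry$pixel_mm, 1)
    paths$fieldmap <- file.path(outdir, "fieldmap_hz.nii")
    nu_out <- field$nu_hat; nu_out[!is.finite(nu_out)] <- 0
    write_nifti(nu_out, paths$fieldmap, pd)
    res_out <- residual$nu_hat; res_out[!is.finite(res_out)] <- 0
    paths$residual <- file.path(outdir, "residual_hz.nii")
    write_nifti(res_out, paths$residual, pd)
    paths$mask <- file.path(outdir, "lung_mask.nii")
    write_nifti(lmask$mask, paths$mask, pd, datatype = "uint8")
    paths$figures <- write_report_figures(field, residual, lmask,
                                          pre_stats, post_stats,
                                          bssfp_pre, bssfp_post, outdir)
    log_stage("done", "outputs in ", outdir, logfile = logfile)
  }

  list(solution = solution, field = field, residual = residual, mask = lmask,
       aligned = aligned, basis = basis, report = report, paths = paths)
}

write_report_figures <- function(field, residual, lmask, pre_stats, post_stats,
                                 bssfp_pre, bssfp_post, outdir) {
  figdir <- file.path(outdir, "figures")
  dir.create(figdir, showWarnings = FALSE)
  draw_map <- function(nu, main) {
    v <- nu; v[!is.finite(v)] <- 0
    graphics::image(t(v[nrow(v):1, ]), col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  f1 <- file.path(figdir, "fieldmaps.png")
  grDevices::png(f1, width = 900, height = 450)
  graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  draw_map(field$nu_hat, "field map (Hz)")
  draw_map(residual$nu_hat, "predicted residual (Hz)")
  grDevices::dev.off()
  f2 <- file.path(figdir, "histograms.png")
  grDevices::png(f2, width = 900, height = 450)
  graphics::par(mfrow = c(1, 2))
  plot_hist <- function(st, main) {
    graphics::plot(st$histogram$breaks,
                   c(st$histogram$counts, 0), type = "s",
                   xlab = "off-resonance (Hz)", ylab = "voxels", main = main)
  }
  plot_hist(pre_stats, sprintf("pre-shim (mean %.0f Hz, range %.0f Hz)",
                               pre_stats$mean_hz, pre_stats$range_hz))
  plot_hist(post_stats, sprintf("post-shim (mean %.0f Hz, range %.0f Hz)",
                                post_stats$mean_hz, post_stats$range_hz))
  grDevices::dev.off()
  f3 <- file.path(figdir, "bssfp.png")
  grDevices::png(f3, width = 900, height = 450)
  graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  graphics::image(t(bssfp_pre$image[nrow(bssfp_pre$image):1, ]),
                  col = grDevices::gray.colors(64), axes = FALSE,
                  main = "bSSFP pre-shim", useRaster = TRUE)
  graphics::image(t(bssfp_post$image[nrow(bssfp_post$image):1, ]),
                  col = grDevices::gray.colors(64), axes = FALSE,
                  main = "bSSFP post-shim", useRaster = TRUE)
  grDevices::dev.off()
  c(f1, f2, f3)
}

#' Read a shim configuration file (Adjust Shim)
#'
#' @param config_path path to the plain-text shim configuration.
#' @return a `shim_solution` (see [read_shim_config()]).
#' @export
adjust_shim <- function(config_path) {
  read_shim_config(config_path)
}
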