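# End-to-end orchestration: chemistry -> refractive index -> sphere
# training set -> PCA subspace -> semi-capsule reconstruction sweep ->
# peak-shift negative control -> report files.

#' Default pipeline configuration
#'
#' The study conditions of the sphere-subspace experiment: four-band
#' chemistry (1500, 2010, 3000, 5400 cm^-1; FWHM 60 cm^-1; amplitude 0.1;
#' offset 1.5), grid 1000-6000 cm^-1 in 2 cm^-1 steps, a 10 x 10 training
#' grid (offsets 1.3-1.7, radii 5-10 um), a semi-capsule target with
#' R = 10 um and L = 10 um, component sweep 5..12, and the four-band
#' peak-shift control 1500 -> 1520, 2010 -> 1950, 3000 -> 3500,
#' 5400 -> 5350 cm^-1 at n_comp = 12.
#'
#' @return a nested configuration list accepted by \code{\link{run_pipeline}}
#' @export
default_pipeline_config <- function() {
  list(
    grid = list(start = 1000, stop = 6000, step = 2),
    chemistry = list(
      n_offset = 1.5,
      bands = lapply(c(1500, 2010, 3000, 5400), function(cc)
        list(center = cc, width = 60, amplitude = 0.1))),
    training = list(offsets = list(min = 1.3, max = 1.7, n = 10),
                    radii = list(min = 5, max = 10, n = 10)),
    target = list(shape = "semi-capsule", R = 10, L = 10),
    n_comp = 5:12,
    peak_shift = list(mapping = list(`1500` = 1520, `2010` = 1950,
                                     `3000` = 3500, `5400` = 5350),
                      n_comp = 12))
}

#' Read a pipeline configuration file
#'
#' Configurations are YAML files with the structure of
#' \code{\link{default_pipeline_config}}; missing sections fall back to
#' the defaults.
#'
#' @param path YAML file path
#' @return a configuration list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

config_chemistry <- function(cfg) {
  chemistry_model(lapply(cfg$chemistry$bands, function(b)
    lorentz_band(b$center, b$width, b$amplitude)),
    n_offset = cfg$chemistry$n_offset)
}

config_grid <- function(cfg) {
  default_grid(cfg$grid$start, cfg$grid$stop, cfg$grid$step)
}

config_axis <- function(ax) {
  if (is.list(ax)) seq(ax$min, ax$max, length.out = ax$n) else as.numeric(ax)
}

config_mapping <- function(mp) {
  out <- vapply(mp, as.numeric, numeric(1))
  names(out) <- names(mp)
  out
}

#' Run the full sphere-subspace pipeline
#'
#' Executes every stage of the subspace experiment from one configuration:
#' synthesize the complex refractive index, build the sphere extinction
#' training set, fit the PCA subspace, reconstruct the target geometry's
#' extinction curve over the component sweep, and (if configured) run the
#' peak-shift negative control. Writes, under \code{out_dir}:
#' \code{index.csv} (the synthesized refractive index),
#' \code{basis.csv} (mean curve and components), \code{basis_meta.json},
#' \code{target_qext.csv}, \code{summary.json} (machine-readable results)
#' and \code{log.txt} (per-stage parameters and durations). All outputs
#' except the log are byte-deterministic for identical configurations; on
#' any stage error, partial outputs are removed.
#'
#' @param config a configuration list (see
#'   \code{\link{default_pipeline_config}}) or the path of a YAML file
#' @param out_dir output directory, created if needed
#' @return the summary list, invisibly
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "pipeline-out") {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- character(0)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, params, expr) {
    log_lines <<- c(log_lines, sprintf("stage %s: %s", name, params))
    t1 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: done in %.2f s", name,
                                       proc.time()[["elapsed"]] - t1))
    val
  }
  emit <- function(fname, writer) {
    p <- file.path(out_dir, fname)
    writer(p)
    written <<- c(written, p)
    p
  }

  grid <- config_grid(config)
  chem <- config_chemistry(config)

  m <- stage("synth-index",
             sprintf("%d bands, n_offset %.3g, grid %g:%g:%g",
                     length(chem$bands), chem$n_offset, config$grid$start,
                     config$grid$stop, config$grid$step),
             synth_refractive_index(chem, grid))
  emit("index.csv", function(p) write_spectrum(m, p))

  tg <- training_grid(config_axis(config$training$offsets),
                      config_axis(config$training$radii))
  curves <- stage("training-set",
                  sprintf("%d offsets x %d radii", length(tg$offsets),
                          length(tg$radii)),
                  build_training_set(chem, tg, grid))

  max_comp <- max(config$n_comp,
                  if (!is.null(config$peak_shift)) config$peak_shift$n_comp)
  basis <- stage("fit-subspace", sprintf("max_comp %d", max_comp),
                 fit_subspace(curves, max_comp = max_comp))
  emit("basis.csv", function(p) {
    M <- cbind(grid, basis$mean_curve, basis$components)
    colnames(M) <- c("wavenumber_cm-1", "mean",
                     sprintf("pc%02d", seq_len(ncol(basis$components))))
    write_matrix_csv(M, p)
  })
  emit("basis_meta.json", function(p) write_json_file(list(
    n_curves = tg$n_curves,
    offsets = tg$offsets, radii_um = tg$radii,
    explained_variance = basis$explained_variance,
    centered = basis$centered), p))

  ts <- stage("target-qext",
              sprintf("%s R=%g L=%g", config$target$shape, config$target$R,
                      config$target$L %||% 0), {
    geom <- scatterer_geometry(config$target$shape, R = config$target$R,
                               L = config$target$L %||% 0)
    list(geom = geom, q = qext_for_geometry(chem, geom, grid))
  })
  geom <- ts$geom
  target <- ts$q
  emit("target_qext.csv", function(p) write_spectrum(target, p))

  reports <- stage("reconstruct",
                   paste("n_comp", paste(config$n_comp, collapse = ",")),
                   sweep_ncomp(target, basis, config$n_comp, chem = chem))
  summary <- list(
    target = list(shape = geom$shape, R_um = geom$R, L_um = geom$L),
    n_curves = tg$n_curves,
    reconstruction = lapply(reports, function(r)
      list(n_comp = r$n_comp, rel_rmse = r$rel_rmse,
           band_residuals = as.list(r$band_residuals))))

  if (!is.null(config$peak_shift)) {
    mapping <- config_mapping(config$peak_shift$mapping)
    ps <- stage("peak-shift",
                sprintf("%d bands moved, n_comp %d", length(mapping),
                        config$peak_shift$n_comp),
                peak_shift_experiment(chem, mapping, basis, geom,
                                      config$peak_shift$n_comp, grid))
    summary$peak_shift <- list(
      mapping = as.list(mapping),
      n_comp = config$peak_shift$n_comp,
      rel_rmse_original = ps$original$rel_rmse,
      rel_rmse_shifted = ps$shifted$rel_rmse,
      window_energy_original = as.list(ps$energy_original),
      window_energy_shifted = as.list(ps$energy_shifted),
      window_ratio = as.list(ps$ratio),
      total_ratio = ps$total_ratio)
  }

  emit("summary.json", function(p) write_json_file(summary, p))
  log_lines <- c(log_lines, sprintf("pipeline done in %.2f s",
                                    proc.time()[["elapsed"]] - t0))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(summary)
}

write_matrix_csv <- function(M, path) {
  lines <- c(paste(colnames(M), collapse = ","),
             apply(M, 1L, function(r) paste(fmt_num(r), collapse = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

write_json_file <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
}
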