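#' Write simulation outputs to a directory
#'
#' Emits the probe series as CSV (`probe.csv`, header `t,u,v`, SI units,
#' one row per step), the run manifest as JSON (`manifest.json`), and the
#' final-state fields as plain-text snapshot CSVs (`snapshot_u.csv`,
#' `snapshot_v.csv`, `snapshot_p.csv`, `snapshot_nu_sgs.csv`,
#' `snapshot_mask.csv`) with the grid attributes in `grid.json` — a
#' text-based field container readable anywhere.
#'
#' @param result a `simulation_result`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(result, outdir) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pr <- data.frame(t = result$probe$t,
                   u = result$probe$u[, 1], v = result$probe$u[, 2])
  utils::write.csv(pr, file.path(outdir, "probe.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  st <- result$final
  wf <- function(m, nm) utils::write.table(
    m, file.path(outdir, paste0("snapshot_", nm, ".csv")),
    sep = ",", row.names = FALSE, col.names = FALSE)
  wf(st$u, "u"); wf(st$v, "v"); wf(st$p, "p")
  wf(if (is.null(st$nu_sgs)) matrix(0, result$grid$nx, result$grid$ny)
     else st$nu_sgs, "nu_sgs")
  wf(result$grid$mask * 1L, "mask")
  jsonlite::write_json(
    list(nx = result$grid$nx, ny = result$grid$ny, h = result$grid$h,
         Lx = result$grid$Lx, Ly = result$grid$Ly, t = st$t, units = "SI"),
    file.path(outdir, "grid.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a probe CSV written by [write_simulation()]
#'
#' @param path path to a `t,u,v` CSV.
#' @param window optional statistics window `c(t0, t1)`.
#' @return A [probe_series()].
#' @export
read_probe_csv <- function(path, window = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("t", "u", "v") %in% names(d)))
    stop("read_probe_csv: expected header t,u,v", call. = FALSE)
  ser <- probe_series(d$t, cbind(u = d$u, v = d$v))
  if (!is.null(window)) ser$window <- window
  ser
}

#' Build a simulation configuration from a YAML file
#'
#' Reads the run configuration (geometry, resolution, closure via
#' `les.model` / optional `les.cm`, inlet, stations, seed) from YAML and
#' returns the corresponding [simulation_config()]. Sensible defaults apply
#' for omitted keys; see the shipped example under
#' `system.file("extdata", "example_config.yaml", package = "stenoflow")`.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$geometry
  geometry <- channel_geometry(
    length = g$length, width = g$width,
    occlusion = if (is.null(g$occlusion)) 0 else g$occlusion,
    center = if (is.null(g$center)) 0.375 * g$length else g$center)
  les <- y$les
  closure <- sgs_closure(if (is.null(les$model)) "none" else les$model,
                         cm = les$cm)
  inl <- y$inlet
  for (k in c("mean_flow", "peak_flow", "period"))
    if (!is.null(inl[[k]])) inl[[k]] <- as.numeric(inl[[k]])
  inlet <- if (identical(inl$kind, "pulsatile")) {
    make_waveform(mean_flow = inl$mean_flow, peak_flow = inl$peak_flow,
                  period = if (is.null(inl$period)) 1 else inl$period,
                  nu = if (is.null(y$nu)) 1e-6 else y$nu)
  } else {
    inlet_waveform("constant", mean_flow = inl$mean_flow,
                   nu = if (is.null(y$nu)) 1e-6 else y$nu)
  }
  simulation_config(
    geometry = geometry, dx = y$dx, dt = y$dt,
    end_time = y$end_time,
    washout = if (is.null(y$washout)) y$end_time / 5 else y$washout,
    closure = closure, inlet = inlet,
    nu = if (is.null(y$nu)) 1e-6 else y$nu,
    stations = if (is.null(y$stations)) c(-0.75, 0, 0.6, 1.2)
               else as.numeric(y$stations),
    noise_amplitude = if (is.null(y$noise_amplitude)) 0.01
                      else y$noise_amplitude,
    seed = if (is.null(y$seed)) 1L else y$seed,
    snapshot_every = if (is.null(y$snapshot_every)) 0L else y$snapshot_every)
}

#' Write station analytics as a tidy CSV
#'
#' One row per (station, y, quantity): the tidy table the reporting layer
#' and external plotting consume.
#'
#' @param profiles output of [station_tke()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(station = p$offset, y = p$y, quantity = "tke",
               value = p$tke)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a Welch PSD as CSV (`frequency, psd`)
#'
#' @param psd a `spectral_density`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(psd, path) {
  utils::write.csv(data.frame(frequency = psd$freq, psd = psd$psd),
                   path, row.names = FALSE)
  invisible(path)
}
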