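#' Simulation configuration
#'
#' Bundles everything one run needs: geometry, resolution, time stepping,
#' closure, inlet, probe/station layout and the statistics window. Stations
#' are expressed in reference-width units relative to the constriction
#' centre, mirroring the slice layout used to interrogate post-stenotic
#' flow (`-0.75, 0.0, 0.6, 1.2` by default, plus a point probe one width
#' downstream on the centreline).
#'
#' @param geometry a [channel_geometry()].
#' @param dx grid spacing (m).
#' @param dt time step (s); `NULL` picks `0.35 * h / u_max_expected` from
#'   the inlet peak velocity through the throat.
#' @param end_time physical end time (s).
#' @param washout initial interval discarded from statistics (s); default
#'   one fifth of `end_time`.
#' @param closure an [sgs_closure()].
#' @param inlet an [inlet_waveform()].
#' @param nu molecular kinematic viscosity (m^2/s).
#' @param stations slice positions in widths relative to the constriction
#'   centre.
#' @param probe point-probe position `c(x, y)` in metres, or `NULL` for the
#'   default (1 width downstream of the constriction, mid-channel).
#' @param noise_amplitude inlet white-noise seeding amplitude as a fraction
#'   of the mean inlet velocity (0 disables).
#' @param seed integer seed for the noise generator (bit-reproducible runs).
#' @param snapshot_every save a field snapshot every this many steps
#'   (0 = none; the final state is always kept).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(geometry, dx, dt = NULL, end_time,
                              washout = end_time / 5,
                              closure = sgs_closure("none"),
                              inlet,
                              nu = 1e-6,
                              stations = c(-0.75, 0, 0.6, 1.2),
                              probe = NULL,
                              noise_amplitude = 0.01,
                              seed = 1L,
                              snapshot_every = 0L) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(closure, "sgs_closure"),
            inherits(inlet, "inlet_waveform"),
            end_time > 0, washout >= 0)
  if (washout >= end_time)
    warning("simulation_config: washout >= end_time; ",
            "the statistics window is empty", call. = FALSE)
  if (is.null(probe))
    probe <- c(geometry$center + geometry$width, geometry$width / 2)
  structure(list(geometry = geometry, dx = dx, dt = dt,
                 end_time = end_time, washout = washout,
                 closure = closure, inlet = inlet, nu = nu,
                 stations = stations, probe = probe,
                 noise_amplitude = noise_amplitude, seed = as.integer(seed),
                 snapshot_every = as.integer(snapshot_every)),
            class = "simulation_config")
}

# peak inlet velocity estimate (centreline through the throat)
peak_velocity <- function(config) {
  g <- config$geometry
  tt <- seq(0, config$inlet$period, length.out = 65)
  qmax <- max(flow_rate(config$inlet, tt))
  umean <- ml_min_to_m3s(qmax) / (pi * g$width^2 / 4)
  1.5 * umean / (1 - g$occlusion)
}

# rolling polynomial hash of a serialized R object, for run provenance
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  hash <- 0
  for (b in bytes) hash <- (hash * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(hash))
}

#' Number of flow-throughs in a washout interval
#'
#' `T * U / L`: how many domain lengths a fluid parcel at the characteristic
#' velocity traverses during the discarded initialization interval, the
#' usual gauge for whether artificial initial transients have left the
#' domain.
#'
#' @param t_washout washout duration (s).
#' @param length domain length L (m).
#' @param velocity characteristic (peak inlet) velocity (m/s).
#' @return Dimensionless flow-through count.
#' @examples
#' washout_flow_throughs(2, 0.2, 0.15)  # 1.5
#' @export
washout_flow_throughs <- function(t_washout, length, velocity) {
  if (!(t_washout > 0 && length > 0 && velocity > 0))
    stop("washout_flow_throughs: all arguments must be positive",
         call. = FALSE)
  t_washout * velocity / length
}

#' Run a simulation
#'
#' Time-integrates the configured channel flow, recording a point-probe
#' velocity series at every step, cell-centre velocity samples along the
#' vertical station lines at every step, and (optionally) field snapshots.
#' Two runs with the same config and seed produce bit-identical series.
#'
#' @param config a [simulation_config()].
#' @param outdir optional directory; when given, probe CSV (`t,u,v`), run
#'   manifest JSON and final-state snapshot CSVs are written there.
#' @param verbose print progress every ~500 steps.
#' @return A `simulation_result` list: `probe` (a [probe_series()]),
#'   `stations` (per-station list with `x`, `y`, `u`/`v` matrices of
#'   step-by-station-line samples), `snapshots`, `final` state, `manifest`.
#' @export
run_simulation <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- build_grid(config$geometry, config$dx)
  g <- config$geometry
  upeak <- peak_velocity(config)
  dt <- config$dt
  if (is.null(dt)) dt <- 0.35 * grid$h / upeak
  nsteps <- as.integer(ceiling(config$end_time / dt))
  dt <- config$end_time / nsteps

  state <- flow_state(grid)
  closure <- config$closure

  # seeded inlet white noise: pregenerated once so runs are bit-identical
  # for a given (config, seed) and the global RNG stream is untouched
  noise_fun <- NULL
  k_cur <- 0L
  if (config$noise_amplitude > 0) {
    umean <- ml_min_to_m3s(config$inlet$mean_flow) / (pi * g$width^2 / 4)
    amp <- config$noise_amplitude * umean
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(config$seed)
    noise_mat <- matrix(stats::rnorm(nsteps * grid$ny, 0, amp),
                        nsteps, grid$ny)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    noise_fun <- function(ny, t) noise_mat[k_cur, ]
  }

  # station line columns (nearest cell-centre column per station)
  st_x <- g$center + config$stations * g$width
  st_i <- vapply(st_x, function(x) which.min(abs(grid$x - x)), integer(1))
  if (any(st_x < 0 | st_x > grid$Lx))
    stop("run_simulation: station outside the domain", call. = FALSE)
  pr_i <- which.min(abs(grid$x - config$probe[1]))
  pr_j <- which.min(abs(grid$y - config$probe[2]))

  times <- numeric(nsteps)
  probe_u <- numeric(nsteps); probe_v <- numeric(nsteps)
  st_u <- lapply(st_i, function(i) matrix(0, nsteps, grid$ny))
  st_v <- lapply(st_i, function(i) matrix(0, nsteps, grid$ny))
  snapshots <- list()
  nu_sgs_sum <- matrix(0, grid$nx, grid$ny); nu_sgs_n <- 0L

  ok <- TRUE; fail_msg <- NULL
  for (k in seq_len(nsteps)) {
    k_cur <- k
    state <- tryCatch(
      step(state, dt, config$nu, closure, inlet = config$inlet,
           geometry = g, inlet_noise = noise_fun),
      error = function(e) e)
    if (inherits(state, "error")) {
      ok <- FALSE; fail_msg <- conditionMessage(state)
      nsteps <- k - 1L
      break
    }
    closure <- state$closure
    times[k] <- state$t
    uc <- (state$u[1:grid$nx, , drop = FALSE] +
           state$u[2:(grid$nx + 1), , drop = FALSE]) / 2
    vc <- (state$v[, 1:grid$ny, drop = FALSE] +
           state$v[, 2:(grid$ny + 1), drop = FALSE]) / 2
    probe_u[k] <- uc[pr_i, pr_j]; probe_v[k] <- vc[pr_i, pr_j]
    for (s in seq_along(st_i)) {
      st_u[[s]][k, ] <- uc[st_i[s], ]
      st_v[[s]][k, ] <- vc[st_i[s], ]
    }
    if (state$t > config$washout && !is.null(state$nu_sgs)) {
      nu_sgs_sum <- nu_sgs_sum + state$nu_sgs; nu_sgs_n <- nu_sgs_n + 1L
    }
    if (config$snapshot_every > 0 && k %% config$snapshot_every == 0)
      snapshots[[length(snapshots) + 1]] <-
        list(t = state$t, u = state$u, v = state$v, p = state$p,
             nu_sgs = state$nu_sgs)
    if (verbose && k %% 500 == 0)
      message(sprintf("  t = %.3f / %.3f (%d steps)", state$t,
                      config$end_time, k))
  }

  keep <- seq_len(nsteps)
  probe <- probe_series(t = times[keep],
                        u = cbind(u = probe_u[keep], v = probe_v[keep]),
                        location = c(grid$x[pr_i], grid$y[pr_j]),
                        window = c(config$washout, config$end_time))
  stations <- lapply(seq_along(st_i), function(s) {
    list(x = grid$x[st_i[s]], offset = config$stations[s],
         y = grid$y, mask = grid$mask[st_i[s], ],
         u = st_u[[s]][keep, , drop = FALSE],
         v = st_v[[s]][keep, , drop = FALSE])
  })
  names(stations) <- sprintf("%+.2fd", config$stations)

  manifest <- list(
    config_hash = config_hash(config[setdiff(names(config), "dt")]),
    seed = config$seed, cells = grid$cells,
    avg_cell_length = grid$avg_cell_length,
    dt = dt, steps = nsteps,
    statistics_window = c(config$washout, config$end_time),
    closure = closure$model, completed = ok,
    failure = if (!ok) fail_msg)
  if (config$washout >= config$end_time)
    warning("run_simulation: empty statistics window (washout >= end time)",
            call. = FALSE)

  res <- structure(
    list(probe = probe, stations = stations, snapshots = snapshots,
         final = state, grid = grid, dt = dt, times = times[keep],
         nu_sgs_mean = if (nu_sgs_n > 0) nu_sgs_sum / nu_sgs_n,
         manifest = manifest, config = config),
    class = "simulation_result")
  if (!is.null(outdir)) write_simulation(res, outdir)
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$manifest$closure, "closure,",
      x$manifest$steps, "steps, dt =", signif(x$dt, 3), "s,",
      if (x$manifest$completed) "completed" else
        paste("FAILED:", x$manifest$failure), "\n")
  invisible(x)
}
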