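#' Probe time series
#'
#' Uniformly sampled velocity components at a point, with the statistics
#' window (the post-washout interval actually used for averaging).
#'
#' @param t sample times (s), uniformly spaced.
#' @param u numeric matrix, one column per velocity component (m/s).
#' @param location probe position (m), informational.
#' @param window `c(t0, t1)` statistics window; defaults to the full record.
#' @return Object of class `probe_series`.
#' @export
probe_series <- function(t, u, location = c(NA_real_, NA_real_),
                         window = range(t)) {
  u <- as.matrix(u)
  stopifnot(length(t) == nrow(u), length(t) >= 2)
  dt <- diff(t)
  if (diff(range(dt)) > 1e-8 * max(abs(dt)))
    stop("probe_series: sampling must be uniform", call. = FALSE)
  structure(list(t = t, u = u, dt = dt[1], location = location,
                 window = window),
            class = "probe_series")
}

#' @export
print.probe_series <- function(x, ...) {
  cat("<probe_series>", nrow(x$u), "samples x", ncol(x$u),
      "components, dt =", signif(x$dt, 4), "s\n")
  invisible(x)
}

window_index <- function(series) {
  idx <- which(series$t >= series$window[1] & series$t <= series$window[2])
  if (!length(idx))
    stop("empty statistics window", call. = FALSE)
  idx
}

#' Reynolds decomposition of a probe series
#'
#' Splits `u = u_bar + u'` with `u_bar` the arithmetic time mean over the
#' statistics window, the appropriate fluctuation extraction for
#' statistically stationary (constant-inflow) records.
#'
#' @param series a [probe_series()].
#' @return Object of class `flow_decomposition` with `mean` (per component),
#'   `fluct` (matrix over the window), `t`, `dt`, `method = "reynolds"`.
#' @export
reynolds_decompose <- function(series) {
  stopifnot(inherits(series, "probe_series"))
  idx <- window_index(series)
  uw <- series$u[idx, , drop = FALSE]
  m <- colMeans(uw)
  structure(list(mean = m, fluct = sweep(uw, 2, m), low = NULL,
                 t = series$t[idx], dt = series$dt, method = "reynolds"),
            class = "flow_decomposition")
}

#' High-pass Fourier-mode fluctuation extraction
#'
#' For pulsatile records a time mean is not a meaningful base flow without
#' phase-averaging many cycles, so the fluctuation is instead defined by
#' discrete Fourier decomposition of the windowed record with the lowest
#' `cutoff_mode` harmonics (indices `0 .. cutoff_mode - 1`, i.e. the mean
#' and the low-frequency pulsatile content) set to zero, conjugate partners
#' included so the reconstruction stays real. The removed low-frequency part
#' is returned as the time-varying base flow.
#'
#' @param series a [probe_series()].
#' @param cutoff_mode first retained harmonic of the analyzed record
#'   (default 16).
#' @return A `flow_decomposition` with `method = "highpass"`, `fluct` the
#'   high-frequency part and `low` the removed low-frequency signal.
#' @export
highpass_modes <- function(series, cutoff_mode = 16) {
  stopifnot(inherits(series, "probe_series"))
  idx <- window_index(series)
  uw <- series$u[idx, , drop = FALSE]
  n <- nrow(uw)
  if (n < 2 * cutoff_mode)
    stop("highpass_modes: need at least 2 * cutoff_mode = ",
         2 * cutoff_mode, " samples in the window", call. = FALSE)
  if (cutoff_mode >= floor(n / 2))
    stop("highpass_modes: cutoff_mode must lie below the Nyquist index ",
         floor(n / 2), call. = FALSE)
  keep <- rep(TRUE, n)
  if (cutoff_mode > 0) {
    kill <- c(seq_len(cutoff_mode),                       # modes 0..c-1
              if (cutoff_mode > 1) n - seq_len(cutoff_mode - 1) + 1)
    keep[kill] <- FALSE
  }
  hp <- apply(uw, 2, function(col) {
    X <- stats::fft(col)
    X[!keep] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  })
  hp <- matrix(hp, nrow = n)
  colnames(hp) <- colnames(uw)
  structure(list(mean = colMeans(uw), fluct = hp, low = uw - hp,
                 t = series$t[idx], dt = series$dt, method = "highpass",
                 cutoff_mode = cutoff_mode),
            class = "flow_decomposition")
}

#' Turbulent kinetic energy of a decomposition
#'
#' `tke = 0.5 * sum_i mean(u_i'^2)` over the velocity components of the
#' fluctuation series, in m^2/s^2.
#'
#' @param decomposition a `flow_decomposition` (from [reynolds_decompose()]
#'   or [highpass_modes()]).
#' @return Scalar tke (m^2/s^2), non-negative.
#' @export
tke <- function(decomposition) {
  stopifnot(inherits(decomposition, "flow_decomposition"))
  0.5 * sum(colMeans(decomposition$fluct^2))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram of the fluctuating-velocity-magnitude
#' signal: the record is split into `n_segments` half-overlapping segments,
#' each mean-removed, Hann-windowed and periodogram-normalized by the window
#' power, then averaged into a one-sided PSD. Segment length is the largest
#' integer allowing exactly `n_segments` segments at 50% overlap.
#'
#' @param signal numeric vector (typically `|u'|`), uniformly sampled.
#' @param dt sample interval (s).
#' @param n_segments number of segments (default 16).
#' @param overlap fractional overlap (default 0.5).
#' @return Object of class `spectral_density`: `freq` (Hz, ascending,
#'   excluding DC), `psd` ((m/s)^2/Hz, >= 0), `n_segments`, `window`
#'   (`"hann"`), `overlap`, `segment_length`.
#' @export
welch_psd <- function(signal, dt, n_segments = 16, overlap = 0.5) {
  n <- length(signal)
  stopifnot(dt > 0, n_segments >= 1, overlap >= 0, overlap < 1)
  seg <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  if (seg < 8)
    stop("welch_psd: record too short; need at least ",
         ceiling(8 * (1 + (n_segments - 1) * (1 - overlap))),
         " samples for ", n_segments, " segments", call. = FALSE)
  hop <- max(1, floor(seg * (1 - overlap)))
  starts <- 1 + (seq_len(n_segments) - 1) * hop
  starts <- starts[starts + seg - 1 <= n]
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))  # Hann
  wpow <- sum(w^2)
  fs <- 1 / dt
  nf <- floor(seg / 2)
  acc <- numeric(nf)
  for (s0 in starts) {
    x <- signal[s0:(s0 + seg - 1)]
    x <- (x - mean(x)) * w
    X <- stats::fft(x)
    pg <- (Mod(X[2:(nf + 1)])^2) / (fs * wpow)
    two <- rep(2, nf)
    if (seg %% 2 == 0) two[nf] <- 1                        # Nyquist bin
    acc <- acc + two * pg
  }
  psd <- acc / length(starts)
  freq <- (1:nf) * fs / seg
  structure(list(freq = freq, psd = psd, n_segments = length(starts),
                 window = "hann", overlap = overlap, segment_length = seg),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat("<spectral_density>", length(x$freq), "bins to",
      signif(max(x$freq), 4), "Hz,", x$n_segments, "Hann segments\n")
  invisible(x)
}

# ---- field-level analytics ----------------------------------------------

#' Q-criterion field from a flow snapshot
#'
#' Cell-centred `Q = (|W|^2 - |S|^2)/2` via centred differences of the
#' staggered velocities (one-sided at walls), zero on solid cells.
#'
#' @param state a `flow_state`.
#' @return nx-by-ny matrix of Q (1/s^2).
#' @export
q_field <- function(state) {
  stopifnot(inherits(state, "flow_state"))
  grid <- state$grid
  gf <- gradient_fields(grid, state$u, state$v)
  s12 <- (gf$dudy + gf$dvdx) / 2
  w12 <- (gf$dudy - gf$dvdx) / 2
  q <- (2 * w12^2 - (gf$dudx^2 + gf$dvdy^2 + 2 * s12^2)) / 2
  q[grid$mask] <- 0
  q
}

#' Station tke profiles from recorded line samples
#'
#' Applies the chosen fluctuation extraction to the per-step velocity
#' samples along each station line of a [run_simulation()] result and
#' returns time-averaged tke profiles.
#'
#' @param result a `simulation_result`.
#' @param method `"reynolds"` (constant inflow) or `"highpass"` (pulsatile).
#' @param cutoff_mode high-pass cutoff when `method = "highpass"`.
#' @return List of per-station lists: `offset` (widths from the
#'   constriction), `y`, `tke` (length-ny profile, `NA` on solid cells),
#'   `mean_tke` (fluid-cell average).
#' @export
station_tke <- function(result, method = c("reynolds", "highpass"),
                        cutoff_mode = 16) {
  method <- match.arg(method)
  stopifnot(inherits(result, "simulation_result"))
  win <- result$manifest$statistics_window
  idx <- which(result$times >= win[1] & result$times <= win[2])
  lapply(result$stations, function(st) {
    prof <- vapply(seq_along(st$y), function(j) {
      if (st$mask[j]) return(NA_real_)
      uu <- cbind(st$u[idx, j], st$v[idx, j])
      d <- if (method == "reynolds") {
        m <- colMeans(uu)
        sweep(uu, 2, m)
      } else {
        ser <- probe_series(result$times[idx], uu)
        highpass_modes(ser, cutoff_mode)$fluct
      }
      0.5 * sum(colMeans(d^2))
    }, numeric(1))
    list(offset = st$offset, y = st$y, tke = prof,
         mean_tke = mean(prof, na.rm = TRUE))
  })
}

#' Time-averaged tke and filtered-tke fields from snapshots
#'
#' Per-point application of the fluctuation statistics to a stack of field
#' snapshots: `tke_field()` uses the Reynolds split about the snapshot-mean
#' field; `filtered_tke_field()` first removes the lowest `cutoff_mode`
#' temporal Fourier modes at every point, the field-level analogue of the
#' probe high-pass filter. Removing modes can only remove variance, so the
#' filtered field is bounded above by the unfiltered one pointwise.
#'
#' @param snapshots list of snapshot lists with `u`, `v` matrices (as stored
#'   by [run_simulation()]); at least 2.
#' @param grid the `flow_grid` the snapshots live on.
#' @param cutoff_mode temporal modes removed by the filtered variant.
#' @return nx-by-ny matrix (m^2/s^2), zero on solid cells.
#' @export
tke_field <- function(snapshots, grid) {
  uc <- snapshot_centres(snapshots, grid)
  n <- length(snapshots)
  if (n < 2) stop("tke_field: need >= 2 snapshots", call. = FALSE)
  um <- Reduce(`+`, lapply(uc, `[[`, "u")) / n
  vm <- Reduce(`+`, lapply(uc, `[[`, "v")) / n
  acc <- 0
  for (s in uc) acc <- acc + (s$u - um)^2 + (s$v - vm)^2
  f <- 0.5 * acc / n
  f[grid$mask] <- 0
  f
}

#' @rdname tke_field
#' @export
filtered_tke_field <- function(snapshots, grid, cutoff_mode = 16) {
  uc <- snapshot_centres(snapshots, grid)
  n <- length(snapshots)
  if (n < 2 * cutoff_mode)
    stop("filtered_tke_field: need >= ", 2 * cutoff_mode, " snapshots",
         call. = FALSE)
  keep <- rep(TRUE, n)
  kill <- c(seq_len(cutoff_mode),
            if (cutoff_mode > 1) n - seq_len(cutoff_mode - 1) + 1)
  keep[kill] <- FALSE
  hp_var <- function(mats) {
    arr <- array(unlist(mats), dim = c(grid$nx, grid$ny, n))
    out <- matrix(0, grid$nx, grid$ny)
    for (j in seq_len(grid$ny)) {
      X <- stats::mvfft(t(arr[, j, ]))          # time x nx slabs
      X[!keep, ] <- 0
      hp <- Re(stats::mvfft(X, inverse = TRUE)) / n
      out[, j] <- colMeans(hp^2)
    }
    out
  }
  f <- 0.5 * (hp_var(lapply(uc, `[[`, "u")) + hp_var(lapply(uc, `[[`, "v")))
  f[grid$mask] <- 0
  f
}

snapshot_centres <- function(snapshots, grid) {
  nx <- grid$nx; ny <- grid$ny
  lapply(snapshots, function(s) list(
    u = (s$u[1:nx, , drop = FALSE] + s$u[2:(nx + 1), , drop = FALSE]) / 2,
    v = (s$v[, 1:ny, drop = FALSE] + s$v[, 2:(ny + 1), drop = FALSE]) / 2))
}
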