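#' Inlet waveform specification
#'
#' Describes the volumetric inflow driving the channel: either a constant
#' flow rate (the "peak-systolic" worst case used for refinement studies) or
#' a pulsatile, carotid-like flow rate expressed as a truncated Fourier
#' series over one period.
#'
#' For the pulsatile kind, `harmonics` is a complex vector `c_n`
#' (n = 1, ..., N) so that `Q(t) = mean + sum_n Re(c_n * exp(2i pi n t/T))`
#' in mL/min. Velocity profiles for each harmonic follow the analytic
#' oscillatory channel (planar Womersley) solution.
#'
#' @param kind `"constant"` or `"pulsatile"`.
#' @param mean_flow mean flow rate (mL/min); for `"constant"` this is the
#'   flow rate.
#' @param harmonics complex coefficients of the oscillatory part (mL/min);
#'   ignored for `"constant"`.
#' @param period period T (s) of the pulsatile waveform.
#' @param nu kinematic viscosity (m^2/s), needed for the Womersley profile
#'   shapes.
#' @return Object of class `inlet_waveform` with a `flow_rate(t)` evaluator
#'   (mL/min).
#' @export
inlet_waveform <- function(kind = c("constant", "pulsatile"),
                           mean_flow, harmonics = complex(0), period = 1,
                           nu = 1e-6) {
  kind <- match.arg(kind)
  stopifnot(mean_flow > 0, period > 0, nu > 0)
  harmonics <- as.complex(harmonics)
  wf <- structure(list(kind = kind, mean_flow = mean_flow,
                       harmonics = harmonics, period = period, nu = nu),
                  class = "inlet_waveform")
  wf
}

#' @rdname inlet_waveform
#' @param waveform an `inlet_waveform`.
#' @param t time(s) in seconds.
#' @return `flow_rate()`: instantaneous flow rate (mL/min).
#' @export
flow_rate <- function(waveform, t) {
  q <- rep(waveform$mean_flow, length(t))
  if (waveform$kind == "pulsatile" && length(waveform$harmonics)) {
    w0 <- 2 * pi / waveform$period
    for (n in seq_along(waveform$harmonics))
      q <- q + Re(waveform$harmonics[n] * exp(1i * n * w0 * t))
  }
  q
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat("<inlet_waveform>", x$kind, "mean", x$mean_flow, "mL/min",
      if (x$kind == "pulsatile")
        paste0("(", length(x$harmonics), " harmonics, T = ", x$period, " s)"),
      "\n")
  invisible(x)
}

# mL/min -> m^3/s
ml_min_to_m3s <- function(q) q / 6e7

# Planar Womersley shape for one harmonic: complex profile phi(y) with unit
# flow rate, across a channel of half-width a, angular frequency w.
#   u(y) = K (1 - cosh(l y)/cosh(l a)),  l = sqrt(i w / nu)
# normalized so that integral over (-a, a) (per unit depth) equals 1.
womersley_shape <- function(y_rel, a, w, nu) {
  if (w <= 0) {                       # steady limit: parabola
    return(0.75 / a * (1 - (y_rel / a)^2))
  }
  l <- sqrt(1i * w / nu)
  ch <- function(z) (exp(z) + exp(-z)) / 2
  sh <- function(z) (exp(z) - exp(-z)) / 2
  la <- l * a
  num <- 1 - ch(l * y_rel) / ch(la)
  denom <- 2 * a * (1 - sh(la) / (la * ch(la)))   # integral of num over (-a,a)
  num / denom
}

#' Instantaneous inlet velocity profile
#'
#' Evaluates the streamwise inlet velocity across the channel at time `t`
#' such that the profile integrates (per unit depth) to the instantaneous
#' target flow rate. A constant waveform gives the parabolic (plane
#' Poiseuille) profile with centreline velocity 1.5x the mean; a pulsatile
#' waveform superposes the analytic oscillatory-channel (planar Womersley)
#' solution of each harmonic, which flattens toward a plug profile at high
#' Womersley number.
#'
#' The flow rate is interpreted per the circular-vessel convention used for
#' the Reynolds-number bookkeeping: the 2-D profile carries the mean
#' velocity `U = Q / (pi d^2 / 4)` of the equivalent circular vessel of
#' diameter `d = width`.
#'
#' @param waveform an [inlet_waveform()].
#' @param geometry a [channel_geometry()].
#' @param y cross-channel cell-centre coordinates (m), in `(0, width)`.
#' @param t time (s).
#' @return Numeric vector of streamwise velocities (m/s) at `y`.
#' @export
inlet_profile <- function(waveform, geometry, y, t) {
  stopifnot(inherits(waveform, "inlet_waveform"),
            inherits(geometry, "channel_geometry"))
  if (any(t < 0)) stop("inlet_profile: t must be >= 0", call. = FALSE)
  d <- geometry$width
  a <- d / 2
  y_rel <- y - a
  area <- pi * d^2 / 4                 # equivalent circular-vessel area
  # per-unit-depth 2-D flow rate carrying the same mean velocity:
  q2d <- function(q_m3s) q_m3s / area * d
  u <- q2d(ml_min_to_m3s(waveform$mean_flow)) *
    0.75 / a * (1 - (y_rel / a)^2)
  if (waveform$kind == "pulsatile" && length(waveform$harmonics)) {
    w0 <- 2 * pi / waveform$period
    for (n in seq_along(waveform$harmonics)) {
      qn <- q2d(ml_min_to_m3s(waveform$harmonics[n]))
      shape <- womersley_shape(y_rel, a, n * w0, waveform$nu)
      u <- u + Re(qn * shape * exp(1i * n * w0 * t))
    }
  }
  u
}

#' Womersley number of a harmonic
#'
#' `alpha = a * sqrt(w / nu)` with `a` the channel half-width; gauges how
#' plug-like the oscillatory profile is (parabolic for `alpha << 1`).
#'
#' @param a half-width (m).
#' @param w angular frequency (rad/s).
#' @param nu kinematic viscosity (m^2/s).
#' @export
womersley_number <- function(a, w, nu) a * sqrt(w / nu)
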