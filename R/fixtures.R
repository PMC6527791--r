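#' Carotid-like pulsatile inflow waveform
#'
#' Builds a deterministic truncated Fourier series `Q(t)` (mL/min) with a
#' prescribed period, mean and peak, shaped like a common-carotid flow
#' waveform: a sharp systolic peak near `t = 0.1 s` followed by a gentle
#' diastolic decay. The shape template uses `n_harmonics` fixed-phase
#' harmonics; its oscillatory part is rescaled so the generated waveform
#' hits the requested mean exactly and the requested peak to within 1%.
#'
#' @param mean_flow target time-average flow (mL/min), e.g. 368-370 for a
#'   common carotid artery.
#' @param peak_flow target peak flow (mL/min), e.g. 521.
#' @param period cardiac period (s), default 1.
#' @param n_harmonics harmonics in the series (default 6).
#' @param nu kinematic viscosity handed to the waveform (m^2/s).
#' @return An [inlet_waveform()] of kind `"pulsatile"` whose `flow_rate()`
#'   has the requested mean (to round-off) and peak (to 1%), and is
#'   positive throughout the cycle.
#' @examples
#' wf <- make_waveform(368, 521)
#' mean(flow_rate(wf, seq(0, 1, length.out = 1001)[-1001]))  # ~368
#' @export
make_waveform <- function(mean_flow, peak_flow, period = 1,
                          n_harmonics = 6, nu = 1e-6) {
  if (!(peak_flow > mean_flow && mean_flow > 0))
    stop("make_waveform: need peak_flow > mean_flow > 0", call. = FALSE)
  # fixed shape template: systolic peak near t/T ~ 0.1, mild dicrotic bump
  n <- seq_len(n_harmonics)
  amp0 <- exp(-0.45 * (n - 1))              # decaying harmonic amplitudes
  phase <- -2 * pi * n * 0.1 - 0.35 * (n - 1)  # aligns crests near t = 0.1 T
  c0 <- amp0 * exp(1i * phase)
  tt <- seq(0, period, length.out = 2049)[-2049]
  osc <- function(scale) {
    q <- rep(0, length(tt))
    for (k in n) q <- q + Re(scale * c0[k] * exp(2i * pi * k * tt / period))
    q
  }
  base <- osc(1)
  target <- peak_flow - mean_flow
  scale <- target / max(base)
  if (mean_flow + scale * min(base) <= 0)
    stop("make_waveform: requested peak/mean ratio drives the waveform ",
         "negative with ", n_harmonics, " harmonics", call. = FALSE)
  inlet_waveform("pulsatile", mean_flow = mean_flow,
                 harmonics = scale * c0, period = period, nu = nu)
}

#' Planted-statistics synthetic probe signal
#'
#' Generates a velocity probe series whose structure mirrors a pulsatile
#' post-stenotic record: deterministic low-frequency harmonic content
#' (modes below the high-pass cutoff) plus seeded Gaussian broadband
#' fluctuations of known per-component variance. The machine-readable
#' ground truth travels with the series so downstream tests never hard-code
#' derived numbers.
#'
#' @param duration record length (s).
#' @param dt sample interval (s).
#' @param sigma2 broadband variance per component ((m/s)^2).
#' @param n_components velocity components (default 3).
#' @param low_modes integer harmonic indices of the record (< cutoff) given
#'   deterministic content.
#' @param low_amplitude amplitude of each low mode (m/s).
#' @param mean_u per-component mean offset (m/s).
#' @param seed RNG seed; same seed, same series, bit for bit.
#' @return A [probe_series()] with attribute `ground_truth`: list with
#'   `broadband_tke = n_components * sigma2 / 2`, `low_tke` (deterministic
#'   harmonic contribution to unfiltered tke), `sigma2`, `seed`.
#' @export
make_probe_signal <- function(duration, dt, sigma2 = 0.01,
                              n_components = 3, low_modes = integer(0),
                              low_amplitude = 0.5, mean_u = 0, seed = 1L) {
  n <- as.integer(round(duration / dt))
  stopifnot(n >= 4)
  t <- (seq_len(n) - 1) * dt
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  u <- matrix(stats::rnorm(n * n_components, 0, sqrt(sigma2)),
              n, n_components)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  mean_u <- rep_len(mean_u, n_components)
  u <- sweep(u, 2, mean_u, `+`)
  for (m in low_modes)
    u[, 1] <- u[, 1] + low_amplitude * sin(2 * pi * m * seq_len(n) / n)
  ser <- probe_series(t, u)
  attr(ser, "ground_truth") <- list(
    broadband_tke = n_components * sigma2 / 2,
    low_tke = 0.5 * length(low_modes) * low_amplitude^2 / 2,
    sigma2 = sigma2, seed = seed)
  ser
}

#' Planted-order refinement ladder
#'
#' Exact synthetic ladder `f_i = f_star + c * dx_i^p`, the oracle fixture
#' for the Richardson operations: [observed_order()] must recover `p` and
#' [richardson_extrapolate()] must recover `f_star`.
#'
#' @param f_star grid-independent value.
#' @param c error constant.
#' @param p planted order, > 0.
#' @param dx_list cell lengths, coarse to fine.
#' @return A [refinement_ladder()] with attribute
#'   `ground_truth = list(f_star, c, p)`.
#' @examples
#' lad <- make_refinement_ladder(1, 0.5, 2, c(0.4, 0.2, 0.1))
#' observed_order(lad)  # 2
#' @export
make_refinement_ladder <- function(f_star, c, p, dx_list) {
  stopifnot(p > 0)
  dx <- sort(as.numeric(dx_list), decreasing = TRUE)
  f <- f_star + c * dx^p
  lad <- refinement_ladder(sprintf("L%d", seq_along(dx)), dx, f)
  attr(lad, "ground_truth") <- list(f_star = f_star, c = c, p = p)
  lad
}

#' Canonical velocity-gradient suite
#'
#' Named archetypal gradient tensors with machine-readable expectations for
#' each closure operator: zero, pure shear, solid-body rotation, planar
#' strain, a 3-D diagonal gradient, and randomly rotated copies (same
#' singular values, hence same frame-invariant operator values).
#'
#' @param gamma shear rate (1/s).
#' @param omega rotation rate (1/s).
#' @param seed seed for the random rotations.
#' @param n_rotated rotated copies per base tensor.
#' @return Named list; each element has `g` (matrix) and `expected` (list
#'   with any of `smagorinsky`, `sigma`, `q`).
#' @export
canonical_gradients <- function(gamma = 10, omega = 5, seed = 1L,
                                n_rotated = 3) {
  base <- list(
    zero = list(g = matrix(0, 3, 3),
                expected = list(smagorinsky = 0, sigma = 0, q = 0)),
    pure_shear = list(g = pure_shear_gradient(gamma),
                      expected = list(smagorinsky = gamma, sigma = 0, q = 0)),
    rotation = list(g = rotation_gradient(omega),
                    expected = list(sigma = 0, q = omega^2)),
    planar_strain = list(g = diagonal_gradient(c(gamma, -gamma, 0)),
                         expected = list(smagorinsky = 2 * gamma, sigma = 0,
                                         q = -gamma^2)),
    diag_321 = list(g = diagonal_gradient(c(3, 2, 1)),
                    expected = list(sigma = 1 / 9)))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  rot <- replicate(n_rotated, random_rotation(), simplify = FALSE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  rotated <- list()
  for (nm in c("pure_shear", "rotation", "diag_321")) {
    for (r in seq_along(rot)) {
      R <- rot[[r]]
      rotated[[paste0(nm, "_rot", r)]] <-
        list(g = R %*% base[[nm]]$g %*% t(R),
             expected = base[[nm]]$expected)
    }
  }
  c(base, rotated)
}

# Haar-ish random rotation from QR of a Gaussian matrix, det +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
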