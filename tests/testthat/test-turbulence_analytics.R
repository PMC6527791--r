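make_series <- function(u, dt = 1e-3) {
  u <- as.matrix(u)
  probe_series(t = (seq_len(nrow(u)) - 1) * dt, u = u)
}

test_that("Reynolds decomposition has exact mean/fluctuation structure", {
  # constant series
  d <- reynolds_decompose(make_series(rep(3.2, 100)))
  expect_equal(unname(d$mean), 3.2)
  expect_true(all(d$fluct == 0))
  # sine over integer periods: zero mean, fluctuation = input
  n <- 1000
  x <- 0.7 * sin(2 * pi * 5 * seq_len(n) / n)
  d2 <- reynolds_decompose(make_series(x))
  expect_equal(unname(d2$mean), 0, tolerance = 1e-12)
  expect_equal(as.numeric(d2$fluct), x, tolerance = 1e-12)
  # random input: fluctuation mean is zero by construction, u = mean + u'
  set.seed(5)
  u <- matrix(rnorm(3000), 1000, 3)
  d3 <- reynolds_decompose(make_series(u))
  expect_equal(max(abs(colMeans(d3$fluct))), 0, tolerance = 1e-12)
  expect_equal(sweep(d3$fluct, 2, d3$mean, `+`), u, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("high-pass mode filter annihilates low modes and passes high ones", {
  n <- 1000
  k <- seq_len(n)
  # constant: DC is mode 0
  d0 <- highpass_modes(make_series(rep(2, n)), 16)
  expect_lt(max(abs(d0$fluct)), 1e-12)
  # mode 40 passes unchanged
  x40 <- sin(2 * pi * 40 * k / n + 0.3)
  d40 <- highpass_modes(make_series(x40), 16)
  expect_lt(sqrt(mean((d40$fluct - x40)^2)) / sqrt(mean(x40^2)), 1e-10)
  # mode 3 + mode 40: only mode 40 survives
  x3 <- 2 * sin(2 * pi * 3 * k / n)
  dmix <- highpass_modes(make_series(x3 + x40), 16)
  expect_lt(sqrt(mean((dmix$fluct - x40)^2)) / sqrt(mean(x40^2)), 1e-10)
  expect_lt(sqrt(mean((dmix$low - x3)^2)) / sqrt(mean(x3^2)), 1e-10)
  # mode 15 (just below cutoff) is removed
  x15 <- sin(2 * pi * 15 * k / n)
  expect_lt(max(abs(highpass_modes(make_series(x15), 16)$fluct)), 1e-12)
  # mode 16 (first retained) passes
  x16 <- sin(2 * pi * 16 * k / n)
  expect_lt(sqrt(mean((highpass_modes(make_series(x16), 16)$fluct - x16)^2)),
            1e-10)
  expect_error(highpass_modes(make_series(rnorm(20)), 16), "2 \\* cutoff")
  expect_error(highpass_modes(make_series(rnorm(42)), 21), "Nyquist")
})

test_that("mode split conserves energy (Fourier orthogonality)", {
  set.seed(6)
  u <- matrix(rnorm(2048, sd = 0.5), 1024, 2) +
    outer(sin(2 * pi * 4 * (1:1024) / 1024), c(1, -0.5))
  d <- highpass_modes(make_series(u), 16)
  expect_equal(colSums(u^2), colSums(d$low^2) + colSums(d$fluct^2),
               tolerance = 1e-10)
})

test_that("tke closed forms hold", {
  n <- 4000
  # u' = A sin over integer periods -> A^2 / 4
  A <- 0.8
  x <- A * sin(2 * pi * 10 * seq_len(n) / n)
  d <- reynolds_decompose(make_series(cbind(x, 0, 0)))
  expect_equal(tke(d), A^2 / 4, tolerance = 1e-10)
  # white noise, 3 components, variance sigma2 -> 3 sigma2 / 2 within 5%
  set.seed(7)
  sigma2 <- 0.04
  u <- matrix(rnorm(3e5, 0, sqrt(sigma2)), 1e5, 3)
  dn <- reynolds_decompose(make_series(u))
  expect_equal(tke(dn), 3 * sigma2 / 2, tolerance = 0.05)
  # invariance: component permutation and sign flip
  dp <- dn; dp$fluct <- dn$fluct[, c(2, 3, 1)]
  ds <- dn; ds$fluct[, 2] <- -ds$fluct[, 2]
  expect_equal(tke(dp), tke(dn))
  expect_equal(tke(ds), tke(dn))
  # zero fluctuation
  expect_equal(tke(reynolds_decompose(make_series(rep(1, 10)))), 0)
})

test_that("Welch PSD locates peaks and satisfies Parseval", {
  fs <- 1000; dt <- 1 / fs; n <- 8192
  A <- 0.6; f0 <- 87
  x <- A * sin(2 * pi * f0 * (seq_len(n) - 1) * dt)
  ps <- welch_psd(x, dt, n_segments = 16, overlap = 0.5)
  expect_equal(ps$n_segments, 16)
  expect_true(all(ps$psd >= 0))
  expect_true(all(diff(ps$freq) > 0))
  # peak at the nearest bin to f0
  expect_lt(abs(ps$freq[which.max(ps$psd)] - f0), fs / ps$segment_length)
  # integral of the PSD recovers the signal variance A^2/2 within 3%
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(sum(ps$psd) * df, A^2 / 2, tolerance = 0.03)
  # invariance to a constant offset (per-segment mean removal)
  ps2 <- welch_psd(x + 5, dt)
  expect_equal(ps2$psd, ps$psd, tolerance = 1e-10)
  expect_error(welch_psd(rnorm(50), dt), "too short")
})

test_that("Welch PSD is flat for white noise and Parseval-consistent", {
  set.seed(8)
  fs <- 500; n <- 2^14
  x <- rnorm(n, 0, 0.3)
  ps <- welch_psd(x, 1 / fs)
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(sum(ps$psd) * df, var(x), tolerance = 0.05)
  # band-averaged levels across 4 bands within a factor 1.3
  bands <- cut(seq_along(ps$freq), 4)
  lev <- tapply(ps$psd, bands, mean)
  expect_lt(max(lev) / min(lev), 1.3)
})

test_that("Q-criterion distinguishes rotation from strain and is invariant", {
  expect_equal(q_criterion(matrix(0, 3, 3)), 0)
  expect_equal(q_criterion(pure_shear_gradient(7)), 0, tolerance = 1e-12)
  expect_equal(q_criterion(rotation_gradient(3)), 9, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:30) {
    g <- matrix(rnorm(9), 3, 3)
    R <- stenoflow:::random_rotation()
    expect_equal(q_criterion(R %*% g %*% t(R)), q_criterion(g),
                 tolerance = 1e-10)
  }
})

test_that("q_field matches the pointwise operator on a planted linear field", {
  # u = gamma * y gives uniform pure shear: Q = 0 in the interior;
  # solid-body-like field u = -omega y, v = omega x gives Q = omega^2
  geo <- straight_geometry()
  grid <- build_grid(geo, 1 / 32)
  gam <- 4
  u <- matrix(rep(gam * grid$y, each = grid$nx + 1), grid$nx + 1, grid$ny)
  st <- flow_state(grid, u = u)
  qf <- q_field(st)
  inner <- qf[2:(grid$nx - 1), 2:(grid$ny - 1)]
  expect_lt(max(abs(inner)), 1e-10)
  om <- 2
  yv <- (0:grid$ny) * grid$h
  st2 <- flow_state(grid,
                    u = matrix(rep(-om * (grid$y - 0.5),
                                   each = grid$nx + 1), grid$nx + 1, grid$ny),
                    v = om * matrix(rep(grid$x - 0.5, grid$ny + 1),
                                    grid$nx, grid$ny + 1))
  qf2 <- q_field(st2)
  expect_equal(max(abs(qf2[2:(grid$nx - 1), 2:(grid$ny - 1)] - om^2)), 0,
               tolerance = 1e-10)
})

test_that("tke and filtered-tke fields recover planted fluctuations", {
  geo <- straight_geometry()
  grid <- build_grid(geo, 1 / 8)
  nx <- grid$nx; ny <- grid$ny
  nsnap <- 64
  set.seed(10)
  amp <- runif(ny, 0.1, 0.5)               # planted amplitude per y row
  mkuv <- function(k, mode) {
    ph <- 2 * pi * mode * k / nsnap
    list(t = k,
         u = matrix(rep(amp, each = nx + 1), nx + 1, ny) * sin(ph),
         v = matrix(0, nx, ny + 1))
  }
  # uniform snapshots -> all-zero fields
  unif <- lapply(1:8, function(k) list(t = k, u = matrix(1, nx + 1, ny),
                                       v = matrix(0, nx, ny + 1)))
  expect_true(all(tke_field(unif, grid) == 0))
  # sinusoidal planted fluctuation at mode 20: tke = amp^2 / 4 per cell
  # (time-mean of sin^2 over whole periods is exactly 1/2)
  snaps <- lapply(seq_len(nsnap), mkuv, mode = 20)
  tf <- tke_field(snaps, grid)
  planted <- matrix(rep(amp^2 / 4, each = nx), nx, ny)
  expect_equal(tf, planted, tolerance = 1e-10, ignore_attr = TRUE)
  # mode 20 survives a cutoff of 16; mode 4 does not
  ff <- filtered_tke_field(snaps, grid, cutoff_mode = 16)
  expect_equal(ff, tf, tolerance = 1e-10)
  low <- lapply(seq_len(nsnap), mkuv, mode = 4)
  expect_lt(max(filtered_tke_field(low, grid, cutoff_mode = 16)), 1e-20)
  # removing modes can never add variance
  set.seed(30)
  rnd <- lapply(seq_len(nsnap), function(k)
    list(t = k, u = matrix(rnorm((nx + 1) * ny), nx + 1, ny),
         v = matrix(rnorm(nx * (ny + 1)), nx, ny + 1)))
  expect_true(all(filtered_tke_field(rnd, grid, 8) <=
                    tke_field(rnd, grid) + 1e-12))
})

test_that("stations must lie inside the domain", {
  geo <- straight_geometry(length = 2)
  inl <- constant_inlet(200)
  cfg <- simulation_config(geo, dx = 1 / 8, end_time = 0.05, washout = 0.01,
                           inlet = inl, nu = 1 / 200,
                           stations = c(-0.75, 5), noise_amplitude = 0)
  expect_error(run_simulation(cfg), "station outside")
})
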