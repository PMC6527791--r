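test_that("gradient tensor splits exactly into strain and vorticity", {
  set.seed(4)
  for (g in random_gradients(50)) {
    G <- gradient_tensor(g)
    expect_equal(G$S, t(G$S))
    expect_equal(G$W, -t(G$W))
    expect_equal(G$S + G$W, g)
  }
  expect_error(gradient_tensor(matrix(c(1, NA, rep(0, 7)), 3, 3)),
               "non-finite")
})

test_that("canonical gradients give the closed-form operator values", {
  suite <- canonical_gradients(gamma = 10, omega = 5, seed = 3)
  expect_true(all(c("zero", "pure_shear", "rotation", "planar_strain",
                    "diag_321") %in% names(suite)))
  for (nm in names(suite)) {
    cg <- suite[[nm]]
    ex <- cg$expected
    if (!is.null(ex$smagorinsky))
      expect_equal(smagorinsky_dm(cg$g), ex$smagorinsky, tolerance = 1e-10,
                   label = paste("smagorinsky on", nm))
    if (!is.null(ex$sigma))
      expect_equal(sigma_dm(cg$g), ex$sigma, tolerance = 1e-10,
                   label = paste("sigma on", nm))
    if (!is.null(ex$q))
      expect_equal(q_criterion(cg$g), ex$q, tolerance = 1e-10,
                   label = paste("q on", nm))
  }
})

test_that("smagorinsky operator matches a direct tensor contraction", {
  set.seed(11)
  for (g in random_gradients(100)) {
    s <- (g + t(g)) / 2
    brute <- sqrt(2 * sum(vapply(1:3, function(i)
      sum(s[i, ]^2), numeric(1))))
    expect_equal(smagorinsky_dm(g), brute, tolerance = 1e-12)
  }
  # pure shear du/dy = 10: S12 = S21 = 5 -> sqrt(2 * 50) = 10
  expect_equal(smagorinsky_dm(pure_shear_gradient(10)), 10)
  expect_equal(smagorinsky_dm(diagonal_gradient(c(1, -1, 0))), 2)
})

test_that("sigma operator agrees with an independent eigenvalue route", {
  set.seed(12)
  for (g in random_gradients(200)) {
    ev <- sort(sqrt(pmax(eigen(t(g) %*% g, symmetric = TRUE,
                               only.values = TRUE)$values, 0)),
               decreasing = TRUE)
    brute <- if (ev[1] > 0)
      ev[3] * (ev[1] - ev[2]) * (ev[2] - ev[3]) / ev[1]^2 else 0
    expect_equal(sigma_dm(g), brute, tolerance = 1e-9)
  }
  expect_equal(sigma_dm(diagonal_gradient(3:1)), 1 / 9, tolerance = 1e-12)
})

test_that("sigma operator vanishes on shear, rotation and planar flow", {
  set.seed(13)
  for (gamma in c(0.1, 3, 50))
    expect_equal(sigma_dm(pure_shear_gradient(gamma)), 0, tolerance = 1e-14)
  for (omega in c(0.5, 7))
    expect_equal(sigma_dm(rotation_gradient(omega)), 0, tolerance = 1e-14)
  for (g in random_gradients(200, planar = TRUE))
    expect_lt(sigma_dm(g), 1e-12 * max(abs(g), 1))
})

test_that("both static operators are frame-rotation invariant", {
  set.seed(14)
  for (i in 1:30) {
    g <- matrix(rnorm(9), 3, 3)
    R <- stenoflow:::random_rotation()
    gr <- R %*% g %*% t(R)
    expect_equal(smagorinsky_dm(gr), smagorinsky_dm(g),
                 tolerance = 1e-10)
    expect_equal(sigma_dm(gr), sigma_dm(g), tolerance = 1e-10)
  }
})

test_that("static nu_sgs follows (Cm Delta)^2 Dm with the stated constants", {
  expect_equal(sgs_closure("smagorinsky")$cm, 0.168)
  expect_equal(sgs_closure("sigma")$cm, 1.5)
  # (0.168 * 1e-3)^2 * 10 for pure shear at 10 1/s
  expect_equal(static_nu_sgs(pure_shear_gradient(10),
                             sgs_closure("smagorinsky"), 1e-3),
               2.8224e-7, tolerance = 1e-12)
  expect_equal(static_nu_sgs(rotation_gradient(4), sgs_closure("sigma"),
                             1e-3), 0)
  expect_equal(static_nu_sgs(matrix(0, 3, 3), sgs_closure("smagorinsky"),
                             1e-3), 0)
  expect_error(static_nu_sgs(matrix(0, 3, 3), sgs_closure("none"), 1e-3),
               "smagorinsky|sigma")
  expect_error(static_nu_sgs(matrix(0, 3, 3), sgs_closure("smagorinsky"),
                             -1), "delta")
})

test_that("every closure is non-negative and scales as Delta^2 and |G|", {
  set.seed(15)
  closures <- list(sgs_closure("smagorinsky"), sgs_closure("sigma"))
  gs <- random_gradients(1e4)
  for (cl in closures) {
    vals <- vapply(gs, static_nu_sgs, numeric(1), closure = cl,
                   delta = 1e-3)
    expect_true(all(vals >= 0))
  }
  for (g in gs[1:50]) {
    for (cl in closures) {
      v1 <- static_nu_sgs(g, cl, 1e-3)
      expect_equal(static_nu_sgs(g, cl, 2e-3), 4 * v1, tolerance = 1e-10)
      expect_equal(static_nu_sgs(3 * g, cl, 1e-3), 3 * v1,
                   tolerance = 1e-10)
    }
  }
})

test_that("nu_sgs_field is zero for no model, uniform flow, and 2-D sigma", {
  geo <- straight_geometry()
  grid <- build_grid(geo, 1 / 16)
  # uniform flow: zero everywhere away from the no-slip walls (the wall
  # ghost reflection sees the slip of a uniform stream as wall shear)
  st <- flow_state(grid, u = matrix(1, grid$nx + 1, grid$ny))
  inner <- 2:(grid$ny - 1)
  for (m in c("none", "smagorinsky", "sigma")) {
    f <- nu_sgs_field(st, sgs_closure(m))
    expect_true(all(f$nu_sgs[, inner] == 0),
                label = paste("uniform flow,", m))
  }
  expect_true(all(nu_sgs_field(st, sgs_closure("none"))$nu_sgs == 0))
  # Poiseuille: sigma vanishes (planar field), smagorinsky does not
  stp <- poiseuille_state(grid)
  expect_true(all(nu_sgs_field(stp, sgs_closure("sigma"))$nu_sgs == 0))
  expect_true(all(nu_sgs_field(stp, sgs_closure("none"))$nu_sgs == 0))
  expect_gt(max(nu_sgs_field(stp, sgs_closure("smagorinsky"))$nu_sgs), 0)
})

test_that("dynamic model matches a brute-force Germano evaluation", {
  # frozen single step (no averaging history) on a synthetic 16x16 field,
  # against a loop-based assembly of L_ij, M_ij and Cs^2
  geo <- straight_geometry()
  grid <- build_grid(geo, 1 / 16)
  set.seed(21)
  nx <- grid$nx; ny <- grid$ny
  st <- flow_state(grid,
                   u = matrix(sin(seq_len((nx + 1) * ny)) +
                                rnorm((nx + 1) * ny, 0, 0.2), nx + 1, ny),
                   v = matrix(rnorm(nx * (ny + 1), 0, 0.3), nx, ny + 1))
  res <- dynamic_smagorinsky_nu(st, sgs_closure("dynamic_smagorinsky"),
                                dt = NULL)

  # ---- independent oracle ----
  filt <- function(f) {                     # plain-loop top-hat filter
    out <- f
    for (i in 1:nx) for (j in 1:ny) {
      iw <- max(i - 1, 1); ie <- min(i + 1, nx)
      js <- max(j - 1, 1); jn <- min(j + 1, ny)
      out[i, j] <- 0.5 * f[i, j] +
        0.125 * (f[iw, j] + f[ie, j] + f[i, js] + f[i, jn])
    }
    out
  }
  sf <- stenoflow:::strain_fields(grid, st$u, st$v)
  uc <- (st$u[1:nx, ] + st$u[2:(nx + 1), ]) / 2
  vc <- (st$v[, 1:ny] + st$v[, 2:(ny + 1)]) / 2
  l11 <- filt(uc * uc) - filt(uc)^2
  l22 <- filt(vc * vc) - filt(vc)^2
  l12 <- filt(uc * vc) - filt(uc) * filt(vc)
  h11 <- filt(sf$s11); h22 <- filt(sf$s22); h12 <- filt(sf$s12)
  hmag <- sqrt(2 * (h11^2 + h22^2 + 2 * h12^2))
  d2 <- grid$h^2
  m11 <- 2 * d2 * (filt(sf$smag * sf$s11) - 4 * hmag * h11)
  m22 <- 2 * d2 * (filt(sf$smag * sf$s22) - 4 * hmag * h22)
  m12 <- 2 * d2 * (filt(sf$smag * sf$s12) - 4 * hmag * h12)
  lm <- l11 * m11 + l22 * m22 + 2 * l12 * m12
  mm <- m11^2 + m22^2 + 2 * m12^2
  cs2 <- ifelse(mm > 0, pmax(lm / mm, 0), 0)
  nu_oracle <- cs2 * d2 * sf$smag

  expect_equal(res$nu_sgs, nu_oracle, tolerance = 1e-12)
  expect_true(all(res$nu_sgs >= 0))
})

test_that("dynamic model returns zero viscosity on trivial and laminar flow", {
  geo <- straight_geometry()
  grid <- build_grid(geo, 1 / 32)
  # spatially uniform velocity: all gradients zero
  st <- flow_state(grid, u = matrix(2, grid$nx + 1, grid$ny))
  f <- nu_sgs_field(st, sgs_closure("dynamic_smagorinsky"), dt = 1e-3)
  expect_true(all(f$nu_sgs == 0))
  # laminar Poiseuille after transients: mean nu_sgs < 1% of molecular
  re <- 100; nu <- 1 / re
  inl <- constant_inlet(re)
  stp <- poiseuille_state(grid)
  cl <- sgs_closure("dynamic_smagorinsky")
  dt <- 0.2 * grid$h / 1.6
  for (k in 1:100) {
    stp <- step(stp, dt, nu, cl, inlet = inl, geometry = geo)
    cl <- stp$closure
  }
  expect_lt(mean(stp$nu_sgs), 0.01 * nu)
})

test_that("dynamic model requires its own closure id", {
  geo <- straight_geometry(); grid <- build_grid(geo, 1 / 8)
  st <- flow_state(grid)
  expect_error(dynamic_smagorinsky_nu(st, sgs_closure("sigma")), "sigma")
})
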