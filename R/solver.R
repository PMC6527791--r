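#' Staggered-grid flow state
#'
#' Velocity/pressure snapshot on a MAC grid: `u` on vertical faces
#' (`(nx+1) x ny`), `v` on horizontal faces (`nx x (ny+1)`), kinematic
#' pressure `p` at cell centres (`nx x ny`, m^2/s^2), and the time `t`.
#'
#' @param grid a [build_grid()] result.
#' @param u,v,p optional initial fields (default: rest).
#' @param t initial time (s).
#' @return Object of class `flow_state`.
#' @export
flow_state <- function(grid, u = NULL, v = NULL, p = NULL, t = 0) {
  stopifnot(inherits(grid, "flow_grid"))
  nx <- grid$nx; ny <- grid$ny
  if (is.null(u)) u <- matrix(0, nx + 1, ny)
  if (is.null(v)) v <- matrix(0, nx, ny + 1)
  if (is.null(p)) p <- matrix(0, nx, ny)
  stopifnot(all(dim(u) == c(nx + 1, ny)), all(dim(v) == c(nx, ny + 1)),
            all(dim(p) == c(nx, ny)))
  structure(list(grid = grid, u = u, v = v, p = p, t = t,
                 rhs_prev = NULL, poisson = NULL),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat("<flow_state> t =", signif(x$t, 6), "s, max |u| =",
      signif(max(abs(x$u)), 4), "m/s on", x$grid$nx, "x", x$grid$ny, "grid\n")
  invisible(x)
}

# ---- discrete operators --------------------------------------------------

# Divergence at cell centres (nx x ny), zero reported on solid cells.
divergence <- function(grid, u, v) {
  nx <- grid$nx; ny <- grid$ny
  d <- (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE] +
        v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / grid$h
  d[grid$mask] <- 0
  d
}

# Face-solid masks: a u/v face is frozen (velocity 0) if it touches a solid
# cell. Domain-boundary faces are handled by the BC logic, not here.
face_masks <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  m <- grid$mask
  mu <- matrix(FALSE, nx + 1, ny)
  mu[1:nx, ] <- m
  mu[2:(nx + 1), ] <- mu[2:(nx + 1), ] | m
  mv <- matrix(FALSE, nx, ny + 1)
  mv[, 1:ny] <- m
  mv[, 2:(ny + 1)] <- mv[, 2:(ny + 1)] | m
  list(u = mu, v = mv)
}

# Explicit momentum RHS (convection in energy-preserving central divergence
# form + conservative variable-viscosity diffusion) for the channel domain.
# nu_c: cell-centred effective viscosity (molecular + SGS).
momentum_rhs <- function(grid, u, v, nu_c) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h

  ## ---- u equation (faces i = 1..nx+1, j = 1..ny) ----
  uc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE]) / 2  # centres
  fxx <- uc * uc                                    # u-flux at centres
  # corner lattice (nx+1) x (ny+1): u and v interpolated to corners
  u_cor <- matrix(0, nx + 1, ny + 1)
  u_cor[, 2:ny] <- (u[, 1:(ny - 1)] + u[, 2:ny]) / 2
  # wall corners (j = 1, ny+1): no-slip => u = 0 there
  v_cor <- matrix(0, nx + 1, ny + 1)
  v_cor[2:nx, ] <- (v[1:(nx - 1), , drop = FALSE] + v[2:nx, , drop = FALSE]) / 2
  v_cor[1, ] <- 0                                   # inlet plane: v = 0
  v_cor[nx + 1, ] <- v[nx, ]                        # outlet: zero-gradient
  fxy <- u_cor * v_cor                              # uv-flux at corners

  conv_u <- matrix(0, nx + 1, ny)
  conv_u[2:nx, ] <- (fxx[2:nx, ] - fxx[1:(nx - 1), ]) / h +
    (fxy[2:nx, 2:(ny + 1)] - fxy[2:nx, 1:ny]) / h

  # diffusion d/dx(nu du/dx) + d/dy(nu du/dy)
  # nu at centres bounds the x-part; nu at corners the y-part
  nu_cor <- matrix(0, nx + 1, ny + 1)
  nu_in <- (nu_c[1:(nx - 1), 1:(ny - 1)] + nu_c[2:nx, 1:(ny - 1)] +
            nu_c[1:(nx - 1), 2:ny] + nu_c[2:nx, 2:ny]) / 4
  nu_cor[2:nx, 2:ny] <- nu_in
  nu_cor[1, 2:ny] <- (nu_c[1, 1:(ny - 1)] + nu_c[1, 2:ny]) / 2
  nu_cor[nx + 1, 2:ny] <- (nu_c[nx, 1:(ny - 1)] + nu_c[nx, 2:ny]) / 2
  nu_cor[, 1] <- nu_cor[, 2]; nu_cor[, ny + 1] <- nu_cor[, ny]
  nu_cor[1, 1] <- nu_c[1, 1]; nu_cor[1, ny + 1] <- nu_c[1, ny]
  nu_cor[nx + 1, 1] <- nu_c[nx, 1]; nu_cor[nx + 1, ny + 1] <- nu_c[nx, ny]

  # ghost rows for wall no-slip: u_ghost = -u_interior
  ue <- cbind(-u[, 1], u, -u[, ny])                 # (nx+1) x (ny+2)
  dify_u <- (nu_cor[, 2:(ny + 1)] *
               (ue[, 3:(ny + 2)] - ue[, 2:(ny + 1)]) -
             nu_cor[, 1:ny] *
               (ue[, 2:(ny + 1)] - ue[, 1:ny])) / h^2
  difx_u <- matrix(0, nx + 1, ny)
  difx_u[2:nx, ] <- (nu_c[2:nx, ] * (u[3:(nx + 1), ] - u[2:nx, ]) -
                     nu_c[1:(nx - 1), ] * (u[2:nx, ] - u[1:(nx - 1), ])) / h^2
  diff_u <- difx_u + dify_u
  diff_u[1, ] <- 0; diff_u[nx + 1, ] <- 0

  ## ---- v equation (faces i = 1..nx, j = 1..ny+1) ----
  vcen <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE]) / 2
  fyy <- vcen * vcen
  fyx <- u_cor * v_cor                              # same corner fluxes
  conv_v <- matrix(0, nx, ny + 1)
  conv_v[, 2:ny] <- (fyy[, 2:ny] - fyy[, 1:(ny - 1)]) / h +
    (fyx[2:(nx + 1), 2:ny] - fyx[1:nx, 2:ny]) / h

  # diffusion for v: x-part bounded by corner nu, y-part by centre nu
  ve <- rbind(-v[1, ], v, v[nx, ])                  # inlet refl., outlet zg
  difx_v <- (nu_cor[2:(nx + 1), ] * (ve[3:(nx + 2), ] - ve[2:(nx + 1), ]) -
             nu_cor[1:nx, ] * (ve[2:(nx + 1), ] - ve[1:nx, ])) / h^2
  dify_v <- matrix(0, nx, ny + 1)
  dify_v[, 2:ny] <- (nu_c[, 2:ny] * (v[, 3:(ny + 1)] - v[, 2:ny]) -
                     nu_c[, 1:(ny - 1)] * (v[, 2:ny] - v[, 1:(ny - 1)])) / h^2
  diff_v <- difx_v + dify_v
  diff_v[, 1] <- 0; diff_v[, ny + 1] <- 0

  list(u = diff_u - conv_u, v = diff_v - conv_v)
}

# ---- pressure Poisson ----------------------------------------------------

# Build and cache the Cholesky factor of the (negated, SPD) 5-point Poisson
# operator over fluid cells. Neumann at walls/inlet/solid (face velocities
# fixed), Dirichlet phi = 0 at the outlet ghost.
poisson_setup <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  fluid_m <- !grid$mask
  fluid <- which(fluid_m)                           # column-major indices
  idx <- matrix(0L, nx, ny)
  idx[fluid] <- seq_along(fluid)
  n <- length(fluid)
  # fluid-neighbour indicator matrices (FALSE beyond the domain)
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nx, ny)
    xs <- max(1, 1 + di):min(nx, nx + di)
    ys <- max(1, 1 + dj):min(ny, ny + dj)
    out[xs, ys] <- m[xs - di, ys - dj]
    out
  }
  nb_e <- shift(fluid_m, -1, 0)   # TRUE where the east neighbour is fluid
  nb_w <- shift(fluid_m, 1, 0)
  nb_n <- shift(fluid_m, 0, -1)
  nb_s <- shift(fluid_m, 0, 1)
  outlet <- matrix(FALSE, nx, ny); outlet[nx, ] <- TRUE
  diagv <- (nb_e + nb_w + nb_n + nb_s + 2 * outlet)[fluid]
  pair <- function(nb, di, dj) {
    cells <- which(fluid_m & nb)
    ij <- arrayInd(cells, c(nx, ny))
    nb_cells <- (ij[, 1] + di) + (ij[, 2] + dj - 1L) * nx
    cbind(idx[cells], idx[nb_cells])
  }
  pp <- rbind(pair(nb_e, 1L, 0L), pair(nb_w, -1L, 0L),
              pair(nb_n, 0L, 1L), pair(nb_s, 0L, -1L))
  A <- Matrix::sparseMatrix(i = c(seq_len(n), pp[, 1]),
                            j = c(seq_len(n), pp[, 2]),
                            x = c(diagv, rep(-1, nrow(pp))) / h^2,
                            dims = c(n, n))
  list(chol = Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE),
       fluid = fluid, n = n)
}

poisson_solve <- function(grid, ps, rhs) {
  # solves  lap(phi) = rhs  (rhs at fluid cells); returns nx x ny matrix
  b <- -as.numeric(rhs[ps$fluid])
  phi_f <- as.numeric(Matrix::solve(ps$chol, b))
  phi <- matrix(0, grid$nx, grid$ny)
  phi[ps$fluid] <- phi_f
  phi
}

# FFT Poisson solve for the doubly-periodic box.
poisson_solve_periodic <- function(grid, rhs) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  eig <- outer(2 * cos(2 * pi * (0:(nx - 1)) / nx) - 2,
               2 * cos(2 * pi * (0:(ny - 1)) / ny) - 2, "+") / h^2
  rh <- stats::fft(rhs)
  rh[1, 1] <- 0
  eig[1, 1] <- 1
  phi <- Re(stats::fft(rh / eig, inverse = TRUE)) / (nx * ny)
  phi
}

# ---- time step -----------------------------------------------------------

#' Advance the flow one time step
#'
#' One incremental pressure-correction (fractional) step: explicit
#' Adams-Bashforth convection in the kinetic-energy-preserving central
#' divergence form, explicit conservative diffusion with effective viscosity
#' `nu + nu_sgs`, then a pressure-Poisson solve and projection to the
#' discrete divergence-free space. The first call uses forward Euler to
#' start the multi-step scheme.
#'
#' @param state a [flow_state()].
#' @param dt time step (s); must respect the advective CFL and diffusive
#'   stability bounds, which are checked.
#' @param nu molecular kinematic viscosity (m^2/s).
#' @param closure an [sgs_closure()] (default: none).
#' @param inlet optional [inlet_waveform()]; required for channel domains.
#' @param geometry the [channel_geometry()]; defaults to the grid's.
#' @param inlet_noise optional function `(ny, t) ->` additive velocity noise
#'   for the inlet faces (instability seeding).
#' @return Updated `flow_state` (carrying the updated closure in
#'   `$closure`).
#' @export
step <- function(state, dt, nu, closure = sgs_closure("none"),
                 inlet = NULL, geometry = NULL, inlet_noise = NULL) {
  stopifnot(inherits(state, "flow_state"), dt > 0, nu >= 0)
  grid <- state$grid
  if (is.null(geometry)) geometry <- grid$geometry
  nx <- grid$nx; ny <- grid$ny; h <- grid$h

  nsf <- nu_sgs_field(state, closure, dt = dt)
  closure <- nsf$closure
  nu_c <- nu + nsf$nu_sgs

  umax <- max(abs(state$u), abs(state$v), 1e-12)
  if (dt > 0.9 * h / umax)
    stop(sprintf("step: advective CFL violated (dt = %.3g > 0.9 h/|u|max = %.3g)",
                 dt, 0.9 * h / umax), call. = FALSE)
  if (max(nu_c) > 0 && dt > 0.3 * h^2 / max(nu_c))
    stop(sprintf("step: diffusive bound violated (dt = %.3g > 0.3 h^2/nu = %.3g)",
                 dt, 0.3 * h^2 / max(nu_c)), call. = FALSE)

  if (grid$bc == "periodic")
    return(step_periodic(state, dt, nu, closure))

  fm <- face_masks(grid)
  rhs <- momentum_rhs(grid, state$u, state$v, nu_c)
  if (is.null(state$rhs_prev)) {
    ru <- rhs$u; rv <- rhs$v
  } else {
    ru <- 1.5 * rhs$u - 0.5 * state$rhs_prev$u
    rv <- 1.5 * rhs$v - 0.5 * state$rhs_prev$v
  }

  # incremental pressure correction: old pressure gradient in the predictor
  gpx <- matrix(0, nx + 1, ny)
  gpx[2:nx, ] <- (state$p[2:nx, ] - state$p[1:(nx - 1), ]) / h
  gpx[nx + 1, ] <- (-2 * state$p[nx, ]) / h         # outlet p ghost = -p
  gpy <- matrix(0, nx, ny + 1)
  gpy[, 2:ny] <- (state$p[, 2:ny] - state$p[, 1:(ny - 1)]) / h

  us <- state$u + dt * (ru - gpx)
  vs <- state$v + dt * (rv - gpy)

  tn <- state$t + dt
  if (!is.null(inlet)) {
    uin <- inlet_profile(inlet, geometry, grid$y, tn)
    if (!is.null(inlet_noise)) uin <- uin + inlet_noise(ny, tn)
    us[1, ] <- uin
  } else {
    us[1, ] <- 0
  }
  us[nx + 1, ] <- us[nx, ]                          # outlet zero-gradient
  vs[, 1] <- 0; vs[, ny + 1] <- 0                   # wall faces
  us[fm$u] <- 0; vs[fm$v] <- 0                      # solid faces

  if (is.null(state$poisson)) state$poisson <- poisson_setup(grid)
  div_s <- divergence(grid, us, vs)
  phi <- poisson_solve(grid, state$poisson, div_s / dt)

  un <- us; vn <- vs
  un[2:nx, ] <- us[2:nx, ] - dt * (phi[2:nx, ] - phi[1:(nx - 1), ]) / h
  un[nx + 1, ] <- us[nx + 1, ] - dt * (-2 * phi[nx, ]) / h
  vn[, 2:ny] <- vs[, 2:ny] - dt * (phi[, 2:ny] - phi[, 1:(ny - 1)]) / h
  un[fm$u] <- 0; vn[fm$v] <- 0
  pn <- state$p + phi
  pn[grid$mask] <- 0

  if (anyNA(un) || any(!is.finite(un)))
    stop("step: non-finite values in velocity field 'u' at t = ", tn,
         call. = FALSE)
  if (anyNA(vn) || any(!is.finite(vn)))
    stop("step: non-finite values in velocity field 'v' at t = ", tn,
         call. = FALSE)
  resid <- max(abs(divergence(grid, un, vn)))
  tol <- 1e-8 * max(umax / h, 1)
  if (resid > tol)
    stop(sprintf("step: divergence residual %.3g exceeds tolerance %.3g",
                 resid, tol), call. = FALSE)

  state$u <- un; state$v <- vn; state$p <- pn
  state$t <- tn
  state$rhs_prev <- rhs
  state$closure <- closure
  state$div_resid <- resid
  state$nu_sgs <- nsf$nu_sgs
  state
}

# Periodic-box variant (conservation tests): central divergence-form
# convection, diffusion, FFT projection. No walls, no mask.
step_periodic <- function(state, dt, nu, closure) {
  grid <- state$grid
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  # unique faces: u[1..nx, ], v[, 1..ny]; the (nx+1)/(ny+1) slots mirror them
  u <- state$u[1:nx, , drop = FALSE]
  v <- state$v[, 1:ny, drop = FALSE]
  ip <- c(2:nx, 1); im <- c(nx, 1:(nx - 1))
  jp <- c(2:ny, 1); jm <- c(ny, 1:(ny - 1))

  uc <- (u + u[ip, ]) / 2                           # centre i+1/2 ... at cell i
  fxx <- uc * uc
  u_cor <- (u + u[, jm]) / 2                        # corner (i, j-1/2)
  v_cor <- (v + v[im, ]) / 2
  fxy <- u_cor * v_cor
  conv_u <- (fxx - fxx[im, ]) / h + (fxy[, jp] - fxy) / h
  vcen <- (v + v[, jp]) / 2
  fyy <- vcen * vcen
  conv_v <- (fyy - fyy[, jm]) / h + (fxy[ip, ] - fxy) / h

  lap <- function(f) (f[ip, ] + f[im, ] + f[, jp] + f[, jm] - 4 * f) / h^2
  rhs_u <- nu * lap(u) - conv_u
  rhs_v <- nu * lap(v) - conv_v
  if (is.null(state$rhs_prev)) {
    ru <- rhs_u; rv <- rhs_v
  } else {
    ru <- 1.5 * rhs_u - 0.5 * state$rhs_prev$u
    rv <- 1.5 * rhs_v - 0.5 * state$rhs_prev$v
  }
  gpx <- (state$p - state$p[im, ]) / h
  gpy <- (state$p - state$p[, jm]) / h
  us <- u + dt * (ru - gpx)
  vs <- v + dt * (rv - gpy)
  div_s <- (us[ip, ] - us + vs[, jp] - vs) / h
  phi <- poisson_solve_periodic(grid, div_s / dt)
  un <- us - dt * (phi - phi[im, ]) / h
  vn <- vs - dt * (phi - phi[, jm]) / h

  state$u <- rbind(un, un[1, ])
  state$v <- cbind(vn, vn[, 1])
  state$p <- state$p + phi
  state$t <- state$t + dt
  state$rhs_prev <- list(u = rhs_u, v = rhs_v)
  state$closure <- closure
  state$div_resid <- max(abs((un[ip, ] - un + vn[, jp] - vn) / h))
  state
}

#' Total kinetic energy of a state
#'
#' `KE = 0.5 * sum(u^2 + v^2) * h^2` over unique faces, the discrete
#' invariant the energy-preserving convection scheme conserves in the
#' inviscid periodic limit.
#'
#' @param state a `flow_state`.
#' @return Scalar kinetic energy (m^4/s^2 per unit depth).
#' @export
kinetic_energy <- function(state) {
  grid <- state$grid
  if (grid$bc == "periodic") {
    u <- state$u[1:grid$nx, , drop = FALSE]
    v <- state$v[, 1:grid$ny, drop = FALSE]
  } else {
    u <- state$u; v <- state$v
  }
  0.5 * (sum(u^2) + sum(v^2)) * grid$h^2
}
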