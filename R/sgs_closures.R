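#' Sub-grid-scale closure specification
#'
#' A closure is an eddy-viscosity model `nu_sgs = (Cm * Delta)^2 * Dm(u)`,
#' where `Cm` is the model constant, `Delta` the cutoff length and `Dm` a
#' model-specific differential operator of the resolved velocity gradient.
#' The deviatoric sub-grid stress enters the momentum equation only through
#' `nu_sgs` added to the molecular viscosity; the isotropic part is absorbed
#' into pressure, the standard realization in incompressible constant-density
#' solvers.
#'
#' Supported models and default constants:
#' * `"none"` — no added viscosity (under-resolved DNS strategy);
#' * `"smagorinsky"` — static Smagorinsky, `Cm = 0.168`, `Dm = |S|`;
#' * `"sigma"` — singular-value based Sigma model, `Cm = 1.5`; its operator
#'   vanishes identically for two-dimensional / two-component flow, pure
#'   shear and pure rotation, giving cubic near-wall decay;
#' * `"dynamic_smagorinsky"` — Germano-identity dynamic procedure with
#'   Lagrangian time averaging of the numerator/denominator products and
#'   clipping at zero.
#'
#' @param model one of `"none"`, `"smagorinsky"`, `"sigma"`,
#'   `"dynamic_smagorinsky"`.
#' @param cm model constant override; defaults per model as above (ignored
#'   for `"none"` and `"dynamic_smagorinsky"`, which determines its constant
#'   from the resolved field).
#' @return Object of class `sgs_closure` with fields `model`, `cm`, and (for
#'   the dynamic model) mutable averaging `state` initialized on first use.
#' @examples
#' sgs_closure("sigma")$cm        # 1.5
#' sgs_closure("smagorinsky")$cm  # 0.168
#' @export
sgs_closure <- function(model = c("none", "smagorinsky", "sigma",
                                  "dynamic_smagorinsky"),
                        cm = NULL) {
  model <- match.arg(model)
  default_cm <- c(none = 0, smagorinsky = 0.168, sigma = 1.5,
                  dynamic_smagorinsky = NA_real_)[[model]]
  if (is.null(cm)) cm <- default_cm
  if (model %in% c("smagorinsky", "sigma") && !(is.finite(cm) && cm >= 0))
    stop("sgs_closure: Cm must be a non-negative number for static models",
         call. = FALSE)
  structure(list(model = model, cm = cm, state = NULL),
            class = "sgs_closure")
}

#' @export
print.sgs_closure <- function(x, ...) {
  cat("<sgs_closure>", x$model,
      if (is.finite(x$cm)) paste0("(Cm = ", x$cm, ")") else "", "\n")
  invisible(x)
}

#' Smagorinsky differential operator |S|
#'
#' The static Smagorinsky operator is the strain-rate magnitude
#' `|S| = sqrt(2 * sum_ij S_ij^2)`.
#'
#' @param G a [gradient_tensor()] (or raw matrix).
#' @return Scalar `|S|` in 1/s, non-negative.
#' @examples
#' smagorinsky_dm(pure_shear_gradient(10))  # 10
#' @export
smagorinsky_dm <- function(G) {
  G <- as_gradient_tensor(G)
  sqrt(2 * sum(G$S^2))
}

#' Sigma differential operator from singular values
#'
#' With `sigma1 >= sigma2 >= sigma3` the singular values of the velocity
#' gradient, the operator is `sigma3 * (sigma1 - sigma2) * (sigma2 - sigma3)
#' / sigma1^2`. It vanishes for any planar (two-dimensional or two-component)
#' gradient, for pure shear and for pure rotation, and behaves cubically in
#' the near-wall region — the properties that make the Sigma closure
#' attractive for transitional flow.
#'
#' @param G a [gradient_tensor()] (or raw matrix).
#' @return Scalar operator value in 1/s; 0 when `sigma1 = 0` (limit value,
#'   avoiding 0/0).
#' @examples
#' sigma_dm(pure_shear_gradient(3))     # 0
#' sigma_dm(diagonal_gradient(3:1))     # 1/9
#' @export
sigma_dm <- function(G) {
  G <- as_gradient_tensor(G)
  s <- svd(G$g, nu = 0, nv = 0)$d       # decreasing, >= 0
  if (s[1] <= 0) return(0)
  val <- s[3] * (s[1] - s[2]) * (s[2] - s[3]) / s[1]^2
  max(val, 0)
}

#' Static eddy viscosity (Cm * Delta)^2 * Dm
#'
#' @param G a [gradient_tensor()] (or raw matrix).
#' @param closure an [sgs_closure()] with `model` `"smagorinsky"` or
#'   `"sigma"`.
#' @param delta cutoff length Delta (m), > 0.
#' @return Kinematic sub-grid viscosity in m^2/s.
#' @examples
#' static_nu_sgs(pure_shear_gradient(10), sgs_closure("smagorinsky"), 1e-3)
#' @export
static_nu_sgs <- function(G, closure, delta) {
  stopifnot(inherits(closure, "sgs_closure"))
  if (!closure$model %in% c("smagorinsky", "sigma"))
    stop("static_nu_sgs: closure model must be 'smagorinsky' or 'sigma', got '",
         closure$model, "'", call. = FALSE)
  if (!(is.finite(delta) && delta > 0))
    stop("static_nu_sgs: delta must be a positive length", call. = FALSE)
  dm <- switch(closure$model,
               smagorinsky = smagorinsky_dm(G),
               sigma = sigma_dm(G))
  (closure$cm * delta)^2 * dm
}

# ---- field-level operators on the staggered grid -------------------------

# Strain components at cell centres from a staggered (u, v) pair.
# Returns list(s11, s22, s12, smag) with s12 the cell-centre average of the
# four corner values; smag = sqrt(2 S_ij S_ij) embedding the 2-D tensor.
strain_fields <- function(grid, u, v) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  s11 <- (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE]) / h
  s22 <- (v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / h
  # corner values of (du/dy + dv/dx)/2 on the (nx+1) x (ny+1) corner lattice,
  # one-sided (zero ghost) at the domain edge; then averaged to centres
  ue <- rbind(u[1, , drop = FALSE] * 0, u, u[nx + 1, , drop = FALSE] * 0)
  ue <- cbind(-ue[, 1], ue, -ue[, ny])            # no-slip wall reflection
  dudy <- (ue[2:(nx + 2), 2:(ny + 2)] - ue[2:(nx + 2), 1:(ny + 1)]) / h
  ve <- cbind(v[, 1, drop = FALSE] * 0, v, v[, ny + 1, drop = FALSE] * 0)
  ve <- rbind(-ve[1, ], ve, -ve[nx, ])
  dvdx <- (ve[2:(nx + 2), 2:(ny + 2)] - ve[1:(nx + 1), 2:(ny + 2)]) / h
  s12c <- (dudy + dvdx) / 2                       # corners
  s12 <- (s12c[1:nx, 1:ny] + s12c[2:(nx + 1), 1:ny] +
          s12c[1:nx, 2:(ny + 1)] + s12c[2:(nx + 1), 2:(ny + 1)]) / 4
  smag <- sqrt(2 * (s11^2 + s22^2 + 2 * s12^2))
  list(s11 = s11, s22 = s22, s12 = s12, smag = smag)
}

# Full cell-centre velocity-gradient components (for Sigma / Q fields).
gradient_fields <- function(grid, u, v) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  dudx <- (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE]) / h
  dvdy <- (v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / h
  ue <- rbind(u[1, , drop = FALSE] * 0, u, u[nx + 1, , drop = FALSE] * 0)
  ue <- cbind(-ue[, 1], ue, -ue[, ny])
  dudy_c <- (ue[2:(nx + 2), 2:(ny + 2)] - ue[2:(nx + 2), 1:(ny + 1)]) / h
  dudy <- (dudy_c[1:nx, 1:ny] + dudy_c[2:(nx + 1), 1:ny] +
           dudy_c[1:nx, 2:(ny + 1)] + dudy_c[2:(nx + 1), 2:(ny + 1)]) / 4
  ve <- cbind(v[, 1, drop = FALSE] * 0, v, v[, ny + 1, drop = FALSE] * 0)
  ve <- rbind(-ve[1, ], ve, -ve[nx, ])
  dvdx_c <- (ve[2:(nx + 2), 2:(ny + 2)] - ve[1:(nx + 1), 2:(ny + 2)]) / h
  dvdx <- (dvdx_c[1:nx, 1:ny] + dvdx_c[2:(nx + 1), 1:ny] +
           dvdx_c[1:nx, 2:(ny + 1)] + dvdx_c[2:(nx + 1), 2:(ny + 1)]) / 4
  list(dudx = dudx, dudy = dudy, dvdx = dvdx, dvdy = dvdy)
}

# Closed-form Sigma operator for planar gradients, vectorized over fields.
# For a 2-D gradient the third singular value is 0, so the operator is 0
# identically; kept explicit so the field path is exact (no SVD round-off).
sigma_dm_planar_field <- function(gf) {
  array(0, dim = dim(gf$dudx))
}

#' Eddy-viscosity field for a flow state
#'
#' Vectorized application of the chosen closure over every (fluid) cell of a
#' staggered-grid flow state; this is the per-step source of the added
#' viscosity and of the time-averaged `nu_sgs` maps used to compare closures.
#'
#' @param state a `flow_state` (see [flow_state()]).
#' @param closure an [sgs_closure()]. For `"dynamic_smagorinsky"` the
#'   closure's Lagrangian averaging state is created on first call and
#'   updated in the returned closure.
#' @param dt time step (s); required only by the dynamic model's Lagrangian
#'   averaging transport.
#' @return A list with `nu_sgs` (nx-by-ny matrix, m^2/s, zero on solid
#'   cells, non-negative everywhere) and `closure` (possibly updated state).
#' @export
nu_sgs_field <- function(state, closure, dt = NULL) {
  stopifnot(inherits(state, "flow_state"), inherits(closure, "sgs_closure"))
  grid <- state$grid
  zero <- matrix(0, grid$nx, grid$ny)
  nu <- switch(
    closure$model,
    none = zero,
    smagorinsky = {
      sf <- strain_fields(grid, state$u, state$v)
      (closure$cm * grid$h)^2 * sf$smag
    },
    sigma = {
      # planar velocity field: the Sigma operator vanishes identically
      zero
    },
    dynamic_smagorinsky = {
      res <- dynamic_smagorinsky_nu(state, closure, dt = dt)
      closure <- res$closure
      res$nu_sgs
    })
  nu[state$grid$mask] <- 0
  list(nu_sgs = pmax(nu, 0), closure = closure)
}

# ---- dynamic Smagorinsky -------------------------------------------------

# Discrete top-hat test filter over face neighbours (nominal ratio 2):
# 1/2 centre + 1/8 each of the 4 face neighbours, zero-gradient at edges.
test_filter <- function(f) {
  nx <- nrow(f); ny <- ncol(f)
  fw <- f[c(1, 1:(nx - 1)), ]; fe <- f[c(2:nx, nx), ]
  fs <- f[, c(1, 1:(ny - 1))]; fn <- f[, c(2:ny, ny)]
  0.5 * f + 0.125 * (fw + fe + fs + fn)
}

# Germano-identity products at cell centres for a 2-D field.
# Returns list(lm, mm): numerator L_ij M_ij and denominator M_ij M_ij of the
# least-squares Cs^2, with M_ij = 2 Delta^2 (hat(|S| S_ij) - 4 |S^|S^_ij)
# (test/grid filter-width ratio 2).
germano_products <- function(grid, u, v) {
  uc <- (u[1:grid$nx, , drop = FALSE] + u[2:(grid$nx + 1), , drop = FALSE]) / 2
  vc <- (v[, 1:grid$ny, drop = FALSE] + v[, 2:(grid$ny + 1), drop = FALSE]) / 2
  sf <- strain_fields(grid, u, v)
  d2 <- grid$h^2

  l11 <- test_filter(uc * uc) - test_filter(uc)^2
  l22 <- test_filter(vc * vc) - test_filter(vc)^2
  l12 <- test_filter(uc * vc) - test_filter(uc) * test_filter(vc)

  hs11 <- test_filter(sf$s11); hs22 <- test_filter(sf$s22)
  hs12 <- test_filter(sf$s12)
  hsmag <- sqrt(2 * (hs11^2 + hs22^2 + 2 * hs12^2))

  m11 <- 2 * d2 * (test_filter(sf$smag * sf$s11) - 4 * hsmag * hs11)
  m22 <- 2 * d2 * (test_filter(sf$smag * sf$s22) - 4 * hsmag * hs22)
  m12 <- 2 * d2 * (test_filter(sf$smag * sf$s12) - 4 * hsmag * hs12)

  lm <- l11 * m11 + l22 * m22 + 2 * l12 * m12
  mm <- m11 * m11 + m22 * m22 + 2 * m12 * m12
  list(lm = lm, mm = mm, smag = sf$smag)
}

# First-order upwind advection of a cell-centred scalar by the resolved
# velocity (used only for the Lagrangian averaging fields).
upwind_advect <- function(grid, f, uc, vc, dt) {
  h <- grid$h; nx <- grid$nx; ny <- grid$ny
  fw <- f[c(1, 1:(nx - 1)), ]; fe <- f[c(2:nx, nx), ]
  fs <- f[, c(1, 1:(ny - 1))]; fn <- f[, c(2:ny, ny)]
  dfdx <- ifelse(uc > 0, (f - fw) / h, (fe - f) / h)
  dfdy <- ifelse(vc > 0, (f - fs) / h, (fn - f) / h)
  f - dt * (uc * dfdx + vc * dfdy)
}

#' Dynamic Smagorinsky eddy viscosity (Lagrangian-averaged Germano identity)
#'
#' Computes the per-cell `Cs^2` from the Germano identity with a discrete
#' top-hat test filter (nominal filter ratio 2), Lagrangian time averaging of
#' the numerator (`L_ij M_ij`) and denominator (`M_ij M_ij`) products along
#' resolved-flow pathlines, and clipping of negative `Cs^2` at zero. The
#' model constant thus adapts every step to the resolved field instead of
#' being fixed a priori.
#'
#' The two averaging fields are advected with first-order upwinding and
#' relaxed over the timescale `T = 1.5 * Delta * (I_LM I_MM)^(-1/8)`; when
#' `dt` is `NULL` (single-shot use) the instantaneous, un-averaged products
#' are used, which is the configuration the brute-force identity check
#' exercises.
#'
#' @param state a `flow_state`.
#' @param closure an [sgs_closure()] with `model = "dynamic_smagorinsky"`.
#' @param dt time step for the averaging transport, or `NULL` for a frozen
#'   single-step evaluation without history.
#' @return list with `nu_sgs` (matrix, >= 0), `cs2` (clipped field) and
#'   `closure` carrying the updated averaging state.
#' @export
dynamic_smagorinsky_nu <- function(state, closure, dt = NULL) {
  stopifnot(inherits(closure, "sgs_closure"))
  if (closure$model != "dynamic_smagorinsky")
    stop("dynamic_smagorinsky_nu: closure model is '", closure$model, "'",
         call. = FALSE)
  grid <- state$grid
  gp <- germano_products(grid, state$u, state$v)

  if (is.null(dt)) {
    lm <- gp$lm; mm <- gp$mm
  } else {
    if (is.null(closure$state)) {
      # initialize averaging fields with the instantaneous products
      closure$state <- list(ilm = pmax(gp$lm, 0), imm = gp$mm)
    }
    uc <- (state$u[1:grid$nx, , drop = FALSE] +
           state$u[2:(grid$nx + 1), , drop = FALSE]) / 2
    vc <- (state$v[, 1:grid$ny, drop = FALSE] +
           state$v[, 2:(grid$ny + 1), drop = FALSE]) / 2
    ilm <- upwind_advect(grid, closure$state$ilm, uc, vc, dt)
    imm <- upwind_advect(grid, closure$state$imm, uc, vc, dt)
    prod8 <- pmax(ilm * imm, 0)
    tscale <- 1.5 * grid$h * (prod8 + 1e-300)^(-1 / 8)
    eps <- (dt / tscale) / (1 + dt / tscale)
    ilm <- eps * gp$lm + (1 - eps) * ilm
    imm <- eps * gp$mm + (1 - eps) * imm
    ilm <- pmax(ilm, 0)                  # clip negative Cs^2 each step
    closure$state <- list(ilm = ilm, imm = imm)
    lm <- ilm; mm <- imm
  }

  cs2 <- ifelse(mm > 0, pmax(lm / mm, 0), 0)
  nu <- cs2 * grid$h^2 * gp$smag
  list(nu_sgs = pmax(nu, 0), cs2 = cs2, closure = closure)
}
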