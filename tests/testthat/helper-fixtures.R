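# Shared fixtures: nondimensional desk-scale units with reference width
# d = 1 m and mean inlet velocity U = 1 m/s, so the inlet Reynolds number
# is 1/nu and one flow-through of a length-L domain takes L seconds.

# flow rate (mL/min) giving mean velocity u_mean through a circular vessel
# of diameter d
nd_flow <- function(u_mean = 1, d = 1) u_mean * (pi * d^2 / 4) * 6e7

straight_geometry <- function(length = 1, width = 1)
  channel_geometry(length = length, width = width, occlusion = 0)

stenosed_geometry <- function(length = 4, width = 1, occlusion = 0.76)
  channel_geometry(length = length, width = width, occlusion = occlusion)

constant_inlet <- function(re = 100, u_mean = 1, d = 1)
  inlet_waveform("constant", mean_flow = nd_flow(u_mean, d),
                 nu = u_mean * d / re)

# developed-profile initial state for a straight channel (skips the
# impulsive-start transient in steady-state tests)
poiseuille_state <- function(grid, u_mean = 1) {
  uex <- 1.5 * u_mean * (1 - ((grid$y - grid$Ly / 2) / (grid$Ly / 2))^2)
  flow_state(grid, u = matrix(rep(uex, each = grid$nx + 1),
                              grid$nx + 1, grid$ny))
}

poiseuille_exact <- function(grid, u_mean = 1)
  1.5 * u_mean * (1 - ((grid$y - grid$Ly / 2) / (grid$Ly / 2))^2)

# random velocity-gradient tensors with entries ~ N(0, scale)
random_gradients <- function(n, scale = 1, planar = FALSE) {
  lapply(seq_len(n), function(i) {
    g <- matrix(rnorm(9, 0, scale), 3, 3)
    if (planar) { g[3, ] <- 0; g[, 3] <- 0 }
    g
  })
}
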