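# shared fixtures: the fitted kinetic constants and default geometry used
# throughout, plus independent oracles kept deliberately separate from the
# package's own solution paths.

fitted_protein <- function() protein_params(k_a = 6.2e-4, k_d = 0.2,
                                            c_s_max = 31.5, D = 0.3)
default_geom <- function() well_geometry()

protein_sampling_schedule <- c(2, 4, 6, 8, 24, 48, 72)
cell_culture_schedule <- c(0.5, 1, 2, 4, 6)

# Independent PDE oracle: vertex-centred method of lines integrated by
# lsoda (deSolve). Different spatial discretisation (nodes incl. the face,
# ghost-node boundaries) and different time integrator from the package's
# finite-volume TR-BDF2 path.
pde_oracle <- function(params, geometry, initial_fluid, initial_surface,
                       times, n_nodes = 101) {
  h <- geometry$height_mm
  dz <- h / (n_nodes - 1)
  D <- params$D
  rhs <- function(t, y, parms) {
    cs <- y[1]
    cc <- y[-1] # ug/mL at nodes z = 0, dz, ..., h
    r <- params$k_a * cc[1] * (params$c_s_max - cs) - params$k_d * cs
    d <- numeric(n_nodes)
    # ghost node below the face encodes the flux condition
    # D dc/dz|0 = 1000 r  (c in ug/mL)
    ghost <- cc[2] - 2 * dz * 1000 * r / D
    d[1] <- D * (cc[2] - 2 * cc[1] + ghost) / dz^2
    for (i in 2:(n_nodes - 1))
      d[i] <- D * (cc[i + 1] - 2 * cc[i] + cc[i - 1]) / dz^2
    d[n_nodes] <- D * (2 * cc[n_nodes - 1] - 2 * cc[n_nodes]) / dz^2
    list(c(r, d))
  }
  y0 <- c(initial_surface, rep(initial_fluid, n_nodes))
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  cc <- sol[, -(1:2), drop = FALSE]
  w <- rep(1, n_nodes); w[c(1, n_nodes)] <- 0.5 # trapezoid weights
  list(times = sol[, 1],
       c_surface = sol[, 2],
       mean_fluid = as.numeric(cc %*% w) / (n_nodes - 1))
}

# brute-force equilibrium: sign-change scan of the net Langmuir flux under
# the mass constraint, refined by bisection -- no quadratic formula involved
equilibrium_oracle <- function(params, geometry, total_mass) {
  A <- geometry$area_mm2
  V <- geometry$fluid_volume_uL / 1000
  net <- function(cs) {
    cfl <- (total_mass - A * cs) / V
    params$k_a * cfl * (params$c_s_max - cs) - params$k_d * cs
  }
  upper <- min(params$c_s_max, total_mass / A)
  grid <- seq(0, upper, length.out = 2000)
  v <- vapply(grid, net, numeric(1))
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  cs <- stats::uniroot(net, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  list(c_eq = (total_mass - A * cs) / V, c_s_eq = cs)
}
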