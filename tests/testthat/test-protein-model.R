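test_that("a uniform field with no surface exchange is a fixed point", {
  p <- protein_params(k_a = 0, k_d = 0, c_s_max = 31.5, D = 0.3)
  tr <- solve_protein_kinetics(p, initial_fluid = 1234, initial_surface = 5,
                               t_end = 10, output_times = c(0, 1, 5, 10),
                               nz = 50, dt = 0.05)
  expect_equal(tr$c_surface, rep(5, 4))
  expect_true(all(abs(tr$c - 1234) < 1e-8))
})

test_that("mass is conserved and bounds hold across regimes", {
  g <- default_geom()
  cases <- list(
    list(p = fitted_protein(), c0 = 9500, s0 = 0, t = 72),       # adsorption
    list(p = fitted_protein(), c0 = 0, s0 = 29.04, t = 80),      # desorption
    list(p = protein_params(1e-3, 0.01, 20, 0.5), c0 = 500, s0 = 10, t = 48),
    list(p = protein_params(2e-4, 0.15, 31.5, 0.3), c0 = 2000, s0 = 25, t = 24))
  for (cs in cases) {
    tr <- solve_protein_kinetics(cs$p, g, cs$c0, cs$s0, t_end = cs$t,
                                 nz = 100, dt = 0.02)
    m0 <- tr$mass_total[1]
    expect_lt(max(abs(tr$mass_total - m0)) / m0, 1e-3)
    expect_true(all(tr$c >= -1e-9 * max(cs$c0, 1)))
    expect_true(all(tr$c_surface >= -1e-12))
    expect_true(all(tr$c_surface <= cs$p$c_s_max * (1 + 1e-9)))
  }
})

test_that("mass ledger with zero initial mass stays at zero", {
  p <- fitted_protein()
  tr <- solve_protein_kinetics(p, initial_fluid = 0, initial_surface = 0,
                               t_end = 5, nz = 50, dt = 0.05)
  expect_true(all(abs(tr$mass_total) < 1e-6))
})

test_that("surface coverage is monotone in the pure regimes", {
  p <- fitted_protein()
  ads <- solve_protein_kinetics(p, initial_fluid = 9500, initial_surface = 0,
                                t_end = 72, nz = 100, dt = 0.02)
  expect_true(all(diff(ads$c_surface) >= -1e-10))
  des <- solve_protein_kinetics(p, initial_fluid = 0, initial_surface = 29.04,
                                t_end = 80, nz = 100, dt = 0.02)
  expect_true(all(diff(des$c_surface) <= 1e-10))
})

test_that("halving the grid spacings changes mean_fluid by < 0.5%", {
  p <- fitted_protein()
  out <- c(2, 8, 24, 48, 72)
  coarse <- solve_protein_kinetics(p, initial_fluid = 9500, t_end = 72,
                                   output_times = out, nz = 100, dt = 0.02)
  fine <- solve_protein_kinetics(p, initial_fluid = 9500, t_end = 72,
                                 output_times = out, nz = 200, dt = 0.01)
  expect_lt(max(abs(coarse$mean_fluid - fine$mean_fluid) / fine$mean_fluid),
            0.005)
})

test_that("the solver agrees with an independent method-of-lines oracle", {
  p <- fitted_protein()
  g <- default_geom()
  out <- c(1, 4, 12, 24, 48, 72)
  tr <- solve_protein_kinetics(p, g, initial_fluid = 9500, t_end = 72,
                               output_times = out)
  or <- pde_oracle(p, g, initial_fluid = 9500, initial_surface = 0,
                   times = c(0, out))
  expect_equal(tr$mean_fluid, or$mean_fluid[-1], tolerance = 5e-3)
  expect_equal(tr$c_surface, or$c_surface[-1], tolerance = 5e-3)

  des <- solve_protein_kinetics(p, g, initial_fluid = 0,
                                initial_surface = 29.04, t_end = 80,
                                output_times = out)
  or2 <- pde_oracle(p, g, 0, 29.04, times = c(0, out))
  expect_equal(des$mean_fluid, or2$mean_fluid[-1], tolerance = 5e-3)
})

test_that("long-time state converges to the closed-form equilibrium", {
  p <- fitted_protein()
  g <- default_geom()
  tr <- solve_protein_kinetics(p, g, initial_fluid = 9500, t_end = 500,
                               output_times = c(0, 500), nz = 100, dt = 0.05)
  eq <- equilibrium_state(p, g, total_mass = 9500 * 0.2)
  expect_equal(tr$mean_fluid[2], eq$c_eq, tolerance = 5e-3)
  expect_equal(tr$c_surface[2], eq$c_s_eq, tolerance = 5e-3)
})

test_that("sampling-induced mixing conserves mass and accelerates exchange", {
  p <- fitted_protein()
  g <- default_geom()
  plain <- solve_protein_kinetics(p, g, 0, 29.04, t_end = 80,
                                  output_times = c(0, 80),
                                  nz = 100, dt = 0.02)
  mixed <- solve_protein_kinetics(p, g, 0, 29.04, t_end = 80,
                                  output_times = c(0, 80),
                                  mix_times = protein_sampling_schedule,
                                  nz = 100, dt = 0.02)
  expect_lt(max(abs(mixed$mass_total - mixed$mass_total[1])) /
              mixed$mass_total[1], 1e-3)
  expect_gt(mixed$mass_fluid[2], plain$mass_fluid[2])
})

test_that("solver input validation catches bad states", {
  p <- fitted_protein()
  expect_error(solve_protein_kinetics(p, initial_surface = 40, t_end = 1),
               "c_s_max")
  expect_error(solve_protein_kinetics(p, t_end = 10,
                                      output_times = c(0, 20)),
               "output_times")
  expect_error(solve_protein_kinetics(p, initial_fluid = -5, t_end = 1),
               "non-negative")
})

test_that("steady-state capacity balances the Langmuir terms", {
  # hand arithmetic: 10 * (1 + 0.1 / (1e-3 * 1000)) = 11
  expect_equal(steady_state_capacity(1e-3, 0.1, 1000, 10), 11)
  # the experimental endpoint pair gives 30.81, and the net flux vanishes there
  csm <- steady_state_capacity(6.2e-4, 0.2, 5300, 29.04)
  expect_equal(csm, 30.81, tolerance = 1e-3)
  flux <- 6.2e-4 * 5300 * (csm - 29.04) - 0.2 * 29.04
  expect_equal(flux, 0, tolerance = 1e-9)
  # no desorption: equilibrium is exactly the observed coverage
  expect_equal(steady_state_capacity(5e-4, 0, 5300, 29.04), 29.04)
  expect_error(steady_state_capacity(0, 0.1, 5300, 29.04), "undefined")
})

test_that("equilibrium_state matches a brute-force root scan", {
  p <- fitted_protein()
  g <- default_geom()
  for (M in c(29.04 * g$area_mm2, 9500 * 0.2, 50)) {
    eq <- equilibrium_state(p, g, M)
    or <- equilibrium_oracle(p, g, M)
    expect_equal(eq$c_s_eq, or$c_s_eq, tolerance = 1e-6)
    expect_equal(eq$c_eq, or$c_eq, tolerance = 1e-6)
    # zero net flux and exact mass split
    expect_equal(p$k_a * eq$c_eq * (p$c_s_max - eq$c_s_eq),
                 p$k_d * eq$c_s_eq, tolerance = 1e-9)
    expect_equal(eq$c_eq * 0.2 + eq$c_s_eq * g$area_mm2, M)
  }
})

test_that("equilibrium_state handles the degenerate partitions", {
  g <- default_geom()
  p <- fitted_protein()
  expect_equal(equilibrium_state(p, g, 0), list(c_eq = 0, c_s_eq = 0))
  pk <- protein_params(1e-3, 0, 31.5, 0.3) # no desorption: all mass adsorbs
  M <- 10 * g$area_mm2
  expect_equal(equilibrium_state(pk, g, M), list(c_eq = 0, c_s_eq = 10))
  p0 <- protein_params(0, 0.1, 31.5, 0.3) # no adsorption: all mass in fluid
  expect_equal(equilibrium_state(p0, g, 50), list(c_eq = 250, c_s_eq = 0))
  expect_error(equilibrium_state(protein_params(0, 0, 31.5, 0.3), g, 1),
               "undefined")
})

test_that("average surface concentration is a trapezoidal time mean", {
  p <- protein_params(0, 0, 31.5, 0.3)
  tr <- solve_protein_kinetics(p, initial_fluid = 100, initial_surface = 7,
                               t_end = 10, nz = 20, dt = 0.1)
  expect_equal(average_surface_concentration(tr, c(2, 9)), 7)
  # linear ramp: average of c_s(t) = t over [0, 10] is 5
  ramp <- tr
  ramp$c_surface <- ramp$times
  expect_equal(average_surface_concentration(ramp, c(0, 10)), 5)
  expect_equal(average_surface_concentration(ramp, c(2.5, 7.5)), 5)
  expect_error(average_surface_concentration(tr, c(5, 5)), "empty")
  expect_error(average_surface_concentration(tr, c(8, 12)), "range")
})
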