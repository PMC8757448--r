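test_that("model_error is the relative RMS in percent", {
  obs <- measurement_series(c(1, 2), c(100, 200))
  expect_equal(model_error(c(100, 200), obs), 0)
  expect_equal(model_error(c(110, 180), obs), 10)
  # scale invariance
  for (lam in c(0.01, 3, 1e4))
    expect_equal(model_error(lam * c(110, 180),
                             measurement_series(c(1, 2), lam * c(100, 200))),
                 10)
})

test_that("model_error refuses zero observations unless masked", {
  obs <- measurement_series(c(1, 2, 3), c(100, 0, 200))
  expect_error(model_error(c(1, 2, 3), obs), "undefined")
  expect_equal(model_error(c(110, 5, 180), obs,
                           mask = c(TRUE, FALSE, TRUE)), 10)
  expect_error(model_error(c(1, 2), obs), "lengths")
  expect_error(model_error(c(1, 2, 3), obs, mask = rep(FALSE, 3)), "masked")
})

test_that("measurement_series enforces its invariants", {
  expect_error(measurement_series(c(1, 1), c(2, 3)), "increasing")
  expect_error(measurement_series(c(1, 2), c(-1, 3)), "non-negative")
  s <- measurement_series(c(1, 2), c(5, 6), sd = c(0.1, 0.2),
                          label = "desorption")
  expect_s3_class(s, "measurement_series")
  expect_named(as.data.frame(s), c("time_h", "value", "sd", "label"))
})

test_that("the default grid enumerates 400 candidate pairs", {
  gs <- protein_grid_spec()
  expect_length(gs$k_a, 20)
  expect_length(gs$k_d, 20)
  expect_equal(range(gs$k_a), c(2.5e-4, 12.5e-4))
  expect_equal(range(gs$k_d), c(0.01, 0.20))
  expect_equal(diff(gs$k_a)[1], 0.53e-4, tolerance = 0.01)
  expect_equal(diff(gs$k_d)[1], 0.01, tolerance = 1e-9)
})

test_that("adsorption endpoints mirror the depletion arithmetic", {
  s <- measurement_series(c(2, 24, 72), c(8000, 6000, 5300))
  ep <- adsorption_endpoints(s, 9400)
  expect_equal(ep$c_final, 5300)
  expect_equal(ep$depletion, 4100)
  expect_equal(ep$c_s_final, fluid_to_surface(4100))
  expect_error(adsorption_endpoints(
    measurement_series(c(1, 2), c(10, 9600)), 9400), "exceeds")
})

test_that("grid fit recovers a generating grid point from noiseless data", {
  g <- default_geom()
  gs <- protein_grid_spec()
  ka <- gs$k_a[8]; kd <- gs$k_d[5]
  p <- protein_params(ka, kd, 31.5, 0.3)
  # generator and fitter share the forward model and its discretisation
  none <- noise_spec(magnitude = 0, replicates = 1, seed = 1)
  ads <- generate_protein_series(p, g, "adsorption", noise = none,
                                 nz = 80, dt = 0.05)
  ep <- adsorption_endpoints(ads, 9500, g)
  des <- generate_protein_series(p, g, "desorption", noise = none,
                                 initial_surface = ep$c_s_final,
                                 nz = 80, dt = 0.05)
  fit <- grid_fit_protein(ads, des, initial_fluid = 9500, geometry = g)
  expect_equal(fit$k_a, ka)
  expect_equal(fit$k_d, kd)
  # not exactly zero: the fitted capacity comes from the series' endpoint,
  # which has not fully reached steady state by 72 h
  expect_lt(fit$error, 1.5)
  # the stored surface is exhaustive and the winner attains its minimum
  expect_equal(nrow(fit$surface), 400)
  expect_equal(fit$error, min(fit$surface$error_percent))
  expect_equal(fit$n_invalid, 0)
})

test_that("an off-grid truth lands at the exhaustive minimum near truth", {
  g <- default_geom()
  p <- protein_params(6.0e-4, 0.045, 31.5, 0.3)
  none <- noise_spec(magnitude = 0, replicates = 1, seed = 1)
  ads <- generate_protein_series(p, g, "adsorption", noise = none,
                                 nz = 80, dt = 0.05)
  ep <- adsorption_endpoints(ads, 9500, g)
  des <- generate_protein_series(p, g, "desorption", noise = none,
                                 initial_surface = ep$c_s_final,
                                 nz = 80, dt = 0.05)
  fit <- grid_fit_protein(ads, des, initial_fluid = 9500, geometry = g)
  gs <- fit$grid
  # k_a and k_d compensate along a diagonal error valley, so the exhaustive
  # minimum can sit a second k_a step out when the truth straddles two k_d
  # grid lines; the recovery guarantee is two grid steps per coordinate
  expect_lte(abs(fit$k_a - 6.0e-4), 2 * diff(gs$k_a)[1] * (1 + 1e-9))
  expect_lte(abs(fit$k_d - 0.045), 2 * diff(gs$k_d)[1] * (1 + 1e-9))
  # no other grid point has lower error, and the stored surface value at the
  # winner reproduces under direct recomputation of the two simulations
  expect_equal(fit$error, min(fit$surface$error_percent))
  csm <- steady_state_capacity(fit$k_a, fit$k_d, fit$endpoints$c_final,
                               fit$endpoints$c_s_final)
  pw <- protein_params(fit$k_a, fit$k_d, csm, 0.3)
  direct <-
    model_error(solve_protein_kinetics(pw, g, 9500, 0, t_end = 72,
                                       output_times = ads$times,
                                       nz = 80, dt = 0.05)$mean_fluid, ads) +
    model_error(solve_protein_kinetics(pw, g, 0, fit$endpoints$c_s_final,
                                       t_end = 72, output_times = des$times,
                                       nz = 80, dt = 0.05)$mean_fluid, des)
  expect_equal(direct, fit$error)
})

test_that("permuting the grid order leaves the best point unchanged", {
  g <- default_geom()
  p <- protein_params(6.0e-4, 0.05, 31.5, 0.3)
  none <- noise_spec(magnitude = 0, replicates = 1, seed = 1)
  ads <- generate_protein_series(p, g, "adsorption", noise = none,
                                 nz = 60, dt = 0.1)
  ep <- adsorption_endpoints(ads, 9500, g)
  des <- generate_protein_series(p, g, "desorption", noise = none,
                                 initial_surface = ep$c_s_final,
                                 nz = 60, dt = 0.1)
  small <- list(k_a = seq(4e-4, 8e-4, length.out = 5),
                k_d = seq(0.02, 0.10, length.out = 5))
  flipped <- list(k_a = rev(small$k_a), k_d = rev(small$k_d))
  f1 <- grid_fit_protein(ads, des, 9500, g, grid = small,
                         nz = 60, dt = 0.1)
  f2 <- grid_fit_protein(ads, des, 9500, g, grid = flipped,
                         nz = 60, dt = 0.1)
  expect_equal(f1$k_a, f2$k_a)
  expect_equal(f1$k_d, f2$k_d)
  expect_equal(f1$error, f2$error)
})

test_that("noisy replicates recover the equilibrium ratio and capacity", {
  # the sampling design identifies the Langmuir equilibrium constant
  # k_d/k_a (and through it the capacity) much better than the absolute
  # kinetic scale, which sits on a flat diagonal valley of the error surface
  g <- default_geom()
  p_true <- fitted_protein()
  ratio_true <- p_true$k_d / p_true$k_a
  for (seed in 1:10) {
    ads <- generate_protein_series(
      p_true, g, "adsorption",
      noise = noise_spec(magnitude = 0.05, seed = seed),
      mix_at_sampling = TRUE, nz = 80, dt = 0.05)
    cs_end <- utils::tail(attr(ads, "trajectory")$c_surface, 1)
    des <- generate_protein_series(
      p_true, g, "desorption",
      noise = noise_spec(magnitude = 0.05, seed = seed + 1000),
      initial_surface = cs_end, mix_at_sampling = TRUE, nz = 80, dt = 0.05)
    fit <- grid_fit_protein(ads, des, 9500, g, mix_at_sampling = TRUE)
    expect_lt(abs(fit$k_d / fit$k_a - ratio_true) / ratio_true, 0.20)
    expect_lt(abs(fit$c_s_max - p_true$c_s_max) / p_true$c_s_max, 0.10)
  }
})
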