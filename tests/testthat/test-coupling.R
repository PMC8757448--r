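test_that("transfer is zero on a bare surface and saturates at a", {
  tf <- transfer_function(a = 1.32e-5, b = 0.213)
  expect_equal(transfer(0, tf), 0)
  expect_equal(transfer(1e6, tf), 1.32e-5)
  # 1.32e-5 * (1 - exp(-0.213 * 29.4))
  expect_equal(transfer(29.4, tf), 1.3175e-5, tolerance = 1e-4)
  cs <- seq(0, 50, by = 0.5)
  k <- transfer(cs, tf)
  expect_true(all(diff(k) > 0))
  expect_true(all(k <= 1.32e-5))
  expect_error(transfer(-1, tf), "non-negative")
})

test_that("the fitted transfer reproduces the per-condition k values", {
  # the constant coefficients fitted at mean coverages 27.5 and 29.4
  tf <- transfer_function(a = 1.32e-5, b = 0.213)
  expect_equal(transfer(27.5, tf), 1.33e-5, tolerance = 0.015)
  expect_equal(transfer(29.4, tf), 1.31e-5, tolerance = 0.015)
})

test_that("the hyperbolic alternative obeys the same constraints", {
  tf <- transfer_function(a = 1.32e-5, b = 0.213, form = "hyperbolic")
  expect_equal(transfer(0, tf), 0)
  expect_equal(transfer(1e9, tf), 1.32e-5, tolerance = 1e-6)
  k <- transfer(seq(0, 50, 0.5), tf)
  expect_true(all(diff(k) > 0) && all(k < 1.32e-5))
})

test_that("a constant coefficient reproduces the uncoupled model exactly", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  scn <- scenario(24, 6, p, cp)
  tt <- cell_culture_schedule
  k <- 1.31e-5
  coupled <- coupled_attached_cells(scn, k, times = tt)
  expect_identical(coupled$attached, attached_cells_analytic(k * tt, cp))
})

test_that("near-saturated coverage makes coupling collapse to constant k", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  scn <- scenario(48, 6, p, cp)
  tf <- transfer_function(a = 1.32e-5, b = 0.213)
  traj <- scenario_protein_trajectory(scn)
  tt <- cell_culture_schedule
  coupled <- coupled_attached_cells(scn, tf, times = tt, traj = traj)
  k_const <- transfer(scenario_mean_cs(scn, traj), tf)
  const <- attached_cells_analytic(k_const * tt, cp)
  expect_lt(max(abs(coupled$attached - const) / const), 0.02)
})

test_that("without pre-incubation early attachment lags the constant-k path", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  scn <- scenario(0, 6, p, cp)
  tf <- transfer_function(a = 1.32e-5, b = 0.213)
  traj <- scenario_protein_trajectory(scn)
  tt <- cell_culture_schedule
  coupled <- coupled_attached_cells(scn, tf, times = tt, traj = traj)
  # constant-k path anchored at the same 6 h endpoint
  K6 <- utils::tail(coupled$K, 1)
  const <- attached_cells_analytic(K6 / 6 * tt, cp)
  expect_true(all(coupled$attached[tt < 6] < const[tt < 6]))
  # K(t) is convex near t = 0: the adhesion coefficient grows with coverage
  Kt <- coupled_attached_cells(scn, tf, times = c(0.5, 1, 1.5, 2), traj = traj)$K
  expect_true(all(diff(diff(Kt)) > 0))
})

test_that("longer pre-incubation gives pointwise larger exposure and counts", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  tf <- transfer_function(a = 1.32e-5, b = 0.213)
  tt <- cell_culture_schedule
  out <- lapply(c(0, 24, 48), function(pre)
    coupled_attached_cells(scenario(pre, 6, p, cp), tf, times = tt))
  expect_true(all(out[[1]]$K < out[[2]]$K))
  expect_true(all(out[[2]]$K < out[[3]]$K))
  expect_true(all(out[[1]]$attached < out[[2]]$attached))
  expect_true(all(out[[2]]$attached < out[[3]]$attached))
  # bounded above by the uncoupled prediction at k = a
  upper <- attached_cells_analytic(1.32e-5 * tt, cp)
  for (o in out) expect_true(all(o$attached <= upper * (1 + 1e-12)))
})

test_that("scenario mean coverage matches a refined quadrature", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  scn <- scenario(24, 6, p, cp)
  coarse <- scenario_mean_cs(scn)
  fine <- scenario_mean_cs(scn, dt_out = 0.002, nz = 300, dt = 0.005)
  expect_equal(coarse, fine, tolerance = 2e-3)
  # a trajectory already at steady state averages to the equilibrium value
  g <- default_geom()
  eq <- equilibrium_state(p, g, 9500 * 0.2)
  scn_late <- scenario(400, 6, p, cp, g)
  expect_equal(scenario_mean_cs(scn_late, nz = 100, dt = 0.05), eq$c_s_eq,
               tolerance = 1e-3)
})

test_that("transfer fit recovers a noiseless generating (a, b) pair", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  grid <- transfer_grid_spec()
  a_true <- grid$a[42] # 1.32e-5
  b_true <- grid$b[42] # 0.215
  tf <- transfer_function(a_true, b_true)
  scns <- lapply(c(0, 24, 48), scenario, culture_h = 6, protein = p,
                 cell = cp)
  none <- noise_spec(magnitude = 0, replicates = 1, seed = 1)
  counts <- lapply(scns, function(s)
    generate_cell_counts(scn = s, tf = tf, noise = none))
  fit <- fit_transfer(scns, counts, grid = grid)
  expect_lte(abs(fit$a - a_true), diff(grid$a)[1] * (1 + 1e-9))
  expect_lte(abs(fit$b - b_true), diff(grid$b)[1] * (1 + 1e-9))
  expect_true(fit$b_identifiable)
  expect_lt(fit$error, 0.5)
})

test_that("degenerate or saturating scenario sets are flagged", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  scns <- list(scenario(48, 6, p, cp), scenario(48, 6, p, cp))
  counts <- lapply(scns, function(s)
    generate_cell_counts(cp, k = 1.3e-5,
                         noise = noise_spec(magnitude = 0, replicates = 1)))
  expect_error(fit_transfer(scns, counts), "unidentifiable")
})

test_that("noisy counts still pin the transfer asymptote to within 10%", {
  p <- fitted_protein()
  cp <- cell_params(0.63, 3500)
  grid <- transfer_grid_spec()
  tf <- transfer_function(grid$a[42], grid$b[42])
  scns <- lapply(c(0, 24, 48), scenario, culture_h = 6, protein = p,
                 cell = cp)
  errs <- vapply(1:6, function(seed) {
    counts <- lapply(scns, function(s)
      generate_cell_counts(scn = s, tf = tf,
                           noise = noise_spec(magnitude = 0.05,
                                              seed = seed)))
    fit <- fit_transfer(scns, counts, grid = grid)
    abs(fit$a - tf$a) / tf$a
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})
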