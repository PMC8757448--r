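#' Transfer function from protein coverage to the cell adhesion coefficient
#'
#' Couples the protein and cell models one way: the adhesion coefficient a
#' cell population experiences depends on the instantaneous surface protein
#' concentration. The default form is the saturating exponential
#' \deqn{k(c_s) = a (1 - e^{-b c_s}),}
#' which is zero on a bare surface, strictly increasing, and saturates at
#' `a`; a hyperbolic alternative \eqn{a b c_s / (1 + b c_s)} with the same
#' constraints is available behind the `form` switch.
#'
#' @param a Asymptotic adhesion coefficient, cm^2 cells^-1 h^-1. Positive.
#' @param b Protein sensitivity, mm^2 ug^-1. Positive.
#' @param form `"exponential"` (default) or `"hyperbolic"`.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(a, b, form = c("exponential", "hyperbolic")) {
  form <- match.arg(form)
  stopifnot(is.numeric(a), length(a) == 1, a > 0,
            is.numeric(b), length(b) == 1, b > 0)
  structure(list(a = a, b = b, form = form), class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf(
    "Transfer function (%s): a = %.4g cm^2/(cells h), b = %.4g mm^2/ug\n",
    x$form, x$a, x$b))
  invisible(x)
}

#' Evaluate a transfer function
#'
#' @param c_s Surface protein concentration(s), ug/mm^2. Non-negative.
#' @param tf A [transfer_function()].
#' @return Adhesion coefficient(s) k, cm^2 cells^-1 h^-1.
#' @examples
#' tf <- transfer_function(a = 1.32e-5, b = 0.213)
#' transfer(c(0, 29.4), tf)
#' @export
transfer <- function(c_s, tf) {
  if (!inherits(tf, "transfer_function"))
    stop("`tf` must be a transfer_function", call. = FALSE)
  c_s <- as.numeric(c_s)
  if (any(c_s < 0)) stop("surface concentration must be non-negative",
                         call. = FALSE)
  switch(tf$form,
         exponential = tf$a * (1 - exp(-tf$b * c_s)),
         hyperbolic = tf$a * tf$b * c_s / (1 + tf$b * c_s))
}

#' A pre-incubation / culture scenario
#'
#' One experimental condition of the coupled study: the disk sits in
#' protein-rich medium from t = 0; cells are seeded at t = `pre_incubation_h`
#' and cultured for `culture_h`. With no pre-incubation the cells land on a
#' bare surface that acquires its protein coat during the culture itself.
#' The protein simulation runs continuously over the whole span (no medium
#' change at seeding).
#'
#' @param pre_incubation_h Pre-incubation duration, h (0, 24, 48, ...).
#' @param culture_h Culture duration, h (default 6).
#' @param protein A [protein_params()].
#' @param cell A [cell_params()].
#' @param geometry A [well_geometry()].
#' @param initial_fluid Protein concentration of the loading medium, ug/mL.
#' @param initial_surface Protein coverage at t = 0, ug/mm^2 (default 0,
#'   a bare disk).
#' @return An object of class `scenario`.
#' @export
scenario <- function(pre_incubation_h, culture_h = 6, protein, cell,
                     geometry = well_geometry(), initial_fluid = 9500,
                     initial_surface = 0) {
  stopifnot(is.numeric(pre_incubation_h), length(pre_incubation_h) == 1,
            pre_incubation_h >= 0,
            is.numeric(culture_h), length(culture_h) == 1, culture_h > 0)
  assert_protein_params(protein)
  assert_cell_params(cell)
  assert_geometry(geometry)
  structure(list(pre_incubation_h = pre_incubation_h, culture_h = culture_h,
                 protein = protein, cell = cell, geometry = geometry,
                 initial_fluid = initial_fluid,
                 initial_surface = initial_surface),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario: %g h pre-incubation + %g h culture, seeding %.4g cells/cm^2\n",
              x$pre_incubation_h, x$culture_h, x$cell$c_0))
  invisible(x)
}

assert_scenario <- function(x) {
  if (!inherits(x, "scenario"))
    stop("expected a scenario()", call. = FALSE)
  x
}

#' Protein trajectory underlying a scenario
#'
#' Runs the protein simulation from t = 0 to the end of the culture window,
#' with output refined (step `dt_out`) over the culture window where the
#' coupling quadrature needs it.
#'
#' @param scn A [scenario()].
#' @param dt_out Output resolution over the culture window, h.
#' @param nz,dt Solver controls passed to [solve_protein_kinetics()].
#' @return A `protein_trajectory`.
#' @export
scenario_protein_trajectory <- function(scn, dt_out = 0.01,
                                        nz = 200, dt = 0.01) {
  assert_scenario(scn)
  t_total <- scn$pre_incubation_h + scn$culture_h
  out <- sort(unique(c(seq(0, t_total, length.out = 201),
                       seq(scn$pre_incubation_h, t_total, by = dt_out),
                       t_total)))
  solve_protein_kinetics(scn$protein, scn$geometry,
                         initial_fluid = scn$initial_fluid,
                         initial_surface = scn$initial_surface,
                         t_end = t_total, output_times = out,
                         nz = nz, dt = dt)
}

#' Mean surface protein concentration over a scenario's culture window
#'
#' Average coverage \eqn{c_s} the cells experience, i.e. the time average
#' over `[T_pre, T_pre + culture_h]` — the summary used to compare the
#' per-condition constant adhesion coefficients with the transfer function.
#'
#' @param scn A [scenario()].
#' @param traj Optional pre-computed trajectory from
#'   [scenario_protein_trajectory()] (recomputed if missing).
#' @param ... Passed to [scenario_protein_trajectory()].
#' @return Mean c_s over the culture window, ug/mm^2.
#' @export
scenario_mean_cs <- function(scn, traj = NULL, ...) {
  assert_scenario(scn)
  if (is.null(traj)) traj <- scenario_protein_trajectory(scn, ...)
  average_surface_concentration(
    traj, c(scn$pre_incubation_h, scn$pre_incubation_h + scn$culture_h))
}

#' Attached cells under protein-coupled adhesion
#'
#' Evaluates the cumulative adhesion exposure
#' \eqn{K(t) = \int_0^t k(c_s(T_{pre} + t')) dt'} over culture time by
#' trapezoidal quadrature on the protein trajectory, then applies the
#' closed-form attachment solution [attached_cells_analytic()]. Passing a
#' plain number as `tf` short-circuits the quadrature to `K = k t`, which
#' reproduces the uncoupled constant-coefficient model exactly.
#'
#' @param scn A [scenario()].
#' @param tf A [transfer_function()], or a single numeric constant k.
#' @param times Culture-relative output times, h (default the trajectory's
#'   native culture-window grid).
#' @param traj Optional pre-computed `protein_trajectory` for the scenario.
#' @param ... Passed to [scenario_protein_trajectory()].
#' @return A `cell_trajectory` (times are culture-relative, h).
#' @export
coupled_attached_cells <- function(scn, tf, times = NULL, traj = NULL, ...) {
  assert_scenario(scn)
  if (is.numeric(tf) && length(tf) == 1) {
    if (is.null(times))
      stop("output times are required with a constant coefficient",
           call. = FALSE)
    K <- tf * times
    att <- attached_cells_analytic(K, scn$cell)
    return(structure(list(times = times, attached = att,
                          free = scn$cell$gamma * scn$cell$c_0 - att,
                          params = scn$cell, K = K),
                     class = "cell_trajectory"))
  }
  if (!inherits(tf, "transfer_function"))
    stop("`tf` must be a transfer_function or a single number", call. = FALSE)
  if (is.null(traj)) traj <- scenario_protein_trajectory(scn, ...)
  t0 <- scn$pre_incubation_h
  t1 <- t0 + scn$culture_h
  sel <- traj$times >= t0 - 1e-9 & traj$times <= t1 + 1e-9
  tq <- traj$times[sel] - t0
  kq <- transfer(traj$c_surface[sel], tf)
  Kq <- cumtrapz(tq, kq)
  if (is.null(times)) times <- tq
  if (any(times < -1e-9) || any(times > scn$culture_h + 1e-9))
    stop("output times must lie within the culture window", call. = FALSE)
  K <- stats::approx(tq, Kq, xout = times)$y
  att <- attached_cells_analytic(K, scn$cell)
  structure(list(times = times, attached = att,
                 free = scn$cell$gamma * scn$cell$c_0 - att,
                 params = scn$cell, K = K),
            class = "cell_trajectory")
}

#' Default grid for the (a, b) transfer-function search
#'
#' Asymptote `a` over `[0.5e-5, 3.0e-5]` cm^2/(cells h) in steps of 0.02e-5
#' and sensitivity `b` over `[0.01, 1.0]` mm^2/ug in steps of 0.005; the
#' ranges bracket adhesion coefficients typical of osteoblast seeding
#' experiments.
#'
#' @param a Grid of asymptote values.
#' @param b Grid of sensitivity values.
#' @return List with numeric vectors `a` and `b`.
#' @export
transfer_grid_spec <- function(a = seq(0.5e-5, 3.0e-5, by = 0.02e-5),
                               b = seq(0.01, 1.0, by = 0.005)) {
  stopifnot(length(a) >= 2, all(a > 0), length(b) >= 2, all(b > 0))
  list(a = sort(a), b = sort(b))
}

#' Fit the transfer function to cell counts across scenarios
#'
#' Exhaustive 2D grid search over (a, b): for every candidate pair the
#' coupled attachment prediction is evaluated for each scenario and scored
#' against its counts with [model_error()]; the summed error is minimised.
#' The protein trajectory and, for each `b`, the exposure integral
#' \eqn{\int (1 - e^{-b c_s}) dt} are computed once per scenario, since `a`
#' only scales the exposure. Ties are broken deterministically (smaller b,
#' then smaller a).
#'
#' Identifiability: scenarios whose culture windows see essentially the same
#' protein coverage cannot constrain `b` and cause a failure; if the error
#' is flat in `b` all the way to the grid's upper edge (all scenarios
#' saturating), the fit is returned with a warning and `b_identifiable =
#' FALSE`.
#'
#' @param scenarios List of [scenario()] objects (>= 2 with distinct mean
#'   coverage).
#' @param counts List of [measurement_series()] of attached-cell counts,
#'   parallel to `scenarios`.
#' @param grid A [transfer_grid_spec()].
#' @param form Transfer form, as in [transfer_function()].
#' @param dt_out,nz,dt Solver controls for the underlying protein runs.
#' @return List with `tf` (the fitted [transfer_function()]), `a`, `b`,
#'   `error` (summed percent error), `surface` (data.frame a, b,
#'   error_percent), `mean_cs` per scenario, `b_identifiable`.
#' @export
fit_transfer <- function(scenarios, counts, grid = transfer_grid_spec(),
                         form = c("exponential", "hyperbolic"),
                         dt_out = 0.01, nz = 200, dt = 0.01) {
  form <- match.arg(form)
  stopifnot(is.list(scenarios), is.list(counts),
            length(scenarios) == length(counts), length(scenarios) >= 2)
  lapply(scenarios, assert_scenario)
  lapply(counts, function(x) stopifnot(inherits(x, "measurement_series")))

  trajs <- lapply(scenarios, scenario_protein_trajectory,
                  dt_out = dt_out, nz = nz, dt = dt)
  mean_cs <- mapply(scenario_mean_cs, scenarios, trajs)
  if (diff(range(mean_cs)) < 1e-6 * max(mean_cs))
    stop("scenarios have identical mean surface coverage: b is unidentifiable",
         call. = FALSE)

  # culture-window coverage per scenario, on the quadrature grid
  win <- lapply(seq_along(scenarios), function(i) {
    scn <- scenarios[[i]]; tr <- trajs[[i]]
    t0 <- scn$pre_incubation_h
    sel <- tr$times >= t0 - 1e-9 & tr$times <= t0 + scn$culture_h + 1e-9
    list(t = tr$times[sel] - t0, cs = tr$c_surface[sel],
         obs_t = counts[[i]]$times, cell = scn$cell)
  })

  na <- length(grid$a); nb <- length(grid$b)
  err <- matrix(NA_real_, na, nb)
  for (j in seq_len(nb)) {
    b <- grid$b[j]
    # exposure integral per unit a, interpolated at the observation times
    I_obs <- lapply(win, function(w) {
      g <- switch(form,
                  exponential = 1 - exp(-b * w$cs),
                  hyperbolic = b * w$cs / (1 + b * w$cs))
      stats::approx(w$t, cumtrapz(w$t, g), xout = w$obs_t)$y
    })
    for (i in seq_len(na)) {
      a <- grid$a[i]
      e <- 0
      for (s in seq_along(win)) {
        pred <- attached_cells_analytic(a * I_obs[[s]], win[[s]]$cell)
        e <- e + model_error(pred, counts[[s]])
      }
      err[i, j] <- e
    }
  }

  idx <- expand.grid(i = seq_len(na), j = seq_len(nb))
  ord <- order(err[cbind(idx$i, idx$j)], grid$b[idx$j], grid$a[idx$i])
  best <- idx[ord[1], ]
  a_hat <- grid$a[best$i]; b_hat <- grid$b[best$j]
  e_min <- err[best$i, best$j]

  # flat-in-b plateau reaching the top of the grid => b not identified
  flat_b <- which(apply(err, 2, min) <= e_min + 1e-9)
  b_identifiable <- !(length(flat_b) > 1 && max(flat_b) == nb)
  if (!b_identifiable)
    warning("error is flat in b up to the grid edge (scenarios saturate the transfer function); b is a lower bound only")

  list(tf = transfer_function(a_hat, b_hat, form), a = a_hat, b = b_hat,
       error = e_min,
       surface = data.frame(a = grid$a[idx$i], b = grid$b[idx$j],
                            error_percent = err[cbind(idx$i, idx$j)]),
       mean_cs = mean_cs, b_identifiable = b_identifiable)
}
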