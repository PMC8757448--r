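#' A timestamped measurement series
#'
#' Container for experimental or synthetic observations used by all fitting
#' operations: depth-averaged fluid protein concentration (ug/mL) for the
#' sorption experiments, or areal attached-cell counts (cells/cm^2) for the
#' adhesion experiments.
#'
#' @param times Observation times, h; strictly increasing.
#' @param values Observed values, non-negative; same length as `times`.
#' @param sd Optional per-point replicate standard deviation.
#' @param label One of `"adsorption"`, `"desorption"`, `"cell_culture"`.
#' @return An object of class `measurement_series`.
#' @export
measurement_series <- function(times, values, sd = NULL,
                               label = c("adsorption", "desorption",
                                         "cell_culture")) {
  label <- match.arg(label)
  times <- as.numeric(times); values <- as.numeric(values)
  stopifnot(length(times) >= 1, length(times) == length(values))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    stopifnot(length(sd) == length(times), all(sd >= 0))
  }
  structure(list(times = times, values = values, sd = sd, label = label),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("Measurement series (%s): %d points over [%.3g, %.3g] h\n",
              x$label, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.measurement_series <- function(x, ...) {
  d <- data.frame(time_h = x$times, value = x$values)
  if (!is.null(x$sd)) d$sd <- x$sd
  d$label <- x$label
  d
}

#' Relative root-mean-square model error, in percent
#'
#' The fit criterion used throughout: the RMS of pointwise relative
#' deviations between model prediction and observation,
#' \deqn{100 \sqrt{\frac{1}{N} \sum_i \left(\frac{c(t_i) - c^e(t_i)}{c^e(t_i)}\right)^2}.}
#' It is scale-invariant (multiplying both series by a common factor leaves
#' it unchanged) and zero only for identical series.
#'
#' @param predicted Model predictions aligned one-to-one with the observed
#'   times (numeric vector).
#' @param observed A [measurement_series()] (or numeric vector of the same
#'   length as `predicted`).
#' @param mask Optional logical vector: points to include (default all).
#'   Observed zeros must be masked, otherwise the relative error is
#'   undefined and the function fails.
#' @return Percent error (scalar, >= 0).
#' @examples
#' model_error(c(110, 180), measurement_series(c(1, 2), c(100, 200))) # 10
#' @export
model_error <- function(predicted, observed, mask = NULL) {
  obs <- if (inherits(observed, "measurement_series")) observed$values
         else as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(predicted) != length(obs))
    stop("predicted and observed lengths differ", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(obs))
  stopifnot(is.logical(mask), length(mask) == length(obs))
  if (!any(mask)) stop("all points masked", call. = FALSE)
  if (any(obs[mask] == 0))
    stop("observed value of 0 at a compared point: relative error undefined (mask it)",
         call. = FALSE)
  rel <- (predicted[mask] - obs[mask]) / obs[mask]
  100 * sqrt(mean(rel^2))
}

#' Default grid for the (k_a, k_d) exhaustive search
#'
#' 20 equally spaced adsorption coefficients over
#' `[2.5e-4, 12.5e-4]` mL/(ug h) (step ~0.53e-4) crossed with 20 desorption
#' coefficients over `[0.01, 0.20]` 1/h (step 0.01): 400 candidate pairs.
#'
#' @param k_a_range,k_a_n Range (mL ug^-1 h^-1) and number of k_a values.
#' @param k_d_range,k_d_n Range (h^-1) and number of k_d values.
#' @return A list with numeric vectors `k_a` and `k_d`.
#' @export
protein_grid_spec <- function(k_a_range = c(2.5e-4, 12.5e-4), k_a_n = 20,
                              k_d_range = c(0.01, 0.20), k_d_n = 20) {
  stopifnot(length(k_a_range) == 2, k_a_range[1] > 0, diff(k_a_range) > 0,
            length(k_d_range) == 2, k_d_range[1] >= 0, diff(k_d_range) > 0,
            k_a_n >= 2, k_d_n >= 2)
  list(k_a = seq(k_a_range[1], k_a_range[2], length.out = k_a_n),
       k_d = seq(k_d_range[1], k_d_range[2], length.out = k_d_n))
}

#' Steady-state endpoints of an adsorption series
#'
#' The terminal observation of the adsorption experiment is taken as the
#' final fluid concentration c^f; the depletion relative to the starting
#' concentration, converted by [fluid_to_surface()], gives the final surface
#' concentration c_s^f. These endpoints feed [steady_state_capacity()]
#' inside the grid fit.
#'
#' @param adsorption A [measurement_series()] of fluid concentrations.
#' @param initial_fluid Starting (well-mixed) fluid concentration, ug/mL.
#' @param geometry A [well_geometry()].
#' @return List with `c_final` (ug/mL), `depletion` (ug/mL), `c_s_final`
#'   (ug/mm^2).
#' @export
adsorption_endpoints <- function(adsorption, initial_fluid,
                                 geometry = well_geometry()) {
  stopifnot(inherits(adsorption, "measurement_series"),
            is.numeric(initial_fluid), initial_fluid > 0)
  c_final <- utils::tail(adsorption$values, 1)
  depletion <- initial_fluid - c_final
  if (depletion < 0)
    stop("terminal adsorption value exceeds the initial concentration",
         call. = FALSE)
  list(c_final = c_final, depletion = depletion,
       c_s_final = fluid_to_surface(depletion, geometry))
}

#' Exhaustive grid-search fit of the Langmuir kinetic constants
#'
#' For every candidate pair (k_a, k_d) on the grid: the surface capacity is
#' derived from the adsorption series' endpoints via
#' [steady_state_capacity()]; an adsorption simulation (uniform initial
#' fluid, bare surface) and a desorption simulation (protein-free fluid,
#' surface loaded to the observed c_s^f) are run; the depth-averaged fluid
#' predictions at the observed times are scored with [model_error()]; the
#' two errors are summed. The pair with the smallest summed error wins; the
#' full error surface is evaluated with no early stopping, and ties are
#' broken deterministically (smaller k_d, then smaller k_a).
#'
#' @param adsorption,desorption [measurement_series()] of depth-averaged
#'   fluid concentration, ug/mL.
#' @param initial_fluid Starting fluid concentration of the adsorption
#'   experiment, ug/mL (the well-mixed loading concentration).
#' @param geometry A [well_geometry()].
#' @param D Diffusion coefficient, mm^2/h.
#' @param grid A [protein_grid_spec()].
#' @param mix_at_sampling Re-homogenise the simulated fluid column at each
#'   observation time (drawing an aliquot stirs the well). Matching the
#'   sampling protocol makes the kinetic constants far better identified
#'   than purely diffusion-limited runs, where only the ratio k_d/k_a is
#'   well constrained.
#' @param nz,dt Spatial cells and time step for the forward simulations
#'   inside the fit; coarser than single-run defaults because the fit runs
#'   two simulations per grid point (800 in total on the default grid).
#' @return An object of class `protein_grid_fit`: `k_a`, `k_d`, `c_s_max`,
#'   `error` (percent), `surface` (data.frame of k_a, k_d, error_percent over
#'   the whole grid), `endpoints`, and `grid`.
#' @export
grid_fit_protein <- function(adsorption, desorption, initial_fluid,
                             geometry = well_geometry(), D = 0.3,
                             grid = protein_grid_spec(),
                             mix_at_sampling = FALSE,
                             nz = 80, dt = 0.05) {
  stopifnot(inherits(adsorption, "measurement_series"),
            inherits(desorption, "measurement_series"))
  ep <- adsorption_endpoints(adsorption, initial_fluid, geometry)
  if (ep$c_final <= 0)
    stop("terminal adsorption concentration must be positive", call. = FALSE)

  cases <- expand.grid(k_a = grid$k_a, k_d = grid$k_d)
  errs <- vapply(seq_len(nrow(cases)), function(i) {
    ka <- cases$k_a[i]; kd <- cases$k_d[i]
    csm <- steady_state_capacity(ka, kd, ep$c_final, ep$c_s_final)
    p <- protein_params(ka, kd, csm, D)
    tryCatch({
      ads <- solve_protein_kinetics(
        p, geometry, initial_fluid = initial_fluid, initial_surface = 0,
        t_end = max(adsorption$times), output_times = adsorption$times,
        mix_times = if (mix_at_sampling) adsorption$times else NULL,
        nz = nz, dt = dt)
      des <- solve_protein_kinetics(
        p, geometry, initial_fluid = 0, initial_surface = ep$c_s_final,
        t_end = max(desorption$times), output_times = desorption$times,
        mix_times = if (mix_at_sampling) desorption$times else NULL,
        nz = nz, dt = dt)
      model_error(ads$mean_fluid, adsorption) +
        model_error(des$mean_fluid, desorption)
    }, error = function(e) Inf)
  }, numeric(1))

  if (all(!is.finite(errs)))
    stop("every grid point failed to simulate", call. = FALSE)
  # deterministic tie-break: smallest error, then smaller k_d, then smaller k_a
  ord <- order(errs, cases$k_d, cases$k_a)
  best <- ord[1]
  ka <- cases$k_a[best]; kd <- cases$k_d[best]
  structure(
    list(k_a = ka, k_d = kd,
         c_s_max = steady_state_capacity(ka, kd, ep$c_final, ep$c_s_final),
         error = errs[best],
         surface = data.frame(k_a = cases$k_a, k_d = cases$k_d,
                              error_percent = errs),
         endpoints = ep, grid = grid,
         n_invalid = sum(!is.finite(errs))),
    class = "protein_grid_fit")
}

#' @export
print.protein_grid_fit <- function(x, ...) {
  cat(sprintf(
    "Grid fit: k_a = %.4g mL/(ug h), k_d = %.4g 1/h, c_s_max = %.4g ug/mm^2\n",
    x$k_a, x$k_d, x$c_s_max))
  cat(sprintf("  summed error %.3f%% over %d grid points (%d invalid)\n",
              x$error, nrow(x$surface), x$n_invalid))
  invisible(x)
}
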