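#' Replicate-noise specification for synthetic measurements
#'
#' Describes how replicate observations scatter around the model truth.
#' Multiplicative Gaussian noise (a fixed coefficient of variation) mimics
#' assay-style relative error; additive Gaussian uses a fixed SD; Poisson
#' mimics counting cells in a finite field of view. All randomness flows
#' from the single `seed` — identical specs give identical data.
#'
#' @param kind `"multiplicative"`, `"additive"` or `"poisson"`.
#' @param magnitude CV for multiplicative noise, SD (in data units) for
#'   additive; ignored for Poisson. Non-negative.
#' @param replicates Number of replicates per time point (>= 1; triplicates
#'   by default, the usual independent-sample design).
#' @param seed Integer RNG seed.
#' @param field_area_cm2 Field-of-view area used by the Poisson mode to turn
#'   areal densities into integer counts and back.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("multiplicative", "additive", "poisson"),
                       magnitude = 0.05, replicates = 3, seed = 1,
                       field_area_cm2 = 0.01) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(magnitude), magnitude >= 0,
            is.numeric(replicates), replicates >= 1,
            is.numeric(seed), length(seed) == 1,
            is.numeric(field_area_cm2), field_area_cm2 > 0)
  structure(list(kind = kind, magnitude = magnitude,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), field_area_cm2 = field_area_cm2),
            class = "noise_spec")
}

# replicate matrix (replicates x length(truth)) under a local RNG stream
apply_noise <- function(truth, noise) {
  n <- length(truth); r <- noise$replicates
  withr::with_seed(noise$seed, {
    switch(noise$kind,
      multiplicative = matrix(truth, r, n, byrow = TRUE) *
        (1 + noise$magnitude * matrix(stats::rnorm(r * n), r, n)),
      additive = matrix(truth, r, n, byrow = TRUE) +
        noise$magnitude * matrix(stats::rnorm(r * n), r, n),
      poisson = {
        lam <- pmax(truth * noise$field_area_cm2, 0)
        matrix(stats::rpois(r * n, rep(lam, each = r)), r, n) /
          noise$field_area_cm2
      })
  })
}

replicate_summary <- function(reps) {
  vals <- colMeans(reps)
  sds <- if (nrow(reps) > 1) apply(reps, 2, stats::sd) else rep(0, ncol(reps))
  list(values = pmax(vals, 0), sd = sds)
}

#' Generate a synthetic fluid-phase protein series
#'
#' Runs the forward diffusion--Langmuir model for an adsorption experiment
#' (protein-rich medium over a bare disk) or a desorption experiment
#' (protein-free medium over a loaded disk), samples the depth-averaged
#' fluid concentration on the given schedule, and perturbs it with replicate
#' noise. The generating truth rides along so parameter-recovery tests are
#' self-describing.
#'
#' @param params A [protein_params()] — the ground truth.
#' @param geometry A [well_geometry()].
#' @param scenario `"adsorption"` or `"desorption"`.
#' @param schedule Sampling times, h (default 2, 4, 6, 8, 24, 48, 72, a
#'   typical aliquot schedule over a 72 h incubation).
#' @param noise A [noise_spec()].
#' @param initial_fluid Loading concentration for adsorption, ug/mL.
#' @param initial_surface Starting coverage for desorption, ug/mm^2; default
#'   `0.92 * c_s_max`, a nearly saturated disk.
#' @param mix_at_sampling Re-homogenise the column at each schedule time,
#'   emulating the stirring caused by drawing an aliquot.
#' @param nz,dt Solver controls.
#' @return A [measurement_series()] (replicate means, with SDs) carrying
#'   attributes `truth` (noiseless values), `trajectory` (the full
#'   `protein_trajectory`), `replicates` (matrix) and `params`.
#' @export
generate_protein_series <- function(params, geometry = well_geometry(),
                                    scenario = c("adsorption", "desorption"),
                                    schedule = c(2, 4, 6, 8, 24, 48, 72),
                                    noise = noise_spec(),
                                    initial_fluid = 9500,
                                    initial_surface = NULL,
                                    mix_at_sampling = FALSE,
                                    nz = 200, dt = 0.01) {
  scenario <- match.arg(scenario)
  assert_protein_params(params)
  if (scenario == "adsorption") {
    c0 <- initial_fluid; s0 <- 0
  } else {
    c0 <- 0
    s0 <- if (is.null(initial_surface)) 0.92 * params$c_s_max
          else initial_surface
  }
  traj <- solve_protein_kinetics(params, geometry, initial_fluid = c0,
                                 initial_surface = s0,
                                 t_end = max(schedule),
                                 output_times = schedule,
                                 mix_times = if (mix_at_sampling) schedule
                                             else NULL,
                                 nz = nz, dt = dt)
  truth <- traj$mean_fluid
  reps <- apply_noise(truth, noise)
  sm <- replicate_summary(reps)
  out <- measurement_series(schedule, sm$values, sd = sm$sd, label = scenario)
  attr(out, "truth") <- truth
  attr(out, "trajectory") <- traj
  attr(out, "replicates") <- reps
  attr(out, "params") <- params
  out
}

#' Generate synthetic attached-cell counts
#'
#' Evaluates the attachment model on the culture schedule — with a constant
#' adhesion coefficient, or coupled to a protein scenario through a transfer
#' function — and perturbs it with replicate noise (Poisson mode scales
#' through a field of view to integer counts).
#'
#' @param params A [cell_params()] (used in the constant-k mode).
#' @param k Constant adhesion coefficient, cm^2 cells^-1 h^-1 (ignored when
#'   `scn` and `tf` are given).
#' @param scn Optional [scenario()] for the coupled mode.
#' @param tf Optional [transfer_function()] for the coupled mode.
#' @param schedule Culture sampling times, h (default 0.5, 1, 2, 4, 6, the
#'   standard imaging schedule).
#' @param noise A [noise_spec()].
#' @param ... Solver controls passed to [coupled_attached_cells()].
#' @return A [measurement_series()] of counts (cells/cm^2) with attributes
#'   `truth`, `replicates` and the generating parameters.
#' @export
generate_cell_counts <- function(params = NULL, k = NULL, scn = NULL,
                                 tf = NULL,
                                 schedule = c(0.5, 1, 2, 4, 6),
                                 noise = noise_spec(), ...) {
  if (!is.null(scn) && !is.null(tf)) {
    assert_scenario(scn)
    truth <- coupled_attached_cells(scn, tf, times = schedule, ...)$attached
    gen <- list(scenario = scn, tf = tf)
  } else {
    assert_cell_params(params)
    stopifnot(is.numeric(k), length(k) == 1, k >= 0)
    truth <- attached_cells_analytic(k * schedule, params)
    gen <- list(params = params, k = k)
  }
  reps <- apply_noise(truth, noise)
  sm <- replicate_summary(reps)
  out <- measurement_series(schedule, sm$values, sd = sm$sd,
                            label = "cell_culture")
  attr(out, "truth") <- truth
  attr(out, "replicates") <- reps
  attr(out, "generator") <- gen
  out
}
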