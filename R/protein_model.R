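#' Langmuir kinetic parameters for protein adsorption/desorption
#'
#' Bundles the kinetic constants of the diffusion--Langmuir model: protein in
#' the fluid column diffuses (coefficient `D`) and exchanges with the disk
#' face, where attachment is proportional to the local fluid concentration
#' and the free site fraction, and detachment is proportional to coverage:
#' \deqn{dc_s/dt = k_a c(0,t) (c_s^m - c_s) - k_d c_s.}
#'
#' @param k_a Adsorption coefficient, mL ug^-1 h^-1. Non-negative.
#' @param k_d Desorption coefficient, h^-1. Non-negative.
#' @param c_s_max Maximum surface concentration c_s^m, ug/mm^2. Positive.
#' @param D Diffusion coefficient, mm^2/h. Positive. Defaults to 0.3, the
#'   literature value for serum albumin at 37 C in buffered medium.
#' @return An object of class `protein_params`.
#' @export
protein_params <- function(k_a, k_d, c_s_max, D = 0.3) {
  stopifnot(is.numeric(k_a), length(k_a) == 1, is.finite(k_a), k_a >= 0,
            is.numeric(k_d), length(k_d) == 1, is.finite(k_d), k_d >= 0,
            is.numeric(c_s_max), length(c_s_max) == 1, is.finite(c_s_max),
            c_s_max > 0,
            is.numeric(D), length(D) == 1, is.finite(D), D > 0)
  structure(list(k_a = k_a, k_d = k_d, c_s_max = c_s_max, D = D),
            class = "protein_params")
}

#' @export
print.protein_params <- function(x, ...) {
  cat(sprintf(
    "Langmuir protein kinetics: k_a = %.3g mL/(ug h), k_d = %.3g 1/h,\n  c_s_max = %.4g ug/mm^2, D = %.3g mm^2/h\n",
    x$k_a, x$k_d, x$c_s_max, x$D))
  invisible(x)
}

assert_protein_params <- function(params) {
  if (!inherits(params, "protein_params"))
    stop("`params` must be created by protein_params()", call. = FALSE)
  params
}

#' Solve the 1D diffusion--Langmuir protein exchange model
#'
#' Integrates the fluid-phase diffusion equation \eqn{\partial c/\partial t =
#' D \partial^2 c/\partial z^2} over the fluid column (z = 0 at the disk
#' face, z = h at the free surface, zero flux at the top) coupled to the
#' Langmuir surface balance at z = 0, where the diffusive flux into the
#' surface equals \eqn{dc_s/dt}. The discretisation is a finite-volume
#' method of lines with a face-consistent (second-order Robin) closure of
#' the boundary, stepped by the L-stable TR-BDF2 scheme with Newton
#' iteration on the nonlinear boundary term; the discrete exchange flux is
#' shared between the fluid ledger and the surface ledger, so total mass is
#' conserved to solver tolerance.
#'
#' Sampling events can be modelled via `mix_times`: drawing an aliquot stirs
#' the column, so at each listed instant the fluid profile is replaced by
#' its depth average (mass-preserving re-homogenisation). The default is no
#' mixing, i.e. purely diffusion-limited transport between samplings.
#'
#' Units: fluid concentrations are ug/mL, surface concentration ug/mm^2,
#' lengths mm, times h. The Langmuir rate uses c in ug/mL (the conventional
#' unit of `k_a`); the diffusive flux converts via 1 ug/mm^3 = 1000 ug/mL.
#'
#' @param params A [protein_params()].
#' @param geometry A [well_geometry()].
#' @param initial_fluid Initial fluid concentration, ug/mL: either a single
#'   value (uniform column, the post-mixing condition) or a vector of length
#'   `nz` giving a depth profile at the cell centres.
#' @param initial_surface Initial surface concentration, ug/mm^2. Must not
#'   exceed `params$c_s_max`.
#' @param t_end Final time, h.
#' @param output_times Times (h) at which to record the state; defaults to
#'   201 equally spaced points over `[0, t_end]`. Must lie in `[0, t_end]`.
#' @param mix_times Optional times (h) at which the fluid column is
#'   re-homogenised to its depth average (sampling-induced mixing).
#' @param nz Number of spatial cells over the column height (default 200).
#' @param dt Nominal time step, h (default 0.01); sub-steps are shortened so
#'   output and mixing times are hit exactly.
#' @return An object of class `protein_trajectory`: list with `times` (h),
#'   `z_grid` (cell-centre depths, mm), `c` (nz x length(times) matrix of
#'   fluid concentration, ug/mL), `c_surface` (ug/mm^2), `mean_fluid`
#'   (depth-averaged fluid concentration, ug/mL), `mass_total` (ug, fluid +
#'   surface), plus the `params` and `geometry` used.
#' @examples
#' p <- protein_params(k_a = 6.2e-4, k_d = 0.2, c_s_max = 31.5)
#' tr <- solve_protein_kinetics(p, initial_fluid = 9500, initial_surface = 0,
#'                              t_end = 72)
#' tail(tr$mean_fluid, 1) # fluid depletion approaching equilibrium
#' @export
solve_protein_kinetics <- function(params, geometry = well_geometry(),
                                   initial_fluid = 0, initial_surface = 0,
                                   t_end, output_times = NULL,
                                   mix_times = NULL,
                                   nz = 200, dt = 0.01) {
  assert_protein_params(params)
  assert_geometry(geometry)
  stopifnot(is.numeric(t_end), length(t_end) == 1, t_end > 0,
            is.numeric(initial_surface), length(initial_surface) == 1,
            initial_surface >= 0,
            nz >= 2, dt > 0)
  if (initial_surface > params$c_s_max + 1e-12)
    stop("initial_surface exceeds c_s_max", call. = FALSE)
  if (is.null(output_times))
    output_times <- seq(0, t_end, length.out = 201)
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0) || any(output_times > t_end + 1e-9))
    stop("output_times must lie within [0, t_end]", call. = FALSE)
  mix_times <- sort(unique(as.numeric(mix_times)))
  if (length(mix_times) > 0 &&
      (any(mix_times <= 0) || any(mix_times > t_end + 1e-9)))
    stop("mix_times must lie within (0, t_end]", call. = FALSE)

  if (length(initial_fluid) == 1) {
    c0 <- rep(as.numeric(initial_fluid), nz)
  } else if (length(initial_fluid) == nz) {
    c0 <- as.numeric(initial_fluid)
  } else {
    stop("initial_fluid must be a scalar or a vector of length nz",
         call. = FALSE)
  }
  if (any(c0 < 0)) stop("initial_fluid must be non-negative", call. = FALSE)

  sol <- solve_protein_pde_cpp(
    ka = params$k_a, kd = params$k_d, csm = params$c_s_max, D = params$D,
    height = geometry$height_mm, c_init = c0, cs_init = initial_surface,
    output_times = output_times, mix_times = mix_times, dt = dt,
    newton_tol = 1e-8, newton_maxit = 25)

  cmat <- sol$c
  cs <- as.numeric(sol$c_surface)
  dz <- geometry$height_mm / nz
  z_grid <- (seq_len(nz) - 0.5) * dz

  # negative concentrations beyond tolerance are a solver failure, not data
  scale <- max(abs(c0), cs * 1000 / geometry$height_mm, 1)
  if (min(cmat) < -1e-6 * scale || min(cs) < -1e-9 * max(params$c_s_max, 1))
    stop(sprintf(
      "negative concentration beyond tolerance (min fluid %.3g ug/mL, min surface %.3g ug/mm^2); refine dt/nz",
      min(cmat), min(cs)), call. = FALSE)

  mean_fluid <- colMeans(cmat)
  # mass ledger: fluid (ug/mL -> ug/mm^3 via 1e-3) + surface, both in ug
  mass_fluid <- mean_fluid * 1e-3 * geometry$height_mm * geometry$area_mm2
  mass_surface <- cs * geometry$area_mm2

  structure(
    list(times = output_times, z_grid = z_grid, c = cmat, c_surface = cs,
         mean_fluid = mean_fluid, mass_total = mass_fluid + mass_surface,
         mass_fluid = mass_fluid, mass_surface = mass_surface,
         params = params, geometry = geometry),
    class = "protein_trajectory")
}

#' @export
print.protein_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "Protein trajectory: %d output times over [%.3g, %.3g] h, %d depth cells\n",
    n, x$times[1], x$times[n], nrow(x$c)))
  cat(sprintf("  mean fluid: %.4g -> %.4g ug/mL; surface: %.4g -> %.4g ug/mm^2\n",
              x$mean_fluid[1], x$mean_fluid[n], x$c_surface[1], x$c_surface[n]))
  cat(sprintf("  mass ledger drift: %.3g%%\n",
              100 * max(abs(x$mass_total - x$mass_total[1])) /
                max(x$mass_total[1], 1e-12)))
  invisible(x)
}

#' @export
as.data.frame.protein_trajectory <- function(x, ...) {
  data.frame(time_h = x$times,
             mean_fluid_ug_per_mL = x$mean_fluid,
             surface_ug_per_mm2 = x$c_surface,
             mass_ug = x$mass_total)
}

#' Maximum surface capacity from the steady-state balance
#'
#' At steady state the Langmuir attachment and detachment terms balance:
#' \eqn{k_a c^f (c_s^m - c_s^f) = k_d c_s^f}, which solved for the capacity
#' gives \eqn{c_s^m = c_s^f (1 + k_d / (k_a c^f))}. This is how the capacity
#' is derived from the terminal values of an adsorption experiment, rather
#' than fitted as a third free parameter.
#'
#' @param k_a Adsorption coefficient, mL ug^-1 h^-1. Must be positive.
#' @param k_d Desorption coefficient, h^-1.
#' @param c_final Final steady-state fluid concentration c^f, ug/mL. Positive.
#' @param c_s_final Final steady-state surface concentration c_s^f, ug/mm^2.
#' @return The capacity c_s^m in ug/mm^2 (equals `c_s_final` when `k_d = 0`).
#' @examples
#' steady_state_capacity(1e-3, 0.1, c_final = 1000, c_s_final = 10) # 11
#' @export
steady_state_capacity <- function(k_a, k_d, c_final, c_s_final) {
  stopifnot(is.numeric(k_a), is.numeric(k_d), is.numeric(c_final),
            is.numeric(c_s_final), k_d >= 0, c_s_final >= 0)
  if (any(k_a * c_final <= 0))
    stop("capacity undefined: k_a * c_final must be positive", call. = FALSE)
  c_s_final * (1 + k_d / (k_a * c_final))
}

#' Closed-form equilibrium of the diffusion--Langmuir system
#'
#' At equilibrium the fluid column is uniform and the net Langmuir flux is
#' zero, so combining \eqn{k_a c (c_s^m - c_s) = k_d c_s} with conservation
#' of total protein mass gives a quadratic in \eqn{c_s} whose admissible
#' root (within `[0, c_s_max]` and with non-negative fluid concentration)
#' is the long-time limit of [solve_protein_kinetics()]. Used as an
#' independent oracle for the PDE's steady state.
#'
#' @param params A [protein_params()].
#' @param geometry A [well_geometry()].
#' @param total_mass Total protein mass in the system, ug.
#' @return A list with `c_eq` (ug/mL) and `c_s_eq` (ug/mm^2).
#' @export
equilibrium_state <- function(params, geometry = well_geometry(),
                              total_mass) {
  assert_protein_params(params)
  assert_geometry(geometry)
  stopifnot(is.numeric(total_mass), length(total_mass) == 1,
            total_mass >= 0)
  if (total_mass == 0) return(list(c_eq = 0, c_s_eq = 0))
  A <- geometry$area_mm2
  V <- geometry$fluid_volume_uL / 1000 # mL
  ka <- params$k_a; kd <- params$k_d; csm <- params$c_s_max

  if (ka == 0 && kd == 0)
    stop("equilibrium undefined: k_a = k_d = 0 admits any partition",
         call. = FALSE)
  if (ka == 0) return(list(c_eq = total_mass / V, c_s_eq = 0))
  if (kd == 0) {
    if (total_mass <= A * csm)
      return(list(c_eq = 0, c_s_eq = total_mass / A))
    return(list(c_eq = (total_mass - A * csm) / V, c_s_eq = csm))
  }

  # (ka A / V) cs^2 - (ka (M + A csm)/V + kd) cs + ka M csm / V = 0
  a2 <- ka * A / V
  a1 <- -(ka * (total_mass + A * csm) / V + kd)
  a0 <- ka * total_mass * csm / V
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0) stop("no admissible equilibrium root (negative discriminant)",
                     call. = FALSE)
  roots <- (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  upper <- min(csm, total_mass / A)
  ok <- roots >= -1e-12 & roots <= upper * (1 + 1e-12)
  if (!any(ok))
    stop(sprintf("no admissible equilibrium root in [0, %.4g] (roots %.4g, %.4g)",
                 upper, roots[1], roots[2]), call. = FALSE)
  cs_eq <- min(roots[ok])
  cs_eq <- min(max(cs_eq, 0), upper)
  list(c_eq = (total_mass - A * cs_eq) / V, c_s_eq = cs_eq)
}

#' Time-averaged surface concentration over a window
#'
#' Trapezoidal time average of \eqn{c_s(t)} between `window[1]` and
#' `window[2]`, at the trajectory's native time resolution (window endpoints
#' are interpolated linearly if they fall between output times). This is the
#' quantity used to summarise the protein coverage a cell population
#' experiences during a culture window.
#'
#' @param traj A `protein_trajectory` from [solve_protein_kinetics()].
#' @param window Numeric length-2, `c(t_start, t_end)` in h, within the
#'   trajectory's time range and with `t_start < t_end`.
#' @return Average surface concentration, ug/mm^2.
#' @export
average_surface_concentration <- function(traj, window) {
  if (!inherits(traj, "protein_trajectory"))
    stop("`traj` must be a protein_trajectory", call. = FALSE)
  stopifnot(is.numeric(window), length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  tr <- range(traj$times)
  if (!(t0 < t1)) stop("empty averaging window", call. = FALSE)
  if (t0 < tr[1] - 1e-9 || t1 > tr[2] + 1e-9)
    stop("window outside trajectory time range", call. = FALSE)
  tt <- traj$times; cs <- traj$c_surface
  keep <- tt > t0 & tt < t1
  t_in <- c(t0, tt[keep], t1)
  cs_in <- c(stats::approx(tt, cs, xout = t0)$y, cs[keep],
             stats::approx(tt, cs, xout = t1)$y)
  sum(diff(t_in) * (utils::head(cs_in, -1) + utils::tail(cs_in, -1)) / 2) /
    (t1 - t0)
}
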