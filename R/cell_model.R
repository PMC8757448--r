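#' Parameters of the two-compartment cell attachment model
#'
#' Cells seeded over a substrate are either "free" (settled near the surface
#' but unattached) or attached. Free cells attach at a rate proportional to
#' the free-cell density and the remaining surface capacity,
#' \deqn{dc_a/dt = k (\gamma c_0 - c_a)(c_m - c_a),}
#' with no detachment and no proliferation over the culture window. Only a
#' fraction gamma of the seeded cells arrives viable and adhesion-competent.
#'
#' @param gamma Survival fraction in (0, 1]; estimated values above 1 are
#'   accepted with a warning (measurement noise can push the late-time
#'   plateau above the nominal seeding density).
#' @param c_0 Seeded density, cells/cm^2.
#' @param c_m Maximum attached density, cells/cm^2; default from a 25 um
#'   spread-cell footprint via [cell_capacity()].
#' @param k Optional constant adhesion coefficient, cm^2 cells^-1 h^-1.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(gamma, c_0, c_m = cell_capacity(25), k = NULL) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0,
            is.numeric(c_0), length(c_0) == 1, c_0 > 0,
            is.numeric(c_m), length(c_m) == 1, c_m > 0)
  if (gamma > 1)
    warning("survival fraction gamma > 1; keeping the estimated value")
  if (!is.null(k)) stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  structure(list(gamma = gamma, c_0 = c_0, c_m = c_m, k = k),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "Cell attachment: gamma = %.3g, c_0 = %.4g cells/cm^2, c_m = %.4g cells/cm^2%s\n",
    x$gamma, x$c_0, x$c_m,
    if (is.null(x$k)) "" else sprintf(", k = %.4g cm^2/(cells h)", x$k)))
  invisible(x)
}

assert_cell_params <- function(params) {
  if (!inherits(params, "cell_params"))
    stop("`params` must be created by cell_params()", call. = FALSE)
  params
}

#' Maximum attached-cell density from the spread-cell footprint
#'
#' A spread cell is taken to occupy a square of the given side length, so
#' the surface saturates at one cell per square: `1 / side^2` with the side
#' in cm. A 25 um side gives 1.6e5 cells/cm^2.
#'
#' @param cell_side_um Side length of the spread-cell footprint, um.
#' @return Capacity in cells/cm^2.
#' @examples
#' cell_capacity(25) # 160000
#' @export
cell_capacity <- function(cell_side_um) {
  stopifnot(is.numeric(cell_side_um), all(cell_side_um > 0))
  1 / (cell_side_um / 1e4)^2
}

#' Closed-form attached-cell density
#'
#' The attachment ODE with both compartments,
#' \eqn{dc_a/dK = (\gamma c_0 - c_a)(c_m - c_a)} in the cumulative adhesion
#' exposure \eqn{K(t) = \int_0^t k(t') dt'}, integrates to the logistic-type
#' form
#' \deqn{c_a(K) = \gamma c_0 c_m \frac{e^{(c_m - \gamma c_0)K} - 1}{c_m e^{(c_m - \gamma c_0)K} - \gamma c_0},}
#' which starts at 0, increases monotonically, and saturates at
#' \eqn{\gamma c_0} (all viable cells attached) when \eqn{\gamma c_0 < c_m}.
#' The degenerate case \eqn{\gamma c_0 = c_m} is handled by its limit
#' \eqn{c_a = M - M/(1 + M K)}, and large exponents are evaluated in a
#' cancellation-free rearrangement.
#'
#' @param K Cumulative adhesion exposure(s), cm^2 cells^-1 (for a constant
#'   coefficient, `K = k * t`). Non-negative.
#' @param params A [cell_params()]; requires `gamma * c_0 <= c_m`.
#' @return Attached density c_a, cells/cm^2 (vectorised over `K`).
#' @export
attached_cells_analytic <- function(K, params) {
  assert_cell_params(params)
  K <- as.numeric(K)
  if (any(K < 0)) stop("adhesion exposure K must be non-negative",
                       call. = FALSE)
  M <- params$gamma * params$c_0
  cm <- params$c_m
  if (M > cm * (1 + 1e-12))
    stop("gamma * c_0 exceeds c_m: more viable cells than surface capacity",
         call. = FALSE)
  d <- cm - M
  if (d <= cm * 1e-12) return(M - M / (1 + M * K))
  # c_a = M cm (e^{dK} - 1) / (cm e^{dK} - M) = M cm (1 - e^{-dK}) / (cm - M e^{-dK})
  e <- exp(-d * K)
  M * cm * (1 - e) / (cm - M * e)
}

#' Numerical integration of the free/attached cell balance
#'
#' Direct adaptive-step integration of the two-compartment system
#' \eqn{dc^{OB}/dt = -k(t) c^{OB} (c_m - c_a)},
#' \eqn{dc_a/dt = +k(t) c^{OB} (c_m - c_a)} with \eqn{c^{OB}(0) = \gamma c_0},
#' \eqn{c_a(0) = 0}. Serves as the independent oracle for
#' [attached_cells_analytic()]; conservation \eqn{c^{OB} + c_a = \gamma c_0}
#' is checked to 1e-9 relative.
#'
#' @param params A [cell_params()].
#' @param k Adhesion coefficient: a constant (cm^2 cells^-1 h^-1) or a
#'   function of time `k(t)`.
#' @param t_grid Output times, h (must include or start from 0; 0 is
#'   prepended if absent).
#' @return An object of class `cell_trajectory`: list with `times`,
#'   `attached`, `free` (cells/cm^2).
#' @export
attached_cells_numeric <- function(params, k, t_grid) {
  assert_cell_params(params)
  kfun <- if (is.function(k)) k else {
    stopifnot(is.numeric(k), length(k) == 1, k >= 0)
    function(t) k
  }
  t_grid <- sort(unique(as.numeric(t_grid)))
  stopifnot(all(t_grid >= 0))
  prepend <- t_grid[1] > 0
  tt <- if (prepend) c(0, t_grid) else t_grid
  M <- params$gamma * params$c_0
  sol <- deSolve::ode(
    y = c(free = M, attached = 0), times = tt,
    func = function(t, y, p) {
      rate <- kfun(t) * y[["free"]] * (params$c_m - y[["attached"]])
      list(c(-rate, rate))
    }, parms = NULL, method = "lsoda", rtol = 1e-11, atol = 1e-8)
  if (attr(sol, "istate")[1] < 0)
    stop("cell ODE solver failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  free <- sol[, "free"]; attached <- sol[, "attached"]
  drift <- max(abs(free + attached - M)) / M
  if (drift > 1e-9)
    stop(sprintf("cell mass conservation violated (relative drift %.3g)",
                 drift), call. = FALSE)
  if (prepend) { free <- free[-1]; attached <- attached[-1] }
  structure(list(times = t_grid, attached = unname(attached),
                 free = unname(free), params = params),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "Cell trajectory: %d times over [%.3g, %.3g] h; attached %.4g -> %.4g cells/cm^2\n",
    n, x$times[1], x$times[n], x$attached[1], x$attached[n]))
  invisible(x)
}

#' @export
as.data.frame.cell_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, attached_cells_per_cm2 = x$attached,
             free_cells_per_cm2 = x$free)
}

#' Estimate the survival fraction from late-time counts
#'
#' After the attachment transient has saturated, the attached density
#' plateaus at \eqn{\gamma c_0}; gamma is therefore estimated as the mean of
#' the last two counts divided by the seeded density. Values above 1 are
#' kept with a warning.
#'
#' @param counts A [measurement_series()] of attached-cell counts with at
#'   least two points (the last two are assumed to be at the saturated
#'   plateau, e.g. 4 and 6 h of culture).
#' @param c_0 Seeded density, cells/cm^2.
#' @return Estimated gamma (scalar).
#' @examples
#' s <- measurement_series(c(0.5, 1, 2, 4, 6), c(500, 900, 1200, 1400, 1540),
#'                         label = "cell_culture")
#' estimate_gamma(s, 3500) # 0.42
#' @export
estimate_gamma <- function(counts, c_0) {
  stopifnot(inherits(counts, "measurement_series"),
            is.numeric(c_0), length(c_0) == 1, c_0 > 0)
  if (length(counts$values) < 2)
    stop("need at least two counts to estimate gamma", call. = FALSE)
  g <- mean(utils::tail(counts$values, 2)) / c_0
  if (g > 1)
    warning(sprintf("estimated gamma = %.3g > 1; keeping it", g))
  g
}

#' Fit a constant adhesion coefficient to attached-cell counts
#'
#' One-dimensional minimisation of the relative RMS error
#' ([model_error()], with counts in place of concentrations) between
#' [attached_cells_analytic()] at `K = k t` and the observed counts: a
#' log-spaced scan over `k_range` locates the basin, golden-section
#' refinement ([stats::optimize()] on log10 k) pins the minimiser, and the
#' reported uncertainty interval is the connected set around the optimum
#' where the error stays below 1.5x its minimum.
#'
#' If the counts sit at the saturated plateau at every time point the error
#' decreases monotonically in k with no interior minimum; the scan's upper
#' bound is returned with a warning, since saturated data cannot identify k.
#'
#' @param counts A [measurement_series()] of attached-cell counts.
#' @param params A [cell_params()] (gamma already estimated; any `k` in it
#'   is ignored).
#' @param k_range Scan bounds for k, cm^2 cells^-1 h^-1.
#' @param n_scan Number of log-spaced scan points.
#' @return List with `k`, `error` (percent), `interval` (`c(k_lo, k_hi)`
#'   where the error crosses 1.5x the minimum; scan bounds where it never
#'   does), and `saturated` (logical).
#' @export
fit_k_constant <- function(counts, params, k_range = c(1e-8, 1e-2),
                           n_scan = 80) {
  stopifnot(inherits(counts, "measurement_series"))
  assert_cell_params(params)
  if (all(counts$values == 0))
    stop("all-zero counts: error landscape is flat, k unidentifiable",
         call. = FALSE)
  err_of <- function(k)
    model_error(attached_cells_analytic(k * counts$times, params), counts)

  lg <- seq(log10(k_range[1]), log10(k_range[2]), length.out = n_scan)
  scan <- vapply(10^lg, err_of, numeric(1))
  i <- which.min(scan)

  # a minimum plateau reaching the scan's upper bound means the counts sit at
  # the saturated limit: any sufficiently large k fits equally well
  if (scan[n_scan] <= scan[i] + 1e-9 * (1 + scan[i])) {
    warning("error does not rise towards the scan's upper bound: counts look saturated, k unidentifiable")
    k_hat <- 10^lg[n_scan]
    e_min <- scan[n_scan]
    lo <- stats::uniroot(function(l) err_of(10^l) - max(1.5 * e_min, 1e-12),
                         c(lg[1], lg[n_scan]), tol = 1e-10)$root
    return(list(k = k_hat, error = e_min,
                interval = c(10^lo, 10^lg[n_scan]), saturated = TRUE))
  }

  bracket <- c(lg[max(1, i - 1)], lg[min(n_scan, i + 1)])
  opt <- stats::optimize(function(l) err_of(10^l), bracket, tol = 1e-10)
  k_hat <- 10^opt$minimum
  e_min <- opt$objective
  thr <- 1.5 * e_min

  bound <- function(side) {
    f <- function(l) err_of(10^l) - thr
    if (side == "lo") {
      if (f(lg[1]) <= 0) return(10^lg[1])
      10^stats::uniroot(f, c(lg[1], opt$minimum), tol = 1e-10)$root
    } else {
      if (f(lg[n_scan]) <= 0) return(10^lg[n_scan])
      10^stats::uniroot(f, c(opt$minimum, lg[n_scan]), tol = 1e-10)$root
    }
  }
  list(k = k_hat, error = e_min, interval = c(bound("lo"), bound("hi")),
       saturated = FALSE)
}
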