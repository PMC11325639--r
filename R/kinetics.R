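#' One-compartment body-residue kinetics, closed form
#'
#' Internal concentration of an earthworm exposed to an exponentially
#' decaying medium concentration `C(t) = c0 * exp(-k0 * t)`:
#' \deqn{C_w(t) = \frac{k_{in} c_0}{k_{out} - k_0}\left(e^{-k_0 t} - e^{-k_{out} t}\right),\qquad C_w(0)=0.}
#' When `k0 = 0` this reduces to the constant-exposure OECD-317 uptake curve
#' `kin*c0/kout * (1 - exp(-kout*t))`; when `kout == k0` (within
#' `1e-9 * max(kout, 1)`, to avoid catastrophic cancellation) the limit form
#' `kin*c0*t*exp(-k0*t)` is used.
#'
#' @param kin Uptake rate constant, L/kg/d (porewater) or kg/kg/d (soil), > 0.
#' @param kout Elimination rate constant, 1/d, > 0.
#' @param c0 Initial exposure concentration (mg/L or mg/kg dw), >= 0.
#' @param k0 First-order exposure decay rate, 1/d, >= 0 (0 = constant).
#' @param times Days, >= 0.
#' @return A `kinetic_solution` tibble with columns `time` (d) and
#'   `c_earthworm` (mg/kg wet weight); attributes `method` and `params`.
#' @examples
#' body_residue_closed_form(kin = 2, kout = 0.5, c0 = 1, k0 = 0.1,
#'                          times = 0:14)
#' @export
body_residue_closed_form <- function(kin, kout, c0, k0 = 0, times) {
  check_kinetic_params(kin, kout, c0, k0, times)
  cw <- closed_form_cw(kin, kout, c0, k0, times)
  new_kinetic_solution(times, cw, "closed_form",
                       list(kin = kin, kout = kout, c0 = c0, k0 = k0))
}

closed_form_cw <- function(kin, kout, c0, k0, times) {
  if (abs(kout - k0) < 1e-9 * max(kout, 1)) {
    kin * c0 * times * exp(-k0 * times)
  } else {
    kin * c0 / (kout - k0) * (exp(-k0 * times) - exp(-kout * times))
  }
}

check_kinetic_params <- function(kin, kout, c0, k0, times) {
  if (kin <= 0) abort_validation("kin", "must be > 0")
  if (kout <= 0) abort_validation("kout", "must be > 0")
  if (c0 < 0) abort_validation("c0", "must be >= 0")
  if (k0 < 0) abort_validation("k0", "must be >= 0")
  if (any(times < 0)) abort_validation("times", "must be >= 0")
  invisible(TRUE)
}

new_kinetic_solution <- function(times, cw, method, params) {
  out <- tibble::tibble(time = times, c_earthworm = pmax(cw, 0))
  structure(out, method = method, params = params,
            class = c("kinetic_solution", class(out)))
}

#' One-compartment body-residue kinetics, numerical integration
#'
#' Integrates `dC_w/dt = kin * C(t) - kout * C_w`, `C_w(0) = 0`, for an
#' arbitrary piecewise-continuous exposure time course `C(t) >= 0` (pulses,
#' repeated applications, interpolated measurements). Uses an adaptive
#' stiff-capable solver (`deSolve::lsoda`, rtol `1e-8`, atol `1e-12`).
#'
#' @inheritParams body_residue_closed_form
#' @param exposure A function of time returning the exposure concentration.
#' @param rtol,atol Solver tolerances.
#' @return A `kinetic_solution` tibble (see [body_residue_closed_form()]).
#' @examples
#' pulse <- function(t) ifelse(t < 2, 1, 0)
#' body_residue_ode(kin = 2, kout = 0.5, exposure = pulse, times = 0:10)
#' @export
body_residue_ode <- function(kin, kout, exposure, times,
                             rtol = 1e-8, atol = 1e-12) {
  check_kinetic_params(kin, kout, c0 = 0, k0 = 0, times = times)
  stopifnot(is.function(exposure))
  grid <- sort(unique(c(0, times)))
  deriv <- function(t, state, parms) {
    list(kin * exposure(t) - kout * state[[1]])
  }
  sol <- deSolve::lsoda(y = c(cw = 0), times = grid, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  diagn <- attributes(sol)$istate
  if (!is.null(diagn) && diagn[1] < 0)
    abort(sprintf("ODE integration failed (istate = %d)", diagn[1]),
          class = "wormkin_integration_error")
  cw <- sol[match(times, grid), "cw"]
  new_kinetic_solution(times, cw, "ode",
                       list(kin = kin, kout = kout))
}

#' Two-phase (uptake then clean-medium elimination) body residue
#'
#' OECD-317 studies transfer the worms to clean soil at the end of the
#' uptake phase; from the transfer time `t_uptake` onwards the residue
#' decays as `C_w(t_uptake) * exp(-kout * (t - t_uptake))`.
#'
#' @inheritParams body_residue_closed_form
#' @param t_uptake Transfer time, d.
#' @return A `kinetic_solution` tibble.
#' @export
body_residue_two_phase <- function(kin, kout, c0, k0 = 0, t_uptake, times) {
  check_kinetic_params(kin, kout, c0, k0, times)
  stopifnot(t_uptake > 0)
  c_transfer <- closed_form_cw(kin, kout, c0, k0, t_uptake)
  cw <- ifelse(times <= t_uptake,
               closed_form_cw(kin, kout, c0, k0, times),
               c_transfer * exp(-kout * (times - t_uptake)))
  new_kinetic_solution(times, cw, "closed_form",
                       list(kin = kin, kout = kout, c0 = c0, k0 = k0,
                            t_uptake = t_uptake))
}

#' Steady-state bioconcentration factor
#'
#' The long-time plateau of the constant-exposure uptake curve:
#' `bcf = kin / kout`, in L/kg (porewater route) or kg/kg (soil route).
#'
#' @inheritParams body_residue_closed_form
#' @return Numeric BCF.
#' @examples
#' steady_state_bcf(2, 0.5) # 4
#' @export
steady_state_bcf <- function(kin, kout) {
  if (any(kout <= 0)) abort_validation("kout", "must be > 0")
  kin / kout
}

#' Fit a first-order decay to an exposure time series
#'
#' Nonlinear least squares of `C(t) = c0 * exp(-k0 * t)` with `k0 >= 0`,
#' started from a log-linear fit. A series that does not decline yields
#' `k0 = 0` (constant exposure).
#'
#' @param series Data frame with columns `time` (d) and `value`
#'   (concentration, > 0), at least two points.
#' @return A `decay_fit` object: list with `c0`, `k0`, standard errors and
#'   the underlying `nls` fit; `tidy()` and `glance()` methods available.
#' @examples
#' s <- data.frame(time = 0:7, value = 2 * exp(-0.3 * (0:7)))
#' fit_exposure_decay(s)
#' @export
fit_exposure_decay <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("time", "value") %in% names(series)))
    abort_validation("series", "needs columns `time` and `value`")
  if (nrow(series) < 2) abort_validation("series", "needs >= 2 points")
  if (all(series$value == 0)) abort_validation("value", "all-zero series")
  if (any(series$value <= 0)) abort_validation("value", "must be > 0")
  ll <- lm(log(value) ~ time, data = series)
  k0_start <- max(-coef(ll)[[2]], 0)
  if (k0_start < 1e-12) k0_start <- 0  # non-declining series
  start <- list(c0 = exp(coef(ll)[[1]]), k0 = k0_start)
  fit <- minpack.lm::nlsLM(value ~ c0 * exp(-k0 * time), data = series,
                           start = start, lower = c(c0 = 0, k0 = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 2), names(est)))
  structure(list(c0 = est[["c0"]], k0 = est[["k0"]],
                 se = se, fit = fit, data = tibble::as_tibble(series)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> c0 = %.4g, k0 = %.4g 1/d (n = %d)\n",
              x$c0, x$k0, nrow(x$data)))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("c0", "k0"),
                 estimate = c(x$c0, x$k0),
                 std_error = unname(x$se[c("c0", "k0")]))
}

#' @export
glance.decay_fit <- function(x, ...) {
  r <- residuals(x$fit)
  tibble::tibble(n = nrow(x$data), rmse = sqrt(mean(r^2)),
                 half_life = if (x$k0 > 0) log(2) / x$k0 else Inf)
}

#' Time of the body-residue peak under decaying exposure
#'
#' With `k0 > 0` the residue rises to a single maximum at
#' `t = log(kout / k0) / (kout - k0)` (or `1 / k0` when `kout == k0`).
#'
#' @inheritParams body_residue_closed_form
#' @return Peak time, d (`Inf` for constant exposure).
#' @export
peak_time <- function(kin, kout, k0) {
  if (k0 <= 0) return(Inf)
  if (abs(kout - k0) < 1e-9 * max(kout, 1)) return(1 / k0)
  log(kout / k0) / (kout - k0)
}
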