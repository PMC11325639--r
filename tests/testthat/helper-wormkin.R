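# shared fixtures, built in code

with_overrides <- function(base, ...) {
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

demo_chemical <- function(...) {
  with_overrides(
    tibble::tibble(name = "dieldrin", log_kow = 5.2, pka = NA_real_,
                   charge_type = "neutral", tpsa = 12.5,
                   kd_measured = NA_real_), ...)
}

demo_soil <- function(...) {
  with_overrides(
    tibble::tibble(name = "loam", om = 8.2, clay = 20, cec = 15, ph = 6.1),
    ...)
}

demo_worm <- function(...) {
  with_overrides(
    tibble::tibble(species = "Eisenia fetida", lipid = 2.64, ssa = 1.45),
    ...)
}

demo_scenario <- function(route = "soil", c0 = 1, k0 = 0.02,
                          times = list(c(1, 2, 4, 7, 14, 21))) {
  tibble::tibble(route = route, c0 = c0, k0 = k0, times = times)
}

reference_calibration <- function() {
  readr::read_csv(
    system.file("extdata", "reference_calibration_synthetic.csv",
                package = "wormkin"),
    show_col_types = FALSE)
}

# independent numerical oracle for the exponential-exposure kinetics:
# integrates dCw/dt = kin*c0*exp(-k0 t) - kout*Cw directly with deSolve,
# bypassing the package's closed form
ode_oracle <- function(kin, kout, c0, k0, times) {
  grid <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(
    c(cw = 0), grid,
    function(t, y, p) list(kin * c0 * exp(-k0 * t) - kout * y[[1]]),
    parms = NULL, rtol = 1e-10, atol = 1e-14)
  unname(sol[match(times, grid), "cw"])
}

# mixed relative/absolute difference: body residues below `floor`
# (mg/kg ww; default 0.1 ug/kg, far below analytical detection) are compared
# against the floor, since the ODE solver cannot resolve relative accuracy
# below its absolute tolerance
rel_diff <- function(a, b, floor = 1e-4) abs(a - b) / pmax(abs(a), abs(b), floor)
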