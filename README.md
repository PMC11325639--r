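# wormkin

One-compartment toxicokinetic prediction of pesticide accumulation in
earthworms, for ecotoxicologists and risk assessors who need time-resolved
body residues across chemicals, soils and earthworm species without
recalibrating rate constants for every combination.

## What it computes

Internal concentration under first-order uptake/elimination with
exponentially decaying exposure `C(t) = C0 exp(-k0 t)`:

    Cw(t) = kin * C0 / (kout - k0) * (exp(-k0 t) - exp(-kout t)),   Cw(0) = 0

with the steady-state bioconcentration factor `BCF = kin / kout`. The rate
constants come from multiple linear regressions on log10 scale:

* uptake `kin` (porewater or bulk-soil route) from log K_om, soil organic
  matter (OM, %) and SSAlipid (earthworm specific surface area × lipid
  content);
* elimination `kout` from TPSA and OM (porewater route; earthworm traits
  have negligible effect there), plus SSAlipid for the soil route;
* the sorption coefficient log K_d from the pH-adjusted log D_ow and OM,
  used to convert bulk-soil to porewater concentrations (`C_pw = C_soil /
  Kd`) when no measured K_d is available.

Around that core the package provides applicability-domain checking,
OECD-317-style kinetic fitting (`fit_exposure_decay()`,
`fit_kinetics_to_timeseries()`), the full QSAR model-building workflow
(collinearity screening, p-value stepwise selection with VIF < 2,
leave-one-out Q2 and Lin's CCC), Nash-Sutcliffe / factor-of-N evaluation,
seeded synthetic-data generators, ggplot2 `autoplot()` methods and a thin
CLI (`inst/cli/wormkin.R`).

**The packaged rate models are a synthetic reference calibration** —
authored coefficients with computed validation statistics, clearly labelled
as such (`inst/extdata/reference_models_synthetic.json`). They reproduce
the documented structure of OECD-317-derived regressions (descriptor sets,
signs, applicability domains, realistic rate ranges) but are not
field-validated. See `vignettes/wormkin-methods.Rmd`, and
`inst/extdata/transcribed/README.md` for how to plug in a transcribed
published calibration.

## Worked example

Dieldrin (log Kow 5.2, TPSA 12.5 Å²) in a loam (OM 8.2 %, pH 6.1) with
*Eisenia fetida*, soil dosed at 1 mg/kg dw and degrading at k0 = 0.02 1/d,
predicted on the porewater route:

```r
library(wormkin)

chem <- data.frame(name = "dieldrin", log_kow = 5.2, pka = NA,
                   charge_type = "neutral", tpsa = 12.5, kd_measured = NA)
soil <- data.frame(name = "loam", om = 8.2, clay = 20, cec = 15, ph = 6.1)
worm <- data.frame(species = "Eisenia fetida", lipid = 2.64, ssa = 1.45)
scen <- data.frame(route = "soil", c0 = 1, k0 = 0.02,
                   times = "1;2;4;7;14;21;28")

pred <- predict_residues(chem, soil, worm, scen, route = "porewater")
pred[, c("time", "log_kom", "kin", "kout", "bcf", "c_earthworm")]
#>   time log_kom   kin    kout  bcf c_earthworm
#> 1    1   3.591 106.8 0.05384 1984      0.3223
#> 2    2   3.591 106.8 0.05384 1984      0.6214
#> 3    4   3.591 106.8 0.05384 1984      1.1550
#> 4    7   3.591 106.8 0.05384 1984      1.8121
#> 5   14   3.591 106.8 0.05384 1984      2.8185
#> 6   21   3.591 106.8 0.05384 1984      3.3031
#> 7   28   3.591 106.8 0.05384 1984      3.4566
```

Reading the output: the predicted K_d (no measurement supplied) gives
log K_om = 3.59; the porewater-route uptake constant is 107 L/kg/d and
elimination 0.054 1/d, hence a steady-state BCF of ~1984 L porewater per kg
worm; the body residue (mg/kg wet weight) climbs toward — but, because the
exposure itself decays, never reaches — the constant-exposure plateau; it
peaks near day 29 (`peak_time(kin, kout, k0)`) and declines afterwards. `autoplot()` on a
`body_residue_closed_form()` result plots the time course.

Fitting rate constants from an observed uptake series instead:

```r
d <- sim_uptake_series(kin = 10, kout = 0.4, c0 = 0.5, k0 = 0.05,
                       days = c(1, 2, 4, 7, 14, 21), cv = 0.1, seed = 42)
fit <- fit_kinetics_to_timeseries(data.frame(time = d$time,
                                             value = d$body_residue),
                                  c0 = 0.5, k0 = 0.05)
tidy(fit)
#>   term  estimate std_error
#> 1 kin     10.7      1.42
#> 2 kout     0.384    0.0633
```

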