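---
title: "wormkin: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormkin: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormkin)
```

## The model

`wormkin` predicts internal concentrations of pesticides in earthworms with
a one-compartment first-order toxicokinetic model driven by
regression-predicted rate constants. The chain is:

1. **Hydrophobicity at soil pH.** For monovalent ionizable compounds the
   octanol–water partition coefficient is corrected to the neutral-fraction
   value (Henderson–Hasselbalch): acids
   $\log D_{ow} = \log K_{ow} - \log_{10}(1 + 10^{pH - pK_a})$, bases with
   the exponent reversed. Neutral compounds keep $\log D_{ow} = \log K_{ow}$.
   This is the only convention consistent with a "pH-adjusted
   octanol–water partition coefficient" restricted to monovalent species;
   zwitterions and multivalent ions are out of scope and rejected at
   validation.
2. **Soil–porewater partitioning.** When a measured sorption coefficient
   $K_d$ (L/kg) is available it is used (`kd_policy = "measured_first"`);
   otherwise $\log K_d$ is predicted from $\log D_{ow}$ and soil organic
   matter (OM, % dry weight). Porewater concentration follows equilibrium
   partitioning, $C_{pw} = C_{soil} / K_d$, and the OM-normalized
   coefficient is $\log K_{om} = \log_{10}\!\big(K_d / (OM/100)\big)$. OM
   enters as a *fraction* only in this normalization; everywhere else OM,
   clay and lipid are percent values — a documented unit contract, not an
   auto-conversion (a `fractions_to_percent` ingest flag exists, off by
   default).
3. **Rate constants.** Four linear regressions on $\log_{10}$-transformed
   rate constants: uptake $k_{in}$ from $\log K_{om}$, OM and SSAlipid
   (earthworm specific surface area × lipid content) for both exposure
   routes; elimination $k_{out}$ from TPSA and OM for the porewater route
   (interspecies traits have negligible effect there) plus SSAlipid for the
   bulk-soil route. The $\log_{10}$ response scale is the only one on which
   residual errors of ~0.23–0.28 are plausible for rate constants spanning
   five orders of magnitude, and it guarantees positive back-transformed
   predictions.
4. **Kinetics.** With exposure decaying as $C(t) = C_0 e^{-k_0 t}$, the
   body residue is
   $$C_w(t) = \frac{k_{in} C_0}{k_{out} - k_0}\left(e^{-k_0 t} - e^{-k_{out} t}\right),
   \qquad C_w(0) = 0,$$
   reducing to the familiar OECD-317 uptake curve
   $k_{in} C_0 / k_{out}\,(1 - e^{-k_{out} t})$ at $k_0 = 0$. The
   steady-state bioconcentration factor is $BCF = k_{in}/k_{out}$.
   Arbitrary exposure time courses (pulses, repeated applications) go
   through the numerical route (`body_residue_ode()`), which is the
   designed hook for coupling to movement or degradation models.

Growth dilution, biotransformation and active excretion are deliberately
absent: the model targets adult earthworms and relatively persistent
compounds, and overestimates residues where those processes matter
(phenanthrene- and pyrene-like behavior).

## The packaged reference calibration is synthetic

The regression coefficients shipped in
`inst/extdata/reference_models_synthetic.json` are **not** transcribed from
any publication — no redistributable calibration dataset exists for this
package. They are an authored synthetic reference calibration that
reproduces the documented *structure* of OECD-317-derived earthworm
toxicokinetic regressions:

* descriptor sets per model (step 3 above) and coefficient signs
  (uptake increases with $\log K_{om}$ and SSAlipid, decreases with OM;
  elimination increases with TPSA — hydrophobic, low-TPSA compounds bind
  lipids and eliminate slowly — and with OM);
* applicability domains: $\log K_{om}$ 1.22–5.23, OM 0.97–39.9 %, TPSA
  0–50.9 Å², SSA 0.70–1.45 m²/kg, lipid 1.55–2.64 % ww, $\log D_{ow}$
  1.69–6.63 (closed intervals; boundary values are inside);
* realistic in-domain prediction ranges (porewater $k_{in}$ ~0.02–4392
  L/kg/d, soil $k_{in}$ ~0.02–2.30 kg/kg/d, $k_{out}$ ~0.02–4.4 1/d).

Effect sizes were *power-designed*: over the uniform applicability box at
the calibration size $n = 75$ and residual noise $\sigma = 0.25$ log10
units, every descriptor's partial $t$ statistic is at least ~5, so each
retained term is clearly significant at the 95 % level — the property a
real calibration of this kind exhibits. Subject to that, slopes were
balanced so in-domain predictions stay within the ranges above plus at most
one RMSE.

The validation statistics stored with each model ($R^2$, adjusted $R^2$,
RMSE, $Q^2_{LOO}$, LOO CCC) are **computed**, by refitting each descriptor
set on the packaged 75-row synthetic calibration table
(`reference_calibration_synthetic.csv`: five pesticides × five soils ×
three species, generated from the authored equations with $\sigma = 0.25$
noise on rates and 0.6 on $\log K_d$, seed 317, script in `data-raw/`).
The JSON file is md5-checksummed and verified on load. Consequences for
interpretation: predictions are structurally realistic but not
field-validated; users with access to the published supplementary
calibration can transcribe it (schemas in `inst/extdata/transcribed/`) and
either run the published-statistics checks in the test-suite or refit with
`build_regression_stepwise()` + `as_rate_model()` and pass the result to
every prediction function via `models =`.

## Model building and validation

`screen_descriptors()` computes Pearson correlations between all descriptor
pairs within a category (chemical / soil / earthworm) and links pairs with
$p < 0.01$; groups are the transitive closure of the links. Categories are
never merged — cross-category correlations (e.g. a Kd-derived descriptor
with OM) are expected and harmless because only one representative per
group may enter a model.

`build_regression_stepwise()` picks each group's representative as the
member giving the highest $R^2$ of the *resultant multiple regression*,
found by coordinate ascent starting from the best single-descriptor
members. Univariate screening was rejected: for weak-effect descriptors it
cannot separate the true member from a companion correlated at $r \ge 0.7$.
Selection then proceeds by p-value stepwise (entry 0.05, removal 0.10 — the
conventional pairing for "significant at the 95 % confidence level"; both
configurable), with a hard collinearity bar: a candidate whose entry would
push any variance inflation factor to 2 or above is inadmissible. VIF is
computed from the predictor correlation matrix,
$\mathrm{diag}\big(R^{-1}\big)$. If nothing reaches entry significance the
result is an intercept-only model with a warning, never an error.

Validation statistics follow the usual QSAR conventions:

* RMSE $= \sqrt{RSS/n}$ (the plain root-mean-square error, $1/n$, not the
  residual standard error);
* $Q^2_{LOO} = 1 - PRESS/SS_{tot}$ with $SS_{tot}$ about the full-sample
  mean, computed by explicit refits (each fold's singularity is reported
  with its index);
* Lin's CCC $= 2\,\mathrm{cov}(x,y) / \big(\mathrm{var}(x) +
  \mathrm{var}(y) + (\bar x - \bar y)^2\big)$ with population ($1/n$)
  moments, applied in-sample and to LOO predictions;
* NSE $= 1 - \sum(o_i-p_i)^2 / \sum(o_i-\bar o)^2$ on untransformed
  concentrations (mg/kg ww) by default — a log-scale variant is available
  in the acceptance script's synthetic evaluation but is not the default,
  since the evaluation convention on the original scale is the stricter
  one; with pooling across studies rather than per-study aggregation
  (an explicit assumption);
* factor-of-N percentages use the closed inequality
  $\max(p/o, o/p) \le N$: a prediction exactly N-fold off counts as
  within. They are symmetric in observed/predicted and non-decreasing in N.

## The synthetic-data generators

`sim_descriptor_table()` samples descriptors uniformly over the
applicability box and induces the correlation structure real training data
shows, via a Gaussian copula (rank-scaled so the *uniform* marginals hit
the target Pearson correlations): $\log K_{ow}$ at $r \approx 0.7$ and TPSA
at $r \approx -0.85$ with $\log K_{om}$; clay, CEC and pH tracking OM at
$r \approx 0.65, 0.70, -0.50$. SSAlipid is the exact product
`ssa * lipid`, which links the earthworm group transitively. A derived
`kd_measured` is emitted, but $\log K_d$ is *not* offered as a candidate
descriptor: it equals $\log K_{om} + \log_{10}(OM/100)$ by definition, so
with OM among the candidates it is an exact substitute for $\log K_{om}$
and would make representative choice a coin flip.

`sim_rate_dataset()` adds rates as
$10^{\eta + \mathcal{N}(0, \sigma)}$ with $\sigma = 0.25$ log10 units by
default; `sim_uptake_series()` multiplies exact decay/uptake curves by
mean-one lognormal noise with a given CV. All generators are pure
functions of their seed (they save and restore the caller's random state).

What the generators do **not** emulate — and hence what green tests do not
show about real data: discrete chemical/soil/species designs with
study-level clustering and shared measurement error; descriptors outside
the applicability box; non-first-order exposure kinetics; biotransformation
or active excretion; heteroscedastic or censored residue measurements.

## Numerical choices

* Degenerate kinetics branch: when $|k_{out} - k_0| < 10^{-9}
  \max(k_{out}, 1)$ the closed form switches to the cancellation-free limit
  $k_{in} C_0\, t\, e^{-k_0 t}$.
* ODE route: `deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-12}$; solver
  failures raise a typed error with the solver state.
* Closed-form/ODE agreement is asserted with a mixed criterion: relative
  difference with an absolute floor of $10^{-4}$ mg/kg ww (0.1 µg/kg, far
  below analytical detection), because no solver can resolve *relative*
  accuracy below its absolute tolerance on residues of order $10^{-12}$.
* Kinetic fits: `minpack.lm::nlsLM` with positivity bounds and a small
  multistart grid ($k_{out}$ over plausible elimination scales ×
  $k_{in}$ matched to the early-time slope $C_w \approx k_{in} C_0 t$),
  keeping the lowest-RSS solution. Exposure-decay fits start from a
  log-linear fit; a non-declining series snaps the $k_0$ start to exactly 0
  (tiny negative log-slopes otherwise leave the optimizer at a singular
  start) and is fitted with $k_0 \ge 0$, returning $k_0 = 0$ for constant
  exposure.
* Out-of-domain inputs warn and proceed everywhere
  (`domain_policy = "strict"` in the pipeline turns violations into
  errors): extrapolation is routine in evaluation practice and flagged,
  not forbidden.

## Problem sizes in the test-suite

The suite runs entirely on generated data, sized to keep the default run
around a couple of minutes on one CPU: 1 000 parameter draws for the
closed-form/ODE sweep, 100 replicates for each closed-loop recovery study
(CV 5 % exposure, CV 10 % residue series), and 100 seeded training sets
(n = 75, $\sigma = 0.25$) for the descriptor-set-recovery property, where
each of the four generating descriptor sets must be recovered in at least
90 % of the sets. Two further test blocks check published fit statistics
and evaluation percentages; they require the user-transcribed supplementary
tables described in `inst/extdata/transcribed/README.md` and fail with an
informative message when those files are absent.

## Worked example

```{r example}
chem <- data.frame(name = "dieldrin", log_kow = 5.2, pka = NA,
                   charge_type = "neutral", tpsa = 12.5, kd_measured = NA)
soil <- data.frame(name = "loam", om = 8.2, clay = 20, cec = 15, ph = 6.1)
worm <- data.frame(species = "Eisenia fetida", lipid = 2.64, ssa = 1.45)
scen <- data.frame(route = "soil", c0 = 1, k0 = 0.02,
                   times = "1;2;4;7;14;21;28")

pred <- predict_residues(chem, soil, worm, scen, route = "porewater")
pred[, c("time", "kin", "kout", "bcf", "c_earthworm")]
```

```{r plot, fig.width = 6, fig.height = 3.5}
c_pw0 <- 1 / 10^unique(pred$log_kd)   # porewater concentration by equilibrium partitioning
autoplot(body_residue_closed_form(kin = unique(pred$kin),
                                  kout = unique(pred$kout),
                                  c0 = c_pw0, k0 = 0.02,
                                  times = seq(0, 60, 0.5)))
```

## Known limitations

Adult earthworms only; monovalent ionizable compounds at most; no growth
dilution, biotransformation, active excretion or sorption aging — expect
overestimation where these matter; the packaged calibration is synthetic
(see above); exposure decay is single-exponential unless the ODE route is
used; NSE/factor evaluation pools data points rather than aggregating per
study.
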