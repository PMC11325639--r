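# User-transcribed calibration and evaluation tables

The published calibration (75 experimentally determined uptake/elimination
rate constants with chemical, soil and earthworm properties) and the
literature evaluation set (402 internal-concentration data points) are
distributed only as supplementary material of the original publication and
are **not** redistributed with this package. The packaged reference models
are a clearly labelled synthetic stand-in (`reference_models_synthetic.json`).

To run the published-data checks in `tests/testthat/test-acceptance.R`,
transcribe the supplementary tables into the two CSV schemas below (UTF-8,
header row, dot decimal separator) and place them in this directory.

## table_s1_rates.csv — calibration rate constants (one row per treatment)

column          | meaning
----------------|---------------------------------------------------------
chemical        | compound name
soil            | soil name
species         | earthworm species
log_kow         | log10 octanol-water partition coefficient
tpsa            | topological polar surface area, A^2
om              | soil organic matter, % dry weight
clay            | clay content, %
cec             | cation exchange capacity, cmol+/kg
ph              | soil pH
lipid           | earthworm lipid content, % wet weight
ssa             | earthworm specific surface area, m^2/kg
kd_measured     | measured sorption coefficient, L/kg
log_kom         | log10 of kd_measured / (om/100)
kin_porewater   | uptake rate constant, L porewater/kg worm/d
kout_porewater  | elimination rate constant (porewater basis), 1/d
kin_soil        | uptake rate constant, kg soil/kg worm/d
kout_soil       | elimination rate constant (soil basis), 1/d

## table_s2_evaluation.csv — literature evaluation set (one row per data point)

column       | meaning
-------------|------------------------------------------------------------
study        | literature source identifier
chemical     | compound name
charge_type  | neutral / monovalent_acid / monovalent_base
log_kow      | log10 Kow
pka          | pKa (empty for neutral compounds)
tpsa         | TPSA, A^2
kd_measured  | measured Kd, L/kg (empty when unmeasured)
om           | soil OM, %
ph           | soil pH
species      | earthworm species
lipid        | lipid content, % ww
ssa          | SSA, m^2/kg
c0           | initial exposure concentration (mg/kg dw soil, or mg/L if route = porewater)
route        | medium of c0: soil or porewater
k0           | fitted first-order exposure decay rate, 1/d (0 if constant)
time         | exposure time of the measurement, d
observed     | measured internal concentration, mg/kg wet weight
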