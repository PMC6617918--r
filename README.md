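# gasrisk

Risk estimation for intravitreous gas or air expansion during altitude
travel, for vitreoretinal surgeons and their post-vitrectomy patients.

After pars plana vitrectomy with a gas or air tamponade, a buoyant bubble
remains in the vitreous cavity. Travelling to a higher altitude lowers the
ambient pressure, the bubble expands, and — because the eye is a semirigid
container — intraocular pressure can rise sharply, risking irreversible
vision loss. `gasrisk` implements the computational core of a clinical
calculator for this scenario, plus the interobserver-agreement statistics
used to validate patient self-assessment against the surgeon's fundoscopic
judgment.

## The model

- **Geometry.** The vitreous cavity is an oblate spheroid of total volume
  V<sub>total</sub> = 4.5 ml. The gas occupies a superior cap whose
  vertical extent is a fraction *h* of the cavity's vertical diameter; the
  cap volume fraction is the spherical-cap polynomial
  *f(h) = h²(3 − 2h)*, which is exact for any oblate spheroid with a
  vertical axis (axis-aligned scaling preserves slab-volume fractions), so
  V₁ = V<sub>total</sub> · f(h).
- **Atmosphere.** International Standard Atmosphere troposphere:
  P(z) = P₀ (1 − Lz/T₀)^(gM/RL) with P₀ = 101.325 kPa, L = 0.0065 K/m,
  T₀ = 288.15 K, exponent ≈ 5.25588; valid for −500 m ≤ z ≤ 11000 m.
- **Expansion.** Boyle's law P₁V₁ = P₂V₂ gives the unconstrained
  destination volume V₂ = V₁·P₁/P₂ and ΔV = V₂ − V₁. Ocular compensation
  mechanisms (choroidal compression, scleral expansion, aqueous outflow)
  are deliberately not modelled.
- **Risk.** The ratio r = ΔV / V<sub>AC</sub> against the normal
  anterior-chamber volume (default 0.20 ml) is mapped to an ordered
  category `none < low < moderate < high` by configurable cut points
  (defaults 0.5 and 1.0, closed on the left).
- **Agreement.** Bland-Altman bias and 95% limits of agreement
  (bias ± 1.96 · SD of surgeon − patient differences), exact and
  normal-approximation Wilcoxon matched-pairs signed-rank tests,
  median/range summaries and Likert tabulation.

## Worked example

A patient with a 75% gas fill travelling from sea level (10 m) to Lhasa
(3490 m):

```r
library(gasrisk)
assess_risk(75, 10, 3490)
#> # A tibble: 1 × 10
#>   h_pct    z1    z2    v1    p1    p2    v2 delta_v risk_ratio category
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>   <dbl>      <dbl> <ord>
#> 1    75    10  3490  3.80  101.  65.8  5.84    2.04       10.2 high
```

The 75% interface height corresponds to V₁ = 3.80 ml of gas; the ambient
pressure drops from 101.2 kPa to 65.8 kPa, so the unconstrained Boyle
volume is 5.84 ml — an increase of 2.04 ml, over ten times the
anterior-chamber volume, hence a `high` risk report.

Cohort-level agreement analysis on a synthetic 50-patient cohort:

```r
cohort <- simulate_cohort(n = 50, seed = 1)
cohort_agreement(cohort)
#> <cohort_agreement> n = 50 patients
#>   Bland-Altman bias -0.06%, LoA [-5.03, 4.91]%
#>   Wilcoxon on heights: P = 0.62 (approx)
#>   Wilcoxon on expanded volumes: P = 0.91 (approx)
```

`bland_altman()` objects support `tidy()`, `glance()` and `autoplot()`
(the classic difference-vs-mean plot with bias and limit lines).

## Command line

A thin CLI over the same functions is installed as `exec/gasrisk`:

```sh
gasrisk risk --interface-pct 75 --from-alt 10 --to-alt 3490
gasrisk simulate --n 50 --seed 1 --out cohort.csv
gasrisk cohort --in cohort.csv --out report.json --agreement
gasrisk chart --interface-pct 40 --out chart.svg
```

Exit status is 0 on success, 2 on a validation error. Model constants
(cavity volume, atmosphere constants, anterior-chamber volume, risk
thresholds) can be overridden with `--config cfg.yaml`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulating a 50-patient cohort, passing it through the CSV
layer, computing per-patient expansion risk for both judges, and running
the full agreement analysis — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
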