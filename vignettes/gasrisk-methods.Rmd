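---
title: "Models and methods behind gasrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gasrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasrisk)
```

## The clinical problem

After pars plana vitrectomy, many patients carry an intravitreous gas or
air bubble for days to weeks. The bubble is buoyant and sits against the
superior wall of the vitreous cavity, with a horizontal fluid/gas
interface below it. Because the eye is a semirigid, sealed container, a
drop in ambient pressure — an airplane cabin, a drive to a mountain city —
lets the bubble expand against the eyewall and can elevate intraocular
pressure enough to threaten vision. `gasrisk` computes a preliminary risk
estimate from two inputs a patient can supply themselves: the perceived
interface height and the planned route's altitudes.

## Geometry: interface height to gas volume

The cavity is idealised as an oblate spheroid of total volume
$V_\mathrm{total}$ (default 4.5 ml, the conventional adult figure). The
interface height $h \in [0, 1]$ is the fraction of the cavity's
*vertical diameter* occupied by gas, measured downward from the superior
pole — gas floats, and larger percentages mean larger bubbles.

For a unit sphere, the volume above a horizontal plane a fraction $h$
down from the top is the spherical-cap polynomial

$$ f(h) = h^2 (3 - 2h). $$

An oblate spheroid with a vertical symmetry axis is an axis-aligned
scaling of a sphere, and such a scaling multiplies every horizontal slab
volume by the same constant. The cap *fraction* versus normalised height
is therefore identical for every aspect ratio, so $f(h)$ is exact for the
spheroidal cavity and the only geometric parameter that matters is
$V_\mathrm{total}$: $V_1 = V_\mathrm{total} \, f(h)$. This removes an
unidentifiable shape parameter; no biometric aspect ratio is asked of the
user. The inverse mapping (volume to height) has no closed form we care
to maintain — $f$ is a monotone cubic — so it is solved by bracketed
root-finding on $[0,1]$ to a tolerance of $10^{-12}$ in $h$.

Degenerate inputs behave sensibly: $f(0) = 0$, $f(1) = 1$, and
$f(h) + f(1-h) = 1$ (an equatorial symmetry the tests verify to
$10^{-12}$). Heights arriving as percentages (CLI, CSV) are divided by
100 at the boundary; the internal unit is always the fraction.

## Atmosphere: altitude to pressure

The International Standard Atmosphere troposphere formula is used:

$$ P(z) = P_0 \left(1 - \frac{L z}{T_0}\right)^{gM/(RL)}, $$

with $P_0 = 101.325$ kPa, $L = 0.0065$ K/m, $T_0 = 288.15$ K and exponent
$gM/(RL) \approx 5.25588$, valid on $-500 \le z \le 11000$ m. Requests
outside that range raise a domain error naming the range rather than
extrapolating into the stratosphere. All four constants are configurable
(YAML/JSON config) so an alternative barometric parameterisation can be
matched exactly if one is mandated; the ISA default agrees with published
standard-atmosphere tables to well under 0.5% through 5000 m. Weather is
deliberately ignored — altitude is the sole driver, matching how a
patient-facing calculator must work. Pressures are carried in kPa;
clinical mmHg values convert via 1 kPa = 7.500617 mmHg.

## Expansion and the risk report

Boyle's law $P_1 V_1 = P_2 V_2$ gives the unconstrained destination
volume $V_2 = V_1 P_1 / P_2$ and the signed change
$\Delta V = V_2 - V_1$ (negative on descent). Two modelling choices are
worth stating plainly:

- $V_2$ is the *unconstrained* Boyle volume. The real eye pushes back —
  choroidal compression, scleral expansion and accelerated aqueous
  outflow all buffer the expansion — but those compensation mechanisms
  are intentionally excluded, so the report errs on the cautious side.
- The code computes $V_2$ as `v1 * (p1/p2)` so that a flat route
  ($P_1 = P_2$) yields exactly $\Delta V = 0$ in floating point, not a
  $10^{-16}$ residue that could flip a category at the `none` boundary.

The risk ratio $r = \Delta V / V_{AC}$ compares the expansion to the
normal anterior-chamber volume $V_{AC}$ (default 0.20 ml, a typical
anatomic value; the source calculator quotes no number, so it is
configurable). The ordered categories `none < low < moderate < high` use
two ascending cut points, default 0.5 and 1.0, with a closed-left
convention: a ratio exactly at a cut lands in the higher category. The
published calculator's on-screen wording and true cut-offs are not
public, so these defaults are honest placeholders exposed in
configuration — every quantitative test in the package depends on
$\Delta V$ and $r$, never on the labels. Any $\Delta V \le 0$ is `none`.

## Agreement statistics

The validation question for a self-assessment tool is whether patients'
interface judgments agree with the surgeon's fundoscopic ones.

**Bland-Altman.** Differences are `surgeon − patient`; bias is their
mean, spread the sample SD ($n-1$ denominator), and the limits of
agreement are bias $\pm\ 1.96\,\mathrm{SD}$. The multiplier is fixed at
1.96 rather than a $t$ quantile — the conventional large-sample choice —
but is exposed as a parameter. Fitted objects support `tidy()`,
`glance()` and `autoplot()` (difference vs mean with bias/limit lines).

**Wilcoxon matched-pairs signed-rank.** Zero differences are dropped
(Wilcoxon's method, the common statistical-package default); remaining
absolute differences receive average ranks. With $\le 25$ nonzero
differences the two-sided p-value is exact: the null distribution of the
rank sum is built by a generating-function convolution over *doubled*
ranks (doubling makes tied average ranks integers, so ties are handled
exactly — something the reference implementation in base R refuses to
do). Above 25, a normal approximation with continuity correction and the
standard tie correction to the variance is used; the suite checks the
two routes agree within 0.02 at $n = 15$ and that the approximate test's
null rejection rate is calibrated at the 5% level. If every difference
is zero the test is degenerate and reports $p = 1$ with a flag.

**Descriptives.** Skewed clinical variables are summarised as median
(range); Likert responses are tabulated as counts and proportions per
level with validation of the 1–5 domain.

## The synthetic cohort

No patient-level table is distributed with the study, so the generator
stands in for it — a stated world, fixed once:

- Surgeon heights uniform on 9–78% (the observed range); the patient's
  judgment differs by `surgeon − patient = bias + N(0, sd)` with bias
  −0.3% and sd 2.8%, clipped to [0, 100] and rounded to integer percent
  as clinical charts are. The sd is back-solved so the default limits of
  agreement span ≈ 11 percentage points, emulating the reported band —
  an emulation choice, not a published value.
- Destinations: the three named high-altitude cities at their observed
  frequencies (Lhasa 3490 m, 2%; Guiyang 1277 m, 6%; Kunming 1842 m,
  10%) and the remaining 82% uniform over coastal 0–150 m; origin fixed
  at 10 m (a sea-level tertiary centre).
- Travel modes airplane/train/car–bus at 38/30/32%, trains split 11:4
  high-speed:ordinary; Likert mass concentrated on levels 4–5; ages
  18–70, sexes 3:2 M:F.

What a green test on this cohort establishes is that the *pipeline* is
correct — parameter recovery, marginal frequencies, end-to-end execution
— not that the package reproduces the original study's numbers, which
would require the original patient table. Real data would bring features
the generator omits: diagnosis-specific fill levels, gas absorption over
postoperative days, non-Gaussian judgment errors and digit preference.

## Numerical and design notes

- Inversions: interface-from-volume by `uniroot` at $10^{-12}$;
  altitude-from-pressure in closed form; both round-trip to well under
  their documented tolerances ($10^{-8}$ in $h$, 0.01 m in $z$).
- The interface chart (the circle a patient lines the interface out on)
  is emitted as directly composed SVG markup, making the output
  byte-deterministic for a given input; a ggplot2 companion exists for
  interactive sessions.
- Cohort CSVs are UTF-8, comma-separated, "." decimal, percentages as
  0–100 numbers. Unknown extra columns pass through untouched (the
  reference table's exact inventory is unseen); a missing origin-altitude
  column defaults to 10 m. Validation failures name the row and field.
- Exact-vs-approximate Wilcoxon crossover at 25 nonzero differences:
  beyond that the exact DP is still cheap, but 25 keeps the behaviour
  predictable and matches where the approximation is already within a
  fraction of a percent.

## Limitations

The cavity volume is fixed at 4.5 ml and will misstate bubbles in, for
example, highly myopic eyes; phakic status is ignored. No intraocular
pressure in mmHg is predicted — the output is a volume-ratio risk
estimate, not a tonometry forecast. Gas kinetics (SF6/C3F8 absorption
over time) are out of scope: the calculation is a snapshot at the moment
of travel.
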