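---
title: "Models and methods behind ttcsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ttcsynergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcsynergy)
```

ttcsynergy implements the quantitative core of a preclinical combination
study of a targeted thorium-227 conjugate (TTC) with a PARP inhibitor: the
in vitro combination-index analysis, the in vivo Bliss synergy calling on
treatment-over-control ratios, the supporting radionuclide arithmetic, and
synthetic-data generators that make every stage testable. This vignette
records the models, their assumptions, and the design choices that were
genuinely open.

## In vitro: dose–response and combination index

**Normalization.** Raw plate signals are mapped to viability fractions by
anchoring at the mean of untreated control wells (1.0) and cell-free blanks
(0.0). A plate whose control mean does not exceed its blank mean is rejected
as degenerate rather than silently producing negative spans.

**4PL fit.** `fit_4pl()` fits
$v(D) = b + (t - b)\,/\,(1 + (D/e)^{h})$ in log10-dose space by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). Local minima are
handled with three deterministic starts (data-driven, steep $h=3$, shallow
$h=0.5$); the lowest-SSE fit wins, so no randomness enters the fit. Zero-dose
wells are excluded (they have no log-dose); at least four distinct positive
concentrations are required. The *absolute* IC50 — the dose at 50% of
untreated control, not 50% of the fitted span — is inverted in closed form,
$IC_{50} = e\,((t-0.5)/(0.5-b))^{1/h}$, with explicit failure statuses
distinguishing a floor above 0.5 (`bottom-above-half`) from a curve starting
below 0.5 (`top-below-half`), and a flag when the crossing lies more than a
decade outside the tested range.

**Median-effect linearization.** `fit_median_effect()` regresses
$\log_{10}(f_a/f_u)$ on $\log_{10} D$ with $f_a = 1 - v$ defined against
untreated control (consistent with the absolute-IC50 convention; the
alternative, defining $f_a$ against the fitted top, would disagree whenever
a curve has a nonzero floor). Replicates are averaged per concentration
first; viability is clipped to (0.001, 0.999) before the log-odds transform,
which is undefined at 0 and 1 (bounds configurable). Fewer than three
concentrations with fraction affected strictly inside (0, 1) is an
insufficient-dynamic-range error. A noiseless 4PL with unit span is an exact
median-effect curve with $D_m = e$ and $m = h$; this identity anchors the
recovery tests.

**Combination index.** Mixtures are dosed as a fraction $f$ of the two top
concentrations split by a weight pair $(w_A, w_B)$, the nine default pairs
running 0.9:0.1 to 0.1:0.9. Internally the mixture dose axis is
dimensionless ($f$), which avoids mixing kBq/mL and µM on one axis; the
decomposition back to native units uses the design weights and tops. For
each ratio the fraction $f_{50}$ at which the mixture reaches 50% effect is
read from a variable-slope 4PL fit of the mixture curve (median-effect fit
as fallback), and

$$\mathrm{CI} = \frac{f_{50}\, w_A\, C_A}{D_{m,A}} +
               \frac{f_{50}\, w_B\, C_B}{D_{m,B}}.$$

Reading the crossing from the 4PL rather than the global median-effect line
is a deliberate choice: on exact median-effect data the two coincide, but on
surfaces that deviate from the median-effect shape (e.g. a product of two
Hill curves) the globally linearized line is biased by curvature, while the
4PL crossing tracks a brute-force search of the underlying surface to within
about 1.5% in the test suite. The single-agent denominators remain the
median-effect doses, as in the standard Chou–Talalay procedure.

CI is evaluated at the 50% effect level by default (the level at which the
IC50 isobologram is drawn); other levels are available via the `effect`
argument. The average CI is the arithmetic mean over evaluable ratios — the
simplest reading of an unqualified "average". Ratios whose observed maximum
effect never reaches the target level are flagged, excluded from the
average, and counted in the result. Classification uses CI < 0.8
synergistic, CI > 1.2 antagonistic, and a *closed* additive interval in
between, so the boundary values 0.8 and 1.2 are deterministically additive.
CI is invariant under rescaling of either agent's concentration unit, which
the suite checks to eight significant digits.

**Isobolograms.** `isobologram_points()` returns the two single-agent
intercepts plus one $(d_A, d_B)$ point per evaluable ratio; a point's
normalized coordinate sum equals its CI, so points below the straight
additivity line correspond to CI < 1.

## In vivo: growth, T/C, and Bliss calls

**Censoring.** Animals are censored at their first measurement at or above
the humane-endpoint volume (1500 mm³ by default); the triggering measurement
is kept, later ones are excluded from group means. No
last-observation-carried-forward is applied — carrying a capped value
forward would bias group means downward exactly in the arms that fail.

**Doubling time** is $\ln 2$ over the slope of $\ln V$ on study day, per
animal, averaged within an arm; non-positive slopes are reported as
"no growth" rather than negative doubling times.

**T/C and significance.** T/C is the ratio of treated to vehicle mean
volume over uncensored animals at a reference day. The default reference
day is the last day on which *every* vehicle animal is uncensored, so the
control mean is never survivorship-biased; any day can be requested
explicitly. Significance comes from one-way ANOVA across all arms at that
day followed by Tukey's HSD, reading off each arm's contrast against
vehicle at $\alpha = 0.05$.

**Bliss convention.** The textbook Bliss formula $C = A + B - AB$ applied
*literally* to T/C ratios predicts a combination worse than either
monotherapy (e.g. $A=0.8$, $B=0.5$ gives 0.9), which contradicts its use as
an additivity reference. Applied on the inhibition scale
($A' = 1 - A$) and mapped back it gives $C = A \cdot B$ — the default
`"inhibition-scale"` convention, which uniquely reproduces the reported
synergy pattern from the shipped printed T/C table. The literal form is
retained behind `convention = "paper-literal"`, and the suite verifies the
algebraic complement identity $1 - \mathrm{literal}(1-A, 1-B) = AB$ to
machine precision. The "ten percent" margin is interpreted as 0.10 absolute
T/C units (percentage points), the only reading consistent with the printed
call pattern; boundary values classify additive, with a $10^{-9}$
comparison epsilon so exact decimal boundaries are not split by binary
floating point. Monotherapy and combination T/C values entering a Bliss
call must come from the same study at the same reference day.

**Hematology.** Nadir is the series minimum as a fraction of the baseline
(first) sample, with a "no suppression" flag for series that never fall
below baseline; recovery is the first post-nadir day back within a
tolerance (default 10%) of baseline.

## Radiometrics

All internal times are hours; half-lives are stored with native units and
converted once. The registry ships Th-227 at 18.7 d and its daughter Ra-223
at 11.43 d (standard nuclide data), both overridable. Decay correction to
injection time is $A \cdot 2^{t/T_{1/2}}$, the exact inverse of forward
decay. %IA/g decay-corrects the measured activity, then divides by injected
activity and sample mass. Specific activity converts a kBq/kg activity dose
and a mg/kg protein dose to kBq/µg; activity-to-molarity uses
$N = A/\lambda$ atoms and Avogadro's number (for Th-227, 1 Bq ≈ 2.33×10⁶
atoms, so 22 kBq/mL ≈ 85 pM). Bateman ingrowth assumes no daughter at
$t = 0$ and no daughter loss, i.e. the theoretical upper bound against
which measured daughter retention is compared; redistribution of recoiling
daughters is deliberately not modelled. Equal decay constants switch to the
limiting form $A_p(0)\,\lambda t e^{-\lambda t}$. Detector counts are
assumed calibrated to Bq upstream; gamma-spectroscopy peak handling is out
of scope.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its spec and a seed.

* **Plates** (`gen_viability_plates`): single-agent 4PL curves plus mixture
  wells from the surface $s = (s_A(d_1)\, s_B(d_2))^{\gamma}$ — γ = 1 is
  exactly Bliss-independent, γ > 1 synergistic, γ < 1 antagonistic. This
  one-parameter interaction was chosen over mechanistic radiobiology models
  because its null is exactly known and recoverable. Defaults emulate the
  study design: titrations 0.01–50 kBq/mL and 0.01–25 µM, nine fixed
  ratios, IC50s 3 kBq/mL and 0.03 µM (the sensitive line), unit Hill
  slopes. Mixture titrations are log-spaced around each ratio's analytic
  50%-effect fraction, as an experimenter centers a titration on the active
  range. Noise is additive Gaussian on the viability fraction, clipped to
  [0, 1.2] before conversion to raw signal. Note that with unit Hill slopes
  the Bliss-null surface is *mildly Loewe-synergistic*: the two-term CI at
  50% effect equals $1 - x y$ where $x + y + xy = 1$, so per-ratio CIs fall
  between 0.83 and 0.93 and still classify additive. The true CI = 1 null
  is a drug combined with itself, which the suite checks across Hill slopes
  0.5–4.
* **Xenografts** (`gen_xenograft_study`): volumes follow
  $V(t) = V_0 \exp(g t - \psi\, K(t))$ with a radioconjugate kill that
  decays with the Th-227 half-life and a PARP-inhibitor kill active during
  the 28-day dosing window; ψ multiplies the combined kill in arms
  receiving both agents, so ψ = 1 reproduces Bliss-additive T/C exactly
  ($TC_{AB} = TC_A \cdot TC_B$). Defaults: start volume 90 mm³, doubling
  time 8.3 d, 10 animals per arm measured twice weekly, endpoint 1500 mm³,
  and kill rates placing the monotherapy T/C values near the reported
  magnitudes (0.3/0.5/0.8 for 600/300/125 kBq/kg; 0.5 for 50 mg/kg at day
  21). Measurement noise is mean-one lognormal (sdlog 0.1, a typical
  caliper CV).
* **Biodistribution** (`gen_biodistribution`): decay-corrected %IA/g curves
  — bi-exponential blood washout, saturating tumor uptake with a plateau of
  50 %IA/g in targeted mode versus 5 %IA/g for the isotype control —
  sampled at 24/72/168/336 h, three animals per time, forward-decayed to
  measured activities with lognormal noise. Default curve constants give a
  tumor-to-blood ratio near 13 at 336 h, the reported order of magnitude.
* **Hematology** (`gen_hematology`): a lognormal-shaped suppression dip per
  lineage, equal to the programmed depth at the nadir day and back within
  10% of baseline at the programmed recovery day (platelets: day 12, depth
  0.5, recovery 26; white cells: day 11, depth 0.6, recovery 39; red cells
  unaffected), depth scaling linearly with the radioconjugate dose,
  sampled every other week.

What the generators do **not** emulate: receptor-density-dependent uptake,
radiobiological bystander or recoil effects, pharmacokinetics of either
agent, inter-animal growth-rate heterogeneity beyond lognormal measurement
noise, or plate-position effects. Passing recovery tests therefore
demonstrate that the estimators invert the stated statistical models at the
stated noise levels — not that those models capture every feature of real
assay data.

## Numerical choices and degenerate inputs

* 4PL multi-start is deterministic; bounds keep plateaus in [−0.5, 2] and
  |hill| ≤ 20.
* Median-effect clipping bounds (0.001, 0.999) are configurable; recovery
  tests keep their dose spans inside the bounds so the linearization is
  exact where it should be.
* CI boundary values 0.8/1.2 and Bliss margin boundaries classify additive;
  the Bliss comparison carries a 1e-9 epsilon.
* Degenerate inputs fail loudly with specific messages: control ≤ blank
  plates, constant viability curves, insufficient dynamic range, zero
  within-group variance in the ANOVA, vehicle fully censored at the
  requested day, zero blood activity in a tumor/blood ratio, non-positive
  protein dose or sample mass, negative elapsed times.

## Problem sizes in the test suite

The suite runs entirely on generated data: 200-replicate Monte-Carlo loops
for IC50 recovery under 5% relative measurement noise and for the
end-to-end xenograft study (6 animals per arm, measurements to day 21 —
sizes chosen to make the Monte-Carlo operating characteristics stable while
keeping the whole suite fast), an exhaustive permutation oracle
(choose(8,4) relabelings) for the Tukey comparison, a 10⁴-point grid for
the Bliss complement identity, and 10⁴-point grid searches as the
combination-index surface oracle.

## Known limitations

* The CI analysis covers the fixed-ratio median-effect design only; no
  response-surface models (ZIP, HSA, BRAID) and no Loewe surface fitting.
* Day-wise group comparisons only; no longitudinal mixed-effects
  tumor-growth modelling and no time-to-event analysis.
* No absorbed-dose (Gy) dosimetry and no gamma-spectrum processing — the
  radiometric layer starts from calibrated activities.
* Printed published values are shipped as a fixture for the Bliss pattern
  check; the underlying raw measurements are not public, so the in vitro
  and biodistribution layers are validated against synthetic ground truth
  and closed forms rather than the original data.
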