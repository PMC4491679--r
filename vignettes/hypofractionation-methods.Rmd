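---
title: "Isoeffect hypofractionation, neutron second-cancer risk and plan comparison: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoeffect hypofractionation, neutron second-cancer risk and plan comparison: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypofrac)
```

hypofrac collects the desk-scale computations that sit around a passively
scattered proton therapy (PSPT) prostate treatment: converting fractionation
schedules under the linear-quadratic (LQ) isoeffect model, estimating the
lifetime second-cancer risk attributable to stray neutrons, fitting a static
multileaf collimator (MLC) to a custom aperture, comparing plan dosimetry,
and pricing the patient-side savings of hypofractionation. This vignette
documents the models, their assumptions, the defaults, and the numerical
choices; the `analysis/` scripts in the source repository run each analysis
end to end.

## The LQ isoeffect model

Under the linear-quadratic cell-survival model, a total dose $D$ delivered
in fractions of size $d$ has biologically effective dose

$$\mathrm{BED} = D\left(1 + \frac{d}{\alpha/\beta}\right),$$

and two regimens with equal BED (at the same $\alpha/\beta$) are
isoeffective. Given a reference photon regimen $(D_R, d_R)$ and a new
fraction number $n$, the isoeffective photon total solves
$n\,d\,(1 + d/(\alpha/\beta)) = \mathrm{BED}$, whose positive root is

$$D_\gamma(n) = \frac{n\,(\alpha/\beta)}{2}
  \left(-1 + \sqrt{1 + \frac{4\,\mathrm{BED}}{n\,(\alpha/\beta)}}\right).$$

`isoeffective_total_dose()` implements this closed form; the test suite
cross-checks it against an independent root-finding oracle over a
1000-point random grid and verifies the inversion closure
(`compute_bed()` of the returned regimen recovers the input BED to
$10^{-9}$ relative).

**Assumptions.** A slowly proliferating tumor (no repopulation or
time-factor terms), a single $\alpha/\beta$ per evaluation, and no
normal-tissue constraint modelling. Prostate tumors are believed to have a
low $\alpha/\beta$; because the value is uncertain, every prescription is
bracketed over $\alpha/\beta \in \{1, 3, 5\}$ Gy and the max/min ratio of
the bracketed totals is reported as a prescription uncertainty
(`uncertainty_ratio()`). Ratios above 1.10 are flagged clinically
significant — comparable in magnitude to dose-delivery errors — with
1.05–1.10 reported as borderline.

**Proton conversion.** The constant generic clinical RBE of 1.1 is used
throughout: proton absorbed dose $= D_\gamma / 1.1$, so that multiplying a
tabulated proton dose by 1.1 recovers the photon-equivalent dose in
Gy (RBE). We adopt the divide-by-RBE direction because it is the convention
under which the canonical single-fraction entries (16.4 and 18.9 Gy)
reproduce; fraction-size-dependent RBE models (1.1–1.7 towards the distal
SOBP edge) are deliberately out of scope.

**Rounding.** Table output rounds doses to one decimal and ratios to two,
always computed from unrounded values. Published tabulations of this
equivalence appear to truncate rather than round in places (a recomputed
13.09 Gy printed as 13.0), and their entries at high fraction numbers sit
systematically about 0.5–1.7% below this package's recomputation (e.g. a
printed 71.2 Gy against a recomputed 72.0 Gy at $n = 44$, where the photon
anchor $D_\gamma(44) = 79.2$ Gy is exact by construction); the convention
behind those rows is unstated, so no agreement is forced and the package
reports its own consistent recomputation.

```{r}
eq <- equivalence_table()
head(eq[, 1:8], 4)
```

## Neutron second-cancer risk

Stray neutrons (external: produced in the treatment head; internal:
produced in the patient) deliver an equivalent dose obtained by weighting
absorbed dose with a mean radiation weighting factor $\bar{w} = 6.2$
(`weight_neutron_dose()`), an average over both neutron sources. The
lifetime attributable risk (LAR) of second-cancer incidence for an organ is
the product of its mean equivalent dose (Sv) and an organ-specific BEIR VII
coefficient (%/Sv):

- bladder: 0.66 %/Sv;
- rectum: 0.19 %/Sv, i.e. the whole-colon coefficient scaled by a 0.2
  fractional mass correction (`derive_mass_corrected_coefficient()`),
  since applying the colon coefficient to the near-field rectum alone would
  overestimate risk.

Both values are for a 60-year-old man and are treated as given constants;
age-, sex- and latency-resolved risk modelling is out of scope, as is risk
from the therapeutic proton dose itself. Only bladder and rectum carry
default coefficients — other organs require user-supplied values.
`combined_risk()` sums organ risks and reports two decimals in percent (raw
values are retained as attributes).

The bundled organ-dose tables (`neutron_dose_fixture()`) are Monte Carlo
results transcribed as printed; their totals can disagree with
external + internal by 1 mSv from independent rounding, so the loader
tolerates exactly that much. The 52 mSv bound quoted for the plan
difference is interpreted as a bound on the maximum per-organ difference in
total neutron equivalent dose (the computed maximum is 45 mSv, at the
prostate); the referent is not stated in the source, so this interpretation
is documented rather than asserted.

```{r}
combined_risk(neutron_dose_fixture("soc"))
compare_plan_doses(neutron_dose_fixture("soc"),
                   neutron_dose_fixture("mlc_only"))$max_abs_total_delta_mSv
```

## MLC aperture fitting

A static MLC approximates an aperture polygon with one pair of 0.5 cm-wide
leaves per row. `fit_leaf_positions()` applies the midpoint rule: each open
leaf's tip is placed where the line through the midpoint of the leaf edge
crosses the aperture boundary, so every leaf-edge midpoint lies exactly on
the aperture line. Two conventions were genuinely open and are package
decisions:

- **Leaf-grid registration.** The lowest leaf boundary is anchored at the
  polygon's minimum extent along the stacking axis; `anchor` exposes
  alternative registrations.
- **Multi-lobed rows.** A midline of a non-convex aperture can cross the
  boundary more than twice; with one leaf pair per row the outermost
  crossings are used.

The scalloping error — the area of the symmetric difference between the
polygon and the open-leaf union — is computed by `aperture_area_error()`
with one-dimensional quadrature along the stacking axis (default step
2 × 10⁻³ cm; the cross-section symmetric-difference length at each level is
exact). An independent two-dimensional rasterization oracle
(`rasterize_area_error()`, 0.01 cm cells) is kept separate and used in the
tests to validate the quadrature within 1%. For convex apertures the error
is non-increasing under leaf-width halving and vanishes as the width goes
to zero; the tests verify this on 100 seeded random convex polygons at
widths 1, 0.5, 0.25 and 0.125 cm, with oracle cross-checks on a sampled
subset — sizes chosen to keep the default suite fast while exercising the
property broadly. Leaf-end transport physics (edge scatter, divergence,
material) is out of scope; the error metric is purely geometric.

## Plan dosimetry

Dose grids are 3-D arrays in Gy (RBE) on a regular raster with
voxel-center origin; structure masks live on the identical raster. A voxel
belongs to a structure iff its center is inside — stated explicitly because
organ means depend on it. Plans are compared after normalizing the CTV mean
to the 76 Gy (RBE) prescription (`normalize_to_ctv_mean()`, idempotent and
scale-equivariant); fields are combined by scaling each to a 34.5 Gy
per-field CTV mean and summing (`combine_fields()`), so a lateral opposed
pair delivers 69 Gy. Cumulative DVHs (`cumulative_dvh()`, default 0.1 Gy
bins) report the percent volume receiving at least each bin-edge dose;
differential DVHs are not provided. Absolute organ doses of a commercial
treatment-planning system on patient CTs are not reproducible at desk
scale; the bundled ten-patient summary table is a fixture for the
comparison operations, preserved exactly as printed — including an
anterior-rectal-wall mean for the MLC techniques that duplicates the CTV
row and is flagged (`attr(..., "suspect_rows")`), not corrected.

## Cost model

`treatment_calendar_days()` uses a Monday-start calendar with
`fractions_per_week` treatment days per week and the intervening rest days
counted inside the delivery span:
$\mathrm{span} = n + (7 - f)\lfloor (n-1)/f \rfloor$, which for the default
five weekday fractions is $n + 2\lfloor (n-1)/5 \rfloor$. This calendar is
chosen because it makes the canonical 44 → 25 fraction reduction save
exactly 27 days and, at \$200/day, \$5400 in lost wages; with seven
treatment days a week the span is exactly $n$. Planning days (default 5)
are common to both arms and cancel out of every savings computation.
Per-diem defaults are \$51–71 (meals and incidentals) and \$80–185
(lodging); savings are day-difference times rate, unrounded (27 × \$185 =
\$4995 — a published \$4970 lodging figure is not reproducible under any
stated convention and is left as a documented discrepancy). The \$200/day
wage is \$52,100/year over 260.5 working days
(`annual_wage_to_daily()`). Facility-revenue modelling is out of scope.

## Synthetic data

The generators replace patient data so every module is exercisable offline;
all are pure functions of their seed (bit-identical on repeat, caller's RNG
state preserved).

- `synth_plan()` builds two opposed-lateral fields on a 40³ voxel, 0.4 cm
  grid (a 16 cm cube about the isocenter — about 64k voxels, small enough
  that every dosimetry operation runs in well under a second). The depth
  profile is a flat plateau over the SOBP ending at the beam range
  (default 24.5 cm water-equivalent within the clinical 22.0–27.1 cm span;
  SOBP width 9 cm within 8–10 cm) with a sigmoid distal falloff; lateral
  profiles are error-function penumbrae (σ = 0.3 cm). The CTV ellipsoid
  (semi-axes 3.0 × 2.4 × 2.0 cm, 60.3 cm³) sits mid-way inside the printed
  46.3–81.8 cm³ clinical volume span; bladder, rectum and femoral heads are
  placed anatomically around it. This is deliberately minimal realism: no
  Bragg-curve physics, heterogeneity, or range-compensator geometry — the
  beam entrance lies outside the grid — so passing tests demonstrate the
  correctness of the dosimetry *operations*, not transport accuracy.
- `synth_neutron_table()` perturbs the bundled organ-dose tables with
  multiplicative noise (default 3%, about the low end of the 8–12% Monte
  Carlo voxel uncertainties, appropriate for structure means over many
  voxels) while enforcing the qualitative plan signature — MLC-only lowers
  external and raises internal neutron dose in every organ — by resampling
  (at most 10 attempts). Zero noise returns the printed tables unchanged.
- `synth_aperture()` perturbs a circle radially with harmonics 2–5 scaled
  to a peak relative amplitude `irregularity`; the polygon is star-shaped,
  hence always simple. `synth_convex_polygon()` (convex hulls of jittered
  ellipse points) feeds the convergence properties of the leaf fitter.

## Known limitations

- The isoeffect engine is a constant-RBE, single-$\alpha/\beta$, no-time
  LQ model; it should not be extrapolated to regimens where repopulation or
  RBE variation matters without external justification.
- The risk model is linear in dose with two fixed coefficients; it is an
  order-of-magnitude epidemiological estimate, not a patient-specific
  prediction.
- Synthetic plans share one raster for all structures and fields and do not
  emulate inter-patient anatomical variation.
- All published tables bundled here are fixtures: the package reproduces
  the computations defined on them, not the Monte Carlo or
  treatment-planning physics that produced them.
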