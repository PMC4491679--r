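# hypofrac

Desk-scale radiobiology and plan-comparison tools for hypofractionated
passively scattered proton therapy (PSPT) of the prostate, written for
medical physicists and radiation oncology researchers who want the
computations around a treatment-planning study — not the planning system
itself — as tested, reusable code.

The package implements:

- **LQ isoeffect conversion.** Under the linear-quadratic model,
  `BED = D (1 + d/(α/β))`; the photon total dose isoeffective with a
  reference regimen at a new fraction number `n` is the positive root
  `D_γ(n) = (n/2)(α/β)(−1 + √(1 + 4·BED/(n·α/β)))`. Proton absorbed dose is
  `D_γ / RBE` at the constant clinical RBE of 1.1. Because the prostate
  α/β is uncertain, prescriptions are bracketed over α/β ∈ {1, 3, 5} Gy and
  the max/min ratio of the bracketed totals is reported as a prescription
  uncertainty (ratios above 1.10 flagged clinically significant).
- **Neutron second-cancer risk.** Organ equivalent dose from stray
  neutrons (absorbed dose × mean weighting factor 6.2) times a BEIR VII
  lifetime-attributable-risk coefficient — bladder 0.66 %/Sv, rectum
  0.19 %/Sv (whole-colon value × 0.2 fractional mass) — summed over organs;
  plus per-organ comparison of two plans' neutron dose tables.
- **Static MLC fitting.** One 0.5 cm leaf pair per row, tips placed where
  the leaf-edge midpoint line crosses the aperture polygon, with the
  scalloping (symmetric-difference) area error computed by quadrature and
  cross-checked by a rasterization oracle.
- **Plan dosimetry.** CTV-mean normalization (76 Gy (RBE)), opposed-field
  combination (34.5 Gy/field → 69 Gy), cumulative DVHs, and per-organ
  max/mean summaries with plan-to-plan deltas.
- **Cost model.** Calendar-day and per-diem savings of hypofractionation
  (44 → 25 fractions saves 27 days and $5400 in lost wages at $200/day).
- **Synthetic data.** Seeded generators for opposed-lateral dose grids
  with pelvic structure masks, neutron organ-dose tables, and aperture
  polygons, so every analysis runs with no patient data.

Bundled fixtures transcribe the published ten-patient organ-dose summary
and the Monte Carlo neutron dose tables for the standard-of-care and
MLC-only plans; these are inputs to the comparison operations, not
recomputation targets.

## Worked example

```r
library(hypofrac)

eq <- equivalence_table(reference = regimen(79.2, 44))  # 1.8 Gy/fx photon SOC
eq[eq$n %in% c(1, 5, 20, 44), 1:8]
#>   n frac_1 frac_3 frac_5 total_1 total_3 total_5 ratio
#>   1   13.1   16.4   18.9    13.1    16.4    18.9  1.45
#>   5    5.6    6.7    7.4    28.1    33.4    37.2  1.32
#>  20    2.6    2.8    3.0    52.1    56.6    59.3  1.14
#>  44    1.6    1.6    1.6    72.0    72.0    72.0  1.00
```

Each row is the proton prescription (fraction size and total, Gy absorbed;
multiply by 1.1 for Gy (RBE)) isoeffective with 79.2 Gy/44 fx photons at
α/β = 1, 3, 5 Gy. A single 16.4 Gy proton fraction (α/β = 3) is
isoeffective with the full course, but the 1.45 max/min ratio says the
single-fraction prescription is uncertain by 45% across the α/β bracket;
by 20 fractions the spread is 14%, and at the reference fractionation the
bracket collapses (ratio 1.00).

```r
combined_risk(neutron_dose_fixture("soc"))
#> [1] 0.51
#> attr(,"per_organ")
#> bladder  rectum
#> 0.38610 0.12312
```

The combined bladder + rectum lifetime risk of neutron-induced second
cancer is 0.51% for the standard-of-care plan — and also 0.51% for the
MLC-only plan, whose largest per-organ neutron dose difference is 45 mSv.

```r
savings()
#> Days saved: 27
#>   Meals & incidentals: $1377 - $1917
#>   Lodging:             $2160 - $4995
#>   Lost wages:          $5400
```

## Analyses

The `analysis/` scripts run the full set of analyses and write their
tables under `results/`:

```sh
Rscript analysis/01_isoeffect_table.R    # equivalence table CSV
Rscript analysis/02_second_cancer_risk.R # risk report + plan deltas
Rscript analysis/03_plan_dosimetry.R     # synthetic plan, DVHs, summaries
Rscript analysis/04_mlc_fitting.R        # leaf bank, scalloping convergence
Rscript analysis/05_cost_savings.R       # savings JSON
```

The methods vignette (`vignettes/hypofractionation-methods.Rmd`) documents
the models, defaults, numerical conventions and known limitations.

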