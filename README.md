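# liflux — lithium isotope fractionation by cellular ion transport

Cells discriminate between the two stable lithium isotopes when they take
Li⁺ up across the plasma membrane. Passive transport through cation
channels fractionates by a few permil; active transport by the Na⁺/H⁺
exchanger (NHE), which imports one cation per exported proton, enriches
the cytosol in ⁶Li by more than ten permil and does so *cooperatively* —
the preference for ⁶Li grows with the external Li concentration. `liflux`
is an R package for geochemists, membrane physiologists and modellers who
want a mechanistic, calibrated, testable model of this process.

The model couples:

* **electrodiffusion** — Goldman–Hodgkin–Katz fluxes
  `J = P w ([S]out − [S]in e^w)/(e^w − 1)`, `w = zFV_m/RT`, for
  ⁶Li⁺, ⁷Li⁺, Na⁺, K⁺ and Cl⁻, with a dynamic (capacitively charged)
  membrane potential;
* **a dimeric exchanger master equation** — 50 occupancy states of the
  NHE dimer (empty / protonated / ⁶Li / ⁷Li / Na per protomer, plus a
  seniority flag), with first-come-first-served translocation, kinetic
  isotope effects on the binding kinetics and the translocation step,
  sodium competition, and Monod–Wyman–Changeux activation by
  intracellular protons (`K_h = 0.17e-7 M`, `K_l = 36e-7 M`,
  `L0 = 878.6`);
* **whole-cell bookkeeping** — intracellular isotope pools, pH (with
  buffering power β) and V_m for a 2.6×10³ µm³ cell, reported as
  δ⁷Li (‰, vs the LSVEC standard) and Δ⁷Li (cell − medium difference).

Calibration reconstructs the default parameter set from printed anchors —
medium δ⁷Li 15‰, exchanger-null fractionation −4.4‰ at 1 min, the NHE1
plateau 1.2‰ (5–30 s average at 15 mM), the dose-response deltas 5.4‰
(0.3 mM) and 1.4‰ (≥60 mM), and the apparent Km 9.94 mM — by a
root-solve for the channel isotope-permeability ratio plus a
Levenberg–Marquardt fit of the exchanger dials, every model evaluation
integrating the stiff whole-cell ODE system.

See the methods vignette (`vignettes/transport-fractionation.Rmd`) for the
model's assumptions, the numerical choices and the known limitations.

## A worked example

```r
library(liflux)

cell <- cell_config()        # 15 mM Li medium at delta = 15 permil, pH_in 6.0
mem  <- membrane_params()    # calibrated channel isotope ratio rho_ch
exch <- exchanger_params()   # calibrated dimeric exchanger

simulate_uptake(cell, mem, exch, times = c(0, 5, 10, 20, 30, 60))[,
  c("t_s", "Li_cell_mM", "delta7Li_permil", "pH_in")]
#>   t_s Li_cell_mM delta7Li_permil pH_in
#> 1   0      0.000              NA 6.000
#> 2   5      0.369           0.970 6.018
#> 3  10      0.729           1.072 6.036
#> 4  20      1.425           1.282 6.070
#> 5  30      2.086           1.496 6.103
#> 6  60      3.875           2.155 6.191
```

The cell accumulates lithium while holding its δ⁷Li near **1.2‰** over the
5–30 s window — a cell−medium fractionation of about **−13.8‰**, driven by
the exchanger. The proton export alkalinises the cytosol (pH 6.0 → 6.2),
which in turn throttles the exchanger through its MWC activation. A
channel-only (exchanger-null) cell fractionates far less:

```r
simulate_uptake(cell, mem, NULL, times = c(0, 60))$delta7Li_permil[2] - 15
#> [1] -4.4
```

The dose response shows both the Michaelis–Menten saturation of uptake
and the cooperative deepening of the isotope selection:

```r
dr <- dose_response(cell, mem, exch, conc = c(1, 3, 10, 30, 60, 120))
dr
#>   Li_out_mM Li_cell_mM delta7Li_permil
#> 1         1      0.260           4.758
#> 2         3      1.209           3.806
#> 3        10      3.256           2.549
#> 4        30      4.643           1.618
#> 5        60      5.139           1.351
#> 6       120      5.542           1.414

fit_mm(dr$Li_out_mM, dr$Li_cell_mM)
#> model fit (converged, 7 iterations)
#>      estimate        se
#> Vmax 6.061559 0.2203886
#> Km   9.938427 1.4373067
#> r-squared: 0.9922
```

Other entry points: `ph_scan()` and `na_scan()` for pH and sodium
competition scans, `steady_state_flux()` / `flux_delta()` /
`gillespie_flux()` for per-dimer transport, `fit_mwc()` and `joint_fit()`
for parameter estimation, `generate_kinetics()` and friends for seeded
synthetic measurement tables, and `calibrate_defaults()` to re-derive the
whole calibrated bundle from the anchor set. A thin command-line wrapper
lives in `scripts/liflux.R`.

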