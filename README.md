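# tbimc — fast voxel Monte Carlo dose simulation for Co-60 total body irradiation

Total body irradiation (TBI) on a cobalt-60 teletherapy unit uses a
nonstandard geometry — a 50 × 200 cm field at about 1.8 m source-to-floor
distance — that commercial treatment planning systems refuse to calculate.
`tbimc` is a purpose-built, lightweight Monte Carlo dose engine for exactly
this setup, for medical physicists who want volumetric dose estimates in
heterogeneous, CT-derived patient models in minutes on one CPU rather than
point-dose hand calculations.

## The model

Per history, a 1.25 MeV photon (the effective Co-60 line, the mean of the
1.17/1.33 MeV emissions) is emitted from a 2 cm source disk at 195.4 cm,
aimed within the collimated field, and attenuated by a six-plate stacked
lead flattening filter under a zero/single-scatter model,
`A = exp(−μ t)`. Photons reaching the patient window are tracked through a
voxel density grid by survival-probability stepping: one uniform threshold
per flight, fixed 1 mm steps accumulating optical depth

    A = exp( − Σ_j h / λ_j ),   1/λ = [(μ/ρ)_PE + (μ/ρ)_C] · ρ

with the voxel density ρ from the bilinear CT calibration
`ρ = 0.001·HU + 1.034` (HU ≤ 0; slope 0.0006 above). Compton angles are
drawn from discretized inverse-CDF tables of the Klein–Nishina
cross-section (1° × 1000-slot × 10 keV resolution, lookup-only); recoil
electrons carry `Te = hν − hν′` and deposit energy along straight lines at
the collision stopping-power rate (CSDA, 10 keV cutoff). Dose is
`ΔE/(Vρ)` per voxel, convertible to dose-to-water by Bragg–Gray
stopping-power ratios at 0.3 MeV. PDD/profile extraction, mean relative
difference, 2-D gamma analysis (3 mm/3%, 5 mm/5%) and the `1/(δ²T)`
efficiency metric mirror the published validation workflow.

## Worked example

```r
library(tbimc)

# the 31.8 x 48.4 x 30 cm validation water tank at 1 mm depth resolution
phantom <- make_water_phantom(voxel_size = c(0.254, 0.254, 0.1))
dose <- run_simulation(phantom,
                       config = transport_config(n_histories = 2e7, seed = 11))
print(dose)
#> <dose_grid> 125 x 191 x 300 voxels, 2e+07 histories
#>   entered: 1.516e+06 photons, 1.879e+06 MeV
#>   deposited 9.817e+05 MeV, exited 8.973e+05 MeV

pdd <- extract_pdd(dose, lateral_window = 8)
round(pdd$value[c(1, 3, 5, 8, 11, 21, 51, 101, 201)], 1)  # depths 0.05 ... 20.05 cm
#> [1]  4.9 63.3 92.5 99.4 97.5 91.4 80.8 67.8 40.4
round(depth_of_maximum(pdd), 2)
#> [1] 1.1
```

The curve shows the classic Co-60 buildup — ~5% at the surface, ~93% of
maximum by 0.5 cm depth — followed by a near-flat crest through the first
centimetre (broad-field scatter keeps pace with primary attenuation
there) and a slow falloff to ~40% at 20 cm. Heterogeneous cases work the same way via
`make_layered_body()` (lung/bone slabs), `add_aluminum_insert()` (the
high-density validation insert) or `read_ct_series()` (DICOM CT). Dose
planes can be compared with `gamma_index(ref, eval, dta = 3, dd = 3)`,
which reports the pass rate and per-point gamma map.

A thin CLI wrapping these functions ships in `inst/cli/tbimc`
(`simulate`, `pdd`, `profile`, `gamma`, `make-phantom`, `efficiency`).

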