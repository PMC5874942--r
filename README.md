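# fetalct — fetal CT dosimetry on a slab phantom

Fetal CT is used to diagnose severe skeletal dysplasia in late pregnancy, and
the question a physicist or radiologist faces at the console is blunt: given
the displayed dose–length product (DLP), roughly what dose did the fetus
receive? `fetalct` answers this for two acquisition geometries — a 320-row
scanner in **wide-volume mode** (the scan range is covered by several axial
cone-beam rotations with overlapping junctions) and an 80-row scanner in
**helical mode** (pitch > 1, no overlap) — by modelling the whole chain on a
mathematical slab phantom:

- **Phantom.** A pregnant adult divided head to mid-thigh into 208 axial
  slabs of 5 mm, with a documented organ roster (the gravid uterus at
  640–760 mm from the crown); the uterus dose is reported as the fetal dose.
- **Dose coefficients.** Normalized organ dose per irradiated slab per mAs,
  `n[T, i]`, with an in-field plateau over the organ extent and scatter
  tails decaying as `exp(-d/λ)`, scaled per beam-width class by an output
  factor proportional to the scanner's weighted CTDI (nCTDIw). The bundled
  generator is a synthetic, structure-faithful stand-in for proprietary
  Monte Carlo tables.
- **Dose index accounting.** `CTDIvol = nCTDIw · mAs / 100 / pitch` (32-cm
  phantom) and `DLP = CTDIvol · L_irr`, where the irradiated length is
  `N · BW` for N wide-volume rotations of beam width BW, and the scan length
  for helical.
- **Dose engine.** `D_T = Σ_rot Σ_{i∈rot} n[T, i] · (mAs / pitch)`: slabs
  under a junction are irradiated once per covering rotation, which is
  exactly the wide-volume overlap dose penalty. The maternal effective dose
  is the ICRP-103 female-organ sum `E = Σ w_T D_T` with a mean-dose
  remainder term.
- **Conversion analysis.** Per-acquisition ratios `fetal dose / DLP`
  (cm⁻¹, rounded half-up to 2 decimals) and the conservative
  recommendation: the **maximum** rounded ratio per scanner mode, so
  `DLP × CF` never underestimates a tabulated fetal dose by more than the
  rounding slack.

The package ships the seventeen reference acquisitions (nine wide-volume,
eight helical, 100 kV, scan lengths 176–352 mm) with their console CTDIvol
and DLP values, plus the published fetal doses, so the conversion analysis
can be reproduced from published inputs ("reproduction mode") independently
of the synthetic coefficients ("engine mode").

## Worked example

```r
library(fetalct)

# Wide-volume overlap geometry: covering 348 mm with three 160-mm rotations
plan <- plan_wide_volume(348, 160, 3, scan_start_mm = 525)
plan
#> wide_volume plan: L = 348 mm (entered 350), 3 rotation(s) x 160 mm
#>   irradiated 480 mm, overlap 132 mm (38% of scan length)
#>  rotation start_mm end_mm start_slab end_slab
#>         1      525    685        105      137
#>         2      620    780        124      156
#>         3      715    875        143      175

# A full acquisition on the bundled phantom with synthetic coefficients
ph <- default_pregnant_phantom()
co <- generate_coefficients(ph, synth_coeff_params())
rep <- run_acquisition(
  scan_protocol(ma = 103, rotation_time = 0.5, pitch = 1,
                beam_width = 160, n_rotations = 3, scan_length = 348),
  study_scanners()$wide_volume, ph, co)
rep
#> Dose report — 320-row wide-volume
#>   100 kV, 103 mA, 0.5 s, pitch 1, BW 160 mm x 3, L 348 mm
#>   CTDIvol 2.70 mGy   DLP 129.6 mGy.cm (console: 130)
#>   fetal dose 4.196 mGy   effective dose 2.328 mSv

# Reproduction mode: published doses/DLPs through the conversion pipeline
study <- run_study("reproduction")
study$factors$wide_volume
#> Conversion factor (wide_volume): 0.06 cm^-1 (max ratio, at L = 176 mm)
study$factors$helical
#> Conversion factor (helical): 0.05 cm^-1 (max ratio, at L = 176 mm)

# Bedside estimate: console shows DLP 100 mGy.cm in wide-volume mode
estimate_fetal_dose(100, study$factors$wide_volume)
#> [1] 6
```

The plan shows why dose is *not* monotone in scan length in wide-volume
mode: 348 mm needs three 160-mm rotations (480 mm irradiated, 38% of the
scan length doubly covered) while the *longer* 352 mm scan uses four 120-mm
rotations (also 480 mm, but only 36% overlap) and, being in the softer
beam-width class (CTDIvol 2.6 vs 2.7 mGy), delivers a lower fetal dose.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/fetalct.R plan --scan-length 348 --beam-width 160 --rotations 3
Rscript inst/cli/fetalct.R run-study --reproduction --out out/
Rscript inst/cli/fetalct.R estimate --dlp 100 --mode wide
```

## Scope

Absolute organ doses depend on proprietary Monte Carlo coefficient data and
are out of scope: engine mode uses the synthetic generator, which preserves
the structure (plateau, scatter decay, beam-class ordering) but not the
absolute values. Over-ranging, tube-current modulation, patient-size
scaling, and voxel phantoms are not modelled. See the methods vignette
(`vignettes/fetal-ct-dosimetry.Rmd`) for the model, parameter choices and
limitations.
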