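---
title: "Fetal CT dosimetry on a slab phantom: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal CT dosimetry on a slab phantom: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalct)
```

## The problem

Fetal CT for suspected skeletal dysplasia irradiates the fetus directly, and
the scan length follows the fetus, so fetal exposure is effectively
whole-body. The scanner console reports two dose indices — CTDIvol (mGy, the
dose to a standard 32-cm acrylic phantom per acquisition) and DLP
(mGy·cm, CTDIvol times irradiated length) — but neither is a fetal dose.
`fetalct` models the full chain from acquisition geometry to organ dose on a
stylized phantom and derives a *conversion factor* (cm⁻¹) that turns a
displayed DLP into a fetal-dose estimate.

Two geometries are modelled. In **wide-volume mode** a 320-row scanner covers
the range with $N$ axial cone-beam rotations of nominal beam width $BW$
(120–160 mm); the firmware picks $(BW, N)$ from the scan length, and because
$N \cdot BW > L$ the junctions overlap, irradiating part of the anatomy two
or three times. In **helical mode** an 80-row scanner covers the range in one
acquisition at pitch 1.39, with no overlap (over-ranging is not modelled).

## Phantom and coordinates

The phantom spans head to mid-thigh as 208 axial slabs of 5 mm (1040 mm).
All geometry is 0-based and half-open in slab units; every public interface
also accepts millimetres and converts via `mm_to_slab_interval()`. The
half-open convention removes the off-by-one ambiguity inherent in closed
intervals: `[start_mm/5, end_mm/5)` round-trips exactly for any grid-aligned
range.

The organ roster of `default_pregnant_phantom()` is a deterministic,
documented fixture, not measured anatomy: the axial extents of the
originating Monte Carlo phantom are not published, so we place organs at
plausible positions for a late-gestation adult. The gravid uterus occupies
slabs [128, 152) (640–760 mm), strictly inside the small-intestine-to-bladder
span; scan ranges are centred on it (`default_scan_start()`), so every
bundled scan length (176–352 mm) covers the uterus fully and the stomach and
liver at most partially — reproducing the qualitative dose ordering of the
reference acquisitions (in-field pelvic organs high, thoracic organs scatter
only). The roster carries all tissues the ICRP-103 female effective dose
needs, including the 13 remainder tissues. What passing tests therefore show
is fidelity of the *accounting* (geometry, overlap multiplicity, unit
chain), not anatomical accuracy of any individual organ dose.

## Synthetic dose coefficients

Monte Carlo CT dosimetry tables give the normalized dose to organ $T$ per
unit tube-current–time while irradiating slab $i$. The bundled data are
proprietary in origin, so `generate_coefficients()` builds a synthetic,
structure-faithful stand-in:

$$n[T, i] = \mathrm{OF}(c)\;\alpha_T\;e^{-d(i,T)/\lambda_T}\,(1 + u_i)$$

where $d(i,T)$ is the slab distance from the organ extent (0 inside — the
in-field plateau), $\lambda_T$ the scatter decay length,
$\mathrm{OF}(c) = n\mathrm{CTDI_w}(c)/n\mathrm{CTDI_w}(\text{ref})$ the
beam-width-class output factor, and $u_i$ optional uniform jitter.

Parameter choices, made once:

- **α = 1.2·10⁻³ mGy/mAs** for every organ: at the bundled technique
  (51.5 mAs per rotation) this yields fetal doses of a few mGy, the right
  order of magnitude for low-dose fetal CT. A uniform amplitude keeps the
  stand-in transparent; per-organ named vectors are accepted.
- **λ = 10 slabs (5 cm)**: a realistic body-scatter decay scale; doses to
  organs 10 cm out of field fall by ~e⁻².
- **jitter = 0** by default, so the generator is an exact closed form and
  the decay-monotonicity and linearity properties are testable exactly;
  jitter (≤ 20%) exists to exercise robustness.
- **nCTDIw per class** is back-solved from the console CTDIvol via
  $n\mathrm{CTDI_w} = \mathrm{CTDIvol} \cdot 100 \cdot \mathrm{pitch} /
  (\mathrm{mA} \cdot t)$: class A (120/128 mm) 5.049, class B (140/160 mm)
  5.243, class H (helical 40 mm) 5.039 mGy/100 mAs. Substituting back
  reproduces the console values 2.6/2.7/2.9 mGy exactly. The B:A ratio
  2.7/2.6 is what makes the 160-mm acquisitions "harder" per mAs than the
  120/128-mm ones.

What the generator does *not* emulate: true per-organ amplitude differences,
tube-spectrum and bow-tie effects, heel effect, and the real phantom's
composition. Consequently engine-mode absolute doses are indicative only;
every quantitative claim against published numbers runs in reproduction
mode, and engine mode is held to *structural* properties (ordering,
monotonicity, linearity, oracle equivalence).

## Rotation planning

`plan_wide_volume(L, BW, N, start)` first snaps the scan length to the 5-mm
entry grid. The default rule is nearest-5 with ties up; three bundled entries
(232→235, 264→270, 306→310 mm) deviate from any single rule we could
identify and are reproduced by an explicit override table
(`study_length_overrides()`) — a lookup, not a model. Ideal rotation starts
equalize the junction overlap at $(N \cdot BW - L_\text{snap})/(N-1)$ —
the only parameter-free symmetric choice, since the real firmware's
placement is unpublished — and are then snapped to the grid (nearest, ties
toward the scan start). A rotation starting on the grid irradiates
$\lceil BW/5 \rceil$ slabs, so the off-grid 128-mm collimation irradiates 26
slabs (130 mm). Invariants enforced at construction: the slab union covers
the snapped range gap-free, and each junction overlap is within one grid
step (5 mm) of the ideal.

The reported overlap uses the *requested* length: total overlap
$N \cdot BW - L$ and ratio $100(N \cdot BW - L)/L$. This yields the
geometric paradox the planner must reproduce: covering 348 mm with three
160-mm rotations overlaps 132 mm (38%), while the longer 352-mm range with
four 120-mm rotations overlaps 128 mm (36%) — the wider collimation wastes
more.

There is deliberately no inversion from $L$ alone to $(BW, N)$: the firmware
rule is unpublished, so the nine known combinations ship as a lookup
(`study_protocols()`) and unknown lengths require explicit $BW$ and $N$.

## Dose engine and effective dose

$$D_T = \sum_{\text{rotations}} \sum_{i \in \text{rotation}} n[T, i]\,
\frac{\mathrm{mAs}}{\mathrm{pitch}}$$

Overlap slabs contribute once per covering rotation — double or triple
irradiation is the whole mechanism of the wide-volume dose penalty. Helical
acquisitions apply a flat $\mathrm{mAs}/\mathrm{pitch}$ per slab (pitch 1.39,
no overlap), the minimal faithful model. The engine is vectorized
(coefficient matrix times slab-multiplicity vector) and is tested against an
independently written brute-force per-(rotation, slab) accumulator to
10⁻¹² relative on randomized plans.

The maternal effective dose uses the ICRP-103 weights restricted to female
organs: $E = \sum_T w_T D_T + 0.12 \cdot \overline{D}_{\text{remainder}}$
over the 13 female remainder tissues. The configured weights sum to 1.00 and
ship as a documented, swappable constant (`female_tissue_weights()`) because
a female-only effective dose is an approximation of the sex-averaged ICRP
quantity. The uterus dose is hard-wired as the fetal dose in every report.

DLP accounting: wide-volume irradiated length is $N \cdot BW$ (the nominal
beam, unsnapped); helical uses the requested scan length. Unrounded values
are always returned; `round_half_up()` reproduces the console display. The
console table is matched within ±2 mGy·cm across all seventeen
acquisitions — the residual disagreement traces to the console's own
inconsistent rounding (e.g. 2.6 × 48 cm = 124.8 displayed as 124), which we
do not attempt to model beyond round-half-up.

## Conversion analysis

Each acquisition contributes a ratio fetal dose/DLP, rounded half-up at two
decimals *before* taking the per-mode maximum, because published ratio
tables are rounded and the recommended factors are maxima of the rounded
column — the only arithmetic consistent with every published row.
Round-half-up (not R's banker's rounding) is used throughout for displayed
quantities. The recommendation is deliberately conservative: with
$CF = \max_r \mathrm{round}_2(D_r/DLP_r)$, the estimate
$DLP \times CF$ can undershoot a tabulated fetal dose by at most the
rounding slack $0.005 \cdot DLP$, a guarantee asserted in the tests.

Reproduction mode (published doses and DLPs as inputs) is a first-class
path, distinct from engine mode, so the conversion analysis is checkable
without the proprietary coefficients:

```{r}
study <- run_study("reproduction")
study$tables$wide_volume[, c("scan_length_mm", "dlp_mGycm",
                             "fetal_dose_mGy", "ratio")]
study$factors$wide_volume$value
study$factors$helical$value
```

## Numerical and degenerate-input choices

- Exact half values round up at every displayed precision (a tiny epsilon
  guards binary representation of decimal halves).
- A single rotation wider than the snapped range (e.g. 128-mm beam, 125-mm
  range) is legal: the union must *cover* the range; beam-width spill
  beyond it is accepted.
- Zero mA is legal and yields an all-zero report (linearity anchor);
  zero-length or negative inputs, off-grid positions, impossible coverage
  ($N \cdot BW < L$), unknown organs/classes, and malformed coefficient
  CSVs raise classed conditions (`fetalct_grid_error`,
  `fetalct_coverage_error`, `fetalct_format_error`, …) that the CLI maps to
  distinct exit codes.
- Coefficients are stored per mAs internally; nCTDIw stays per 100 mAs to
  match console convention — one documented unit boundary.

## Problem sizes

The test suite runs the full 17-acquisition study on the 208-slab phantom,
120 randomized oracle plans plus 100 in the acceptance checks, and 200
randomized planner geometries; everything completes in seconds on one core.

## Known limitations

Absolute organ and effective doses are only as good as the synthetic
coefficients — order-of-magnitude realism, not dosimetry. No over-ranging,
tube-current modulation, partial-rotation weighting, cone-beam edge effects,
patient-size (abdominal-circumference) scaling, gestational-age-specific
fetal geometry, or tube voltages other than the bundled 100 kV data. The
conversion factors apply to the modelled technique and an average-habitus
patient; larger patients shield the fetus more, smaller ones less.
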