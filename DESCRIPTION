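Package: fetalct
Title: Fetal CT Dosimetry with a Slab Phantom: Organ Doses, DLP Accounting,
    and Fetal Dose Conversion Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fetal and maternal organ doses for fetal computed
    tomography on a mathematical slab phantom (208 axial slabs of 5 mm).
    Models wide-volume axial acquisitions on a 320-row scanner (multiple
    overlapping cone-beam rotations) and helical acquisitions on an 80-row
    scanner; accounts for CTDIvol and dose-length product (DLP); integrates
    per-slab normalized organ-dose coefficients over a rotation plan; computes
    the female-organ effective dose with ICRP-103 tissue weights; and derives
    fetal-dose/DLP conversion factors with a conservative (maximum-ratio)
    recommendation. Ships a synthetic dose-coefficient generator that emulates
    the structure of Monte Carlo normalized organ-dose tables (in-field
    plateau, exponentially decaying scatter tails, beam-quality output
    factors), plus the published protocol set and dose table of a fetal CT
    dosimetry study for reproduction-mode analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
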