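test_that("dose integration is a per-(rotation, slab) sum scaled by effective mAs", {
  m <- coeff_matrix(study_coeffs, "A")
  # single rotation over one slab: D = n[T, slab] * mAs
  one <- slab_plan(130, 131)
  d1 <- integrate_organ_dose(study_coeffs, one, mAs_per_rotation = 51.5)
  expect_equal(d1, m[, 131] * 51.5)
  # two rotations fully overlapping the same interval: exactly twice one
  iv <- slab_plan(c(120, 120), c(150, 150))
  single <- slab_plan(120, 150)
  expect_equal(integrate_organ_dose(study_coeffs, iv, 51.5),
               2 * integrate_organ_dose(study_coeffs, single, 51.5))
  # pitch divides the effective mAs
  expect_equal(integrate_organ_dose(study_coeffs, single, 80, pitch = 1.39),
               integrate_organ_dose(study_coeffs, single, 80 / 1.39))
  # out-of-phantom interval
  expect_error(integrate_organ_dose(study_coeffs, slab_plan(200, 210), 50),
               class = "fetalct_bounds_error")
  expect_error(integrate_organ_dose(study_coeffs, single, 50, beam_class = "Z"),
               class = "fetalct_config_error")
})

test_that("the engine matches the brute-force (rotation, slab) oracle on random plans", {
  set.seed(7)
  for (rep in 1:120) {
    plan <- random_plan()
    mAs <- stats::runif(1, 10, 120)
    pitch <- sample(c(1, 1.39), 1)
    cl <- sample(names(study_coeffs$classes), 1)
    got <- integrate_organ_dose(study_coeffs, plan, mAs, pitch, cl)
    want <- brute_force_organ_dose(study_coeffs, plan, mAs, pitch, cl)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("doses scale linearly with mAs and never decrease when a rotation is added", {
  plan <- slab_plan(c(105, 130), c(137, 162))
  base <- integrate_organ_dose(study_coeffs, plan, 51.5)
  expect_equal(integrate_organ_dose(study_coeffs, plan, 103), 2 * base)
  bigger <- slab_plan(c(105, 130, 150), c(137, 162, 175))
  expect_true(all(integrate_organ_dose(study_coeffs, bigger, 51.5) >= base))
})

test_that("female effective dose applies ICRP-103 weights with a mean-remainder term", {
  w <- female_tissue_weights()
  expect_lte(w$total, 1)
  expect_equal(w$total, 1.0) # every weighted tissue exists in the female roster
  # hand-computed toy: 0.12 * 10 + 0.04 * 5 = 1.4 (no remainder)
  toy <- female_tissue_weights(weights = c(lungs = 0.12, liver = 0.04),
                               remainder = character(0), remainder_weight = 0)
  expect_equal(effective_dose(c(lungs = 10, liver = 5), toy), 1.4)
  # null case and factorization at uniform dose
  ph <- default_pregnant_phantom()
  zero <- stats::setNames(numeric(nrow(ph$organs)), ph$organs$organ)
  expect_identical(effective_dose(zero, w), 0)
  expect_equal(effective_dose(zero + 3, w), 3 * w$total)
  # organ missing from the dose map
  expect_error(effective_dose(c(lungs = 1), w), class = "fetalct_config_error")
  expect_error(female_tissue_weights(weights = c(lungs = 0.95)),
               class = "fetalct_param_error")
})

test_that("a full acquisition assembles CTDIvol, DLP, organ, fetal and effective dose", {
  ph <- default_pregnant_phantom()
  sc <- study_scanners()
  rep176 <- run_acquisition(
    scan_protocol(ma = 103, rotation_time = 0.5, pitch = 1, beam_width = 120,
                  n_rotations = 2, scan_length = 176),
    sc$wide_volume, ph, study_coeffs)
  expect_s3_class(rep176, "dose_report")
  expect_equal(rep176$ctdivol, 2.6)
  expect_identical(rep176$fetal_dose, unname(rep176$organ_dose[["uterus_fetus"]]))
  expect_true(all(rep176$organ_dose >= 0))
  expect_gt(rep176$effective_dose, 0)

  hel348 <- run_acquisition(
    scan_protocol(ma = 160, rotation_time = 0.5, pitch = 1.39, beam_width = 40,
                  scan_length = 348),
    sc$helical, ph, study_coeffs)
  expect_equal(hel348$ctdivol, 2.9)
  expect_identical(round_half_up(hel348$dlp), 101)

  dark <- run_acquisition(
    scan_protocol(ma = 0, rotation_time = 0.5, pitch = 1, beam_width = 120,
                  n_rotations = 2, scan_length = 176),
    sc$wide_volume, ph, study_coeffs)
  expect_identical(unname(dark$organ_dose), numeric(nrow(ph$organs)))
  expect_identical(dark$dlp, 0)
  expect_identical(dark$effective_dose, 0)
})

test_that("helical fetal dose is non-decreasing in scan length", {
  ph <- default_pregnant_phantom()
  sc <- study_scanners()
  doses <- vapply(study_protocols("helical")$scan_length_mm, function(L) {
    run_acquisition(
      scan_protocol(ma = 160, rotation_time = 0.5, pitch = 1.39,
                    beam_width = 40, scan_length = L),
      sc$helical, ph, study_coeffs)$fetal_dose
  }, 0)
  expect_true(all(diff(doses) >= 0))
})

test_that("the 348-mm (160 x 3) acquisition delivers a strictly higher fetal dose than 352 mm (120 x 4)", {
  # same irradiated length (480 mm) and mAs, but the 160-mm collimation runs in
  # the harder beam-quality class (CTDIvol 2.7 vs 2.6) — dose non-monotonicity
  # in scan length
  ph <- default_pregnant_phantom()
  sc <- study_scanners()
  f <- function(L, bw, n) run_acquisition(
    scan_protocol(ma = 103, rotation_time = 0.5, pitch = 1, beam_width = bw,
                  n_rotations = n, scan_length = L),
    sc$wide_volume, ph, study_coeffs)$fetal_dose
  expect_gt(f(348, 160, 3), f(352, 120, 4))
})
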