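test_that("jitter-0 coefficients follow the plateau / exponential-tail closed form", {
  ph <- default_pregnant_phantom()
  tab <- generate_coefficients(ph, synth_coeff_params(alpha = 2e-3, lambda = 10))
  ut <- organ_extent(ph, "uterus_fetus") # slabs [128, 152)
  a <- tab$classes$A$coeff
  # inside the organ the coefficient is the plateau: output_factor (1) * alpha
  expect_equal(unname(a["uterus_fetus", (ut[1] + 1):ut[2]]),
               rep(2e-3, diff(ut)))
  # 10 slabs from the caudal edge with lambda 10: alpha * exp(-1)
  expect_equal(a["uterus_fetus", ut[2] + 10], 2e-3 * exp(-1),
               ignore_attr = TRUE)
  # 1 slab from the cranial edge: alpha * exp(-1/10)
  expect_equal(a["uterus_fetus", ut[1]], 2e-3 * exp(-0.1),
               ignore_attr = TRUE)
})

test_that("the generator is deterministic in the seed and sensitive to it under jitter", {
  ph <- default_pregnant_phantom()
  p1 <- synth_coeff_params(jitter = 0.1, seed = 7)
  expect_identical(generate_coefficients(ph, p1), generate_coefficients(ph, p1))
  p2 <- synth_coeff_params(jitter = 0.1, seed = 8)
  expect_false(identical(generate_coefficients(ph, p1),
                         generate_coefficients(ph, p2)))
  # jitter never produces a negative coefficient and never exceeds 20%
  t1 <- generate_coefficients(ph, synth_coeff_params(jitter = 0.2, seed = 3))
  t0 <- generate_coefficients(ph, synth_coeff_params())
  for (cl in names(t1$classes)) {
    expect_true(all(t1$classes[[cl]]$coeff >= 0))
    expect_true(all(abs(t1$classes[[cl]]$coeff / t0$classes[[cl]]$coeff - 1)
                    <= 0.2 + 1e-12))
  }
})

test_that("jitter-0 coefficients decay monotonically with slab distance from every organ", {
  ph <- default_pregnant_phantom()
  tab <- generate_coefficients(ph, synth_coeff_params())
  slabs <- seq_len(ph$n_slabs) - 1L
  for (cl in names(tab$classes)) {
    m <- tab$classes[[cl]]$coeff
    for (i in seq_len(nrow(ph$organs))) {
      d <- pmax(pmax(ph$organs$slab_start[i] - slabs,
                     slabs - (ph$organs$slab_end[i] - 1L)), 0L)
      v <- m[ph$organs$organ[i], order(d)]
      expect_true(all(diff(v) <= 1e-15))
    }
  }
})

test_that("the generator is linear in alpha and ordered by the class output factor", {
  ph <- default_pregnant_phantom()
  t1 <- generate_coefficients(ph, synth_coeff_params(alpha = 1e-3))
  t2 <- generate_coefficients(ph, synth_coeff_params(alpha = 2e-3))
  expect_equal(t2$classes$A$coeff, 2 * t1$classes$A$coeff)
  expect_equal(t2$classes$H$coeff, 2 * t1$classes$H$coeff)
  # class B (nCTDIw from CTDIvol 2.7) dominates class A (from 2.6) elementwise
  expect_true(all(t1$classes$B$coeff >= t1$classes$A$coeff))
  expect_equal(t1$classes$B$coeff / t1$classes$A$coeff,
               matrix(2.7 / 2.6, nrow(t1$classes$A$coeff),
                      ncol(t1$classes$A$coeff),
                      dimnames = dimnames(t1$classes$A$coeff)))
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_coeff_params(alpha = 0), class = "fetalct_param_error")
  expect_error(synth_coeff_params(lambda = -1), class = "fetalct_param_error")
  expect_error(synth_coeff_params(jitter = 0.3), class = "fetalct_param_error")
  expect_error(synth_coeff_params(nctdiw = c(A = -2)),
               class = "fetalct_param_error")
})

test_that("coefficient tables round-trip through CSV and bad files are rejected", {
  ph <- default_pregnant_phantom()
  tab <- generate_coefficients(ph, synth_coeff_params(jitter = 0.05, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(tab, path)
  back <- read_coefficients(path, phantom = ph)
  expect_equal(back$classes$A$coeff, tab$classes$A$coeff)
  expect_equal(back$classes$H$coeff, tab$classes$H$coeff)
  expect_equal(back$classes$B$output_factor, tab$classes$B$output_factor)
  expect_identical(back$kv, tab$kv)

  # negative coefficient
  bad <- utils::read.csv(path)
  bad$coefficient[5] <- -1
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p2, row.names = FALSE)
  expect_error(read_coefficients(p2), class = "fetalct_format_error")

  # duplicate key
  dup <- utils::read.csv(path)
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rbind(dup, dup[1, ]), p3, row.names = FALSE)
  expect_error(read_coefficients(p3), class = "fetalct_format_error")

  # missing column
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup[, setdiff(names(dup), "slab")], p4, row.names = FALSE)
  expect_error(read_coefficients(p4), class = "fetalct_format_error")

  # organ not on the roster
  alien <- dup
  alien$organ[alien$organ == "uterus_fetus"] <- "antenna"
  p5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(alien, p5, row.names = FALSE)
  expect_error(read_coefficients(p5, phantom = ph),
               class = "fetalct_format_error")

  # empty file is a format error, not an empty table
  p6 <- withr::local_tempfile(fileext = ".csv")
  file.create(p6)
  expect_error(read_coefficients(p6), class = "fetalct_format_error")
})
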