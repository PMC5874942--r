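test_that("the wide-volume planner reproduces the study's overlap geometry exactly", {
  p348 <- plan_wide_volume(348, 160, 3, scan_start_mm = 525)
  expect_identical(attr(p348, "total_overlap_mm"), 3 * 160 - 348) # 132 mm
  expect_identical(attr(p348, "overlap_ratio_pct"), 38)
  expect_identical(attr(p348, "irradiated_length_mm"), 480)

  p352 <- plan_wide_volume(352, 120, 4, scan_start_mm = 525)
  expect_identical(attr(p352, "total_overlap_mm"), 4 * 120 - 352) # 128 mm
  expect_identical(attr(p352, "overlap_ratio_pct"), 36)

  # exact tiling: no overlap, two abutting rotations
  p240 <- plan_wide_volume(240, 120, 2)
  expect_identical(attr(p240, "total_overlap_mm"), 0)
  expect_identical(p240$start_mm, c(0, 120))
  expect_identical(p240$end_mm, c(120, 240))
})

test_that("overlap ratios carry both the exact and the reported integer value", {
  r <- overlap_ratio(348, 160, 3)
  expect_identical(r$total_overlap_mm, 132)
  expect_identical(r$percent, 38)
  expect_equal(r$unrounded, 100 * 132 / 348)
  expect_identical(overlap_ratio(352, 120, 4)$percent, 36)
  expect_identical(overlap_ratio(100, 160, 1)$percent, 60)
  expect_identical(overlap_ratio(480, 160, 3)$percent, 0)
  # the beam-width paradox, in exact arithmetic: the wider collimation at a
  # shorter scan length overlaps a larger fraction of it
  expect_true(132 / 348 > 128 / 352)
  expect_gt(overlap_ratio(348, 160, 3)$unrounded,
            overlap_ratio(352, 120, 4)$unrounded)
})

test_that("rotation unions equal the snapped scan range for every bundled combination", {
  protos <- study_protocols("wide_volume")
  for (i in seq_len(nrow(protos))) {
    L <- protos$scan_length_mm[i]
    start <- default_scan_start(default_pregnant_phantom(), L)
    p <- plan_wide_volume(L, protos$beam_width_mm[i], protos$n_rotations[i],
                          start)
    covered <- sort(unique(unlist(Map(seq, p$start_slab, p$end_slab - 1L))))
    want <- seq(start / 5, start / 5 + snap_length(L) / 5 - 1)
    expect_identical(as.integer(covered), as.integer(want))
    # junction overlaps stay within one grid step of the equalized ideal
    n <- nrow(p)
    if (n > 1) {
      ideal <- (n * protos$beam_width_mm[i] - snap_length(L)) / (n - 1)
      got <- p$end_mm[-n] - p$start_mm[-1]
      expect_true(all(abs(got - ideal) < 5))
      expect_true(all(got >= 0))
    }
  }
})

test_that("rotation unions equal the snapped range on randomized geometries", {
  set.seed(42)
  widths <- c(40, 80, 120, 128, 140, 160)
  for (rep in 1:200) {
    bw <- sample(widths, 1)
    n <- sample.int(4L, 1)
    cand <- seq(max(bw, n * bw - 150), n * bw, by = 1)
    L <- cand[sample.int(length(cand), 1)]
    start <- 5 * sample.int(40, 1)
    if (start + snap_length(L, overrides = NULL) > 1040) next
    p <- plan_wide_volume(L, bw, n, start)
    covered <- sort(unique(unlist(Map(seq, p$start_slab, p$end_slab - 1L))))
    want <- seq(start / 5, start / 5 + attr(p, "snapped_length_mm") / 5 - 1)
    expect_identical(as.integer(covered), as.integer(want))
    expect_identical(attr(p, "total_overlap_mm"), n * bw - L)
  }
})

test_that("impossible coverage and degenerate requests are rejected", {
  expect_error(plan_wide_volume(100, 40, 2), class = "fetalct_coverage_error")
  expect_error(plan_wide_volume(200, 160, 1), class = "fetalct_coverage_error")
  expect_error(overlap_ratio(500, 160, 3), class = "fetalct_coverage_error")
  expect_error(plan_wide_volume(100, 40, 0), class = "fetalct_param_error")
})

test_that("helical plans are a single snapped interval with zero overlap", {
  p <- plan_helical(176, 610)
  expect_identical(nrow(p), 1L)
  expect_identical(p$end_slab - p$start_slab, 35L)
  expect_identical(attr(p, "total_overlap_mm"), 0)
  expect_identical(attr(p, "irradiated_length_mm"), 176)
  expect_identical(plan_helical(5, 0)$end_slab - plan_helical(5, 0)$start_slab, 1L)
  p348 <- plan_helical(348, 525)
  expect_identical(p348$end_slab - p348$start_slab, 70L)
})

test_that("plans export as a rotation-interval CSV", {
  p <- plan_wide_volume(348, 160, 3, scan_start_mm = 525)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plan(p, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("rotation_index", "start_mm", "end_mm", "start_slab",
                     "end_slab"))
  expect_identical(nrow(back), 3L)
  expect_identical(back$start_slab, p$start_slab)
})
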