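# Rotation planning. A wide-volume acquisition covers the scan range with N
# overlapping axial cone-beam rotations; junction overlaps are equalized and
# each rotation start is snapped to the 5-mm slab grid. A helical acquisition
# is a single interval. A rotation irradiates every slab its beam touches, so
# an off-grid collimation (128 mm) irradiates ceiling(128/5) = 26 slabs.

new_rotation_plan <- function(rotations, mode, scan_length_mm, snapped_length_mm,
                              scan_start_mm, beam_width_mm, n_rotations,
                              irradiated_length_mm, total_overlap_mm) {
  structure(rotations,
            mode = mode,
            scan_length_mm = scan_length_mm,
            snapped_length_mm = snapped_length_mm,
            scan_start_mm = scan_start_mm,
            beam_width_mm = beam_width_mm,
            n_rotations = n_rotations,
            irradiated_length_mm = irradiated_length_mm,
            total_overlap_mm = total_overlap_mm,
            overlap_ratio_pct = round_half_up(100 * total_overlap_mm / scan_length_mm),
            overlap_ratio_unrounded = 100 * total_overlap_mm / scan_length_mm,
            class = c("rotation_plan", "data.frame"))
}

# snap x to the 5-mm grid, nearest, ties toward `origin` (i.e. ties rounded
# down in the origin-anchored coordinate)
snap_toward <- function(x, origin) {
  r <- (x - origin) / 5
  origin + 5 * ceiling(r - 0.5)
}

#' Plan a wide-volume acquisition
#'
#' Places `n_rotations` axial rotations of width `beam_width` over the snapped
#' scan range. Ideal starts equalize the junction overlap at
#' `(N * BW - L) / (N - 1)`; each start is then snapped to the 5-mm grid
#' (nearest, ties toward `scan_start`). The union of the per-rotation slab
#' intervals always equals the snapped scan range; slabs under a junction are
#' irradiated by every rotation covering them, which is the mechanism of the
#' wide-volume overlap dose penalty.
#'
#' @param scan_length_mm Requested scan length L (mm).
#' @param beam_width_mm Nominal beam width BW (mm).
#' @param n_rotations Number of rotations N; requires `N * BW >= L`.
#' @param scan_start_mm Scan start in phantom coordinates (mm, snapped to the
#'   grid toward 0).
#' @return A `rotation_plan`: a data frame with one row per rotation
#'   (`rotation`, `start_mm`, `end_mm`, `start_slab`, `end_slab`; slab
#'   intervals half-open, 0-based) and attributes `total_overlap_mm`
#'   (`N * BW - L`), `overlap_ratio_pct`, `irradiated_length_mm` (`N * BW`).
#' @examples
#' p <- plan_wide_volume(348, 160, 3, scan_start_mm = 525)
#' attr(p, "total_overlap_mm")   # 132
#' attr(p, "overlap_ratio_pct")  # 38
#' @export
plan_wide_volume <- function(scan_length_mm, beam_width_mm, n_rotations,
                             scan_start_mm = 0) {
  if (!is_count(n_rotations)) {
    abort_fct("n_rotations must be a positive integer", "fetalct_param_error")
  }
  if (n_rotations * beam_width_mm < scan_length_mm) {
    abort_fct(sprintf("coverage impossible: %d x %g mm < %g mm scan length",
                      n_rotations, beam_width_mm, scan_length_mm),
              "fetalct_coverage_error")
  }
  l_snap <- snap_length(scan_length_mm)
  start0 <- 5 * floor(scan_start_mm / 5)
  # a rotation starting on the grid irradiates ceiling(BW/5) slabs
  if (n_rotations * 5 * ceiling(beam_width_mm / 5) < l_snap) {
    abort_fct("coverage impossible after snapping to the 5-mm grid",
              "fetalct_coverage_error")
  }
  n <- as.integer(n_rotations)
  ideal <- if (n == 1) start0 else
    start0 + (seq_len(n) - 1) * (l_snap - beam_width_mm) / (n - 1)
  starts <- snap_toward(ideal, start0)
  ends <- starts + beam_width_mm
  start_slab <- as.integer(starts / 5)
  end_slab <- as.integer(ceiling(ends / 5))

  covered <- sort(unique(unlist(mapply(seq, start_slab, end_slab - 1L,
                                       SIMPLIFY = FALSE))))
  want <- seq(start0 / 5, start0 / 5 + l_snap / 5 - 1)
  gap_free <- identical(as.integer(covered),
                        seq(min(covered), max(covered)))
  if (!gap_free || !all(want %in% covered)) {
    abort_fct("internal: rotation union does not cover the snapped scan range",
              "fetalct_coverage_error")
  }

  rot <- data.frame(rotation = seq_len(n), start_mm = starts, end_mm = ends,
                    start_slab = start_slab, end_slab = end_slab)
  new_rotation_plan(rot, mode = "wide_volume",
                    scan_length_mm = scan_length_mm,
                    snapped_length_mm = l_snap,
                    scan_start_mm = start0,
                    beam_width_mm = beam_width_mm,
                    n_rotations = n,
                    irradiated_length_mm = n * beam_width_mm,
                    total_overlap_mm = n * beam_width_mm - scan_length_mm)
}

#' Plan a helical acquisition
#'
#' A single interval of the snapped scan length; at pitch > 1 there is no
#' overlap between helical sections, and over-ranging is not modelled, so the
#' irradiated length equals the requested scan length.
#'
#' @param scan_length_mm Requested scan length (mm, > 0).
#' @param scan_start_mm Scan start in phantom coordinates (mm).
#' @return A `rotation_plan` with one row and `total_overlap_mm = 0`.
#' @export
plan_helical <- function(scan_length_mm, scan_start_mm = 0) {
  l_snap <- snap_length(scan_length_mm)
  start0 <- 5 * floor(scan_start_mm / 5)
  rot <- data.frame(rotation = 1L, start_mm = start0, end_mm = start0 + l_snap,
                    start_slab = as.integer(start0 / 5),
                    end_slab = as.integer((start0 + l_snap) / 5))
  new_rotation_plan(rot, mode = "helical",
                    scan_length_mm = scan_length_mm,
                    snapped_length_mm = l_snap,
                    scan_start_mm = start0,
                    beam_width_mm = l_snap,
                    n_rotations = 1L,
                    irradiated_length_mm = scan_length_mm,
                    total_overlap_mm = 0)
}

#' Overlap ratio of a wide-volume acquisition
#'
#' The total junction overlap is `N * BW - L`; its ratio to the scan length,
#' `100 * (N * BW - L) / L`, is the wide-volume dose-penalty figure of merit.
#' Note the paradoxical geometry: covering 348 mm with three 160-mm rotations
#' overlaps 38% of the scan length, while covering the longer 352 mm with four
#' narrower 120-mm rotations overlaps only 36%.
#'
#' @inheritParams plan_wide_volume
#' @return A list: `total_overlap_mm`, `percent` (integer, round-half-up) and
#'   `unrounded`.
#' @examples
#' overlap_ratio(348, 160, 3)$percent # 38
#' overlap_ratio(352, 120, 4)$percent # 36
#' @export
overlap_ratio <- function(scan_length_mm, beam_width_mm, n_rotations) {
  if (n_rotations * beam_width_mm < scan_length_mm) {
    abort_fct(sprintf("coverage impossible: %d x %g mm < %g mm scan length",
                      n_rotations, beam_width_mm, scan_length_mm),
              "fetalct_coverage_error")
  }
  ov <- n_rotations * beam_width_mm - scan_length_mm
  r <- 100 * ov / scan_length_mm
  list(total_overlap_mm = ov, percent = round_half_up(r), unrounded = r)
}

#' @export
print.rotation_plan <- function(x, ...) {
  cat(sprintf("%s plan: L = %g mm (entered %g), %d rotation(s) x %g mm\n",
              attr(x, "mode"), attr(x, "scan_length_mm"),
              attr(x, "snapped_length_mm"), attr(x, "n_rotations"),
              attr(x, "beam_width_mm")))
  if (attr(x, "mode") == "wide_volume") {
    cat(sprintf("  irradiated %g mm, overlap %g mm (%g%% of scan length)\n",
                attr(x, "irradiated_length_mm"), attr(x, "total_overlap_mm"),
                attr(x, "overlap_ratio_pct")))
  }
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Export a rotation plan as CSV
#'
#' Columns `rotation_index,start_mm,end_mm,start_slab,end_slab`.
#'
#' @param plan A `rotation_plan`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  out <- data.frame(rotation_index = plan$rotation, start_mm = plan$start_mm,
                    end_mm = plan$end_mm, start_slab = plan$start_slab,
                    end_slab = plan$end_slab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
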