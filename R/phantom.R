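# Slab geometry of the mathematical phantom and the organ roster used for
# dose accounting. The phantom spans head to mid-thigh as 208 axial slabs of
# 5 mm (1040 mm total); all slab coordinates are 0-based, half-open.

PHANTOM_N_SLABS <- 208L
PHANTOM_SLAB_MM <- 5

#' Construct a slab phantom
#'
#' A `ct_phantom` is the axial slab geometry of a stylized adult mathematical
#' phantom: 208 slabs of 5 mm from the crown of the head (slab 0) toward
#' mid-thigh, plus an organ roster giving each organ's axial extent as a
#' 0-based, half-open slab interval.
#'
#' @param organs Data frame with columns `organ` (character, unique),
#'   `slab_start`, `slab_end` (integers, `0 <= slab_start < slab_end <= 208`).
#' @param n_slabs,slab_thickness_mm Grid dimensions; fixed at 208 x 5 mm.
#' @return An object of class `ct_phantom`.
#' @seealso [default_pregnant_phantom()] for the bundled pregnant-adult roster.
#' @export
ct_phantom <- function(organs, n_slabs = PHANTOM_N_SLABS,
                       slab_thickness_mm = PHANTOM_SLAB_MM) {
  if (!is.data.frame(organs) ||
      !all(c("organ", "slab_start", "slab_end") %in% names(organs))) {
    abort_fct("`organs` must be a data frame with columns organ, slab_start, slab_end",
              "fetalct_format_error")
  }
  organs <- data.frame(organ = as.character(organs$organ),
                       slab_start = as.integer(organs$slab_start),
                       slab_end = as.integer(organs$slab_end),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(organs$organ)) {
    abort_fct("organ names must be unique", "fetalct_format_error")
  }
  bad <- organs$slab_start < 0L | organs$slab_start >= organs$slab_end |
    organs$slab_end > n_slabs
  if (any(bad)) {
    abort_fct(sprintf("invalid slab extent for organ(s): %s",
                      paste(organs$organ[bad], collapse = ", ")),
              "fetalct_bounds_error")
  }
  structure(list(slab_thickness_mm = slab_thickness_mm,
                 n_slabs = as.integer(n_slabs),
                 organs = organs),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("Slab phantom: %d slabs x %g mm (%g mm, crown to mid-thigh)\n",
              x$n_slabs, x$slab_thickness_mm, x$n_slabs * x$slab_thickness_mm))
  cat(sprintf("Organ roster: %d organs\n", nrow(x$organs)))
  invisible(x)
}

#' Convert a millimetre range to a slab interval
#'
#' Scan ranges must be entered on the phantom's 5-mm grid. The returned
#' interval is 0-based and half-open: `[start_mm/5, end_mm/5)`.
#'
#' @param start_mm,end_mm Axial positions in mm from the crown;
#'   `0 <= start_mm < end_mm <= 1040`, both multiples of 5.
#' @return Integer vector `c(start_slab, end_slab)` (half-open).
#' @examples
#' mm_to_slab_interval(0, 1040)  # the whole phantom, c(0, 208)
#' mm_to_slab_interval(600, 950) # 70 slabs
#' @export
mm_to_slab_interval <- function(start_mm, end_mm) {
  if (!is_num1(start_mm) || !is_num1(end_mm)) {
    abort_fct("positions must be single finite numbers", "fetalct_grid_error")
  }
  if (start_mm %% PHANTOM_SLAB_MM != 0 || end_mm %% PHANTOM_SLAB_MM != 0) {
    abort_fct(sprintf("positions must be multiples of %d mm", PHANTOM_SLAB_MM),
              "fetalct_grid_error")
  }
  if (start_mm < 0 || end_mm > PHANTOM_N_SLABS * PHANTOM_SLAB_MM ||
      start_mm >= end_mm) {
    abort_fct("range must satisfy 0 <= start_mm < end_mm <= 1040",
              "fetalct_bounds_error")
  }
  as.integer(c(start_mm, end_mm) / PHANTOM_SLAB_MM)
}

#' Convert a slab interval back to millimetres
#'
#' Inverse of [mm_to_slab_interval()]: the half-open slab interval
#' `[start_slab, end_slab)` maps back to `c(5 * start_slab, 5 * end_slab)` mm.
#'
#' @param start_slab,end_slab 0-based half-open slab interval.
#' @return Numeric vector `c(start_mm, end_mm)`.
#' @export
slab_interval_to_mm <- function(start_slab, end_slab) {
  if (start_slab < 0 || end_slab > PHANTOM_N_SLABS || start_slab >= end_slab) {
    abort_fct("slab interval must satisfy 0 <= start < end <= 208",
              "fetalct_bounds_error")
  }
  c(start_slab, end_slab) * PHANTOM_SLAB_MM
}

#' Bundled pregnant-adult slab phantom
#'
#' A deterministic, documented organ roster for a pregnant adult on the 208 x
#' 5 mm slab grid. The extents are a synthetic anatomical fixture (plausible
#' axial positions for a late-gestation adult), not measured geometry: the
#' gravid uterus (`uterus_fetus`) occupies slabs 128-152 (640-760 mm from the
#' crown), strictly inside the small-intestine-to-bladder span, so that
#' abdominopelvic scan ranges of 175-350 mm centred on the uterus cover it
#' fully while covering the stomach and liver only partially.
#'
#' The roster carries every ICRP-103 tissue needed for the female effective
#' dose, including the 13 female remainder tissues (see
#' [female_tissue_weights()]).
#'
#' @return A [ct_phantom] object; identical on every call.
#' @export
default_pregnant_phantom <- function() {
  organs <- data.frame(
    organ = c("brain", "oral_mucosa", "salivary_glands", "extrathoracic",
              "thyroid", "oesophagus", "thymus", "lungs", "breast", "heart",
              "liver", "stomach", "spleen", "adrenals", "pancreas", "kidneys",
              "gall_bladder", "colon", "small_intestine", "uterus_fetus",
              "ovaries", "bladder", "skin", "red_bone_marrow", "bone_surface",
              "lymphatic_nodes", "muscle"),
    slab_start = c(4L, 26L, 28L, 32L, 46L, 54L, 56L, 56L, 66L, 66L,
                   88L, 90L, 94L, 98L, 98L, 100L, 104L, 110L, 112L, 128L,
                   140L, 152L, 0L, 8L, 8L, 40L, 0L),
    slab_end = c(32L, 36L, 38L, 54L, 52L, 86L, 66L, 92L, 86L, 88L,
                 116L, 112L, 108L, 104L, 108L, 124L, 112L, 158L, 152L, 152L,
                 148L, 160L, 208L, 200L, 200L, 180L, 208L),
    stringsAsFactors = FALSE)
  ct_phantom(organs)
}

#' Axial extent of one organ
#'
#' @param phantom A [ct_phantom].
#' @param organ Organ name from the roster.
#' @return Integer `c(slab_start, slab_end)` (half-open).
#' @export
organ_extent <- function(phantom, organ) {
  i <- match(organ, phantom$organs$organ)
  if (is.na(i)) {
    abort_fct(sprintf("organ '%s' not in the phantom roster", organ),
              "fetalct_config_error")
  }
  c(phantom$organs$slab_start[i], phantom$organs$slab_end[i])
}

#' Default scan start for a given scan length
#'
#' Places the scan range centred on the uterus midpoint (the fetal CT
#' convention: scan length follows fetus length), with the start snapped down
#' to the 5-mm grid.
#'
#' @param phantom A [ct_phantom].
#' @param scan_length_mm Requested scan length in mm.
#' @return Scan start position in mm (grid-aligned).
#' @export
default_scan_start <- function(phantom, scan_length_mm) {
  ext <- organ_extent(phantom, "uterus_fetus")
  centre_mm <- mean(ext) * phantom$slab_thickness_mm
  l <- snap_length(scan_length_mm)
  start <- centre_mm - l / 2
  start <- PHANTOM_SLAB_MM * floor(start / PHANTOM_SLAB_MM)
  max(0, min(start, phantom$n_slabs * phantom$slab_thickness_mm - l))
}

#' Read or write a phantom organ roster as CSV
#'
#' Plain-text serialization with columns `organ,slab_start,slab_end`.
#'
#' @param phantom A [ct_phantom].
#' @param path File path.
#' @return `read_phantom()` returns a [ct_phantom]; `write_phantom()` returns
#'   `path` invisibly.
#' @export
write_phantom <- function(phantom, path) {
  utils::write.csv(phantom$organs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ct_phantom(tab)
}
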