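# Acquisition modelling: scanner descriptions, protocols, 5-mm grid snapping,
# and CTDIvol / DLP accounting (32-cm CTDI phantom convention).

#' Describe a CT scanner
#'
#' A `scanner_model` holds what the dose accounting needs: the acquisition
#' mode, the available beam widths (collimations), the mapping from beam width
#' to a beam-width class, and the weighted CTDI per 100 mAs (nCTDIw, 32-cm
#' phantom) for each class at each tube voltage.
#'
#' @param name Scanner label.
#' @param mode `"wide_volume"` (axial cone-beam rotations with overlapping
#'   junctions, pitch 1) or `"helical"` (single continuous acquisition, one
#'   collimation).
#' @param beam_widths Available beam widths in mm (helical: exactly one).
#' @param beam_class Named character vector mapping beam width (as character)
#'   to class label, e.g. `c("120" = "A", ...)`.
#' @param nctdiw Named numeric vector of nCTDIw (mGy per 100 mAs) per class.
#' @param kv Tube voltage the nCTDIw values apply to (default 100 kV).
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(name, mode = c("wide_volume", "helical"),
                          beam_widths, beam_class, nctdiw, kv = 100) {
  mode <- match.arg(mode)
  if (mode == "wide_volume" && length(beam_widths) < 1) {
    abort_fct("wide-volume scanner must list at least one beam width",
              "fetalct_config_error")
  }
  if (mode == "helical" && length(beam_widths) != 1) {
    abort_fct("helical scanner must have exactly one collimation",
              "fetalct_config_error")
  }
  miss <- setdiff(as.character(beam_widths), names(beam_class))
  if (length(miss)) {
    abort_fct(sprintf("no beam-width class for width(s): %s",
                      paste(miss, collapse = ", ")),
              "fetalct_config_error")
  }
  structure(list(name = name, mode = mode, beam_widths = beam_widths,
                 beam_class = beam_class, nctdiw = nctdiw, kv = kv),
            class = "scanner_model")
}

#' @export
print.scanner_model <- function(x, ...) {
  cat(sprintf("Scanner: %s (%s mode)\n", x$name, x$mode))
  cat(sprintf("  beam widths: %s mm\n", paste(x$beam_widths, collapse = ", ")))
  cat(sprintf("  nCTDIw [mGy/100 mAs]: %s\n",
              paste(sprintf("%s=%.3f", names(x$nctdiw), x$nctdiw),
                    collapse = ", ")))
  invisible(x)
}

#' Beam-width class of a collimation
#'
#' @param scanner A [scanner_model].
#' @param beam_width Beam width in mm.
#' @return Class label (character).
#' @export
beam_width_class <- function(scanner, beam_width) {
  i <- match(as.character(beam_width), names(scanner$beam_class))
  cl <- if (is.na(i)) NULL else scanner$beam_class[[i]]
  if (is.null(cl)) {
    abort_fct(sprintf("scanner '%s' has no class for beam width %g mm",
                      scanner$name, beam_width),
              "fetalct_config_error")
  }
  cl
}

#' Define an acquisition protocol
#'
#' @param kv Tube voltage (kV).
#' @param ma Tube current (mA).
#' @param rotation_time Gantry rotation time (s).
#' @param pitch Pitch factor; 1 for wide-volume, table feed per rotation over
#'   collimation for helical.
#' @param beam_width Nominal beam width (mm).
#' @param n_rotations Number of rotations (helical: 1).
#' @param scan_length Requested scan length (mm).
#' @param scan_start Scan start in phantom coordinates (mm from the crown), or
#'   `NULL` to centre the range on the uterus at run time.
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(kv = 100, ma, rotation_time, pitch = 1,
                          beam_width, n_rotations = 1L, scan_length,
                          scan_start = NULL) {
  for (nm in c("kv", "ma", "rotation_time", "pitch", "beam_width",
               "scan_length")) {
    v <- get(nm)
    if (!is_num1(v) || v < 0) {
      abort_fct(sprintf("`%s` must be a single non-negative number", nm),
                "fetalct_param_error")
    }
  }
  if (!is_count(n_rotations)) {
    abort_fct("`n_rotations` must be a positive integer", "fetalct_param_error")
  }
  structure(list(kv = as.numeric(kv), ma = as.numeric(ma),
                 rotation_time = as.numeric(rotation_time),
                 pitch = as.numeric(pitch), beam_width = as.numeric(beam_width),
                 n_rotations = as.integer(n_rotations),
                 scan_length = scan_length, scan_start = scan_start),
            class = "scan_protocol")
}

#' Snap a scan length to the 5-mm entry grid
#'
#' The slab phantom accepts scan lengths only in 5-mm steps. The default rule
#' is nearest multiple of 5 with ties rounded up; an override table reproduces
#' entered lengths that deviate from that rule (the bundled study entered 235,
#' 270 and 310 mm for requested lengths of 232, 264 and 306 mm — see
#' [study_length_overrides()]).
#'
#' @param scan_length_mm Requested scan length (> 0).
#' @param overrides Named numeric vector mapping requested length (as
#'   character) to entered length; defaults to the bundled study's table.
#' @return Snapped length in mm.
#' @examples
#' snap_length(176) # 175
#' snap_length(184) # 185
#' snap_length(348) # 350
#' @export
snap_length <- function(scan_length_mm, overrides = study_length_overrides()) {
  if (!is_num1(scan_length_mm) || scan_length_mm <= 0) {
    abort_fct("scan length must be > 0", "fetalct_param_error")
  }
  key <- as.character(scan_length_mm)
  if (!is.null(overrides) && key %in% names(overrides)) {
    return(unname(overrides[[key]]))
  }
  5 * round_half_up(scan_length_mm / 5)
}

#' Volume CT dose index of a protocol
#'
#' `CTDIvol = nCTDIw * (mA * rotation_time) / 100 / pitch`, with nCTDIw taken
#' from the scanner for the protocol's tube voltage and beam-width class
#' (32-cm phantom).
#'
#' @param protocol A [scan_protocol].
#' @param scanner A [scanner_model].
#' @return CTDIvol in mGy (unrounded).
#' @export
compute_ctdivol <- function(protocol, scanner) {
  if (!isTRUE(protocol$kv == scanner$kv)) {
    abort_fct(sprintf("scanner '%s' has no nCTDIw data at %g kV",
                      scanner$name, protocol$kv),
              "fetalct_config_error")
  }
  cl <- beam_width_class(scanner, protocol$beam_width)
  n <- scanner$nctdiw[[cl]]
  if (is.null(n)) {
    abort_fct(sprintf("missing nCTDIw for class '%s'", cl),
              "fetalct_config_error")
  }
  n * (protocol$ma * protocol$rotation_time) / 100 / protocol$pitch
}

#' Dose-length product
#'
#' `DLP = CTDIvol * irradiated length`, in mGy.cm. For wide-volume
#' acquisitions the irradiated length is `n_rotations * beam_width` (junction
#' overlaps irradiate tissue repeatedly and are counted); for helical it is
#' the scan length (over-ranging is not modelled). The unrounded value is
#' returned; consoles display [round_half_up()] of it.
#'
#' @param ctdivol CTDIvol in mGy.
#' @param irradiated_length_mm Irradiated length in mm.
#' @return DLP in mGy.cm, unrounded.
#' @examples
#' compute_dlp(2.9, 348)            # 100.92
#' round_half_up(compute_dlp(2.9, 348)) # 101, the console display
#' @export
compute_dlp <- function(ctdivol, irradiated_length_mm) {
  if (!is_num1(ctdivol) || !is_num1(irradiated_length_mm) ||
      ctdivol < 0 || irradiated_length_mm < 0) {
    abort_fct("CTDIvol and irradiated length must be >= 0",
              "fetalct_domain_error")
  }
  ctdivol * irradiated_length_mm / 10
}
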