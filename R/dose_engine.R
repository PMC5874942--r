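# Organ-dose integration over a rotation plan and the female-organ effective
# dose. The dose to the uterus is reported as the fetal dose.

#' ICRP-103 tissue weights, female organs only
#'
#' The standard tissue weighting factors restricted to organs present in a
#' female phantom: gonads (ovaries) 0.08; red bone marrow, colon, lung,
#' stomach and breast 0.12 each; bladder, liver, oesophagus and thyroid 0.04
#' each; skin, bone surface, brain and salivary glands 0.01 each; plus the
#' remainder weight 0.12 applied to the arithmetic mean dose of the 13 female
#' remainder tissues (adrenals, extrathoracic region, gall bladder, heart,
#' kidneys, lymphatic nodes, muscle, oral mucosa, pancreas, small intestine,
#' spleen, thymus, uterus). The configured weights sum to 1.00; because every
#' weighted tissue exists in the female phantom, the female-only restriction
#' here drops nothing, but the resulting effective dose is still an
#' approximation of the sex-averaged ICRP quantity.
#'
#' @param weights Named numeric vector of explicit tissue weights.
#' @param remainder Character vector naming the remainder tissues.
#' @param remainder_weight Weight applied to the mean remainder dose.
#' @return An object of class `tissue_weights`.
#' @export
female_tissue_weights <- function(
    weights = c(ovaries = 0.08,
                red_bone_marrow = 0.12, colon = 0.12, lungs = 0.12,
                stomach = 0.12, breast = 0.12,
                bladder = 0.04, liver = 0.04, oesophagus = 0.04,
                thyroid = 0.04,
                skin = 0.01, bone_surface = 0.01, brain = 0.01,
                salivary_glands = 0.01),
    remainder = c("adrenals", "extrathoracic", "gall_bladder", "heart",
                  "kidneys", "lymphatic_nodes", "muscle", "oral_mucosa",
                  "pancreas", "small_intestine", "spleen", "thymus",
                  "uterus_fetus"),
    remainder_weight = 0.12) {
  if (any(weights < 0) || remainder_weight < 0) {
    abort_fct("tissue weights must be >= 0", "fetalct_param_error")
  }
  total <- sum(weights) + remainder_weight
  if (total > 1 + 1e-12) {
    abort_fct(sprintf("configured weights sum to %.4f > 1", total),
              "fetalct_param_error")
  }
  structure(list(weights = weights, remainder = remainder,
                 remainder_weight = remainder_weight, total = total),
            class = "tissue_weights")
}

#' Integrate organ doses over a rotation plan
#'
#' The dose to organ T is the sum over rotations and over the slabs each
#' rotation irradiates of the normalized coefficient, times the effective
#' tube-current-time product:
#' `D_T = sum_rot sum_{i in rot} n[T, i] * (mAs_per_rotation / pitch)`.
#' A slab under a junction overlap contributes once per rotation covering it —
#' double or triple irradiation is exactly the wide-volume overlap penalty.
#'
#' @param coeffs A `dose_coeff_table` (see [generate_coefficients()]).
#' @param plan A `rotation_plan`.
#' @param mAs_per_rotation Tube current-time product per rotation (mA x s).
#' @param pitch Pitch factor; helical doses scale by `1 / pitch`.
#' @param beam_class Beam-width class selecting the coefficient matrix.
#' @return Named numeric vector of organ doses in mGy.
#' @export
integrate_organ_dose <- function(coeffs, plan, mAs_per_rotation, pitch = 1,
                                 beam_class = names(coeffs$classes)[1]) {
  m <- coeff_matrix(coeffs, beam_class)
  if (any(plan$start_slab < 0) || any(plan$end_slab > coeffs$n_slabs)) {
    abort_fct("rotation interval lies outside the phantom",
              "fetalct_bounds_error")
  }
  if (!is_num1(mAs_per_rotation) || mAs_per_rotation < 0 ||
      !is_num1(pitch) || pitch <= 0) {
    abort_fct("mAs must be >= 0 and pitch > 0", "fetalct_param_error")
  }
  # multiplicity of irradiation per slab (overlap slabs count once per rotation)
  mult <- numeric(coeffs$n_slabs)
  for (k in seq_len(nrow(plan))) {
    idx <- (plan$start_slab[k] + 1L):plan$end_slab[k]
    mult[idx] <- mult[idx] + 1
  }
  drop(m %*% mult) * (mAs_per_rotation / pitch)
}

#' Effective dose from an organ-dose map
#'
#' `E = sum_T w_T D_T + w_remainder * mean(D over the remainder set)`, in mSv
#' (numerically equal to mGy for the photon doses handled here).
#'
#' @param organ_dose Named numeric vector of organ doses in mGy.
#' @param weights A [female_tissue_weights()] object.
#' @return Effective dose in mSv.
#' @export
effective_dose <- function(organ_dose, weights = female_tissue_weights()) {
  need <- c(names(weights$weights), weights$remainder)
  miss <- setdiff(need, names(organ_dose))
  if (length(miss)) {
    abort_fct(sprintf("organ(s) in the weight table absent from the dose map: %s",
                      paste(miss, collapse = ", ")),
              "fetalct_config_error")
  }
  e <- sum(weights$weights * organ_dose[names(weights$weights)])
  if (length(weights$remainder) && weights$remainder_weight > 0) {
    e <- e + weights$remainder_weight * mean(organ_dose[weights$remainder])
  }
  e
}

#' Run one acquisition and assemble a dose report
#'
#' Plans the acquisition (wide-volume or helical), integrates the per-organ
#' doses over the plan, and computes CTDIvol, DLP (wide-volume irradiated
#' length `N x BW`; helical, the scan length), the female effective dose and
#' the fetal dose (the uterus dose, used as the fetal estimate).
#'
#' @param protocol A [scan_protocol].
#' @param scanner A [scanner_model].
#' @param phantom A [ct_phantom].
#' @param coeffs A `dose_coeff_table`.
#' @param weights Tissue weights for the effective dose.
#' @return An object of class `dose_report`: `organ_dose` (mGy),
#'   `fetal_dose` (mGy, identical to `organ_dose["uterus_fetus"]`),
#'   `effective_dose` (mSv), `ctdivol` (mGy), `dlp` (mGy.cm, unrounded), the
#'   `plan`, and the protocol and scanner echoes.
#' @export
run_acquisition <- function(protocol, scanner, phantom, coeffs,
                            weights = female_tissue_weights()) {
  start <- if (is.null(protocol$scan_start)) {
    default_scan_start(phantom, protocol$scan_length)
  } else protocol$scan_start
  if (scanner$mode == "wide_volume") {
    if (protocol$pitch != 1) {
      abort_fct("wide-volume acquisitions use pitch 1", "fetalct_param_error")
    }
    plan <- plan_wide_volume(protocol$scan_length, protocol$beam_width,
                             protocol$n_rotations, start)
  } else {
    if (protocol$n_rotations != 1L) {
      abort_fct("helical protocols are a single acquisition (n_rotations = 1)",
                "fetalct_param_error")
    }
    plan <- plan_helical(protocol$scan_length, start)
  }
  cl <- beam_width_class(scanner, protocol$beam_width)
  ctdivol <- compute_ctdivol(protocol, scanner)
  dlp <- compute_dlp(ctdivol, attr(plan, "irradiated_length_mm"))
  organ_dose <- integrate_organ_dose(coeffs, plan,
                                     protocol$ma * protocol$rotation_time,
                                     protocol$pitch, beam_class = cl)
  if (!"uterus_fetus" %in% names(organ_dose)) {
    abort_fct("coefficient table lacks the uterus_fetus organ",
              "fetalct_config_error")
  }
  structure(list(organ_dose = organ_dose,
                 fetal_dose = unname(organ_dose[["uterus_fetus"]]),
                 effective_dose = effective_dose(organ_dose, weights),
                 ctdivol = ctdivol, dlp = dlp, plan = plan,
                 protocol = protocol, scanner = scanner$name,
                 beam_class = cl),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("Dose report — %s\n", x$scanner))
  cat(sprintf("  %g kV, %g mA, %g s, pitch %g, BW %g mm x %d, L %g mm\n",
              p$kv, p$ma, p$rotation_time, p$pitch, p$beam_width,
              p$n_rotations, p$scan_length))
  cat(sprintf("  CTDIvol %.2f mGy   DLP %.1f mGy.cm (console: %d)\n",
              x$ctdivol, x$dlp, round_half_up(x$dlp)))
  cat(sprintf("  fetal dose %.3f mGy   effective dose %.3f mSv\n",
              x$fetal_dose, x$effective_dose))
  invisible(x)
}

#' @export
summary.dose_report <- function(object, ...) {
  print(object)
  d <- sort(object$organ_dose, decreasing = TRUE)
  cat("  top organ doses (mGy):\n")
  for (nm in names(d)[seq_len(min(6, length(d)))]) {
    cat(sprintf("    %-16s %.3f\n", nm, d[[nm]]))
  }
  invisible(object)
}

#' @export
as.data.frame.dose_report <- function(x, ...) {
  data.frame(organ = names(x$organ_dose), dose_mGy = unname(x$organ_dose),
             stringsAsFactors = FALSE)
}
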