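# Fetal-dose / DLP conversion analysis: ratio tables per scanner mode and the
# conservative (maximum rounded ratio) conversion-factor recommendation, which
# turns a console-displayed DLP into a fetal-dose estimate.

#' Fetal dose to DLP ratio
#'
#' @param fetal_dose Fetal dose in mGy (>= 0).
#' @param dlp Dose-length product in mGy.cm (> 0).
#' @return List with `ratio` (round-half-up to 2 decimals, cm^-1) and
#'   `unrounded`.
#' @examples
#' fetal_dlp_ratio(3.51, 62)$ratio  # 0.06
#' fetal_dlp_ratio(3.30, 101)$ratio # 0.03
#' @export
fetal_dlp_ratio <- function(fetal_dose, dlp) {
  if (!is_num1(dlp) || dlp <= 0) {
    abort_fct("DLP must be > 0", "fetalct_domain_error")
  }
  if (!is_num1(fetal_dose) || fetal_dose < 0) {
    abort_fct("fetal dose must be >= 0", "fetalct_domain_error")
  }
  r <- fetal_dose / dlp
  list(ratio = round_half_up(r, 2), unrounded = r)
}

#' Build a fetal-dose / DLP conversion table
#'
#' One row per acquisition, sorted by scan length, with the 2-decimal
#' round-half-up ratio alongside the exact one. Accepts either a list of
#' [run_acquisition()] dose reports (engine mode) or a data frame of
#' externally supplied dose/DLP pairs (reproduction mode, e.g.
#' [study_dose_table()]), with columns `scan_length_mm`, `dlp_mGycm`,
#' `fetal_dose_mGy` and optionally `beam_width_mm`, `n_rotations`.
#'
#' @param x List of `dose_report` objects, or a data frame as above.
#' @param mode Scanner-mode label for the table (e.g. `"wide_volume"`).
#' @return A data frame of class `conversion_table` with columns
#'   `scan_length_mm`, `beam_width_mm`, `n_rotations`, `dlp_mGycm`,
#'   `fetal_dose_mGy`, `ratio`, `ratio_unrounded`.
#' @export
build_conversion_table <- function(x, mode = "wide_volume") {
  if (is.data.frame(x)) {
    need <- c("scan_length_mm", "dlp_mGycm", "fetal_dose_mGy")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      abort_fct(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
                "fetalct_format_error")
    }
    tab <- data.frame(
      scan_length_mm = x$scan_length_mm,
      beam_width_mm = if ("beam_width_mm" %in% names(x)) x$beam_width_mm else NA,
      n_rotations = if ("n_rotations" %in% names(x)) x$n_rotations else NA,
      dlp_mGycm = x$dlp_mGycm,
      fetal_dose_mGy = x$fetal_dose_mGy,
      stringsAsFactors = FALSE)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "dose_report"))) {
    tab <- do.call(rbind, lapply(x, function(r) {
      data.frame(scan_length_mm = r$protocol$scan_length,
                 beam_width_mm = r$protocol$beam_width,
                 n_rotations = r$protocol$n_rotations,
                 dlp_mGycm = r$dlp, fetal_dose_mGy = r$fetal_dose,
                 stringsAsFactors = FALSE)
    }))
  } else {
    abort_fct("`x` must be a list of dose reports or a data frame",
              "fetalct_format_error")
  }
  if (is.null(tab) || nrow(tab) == 0) {
    abort_fct("cannot build a conversion table from zero acquisitions",
              "fetalct_format_error")
  }
  tab <- tab[order(tab$scan_length_mm), , drop = FALSE]
  rr <- lapply(seq_len(nrow(tab)),
               function(i) fetal_dlp_ratio(tab$fetal_dose_mGy[i], tab$dlp_mGycm[i]))
  tab$ratio <- vapply(rr, `[[`, 0, "ratio")
  tab$ratio_unrounded <- vapply(rr, `[[`, 0, "unrounded")
  rownames(tab) <- NULL
  structure(tab, mode = mode, class = c("conversion_table", "data.frame"))
}

#' Recommend a conversion factor
#'
#' To be conservative, the recommended fetal-dose conversion factor for a
#' scanner mode is the maximum of the table's rounded ratios: multiplying a
#' displayed DLP by it then never underestimates any tabulated fetal dose by
#' more than the 2-decimal rounding slack.
#'
#' @param table A [build_conversion_table()] result.
#' @return An object of class `conversion_factor`: `value` (cm^-1), `mode`,
#'   and the scan length attaining the maximum.
#' @export
recommend_conversion_factor <- function(table) {
  if (!inherits(table, "conversion_table") || nrow(table) == 0) {
    abort_fct("need a non-empty conversion table", "fetalct_format_error")
  }
  i <- which.max(table$ratio)
  structure(list(value = table$ratio[i], mode = attr(table, "mode"),
                 at_scan_length_mm = table$scan_length_mm[i],
                 provenance = "max over table rows"),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("Conversion factor (%s): %.2f cm^-1 (max ratio, at L = %g mm)\n",
              x$mode, x$value, x$at_scan_length_mm))
  invisible(x)
}

#' Estimate the fetal dose from a displayed DLP
#'
#' `fetal dose (mGy) = DLP (mGy.cm) x conversion factor (cm^-1)` — the
#' bedside estimate when no dosimetry software is at hand.
#'
#' @param displayed_dlp Console DLP in mGy.cm (>= 0).
#' @param cf A [recommend_conversion_factor()] object or a bare numeric factor.
#' @return Estimated fetal dose in mGy.
#' @examples
#' estimate_fetal_dose(100, 0.06) # 6 mGy
#' @export
estimate_fetal_dose <- function(displayed_dlp, cf) {
  if (!is_num1(displayed_dlp) || displayed_dlp < 0) {
    abort_fct("DLP must be >= 0", "fetalct_domain_error")
  }
  v <- if (inherits(cf, "conversion_factor")) cf$value else cf
  displayed_dlp * v
}

#' Write a conversion table / factors to disk
#'
#' @param table A `conversion_table`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(table, path) {
  out <- as.data.frame(table)[, c("scan_length_mm", "beam_width_mm",
                                  "n_rotations", "dlp_mGycm",
                                  "fetal_dose_mGy", "ratio")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
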