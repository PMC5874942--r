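# Normalized organ-dose coefficient tables. A table holds, per beam-width
# class, a matrix n[organ, slab] of organ dose (mGy) per mAs delivered while
# irradiating that slab. The synthetic generator emulates the structure of
# Monte Carlo normalized-dose data: a flat in-field plateau over the organ
# extent and exponentially decaying scatter tails, scaled by a beam-quality
# output factor proportional to the scanner's weighted CTDI (nCTDIw).

#' Parameters for the synthetic coefficient generator
#'
#' @param alpha Per-organ peak amplitude in mGy per mAs: a single number
#'   (applied to every organ) or a named vector keyed by organ. Default
#'   1.2e-3 mGy/mAs, giving in-field organ doses of a few mGy at typical
#'   low-dose fetal CT technique (about 50 mAs per rotation).
#' @param lambda Scatter decay length in slabs (single number or named vector).
#'   Default 10 slabs = 5 cm, a realistic body-scatter decay scale.
#' @param nctdiw Named vector of weighted CTDI per 100 mAs (mGy, 32-cm
#'   phantom), one entry per beam-width class. Defaults to the three classes of
#'   the bundled scanners (see [study_scanners()]).
#' @param kv Tube voltage in kV the table applies to (default 100).
#' @param reference_class Beam-width class whose nCTDIw defines output factor
#'   1; defaults to the first element of `nctdiw`.
#' @param jitter Multiplicative jitter fraction in `[0, 0.2]`; each coefficient
#'   is scaled by `1 + u`, `u ~ Uniform(-jitter, jitter)`. Default 0, so the
#'   generated table is an exact closed form.
#' @param seed Integer seed for the jitter draws.
#' @return An object of class `synth_coeff_params`.
#' @export
synth_coeff_params <- function(alpha = 1.2e-3, lambda = 10,
                               nctdiw = c(A = 2.6 * 100 / 51.5,
                                          B = 2.7 * 100 / 51.5,
                                          H = 2.9 * 1.39 * 100 / 80),
                               kv = 100, reference_class = names(nctdiw)[1],
                               jitter = 0, seed = 1L) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    abort_fct("alpha must be > 0", "fetalct_param_error")
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort_fct("lambda must be > 0", "fetalct_param_error")
  }
  if (is.null(names(nctdiw)) || any(!is.finite(nctdiw)) || any(nctdiw <= 0)) {
    abort_fct("nctdiw must be a named vector of positive values",
              "fetalct_param_error")
  }
  if (!is_num1(jitter) || jitter < 0 || jitter > 0.2) {
    abort_fct("jitter fraction must lie in [0, 0.2]", "fetalct_param_error")
  }
  if (!reference_class %in% names(nctdiw)) {
    abort_fct("reference_class must name an entry of nctdiw",
              "fetalct_param_error")
  }
  structure(list(alpha = alpha, lambda = lambda, nctdiw = nctdiw, kv = kv,
                 reference_class = reference_class, jitter = jitter,
                 seed = as.integer(seed)),
            class = "synth_coeff_params")
}

# Slab distance from an organ extent: 0 inside [start, end); adjacent slab
# has distance 1.
slab_distance <- function(slabs, slab_start, slab_end) {
  d <- pmax(slab_start - slabs, slabs - (slab_end - 1L))
  pmax(d, 0L)
}

per_organ <- function(x, organs) {
  if (is.null(names(x))) rep_len(x, length(organs)) else {
    miss <- setdiff(organs, names(x))
    if (length(miss)) {
      abort_fct(sprintf("no value for organ(s): %s", paste(miss, collapse = ", ")),
                "fetalct_param_error")
    }
    unname(x[organs])
  }
}

#' Generate a synthetic dose-coefficient table
#'
#' Builds, for every beam-width class, the matrix
#' `n[organ, slab] = output_factor * alpha_organ * exp(-d / lambda_organ) * (1 + jitter)`,
#' where `d` is the slab's distance from the organ extent (0 inside the organ)
#' and `output_factor = nctdiw(class) / nctdiw(reference class)`. The result is
#' deterministic for a fixed seed.
#'
#' @param phantom A [ct_phantom].
#' @param params A [synth_coeff_params] object.
#' @return An object of class `dose_coeff_table`: coefficient matrices keyed by
#'   beam-width class, with per-class output factors, the tube voltage and the
#'   organ roster.
#' @export
generate_coefficients <- function(phantom, params = synth_coeff_params()) {
  if (!inherits(phantom, "ct_phantom")) {
    abort_fct("`phantom` must be a ct_phantom", "fetalct_param_error")
  }
  if (!inherits(params, "synth_coeff_params")) {
    abort_fct("`params` must be synth_coeff_params()", "fetalct_param_error")
  }
  organs <- phantom$organs$organ
  alpha <- per_organ(params$alpha, organs)
  lambda <- per_organ(params$lambda, organs)
  slabs <- seq_len(phantom$n_slabs) - 1L

  base <- matrix(0, nrow = length(organs), ncol = phantom$n_slabs,
                 dimnames = list(organs, NULL))
  for (i in seq_along(organs)) {
    d <- slab_distance(slabs, phantom$organs$slab_start[i],
                       phantom$organs$slab_end[i])
    base[i, ] <- alpha[i] * exp(-d / lambda[i])
  }

  set.seed(params$seed)
  classes <- lapply(names(params$nctdiw), function(cl) {
    of <- params$nctdiw[[cl]] / params$nctdiw[[params$reference_class]]
    coeff <- base * of
    if (params$jitter > 0) {
      u <- matrix(stats::runif(length(coeff), -params$jitter, params$jitter),
                  nrow = nrow(coeff))
      coeff <- coeff * (1 + u)
    }
    list(coeff = coeff, output_factor = of)
  })
  names(classes) <- names(params$nctdiw)

  structure(list(kv = params$kv, classes = classes, organs = organs,
                 n_slabs = phantom$n_slabs,
                 reference_class = params$reference_class),
            class = "dose_coeff_table")
}

#' @export
print.dose_coeff_table <- function(x, ...) {
  cat(sprintf("Dose coefficient table: %d organs x %d slabs, %d kV\n",
              length(x$organs), x$n_slabs, x$kv))
  for (cl in names(x$classes)) {
    cat(sprintf("  class %s: output factor %.4f\n", cl,
                x$classes[[cl]]$output_factor))
  }
  invisible(x)
}

coeff_matrix <- function(coeffs, beam_class) {
  entry <- coeffs$classes[[beam_class]]
  if (is.null(entry)) {
    abort_fct(sprintf("no coefficients for beam-width class '%s'", beam_class),
              "fetalct_config_error")
  }
  entry$coeff
}

#' Write a dose-coefficient table to CSV
#'
#' Long format with columns `kv,beam_width_class,organ,slab,coefficient`
#' (slab 0-based) plus the per-class `output_factor`, so a written table reads
#' back losslessly.
#'
#' @param table A `dose_coeff_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(table, path) {
  rows <- do.call(rbind, lapply(names(table$classes), function(cl) {
    m <- table$classes[[cl]]$coeff
    data.frame(kv = table$kv, beam_width_class = cl,
               organ = rep(rownames(m), each = ncol(m)),
               slab = rep(seq_len(ncol(m)) - 1L, times = nrow(m)),
               coefficient = as.vector(t(m)),
               output_factor = table$classes[[cl]]$output_factor,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose-coefficient table from CSV
#'
#' Validates the format written by [write_coefficients()]: required columns,
#' non-negative coefficients, no duplicate `(kv, class, organ, slab)` keys, and
#' (when a phantom is supplied) only organs present in the roster.
#'
#' @param path CSV path.
#' @param phantom Optional [ct_phantom] to validate organ names against.
#' @return A `dose_coeff_table`.
#' @export
read_coefficients <- function(path, phantom = NULL) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    abort_fct(sprintf("cannot parse coefficient CSV: %s",
                                      conditionMessage(e)),
                              "fetalct_format_error")
                  })
  required <- c("kv", "beam_width_class", "organ", "slab", "coefficient")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    abort_fct(sprintf("coefficient CSV missing column(s): %s",
                      paste(miss, collapse = ", ")),
              "fetalct_format_error")
  }
  if (nrow(tab) == 0) {
    abort_fct("coefficient CSV contains no rows", "fetalct_format_error")
  }
  if (any(!is.finite(tab$coefficient)) || any(tab$coefficient < 0)) {
    abort_fct("coefficients must be finite and >= 0", "fetalct_format_error")
  }
  key <- paste(tab$kv, tab$beam_width_class, tab$organ, tab$slab)
  if (anyDuplicated(key)) {
    abort_fct("duplicate (kv, class, organ, slab) keys in coefficient CSV",
              "fetalct_format_error")
  }
  kv <- as.numeric(unique(tab$kv))
  if (length(kv) != 1) {
    abort_fct("coefficient CSV must hold a single tube voltage",
              "fetalct_format_error")
  }
  organs <- unique(tab$organ)
  if (!is.null(phantom)) {
    unknown <- setdiff(organs, phantom$organs$organ)
    if (length(unknown)) {
      abort_fct(sprintf("organ(s) not in the phantom roster: %s",
                        paste(unknown, collapse = ", ")),
                "fetalct_format_error")
    }
  }
  n_slabs <- max(tab$slab) + 1L
  classes <- lapply(split(tab, tab$beam_width_class), function(sub) {
    m <- matrix(0, nrow = length(organs), ncol = n_slabs,
                dimnames = list(organs, NULL))
    m[cbind(match(sub$organ, organs), sub$slab + 1L)] <- sub$coefficient
    of <- if ("output_factor" %in% names(sub)) sub$output_factor[1] else 1
    list(coeff = m, output_factor = of)
  })
  ref <- names(classes)[which.min(abs(vapply(classes, `[[`, 0, "output_factor") - 1))]
  structure(list(kv = kv, classes = classes, organs = organs,
                 n_slabs = n_slabs, reference_class = ref),
            class = "dose_coeff_table")
}
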