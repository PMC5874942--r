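# Independent brute-force oracle: enumerate every (rotation, slab) pair of a
# plan and accumulate coefficient * mAs / pitch. Kept loop-based and separate
# from the vectorized engine path.
brute_force_organ_dose <- function(coeffs, plan, mAs_per_rotation, pitch = 1,
                                   beam_class = names(coeffs$classes)[1]) {
  m <- coeffs$classes[[beam_class]]$coeff
  dose <- stats::setNames(numeric(nrow(m)), rownames(m))
  for (k in seq_len(nrow(plan))) {
    for (slab in plan$start_slab[k]:(plan$end_slab[k] - 1L)) {
      dose <- dose + m[, slab + 1L] * mAs_per_rotation / pitch
    }
  }
  dose
}

# A bare plan-shaped data frame from slab intervals (for engine-level tests
# that bypass the planner).
slab_plan <- function(start_slab, end_slab) {
  data.frame(rotation = seq_along(start_slab),
             start_mm = start_slab * 5, end_mm = end_slab * 5,
             start_slab = as.integer(start_slab),
             end_slab = as.integer(end_slab))
}

# Random small plans inside the phantom, for the oracle-equivalence property.
random_plan <- function(n_slabs = 208L, max_rotations = 4L) {
  n <- sample.int(max_rotations, 1L)
  start <- sample.int(n_slabs, n, replace = TRUE) - 1L
  width <- sample.int(40L, n, replace = TRUE)
  end <- pmin(start + width, n_slabs)
  slab_plan(start, end)
}

study_phantom <- default_pregnant_phantom()
study_coeffs <- generate_coefficients(study_phantom, synth_coeff_params())
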