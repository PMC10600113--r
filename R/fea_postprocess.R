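#' Von Mises stress from stress-tensor components
#'
#' Scalar failure criterion computed from the deviatoric part of the
#' Cauchy stress tensor. Component order is `(xx, yy, zz, xy, yz, xz)`;
#' solver exports differ, so reorder before calling if needed.
#'
#' @param sxx,syy,szz Normal stress components, MPa (vectorised).
#' @param sxy,syz,sxz Shear stress components, MPa.
#' @return Von Mises stress, MPa (non-negative). Invariant under addition
#'   of hydrostatic stress.
#' @examples
#' von_mises(5, 0, 0, 0, 0, 0) # 5 (uniaxial)
#' von_mises(0, 0, 0, 1, 0, 0) # sqrt(3) (pure shear)
#' @export
von_mises <- function(sxx, syy, szz, sxy, syz, sxz) {
  for (nm in c("sxx", "syy", "szz", "sxy", "syz", "sxz")) {
    check_finite(get(nm), nm)
  }
  sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
         3 * (sxy^2 + syz^2 + sxz^2))
}

# Normalize an element table to (element_id, weight, svm); accepts either a
# precomputed von Mises column or the 6 tensor components.
as_element_field <- function(field) {
  stopifnot(is.data.frame(field))
  if (nrow(field) == 0L) pj_stop("invalid_field", "element table is empty")
  if (!all(c("element_id", "weight") %in% names(field))) {
    pj_stop("schema", "element table needs columns `element_id`, `weight`")
  }
  if (anyDuplicated(field$element_id)) {
    pj_stop("schema", "element ids must be unique")
  }
  if (anyNA(field$weight) || any(field$weight <= 0)) {
    pj_stop("invalid_field", "element weights must be positive")
  }
  tensor <- c("sxx", "syy", "szz", "sxy", "syz", "sxz")
  if ("svm" %in% names(field)) {
    check_finite(field$svm, "svm")
    if (any(field$svm < 0)) pj_stop("invalid_field", "`svm` must be non-negative")
    svm <- field$svm
  } else if (all(tensor %in% names(field))) {
    svm <- von_mises(field$sxx, field$syy, field$szz,
                     field$sxy, field$syz, field$sxz)
  } else {
    pj_stop("schema",
            "element table needs either `svm` or all of sxx,syy,szz,sxy,syz,sxz")
  }
  data.frame(element_id = field$element_id, weight = field$weight, svm = svm)
}

#' Mesh-Weighted Arithmetic Mean of a per-element stress field
#'
#' Element-size-weighted mean of von Mises stress,
#' `MWAM = sum(svm_i * w_i) / sum(w_i)`, which corrects for mesh
#' heterogeneity and damps artefactually high values carried by tiny
#' elements. Weights are element volumes for solid (tetrahedral) meshes and
#' areas for shells; the schema carries a generic `weight` column.
#' Sums are accumulated in extended precision, so multi-million-element
#' fields are summed stably.
#'
#' @param field Data frame with columns `element_id`, `weight` and either
#'   `svm` (precomputed von Mises stress, MPa) or the six tensor components
#'   `sxx, syy, szz, sxy, syz, sxz`.
#' @param exclude Optional vector of element ids to drop before averaging
#'   (e.g. elements adjacent to point constraints). No heuristic exclusion
#'   is ever applied automatically.
#' @return MWAM in MPa.
#' @examples
#' mwam(data.frame(element_id = 1:2, weight = c(1, 3), svm = c(2, 4))) # 3.5
#' @export
mwam <- function(field, exclude = NULL) {
  f <- as_element_field(field)
  if (!is.null(exclude)) f <- f[!f$element_id %in% exclude, , drop = FALSE]
  if (nrow(f) == 0L) pj_stop("invalid_field", "no elements left after exclusion")
  sum(f$svm * f$weight) / sum(f$weight)
}

#' Weight fraction of a field above a stress cap
#'
#' Fraction of total element weight carried by elements whose von Mises
#' stress exceeds `cap` (the hot-spot display threshold; 4 MPa in the
#' packaged analyses).
#'
#' @inheritParams mwam
#' @param cap Stress cap, MPa (positive).
#' @return Fraction in `[0, 1]`.
#' @export
stress_cap_fraction <- function(field, cap = 4, exclude = NULL) {
  check_positive(cap, "cap")
  f <- as_element_field(field)
  if (!is.null(exclude)) f <- f[!f$element_id %in% exclude, , drop = FALSE]
  if (nrow(f) == 0L) pj_stop("invalid_field", "no elements left after exclusion")
  sum(f$weight[f$svm > cap]) / sum(f$weight)
}

#' Summary statistics for one FE model
#'
#' @inheritParams stress_cap_fraction
#' @param model_id Label for the model (e.g. `"Euoplocephalus_cranium"`).
#' @return A list of class `"paleojaw_model_summary"` with `model_id`,
#'   `MWAM_MPa`, `n_elements`, `min/median/max_MPa` and
#'   `frac_weight_above_cap`.
#' @export
summarize_stress_field <- function(field, model_id = "model", cap = 4,
                                   exclude = NULL) {
  f <- as_element_field(field)
  if (!is.null(exclude)) f <- f[!f$element_id %in% exclude, , drop = FALSE]
  if (nrow(f) == 0L) pj_stop("invalid_field", "no elements left after exclusion")
  structure(list(
    model_id = model_id,
    MWAM_MPa = sum(f$svm * f$weight) / sum(f$weight),
    n_elements = nrow(f),
    min_MPa = min(f$svm),
    median_MPa = median(f$svm),
    max_MPa = max(f$svm),
    cap_MPa = cap,
    frac_weight_above_cap = sum(f$weight[f$svm > cap]) / sum(f$weight)
  ), class = "paleojaw_model_summary")
}

#' @export
print.paleojaw_model_summary <- function(x, ...) {
  cat(sprintf("FE model summary: %s\n", x$model_id))
  cat(sprintf("  elements: %d   MWAM: %.6g MPa\n", x$n_elements, x$MWAM_MPa))
  cat(sprintf("  min/median/max: %.4g / %.4g / %.4g MPa\n",
              x$min_MPa, x$median_MPa, x$max_MPa))
  cat(sprintf("  weight fraction above %.3g MPa: %.4g\n",
              x$cap_MPa, x$frac_weight_above_cap))
  invisible(x)
}

#' Paired comparison of an original and a hypothetical model
#'
#' Signed percent difference in MWAM between a baseline model and an
#' altered (e.g. secondary-palate-removed) model:
#' `100 * (hypothetical - original) / original`.
#'
#' @param original,hypothetical Either `"paleojaw_model_summary"` objects or
#'   bare MWAM values in MPa.
#' @return Signed percent difference.
#' @examples
#' compare_models(0.40, 0.38) # -5
#' @export
compare_models <- function(original, hypothetical) {
  get_mwam <- function(x) {
    if (inherits(x, "paleojaw_model_summary")) x$MWAM_MPa else as.numeric(x)
  }
  o <- get_mwam(original)
  h <- get_mwam(hypothetical)
  if (!is.finite(o) || o <= 0) {
    pj_stop("undefined_comparison", "baseline MWAM must be positive")
  }
  check_finite(h, "hypothetical")
  100 * (h - o) / o
}
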