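#' Muscle fibre length from muscle length
#'
#' Fibre length is approximated as one third of the reconstructed muscle
#' length, the convention of the dry-skull method for parallel-fibred
#' reptilian jaw adductors without measurable pennation.
#'
#' @param ML_mm Muscle length in mm (vectorised). Must be positive.
#' @return Fibre length in mm, at full floating precision.
#' @examples
#' fibre_length(196.6) # 65.53
#' @export
fibre_length <- function(ML_mm) {
  check_positive(ML_mm, "ML_mm")
  ML_mm / 3
}

#' Dry-skull muscle force estimates
#'
#' Implements the dry-skull chain for a table of reconstructed muscles:
#' fibre length `FL = ML/3`, physiological cross-sectional area
#' `PCSA = MV/FL`, and isometric force `F_mus = PCSA * sigma`. All
#' computation is at full floating precision; nothing is rounded before the
#' next step.
#'
#' @param muscles Data frame with columns `muscle`, `ML_mm`, `MV_mm3`
#'   (muscle label, muscle length in mm, muscle volume in mm^3). Muscle
#'   names must be unique.
#' @param sigma Isometric muscle stress in N mm^-2. Default 0.3, the
#'   standard value for reptilian jaw adductors; exposed for sensitivity
#'   analyses.
#' @return The input data frame with columns `FL_mm`, `PCSA_mm2`, `F_mus_N`
#'   appended.
#' @seealso [relative_forces()], [scale_isometric()], [muscle_force_table()]
#' @examples
#' m <- data.frame(muscle = "mAMEP", ML_mm = 196.6, MV_mm3 = 47100)
#' muscle_forces(m) # PCSA ~ 718.9 mm^2, F ~ 215.7 N
#' @export
muscle_forces <- function(muscles, sigma = 0.3) {
  stopifnot(is.data.frame(muscles))
  need <- c("muscle", "ML_mm", "MV_mm3")
  if (!all(need %in% names(muscles))) {
    pj_stop("schema", paste("`muscles` needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(muscles) == 0L) pj_stop("empty_input", "`muscles` has no rows")
  if (anyDuplicated(muscles$muscle)) {
    pj_stop("schema", "muscle names must be unique within a skull")
  }
  check_positive(muscles$ML_mm, "ML_mm")
  check_positive(muscles$MV_mm3, "MV_mm3")
  check_positive(sigma, "sigma")
  out <- muscles
  out$FL_mm <- fibre_length(muscles$ML_mm)
  out$PCSA_mm2 <- muscles$MV_mm3 / out$FL_mm
  out$F_mus_N <- out$PCSA_mm2 * sigma
  out
}

#' Relative muscle force
#'
#' Each muscle's percentage contribution to the summed force of its skull.
#'
#' @param F_N Numeric vector of per-muscle forces (N) for one skull.
#' @return Percentages summing to 100.
#' @examples
#' relative_forces(c(3, 1)) # 75, 25
#' @export
relative_forces <- function(F_N) {
  if (length(F_N) == 0L) pj_stop("empty_input", "no forces supplied")
  check_positive(F_N, "F_N")
  100 * F_N / sum(F_N)
}

#' Isometric force scaling between skulls
#'
#' Scales a force from a source skull to the size of a reference skull by
#' the ratio of their total surface areas. Muscle force is proportional to
#' cross-sectional area, which under isometry scales as L^2 exactly like
#' surface area, so the ratio enters to the first power.
#'
#' @param F_N Force in N (vectorised).
#' @param S_source_mm2 Total skull surface area of the source skull, mm^2.
#' @param S_reference_mm2 Total skull surface area of the reference skull, mm^2.
#' @return Scaled force in N.
#' @examples
#' scale_isometric(122.9, 615095, 867054) # 173.2
#' @export
scale_isometric <- function(F_N, S_source_mm2, S_reference_mm2) {
  check_positive(S_source_mm2, "S_source_mm2")
  check_positive(S_reference_mm2, "S_reference_mm2")
  if (anyNA(F_N) || !is.numeric(F_N)) {
    pj_stop("invalid_measurement", "`F_N` must be numeric and non-missing")
  }
  F_N * (S_reference_mm2 / S_source_mm2)
}

#' Full muscle-force table for one skull
#'
#' Runs the dry-skull chain over a skull's muscle set and appends relative
#' muscle force (RMF, % of the skull total) and, when a reference surface
#' area is given, isometrically scaled forces.
#'
#' @inheritParams muscle_forces
#' @param S_mm2 Total surface area (cranium + mandibles) of this skull, mm^2.
#'   Required when `S_reference_mm2` is given.
#' @param S_reference_mm2 Optional reference surface area to scale forces to.
#' @return Data frame with columns `muscle`, `ML_mm`, `FL_mm`, `MV_mm3`,
#'   `PCSA_mm2`, `F_mus_N`, (`F_scaled_N`,) `RMF_pct`. Forces are unilateral
#'   (per side), following the convention of the packaged measurements.
#' @examples
#' tab <- muscle_force_table(ankylosaur_muscles("Panoplosaurus"),
#'                           S_mm2 = 615095, S_reference_mm2 = 867054)
#' sum(tab$F_scaled_N) # ~ 2014 N
#' @export
muscle_force_table <- function(muscles, sigma = 0.3, S_mm2 = NULL,
                               S_reference_mm2 = NULL) {
  out <- muscle_forces(muscles, sigma = sigma)
  if (!is.null(S_reference_mm2)) {
    if (is.null(S_mm2)) {
      pj_stop("schema", "`S_mm2` is required when scaling to a reference area")
    }
    out$F_scaled_N <- scale_isometric(out$F_mus_N, S_mm2, S_reference_mm2)
  }
  out$RMF_pct <- relative_forces(out$F_mus_N)
  cols <- c("muscle", "ML_mm", "FL_mm", "MV_mm3", "PCSA_mm2", "F_mus_N",
            if (!is.null(S_reference_mm2)) "F_scaled_N", "RMF_pct")
  extra <- setdiff(names(out), cols)
  out[, c(cols, extra), drop = FALSE]
}
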