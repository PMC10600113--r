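deg2rad <- function(x) x * pi / 180

#' Resultant (bite-direction) muscle force
#'
#' Resolves a muscle force along the biting direction given its deviation
#' from vertical measured in the sagittal plane (`alpha`) and the coronal
#' plane (`beta`): `F_res = F_mus * cos(alpha) * cos(beta)`.
#'
#' @param F_mus_N Muscle force in N (non-negative, vectorised).
#' @param alpha_deg Sagittal insertion angle, degrees, in `[0, 90)`.
#' @param beta_deg Coronal insertion angle, degrees, in `[0, 90)`.
#' @return Resultant force in N.
#' @examples
#' resultant_force(232.6, 36, 5.3) # ~ 187.4
#' @export
resultant_force <- function(F_mus_N, alpha_deg, beta_deg) {
  if (anyNA(F_mus_N) || any(F_mus_N < 0)) {
    pj_stop("invalid_measurement", "`F_mus_N` must be non-negative")
  }
  for (a in list(alpha_deg = alpha_deg, beta_deg = beta_deg)) {
    if (anyNA(a) || any(a < 0) || any(a >= 90)) {
      pj_stop("invalid_orientation",
              "insertion angles must lie in [0, 90) degrees")
    }
  }
  F_mus_N * cos(deg2rad(alpha_deg)) * cos(deg2rad(beta_deg))
}

#' Perpendicular in-lever from diagonal distance and angle q
#'
#' The in-lever is the perpendicular distance from the jaw joint to a
#' muscle's line of action, computed as `d * sin(q)` where `d` is the
#' diagonal distance from the joint to the mandibular insertion and `q` the
#' angle between the line of action and `d`. Because a moment arm cannot
#' exceed `d`, angles past 90 degrees are replaced by their supplement
#' (`180 - q`), so the result always lies in `(0, d]`.
#'
#' @param d_mm Diagonal distance joint-to-insertion, mm (positive).
#' @param q_deg Angle between line of action and `d`, degrees, in (0, 180).
#' @return In-lever length in mm.
#' @examples
#' in_lever(59.60, 68.1)  # 55.30
#' in_lever(49.10, 144.5) # 28.51 (supplement 35.5 deg)
#' @export
in_lever <- function(d_mm, q_deg) {
  check_positive(d_mm, "d_mm")
  if (anyNA(q_deg) || any(q_deg <= 0) || any(q_deg >= 180)) {
    pj_stop("invalid_orientation", "`q_deg` must lie in (0, 180) degrees")
  }
  q_eff <- ifelse(q_deg > 90, 180 - q_deg, q_deg)
  d_mm * sin(deg2rad(q_eff))
}

#' Per-muscle bite force from the third-class lever model
#'
#' Moment balance about the jaw joint, `F_bite * L_out = F_res * L_in`,
#' with the resultant force from [resultant_force()]:
#' `F_bite = F_mus * cos(alpha) * cos(beta) * L_in / L_out`. Summing over
#' muscles gives the scenario total.
#'
#' @inheritParams resultant_force
#' @param L_in_mm Perpendicular in-lever, mm (positive).
#' @param L_out_mm Out-lever (jaw joint to bite point), mm (positive).
#' @return Bite-force contribution in N.
#' @examples
#' bite_force(307.3, 38, 9.7, 47.62, 270.5) # ~ 42.0
#' @export
bite_force <- function(F_mus_N, alpha_deg, beta_deg, L_in_mm, L_out_mm) {
  check_positive(L_in_mm, "L_in_mm")
  check_positive(L_out_mm, "L_out_mm")
  resultant_force(F_mus_N, alpha_deg, beta_deg) * L_in_mm / L_out_mm
}

#' Mechanical advantage
#'
#' Ratio of in-lever to out-lever; the efficiency of force transfer of the
#' jaw lever. Values below 1 mark a third-class (speed-favouring) lever.
#'
#' @inheritParams bite_force
#' @return Dimensionless mechanical advantage.
#' @examples
#' mechanical_advantage(55.30, 101.0) # 0.548
#' @export
mechanical_advantage <- function(L_in_mm, L_out_mm) {
  check_positive(L_in_mm, "L_in_mm")
  check_positive(L_out_mm, "L_out_mm")
  L_in_mm / L_out_mm
}

#' Bite-force and mechanical-advantage report for one skull
#'
#' Assembles the full lever-mechanics table: per-muscle resultant forces,
#' in-levers, bite-force contributions and mechanical advantage at each
#' named bite point, plus per-scenario totals.
#'
#' Bite forces are always computed from `F_mus` via the resultant-force
#' equation, never from an externally supplied resultant column. If a lever
#' row supplies a measured `L_in_mm` it is used as-is; otherwise the
#' in-lever is derived from `d` and `q` via [in_lever()].
#'
#' @param forces Data frame with columns `muscle`, `F_mus_N` and optionally
#'   `F_scaled_N` (e.g. from [muscle_force_table()]).
#' @param levers Data frame with columns `muscle`, `alpha_deg`, `beta_deg`,
#'   `d_mm`, `q_deg` and optionally `L_in_mm` (NA entries are derived).
#'   Every muscle in `forces` must have a lever row.
#' @param scenarios Data frame with columns `scenario`, `L_out_mm`, one row
#'   per bite point (e.g. muzzle / anterior / posterior).
#' @param use_scaled If `TRUE`, bite forces use the `F_scaled_N` column.
#' @return An object of class `"paleojaw_bite_report"`: a list with
#'   `per_muscle` (muscle, F_mus_N, F_res_N, L_in_mm), `bite` (long data
#'   frame: muscle x scenario with F_bite_N and MA) and `totals` (scenario,
#'   F_bite_total_N). Forces are unilateral (per side).
#' @examples
#' fr <- muscle_forces(ankylosaur_muscles("Euoplocephalus"))
#' rep <- bite_report(fr, ankylosaur_levers("Euoplocephalus"),
#'                    ankylosaur_bite_points("Euoplocephalus"))
#' rep$totals
#' @export
bite_report <- function(forces, levers, scenarios, use_scaled = FALSE) {
  stopifnot(is.data.frame(forces), is.data.frame(levers), is.data.frame(scenarios))
  if (nrow(scenarios) == 0L) pj_stop("empty_input", "no bite scenarios supplied")
  fcol <- if (use_scaled) "F_scaled_N" else "F_mus_N"
  if (!fcol %in% names(forces)) {
    pj_stop("schema", sprintf("`forces` lacks column `%s`", fcol))
  }
  missing <- setdiff(forces$muscle, levers$muscle)
  if (length(missing)) {
    pj_stop("schema", paste("no lever row for muscle(s):",
                            paste(missing, collapse = ", ")))
  }
  lv <- levers[match(forces$muscle, levers$muscle), , drop = FALSE]
  L_in <- if ("L_in_mm" %in% names(lv)) lv$L_in_mm else rep(NA_real_, nrow(lv))
  derive <- is.na(L_in)
  if (any(derive)) L_in[derive] <- in_lever(lv$d_mm[derive], lv$q_deg[derive])

  F_mus <- forces[[fcol]]
  F_res <- resultant_force(F_mus, lv$alpha_deg, lv$beta_deg)
  per_muscle <- data.frame(muscle = forces$muscle, F_mus_N = F_mus,
                           F_res_N = F_res, L_in_mm = L_in,
                           stringsAsFactors = FALSE)

  bite <- do.call(rbind, lapply(seq_len(nrow(scenarios)), function(i) {
    L_out <- scenarios$L_out_mm[i]
    data.frame(
      muscle = forces$muscle,
      scenario = scenarios$scenario[i],
      L_out_mm = L_out,
      F_bite_N = F_res * L_in / L_out,
      MA = mechanical_advantage(L_in, L_out),
      stringsAsFactors = FALSE
    )
  }))
  totals <- stats::aggregate(F_bite_N ~ scenario, data = bite, FUN = sum)
  names(totals)[2] <- "F_bite_total_N"
  totals <- totals[match(scenarios$scenario, totals$scenario), , drop = FALSE]
  rownames(totals) <- NULL

  structure(list(per_muscle = per_muscle, bite = bite, totals = totals,
                 use_scaled = use_scaled),
            class = "paleojaw_bite_report")
}

#' @export
print.paleojaw_bite_report <- function(x, ...) {
  cat("Bite-force report (", nrow(x$per_muscle), " muscles, ",
      nrow(x$totals), " bite points",
      if (isTRUE(x$use_scaled)) ", scaled forces", ")\n", sep = "")
  cat("Per-scenario totals (N):\n")
  print(x$totals, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Flatten a bite report to one data frame
#'
#' One row per muscle x scenario plus one `TOTAL` row per scenario; fixed
#' column order (`muscle`, `scenario`, `F_mus_N`, `F_res_N`, `L_in_mm`,
#' `L_out_mm`, `F_bite_N`, `MA`) for diffable CSV output.
#'
#' @param x A `"paleojaw_bite_report"`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.paleojaw_bite_report <- function(x, ...) {
  pm <- x$per_muscle[match(x$bite$muscle, x$per_muscle$muscle), , drop = FALSE]
  long <- data.frame(muscle = x$bite$muscle, scenario = x$bite$scenario,
                     F_mus_N = pm$F_mus_N, F_res_N = pm$F_res_N,
                     L_in_mm = pm$L_in_mm, L_out_mm = x$bite$L_out_mm,
                     F_bite_N = x$bite$F_bite_N, MA = x$bite$MA,
                     stringsAsFactors = FALSE)
  tot <- data.frame(muscle = "TOTAL", scenario = x$totals$scenario,
                    F_mus_N = NA_real_, F_res_N = NA_real_, L_in_mm = NA_real_,
                    L_out_mm = NA_real_, F_bite_N = x$totals$F_bite_total_N,
                    MA = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(long, tot)
  out <- out[order(match(out$scenario, x$totals$scenario),
                   out$muscle == "TOTAL"), ]
  rownames(out) <- NULL
  out
}
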