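write_stable_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full skull-biomechanics analysis
#'
#' Chains the stages in methods order — muscle forces, isometric scaling,
#' bite forces and mechanical advantage, MWAM stress summaries, mechanical
#' advantage evolution — over a validated dataset, writing one file per
#' product plus a run manifest. A failure in any stage aborts with the
#' stage name; files already written are preserved. Output bytes depend
#' only on the inputs and config (no timestamps), so a rerun with the same
#' config and seed reproduces the bundle exactly.
#'
#' Products (per available inputs): `muscle_forces_<skull>.csv`,
#' `bite_report_<skull>.csv` (plus `_scaled` for non-reference skulls when
#' a `scale_reference` is set), `mechanical_advantage.csv`,
#' `mwam_summaries.json` (with a signed percent difference when element
#' tables named `original` and `hypothetical` are both given),
#' `calibrated_tree.nwk`, `asr.csv`, `phylomorphospace_points.csv`,
#' `phylomorphospace_edges.csv`, `manifest.json`.
#'
#' @param config A config list (see [validate_and_load()]) or an already
#'   validated `"paleojaw_dataset"`.
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress per-stage messages (logged to stderr otherwise).
#' @return Invisibly, a named list of the files written.
#' @export
run_full_analysis <- function(config, out_dir, quiet = FALSE) {
  ds <- if (inherits(config, "paleojaw_dataset")) config else validate_and_load(config)
  cfg <- ds$config
  dat <- ds$data
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[paleojaw] ", sprintf(...))
  written <- list()
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e) {
      pj_stop("stage", sprintf("stage `%s` failed: %s (partial outputs kept in %s)",
                               name, conditionMessage(e), out_dir))
    })
  }

  ref <- cfg$scale_reference
  S_ref <- if (!is.null(ref)) dat$skulls$S_mm2[dat$skulls$skull == ref] else NULL

  force_tabs <- list()
  stage("muscle forces", {
    for (sk in unique(dat$muscles$skull)) {
      m <- dat$muscles[dat$muscles$skull == sk, , drop = FALSE]
      S <- dat$skulls$S_mm2[dat$skulls$skull == sk]
      tab <- muscle_force_table(m[, c("muscle", "ML_mm", "MV_mm3")],
                                sigma = cfg$sigma, S_mm2 = S,
                                S_reference_mm2 = S_ref)
      force_tabs[[sk]] <- tab
      f <- file.path(out_dir, sprintf("muscle_forces_%s.csv", sk))
      written[[paste0("muscle_forces_", sk)]] <- write_stable_csv(tab, f)
    }
  })

  ma_rows <- list()
  stage("bite forces and mechanical advantage", {
    for (sk in names(force_tabs)) {
      lv <- dat$levers[dat$levers$skull == sk, , drop = FALSE]
      sc <- dat$scenarios[dat$scenarios$skull == sk, , drop = FALSE]
      rep <- bite_report(force_tabs[[sk]], lv, sc)
      f <- file.path(out_dir, sprintf("bite_report_%s.csv", sk))
      written[[paste0("bite_report_", sk)]] <- write_stable_csv(as.data.frame(rep), f)
      ma_rows[[sk]] <- cbind(skull = sk,
                              rep$bite[, c("muscle", "scenario", "MA")])
      if (!is.null(ref) && sk != ref) {
        reps <- bite_report(force_tabs[[sk]], lv, sc, use_scaled = TRUE)
        fs <- file.path(out_dir, sprintf("bite_report_%s_scaled.csv", sk))
        written[[paste0("bite_report_", sk, "_scaled")]] <-
          write_stable_csv(as.data.frame(reps), fs)
      }
    }
    written$mechanical_advantage <- write_stable_csv(
      do.call(rbind, ma_rows), file.path(out_dir, "mechanical_advantage.csv"))
  })

  if (!is.null(dat$elements)) {
    stage("MWAM stress summaries", {
      sums <- lapply(names(dat$elements), function(nm) {
        s <- summarize_stress_field(dat$elements[[nm]], model_id = nm,
                                    cap = cfg$cap)
        unclass(s)
      })
      names(sums) <- names(dat$elements)
      out <- list(models = sums)
      if (all(c("original", "hypothetical") %in% names(sums))) {
        out$percent_difference_MWAM <- compare_models(
          sums$original$MWAM_MPa, sums$hypothetical$MWAM_MPa)
      }
      f <- file.path(out_dir, "mwam_summaries.json")
      jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written$mwam_summaries <- f
    })
  }

  if (!is.null(dat$tree) && !is.null(dat$ranges) && !is.null(dat$traits)) {
    stage("mechanical advantage evolution", {
      tt <- equal_timescale(dat$tree, dat$ranges, root_buffer = cfg$root_buffer)
      f_tree <- file.path(out_dir, "calibrated_tree.nwk")
      ape::write.tree(tt, file = f_tree)
      written$calibrated_tree <- f_tree

      ama <- setNames(dat$traits$AMA, dat$traits$species)
      pma <- setNames(dat$traits$PMA, dat$traits$species)
      asr_a <- bm_asr(tt, ama)
      asr_p <- bm_asr(tt, pma)
      asr <- data.frame(node = as.integer(names(asr_a$ace)),
                        AMA = unname(asr_a$ace), AMA_var = unname(asr_a$var),
                        PMA = unname(asr_p$ace), PMA_var = unname(asr_p$var))
      written$asr <- write_stable_csv(asr, file.path(out_dir, "asr.csv"))

      pms <- phylomorphospace_coords(tt, dat$traits, asr_a, asr_p)
      written$phylomorphospace_points <- write_stable_csv(
        pms$points, file.path(out_dir, "phylomorphospace_points.csv"))
      written$phylomorphospace_edges <- write_stable_csv(
        pms$edges, file.path(out_dir, "phylomorphospace_edges.csv"))
      written$asr_rates <- local({
        f <- file.path(out_dir, "asr_rates.json")
        jsonlite::write_json(list(sigma2_AMA = asr_a$sig2,
                                  sigma2_PMA = asr_p$sig2,
                                  root_AMA = asr_a$root_state,
                                  root_PMA = asr_p$root_state),
                             f, auto_unbox = TRUE, digits = NA)
        f
      })
    })
  }

  stage("manifest", {
    cfg_serial <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                                   digits = NA, null = "null")
    manifest <- list(
      package = "paleojaw",
      version = as.character(utils::packageVersion("paleojaw")),
      seed = cfg$seed,
      config = cfg,
      config_hash = unname(tools::md5sum(local({
        tmp <- file.path(out_dir, ".config.json")
        writeLines(cfg_serial, tmp)
        tmp
      }))),
      outputs = vapply(written, basename, character(1))
    )
    file.remove(file.path(out_dir, ".config.json"))
    f <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written$manifest <- f
  })

  say("done: %d files in %s", length(written), out_dir)
  invisible(written)
}
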