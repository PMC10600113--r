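# CSV dialect: comma, UTF-8, '.' decimal, mandatory header. Values with
# thousands separators are rejected rather than silently mangled.

read_checked_csv <- function(path, required, numeric_cols = character(0)) {
  if (!is.character(path) || !file.exists(path)) {
    pj_stop("schema", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  if (nrow(df) == 0L) pj_stop("empty_input", sprintf("%s: no data rows", path))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    pj_stop("schema", sprintf("%s: missing column(s) %s", path,
                              paste(miss, collapse = ", ")))
  }
  for (col in numeric_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(raw %in% c("NA", "")))
    if (length(bad)) {
      pj_stop("schema", sprintf(
        "%s: column `%s` not numeric at row(s) %s (thousands separators are not accepted)",
        path, col, paste(utils::head(bad, 5), collapse = ", ")))
    }
    df[[col]] <- val
  }
  df
}

#' Read a muscle geometry table
#'
#' Schema: `skull,muscle,ML_mm,MV_mm3` (lengths in mm, volumes in mm^3).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_muscle_table <- function(path) {
  read_checked_csv(path, c("skull", "muscle", "ML_mm", "MV_mm3"),
                   c("ML_mm", "MV_mm3"))
}

#' Read a skull surface-area table
#'
#' Schema: `skull,S_mm2` (total cranium + mandible surface area, mm^2).
#'
#' @inheritParams read_muscle_table
#' @return Data frame.
#' @export
read_skull_table <- function(path) {
  read_checked_csv(path, c("skull", "S_mm2"), "S_mm2")
}

#' Read a muscle lever table
#'
#' Schema: `skull,muscle,alpha_deg,beta_deg,d_mm,q_deg[,L_in_mm]`. A
#' missing or NA `L_in_mm` is derived from `d` and `q` downstream.
#'
#' @inheritParams read_muscle_table
#' @return Data frame.
#' @export
read_lever_table <- function(path) {
  df <- read_checked_csv(path, c("skull", "muscle", "alpha_deg", "beta_deg",
                                 "d_mm", "q_deg"),
                         c("alpha_deg", "beta_deg", "d_mm", "q_deg"))
  if ("L_in_mm" %in% names(df)) {
    df$L_in_mm <- suppressWarnings(as.numeric(df$L_in_mm))
  } else {
    df$L_in_mm <- NA_real_
  }
  df
}

#' Read a bite-scenario table
#'
#' Schema: `skull,scenario,L_out_mm` (out-lever per named bite point).
#'
#' @inheritParams read_muscle_table
#' @return Data frame.
#' @export
read_scenario_table <- function(path) {
  read_checked_csv(path, c("skull", "scenario", "L_out_mm"), "L_out_mm")
}

#' Read a per-element FE result table
#'
#' Schema: `element_id,weight,svm` or
#' `element_id,weight,sxx,syy,szz,sxy,syz,sxz` (stresses in MPa, weights in
#' mm^3 for solid meshes). Gzip-compressed files are read transparently.
#'
#' @inheritParams read_muscle_table
#' @return Data frame normalized to `element_id,weight,svm`.
#' @export
read_element_table <- function(path) {
  if (!file.exists(path)) pj_stop("schema", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_element_field(df)
}

#' Read a stratigraphic range table
#'
#' Schema: `species,FAD_Ma,LAD_Ma` (first/last appearance, Ma).
#'
#' @inheritParams read_muscle_table
#' @return Data frame.
#' @export
read_range_table <- function(path) {
  read_checked_csv(path, c("species", "FAD_Ma", "LAD_Ma"),
                   c("FAD_Ma", "LAD_Ma"))
}

#' Read a mechanical-advantage trait table
#'
#' Schema: `species,AMA,PMA` (dimensionless). Species whose PMA does not
#' exceed AMA trigger a warning (mandibular out-levers shorten
#' posteriorly, so PMA > AMA is expected), not an error.
#'
#' @inheritParams read_muscle_table
#' @return Data frame.
#' @export
read_trait_table <- function(path) {
  df <- read_checked_csv(path, c("species", "AMA", "PMA"), c("AMA", "PMA"))
  if (anyNA(df$AMA) || anyNA(df$PMA) || any(df$AMA <= 0) || any(df$PMA <= 0)) {
    pj_stop("invalid_measurement",
            sprintf("%s: AMA/PMA must be positive and non-missing", path))
  }
  odd <- df$species[df$PMA <= df$AMA]
  if (length(odd)) {
    warning(sprintf("PMA <= AMA for: %s (unusual for mandibles)",
                    paste(odd, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return An `ape` `phylo`.
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) pj_stop("schema", sprintf("file not found: %s", path))
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) pj_stop("schema", sprintf("%s: not parseable Newick", path))
  tr
}

#' Paths to the packaged ankylosaur measurement fixtures
#'
#' The package ships the transcribed unilateral muscle dimensions, lever
#' geometry, out-levers and published-value tables for *Euoplocephalus
#' tutus* (AMNH 5405) and *Panoplosaurus mirus* (ROM 1215), plus a
#' clearly-labelled synthetic 24-taxon comparative dataset (files suffixed
#' `_synthetic`: real genus names, synthetic ages and trait values).
#'
#' @param file Fixture file name; with no argument, lists available files.
#' @return A file path (or a vector of file names).
#' @examples
#' ankylosaur_fixture()
#' @export
ankylosaur_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "paleojaw")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    pj_stop("schema", sprintf("no packaged fixture named `%s`", file))
  }
  path
}

fixture_by_skull <- function(df, skull) {
  if (is.null(skull)) return(df)
  out <- df[df$skull == skull, , drop = FALSE]
  if (nrow(out) == 0L) {
    pj_stop("schema", sprintf("unknown skull `%s` (have: %s)", skull,
                              paste(unique(df$skull), collapse = ", ")))
  }
  rownames(out) <- NULL
  out
}

#' @rdname ankylosaur_fixture
#' @param skull Optional skull id (`"Euoplocephalus"` or `"Panoplosaurus"`)
#'   to filter to.
#' @export
ankylosaur_muscles <- function(skull = NULL) {
  fixture_by_skull(read_muscle_table(ankylosaur_fixture("muscles.csv")), skull)
}

#' @rdname ankylosaur_fixture
#' @export
ankylosaur_skulls <- function() {
  read_skull_table(ankylosaur_fixture("skulls.csv"))
}

#' @rdname ankylosaur_fixture
#' @export
ankylosaur_levers <- function(skull = NULL) {
  fixture_by_skull(read_lever_table(ankylosaur_fixture("levers.csv")), skull)
}

#' @rdname ankylosaur_fixture
#' @export
ankylosaur_bite_points <- function(skull = NULL) {
  fixture_by_skull(read_scenario_table(ankylosaur_fixture("scenarios.csv")), skull)
}

#' Validate and load a full analysis configuration
#'
#' Resolves and cross-checks every input of a run before any computation:
#' all referenced files must parse, every lever row must match a muscle row
#' of the same skull, scenario and lever skulls must be known, and (when a
#' tree is given) trait and range species must match the tips one-to-one.
#' Problems are aggregated and reported together.
#'
#' @param config Named list. File inputs: `muscles`, `skulls`, `levers`,
#'   `scenarios` (required); `elements` (named character vector of element
#'   CSVs), `tree`, `ranges`, `traits` (optional). Parameters: `sigma`
#'   (N mm^-2, default 0.3), `scale_reference` (skull id whose surface area
#'   forces are scaled to), `cap` (MPa, default 4), `root_buffer` (Myr,
#'   default 1), `seed` (default 1).
#' @return A list of class `"paleojaw_dataset"` with the loaded tables and
#'   the completed config.
#' @export
validate_and_load <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(sigma = 0.3, cap = 4, root_buffer = 1, seed = 1,
                   scale_reference = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("sigma", "cap", "root_buffer")) check_positive(config[[nm]], nm)

  errs <- character(0)
  grab <- function(expr) {
    tryCatch(expr, paleojaw_error = function(e) {
      errs <<- c(errs, conditionMessage(e))
      NULL
    })
  }
  for (nm in c("muscles", "skulls", "levers", "scenarios")) {
    if (is.null(config[[nm]])) errs <- c(errs, sprintf("config lacks `%s` path", nm))
  }
  data <- list()
  if (!is.null(config$muscles))  data$muscles  <- grab(read_muscle_table(config$muscles))
  if (!is.null(config$skulls))   data$skulls   <- grab(read_skull_table(config$skulls))
  if (!is.null(config$levers))   data$levers   <- grab(read_lever_table(config$levers))
  if (!is.null(config$scenarios)) data$scenarios <- grab(read_scenario_table(config$scenarios))
  if (!is.null(config$elements)) {
    data$elements <- lapply(config$elements, function(p) grab(read_element_table(p)))
  }
  if (!is.null(config$tree))   data$tree   <- grab(read_tree_file(config$tree))
  if (!is.null(config$ranges)) data$ranges <- grab(read_range_table(config$ranges))
  if (!is.null(config$traits)) data$traits <- grab(read_trait_table(config$traits))

  if (!is.null(data$muscles) && !is.null(data$levers)) {
    for (sk in unique(data$muscles$skull)) {
      m <- data$muscles$muscle[data$muscles$skull == sk]
      l <- data$levers$muscle[data$levers$skull == sk]
      if (length(setdiff(m, l))) {
        errs <- c(errs, sprintf("skull %s: no lever row for muscle(s) %s",
                                sk, paste(setdiff(m, l), collapse = ", ")))
      }
      if (length(setdiff(l, m))) {
        errs <- c(errs, sprintf("skull %s: lever row for unknown muscle(s) %s",
                                sk, paste(setdiff(l, m), collapse = ", ")))
      }
    }
  }
  if (!is.null(data$muscles) && !is.null(data$skulls)) {
    unk <- setdiff(unique(data$muscles$skull), data$skulls$skull)
    if (length(unk)) {
      errs <- c(errs, sprintf("no surface area for skull(s): %s",
                              paste(unk, collapse = ", ")))
    }
  }
  if (!is.null(config$scale_reference) && !is.null(data$skulls) &&
      !config$scale_reference %in% data$skulls$skull) {
    errs <- c(errs, sprintf("scale_reference `%s` is not a known skull",
                            config$scale_reference))
  }
  if (!is.null(data$tree)) {
    if (!is.null(data$ranges)) {
      unk <- setdiff(data$tree$tip.label, data$ranges$species)
      if (length(unk)) errs <- c(errs, sprintf("no range for tip(s): %s",
                                               paste(unk, collapse = ", ")))
    }
    if (!is.null(data$traits)) {
      unk <- setdiff(data$tree$tip.label, data$traits$species)
      if (length(unk)) errs <- c(errs, sprintf("no trait for tip(s): %s",
                                               paste(unk, collapse = ", ")))
    }
  }
  if (length(errs)) {
    pj_stop("schema", paste0("configuration invalid:\n",
                             paste0("  - ", errs, collapse = "\n")))
  }
  structure(list(data = data, config = config), class = "paleojaw_dataset")
}
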