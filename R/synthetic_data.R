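# Canonical jaw adductor labels used across the package and its fixtures.
adductor_names <- c("mAMEP", "mAMEM", "mAMES", "mPTd", "mPTv", "mAMP", "mPSTs")

#' Simulate a skull's muscle set with known ground-truth forces
#'
#' Draws muscle lengths and volumes from log-normal distributions scaled to
#' the magnitudes of reconstructed ankylosaur jaw adductors (lengths of
#' order 100-200 mm, volumes of order 2e4-1e5 mm^3) and returns the
#' analytic dry-skull forces alongside, so downstream estimates can be
#' checked against truth.
#'
#' @param seed Integer seed; required, every generator is a pure function
#'   of its seed and parameters.
#' @param n_muscles Number of muscles (default 7, named as the canonical
#'   adductor set).
#' @param ml_meanlog,ml_sdlog Log-normal parameters for muscle length, mm.
#' @param mv_meanlog,mv_sdlog Log-normal parameters for muscle volume, mm^3.
#' @param S_mm2 Total skull surface area to attach to the set.
#' @param sigma Isometric stress used for the ground-truth forces.
#' @param skull Skull id.
#' @return List with `muscles` (data frame `skull`, `muscle`, `ML_mm`,
#'   `MV_mm3`), `S_mm2`, and `truth` (per-muscle analytic `F_N`).
#' @export
synth_muscle_set <- function(seed, n_muscles = 7,
                             ml_meanlog = log(160), ml_sdlog = 0.15,
                             mv_meanlog = log(40000), mv_sdlog = 0.5,
                             S_mm2 = 740000, sigma = 0.3,
                             skull = "synthetic_skull") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_muscles < 1) pj_stop("schema", "`n_muscles` must be >= 1")
  set.seed(as.integer(seed))
  nm <- if (n_muscles == length(adductor_names)) adductor_names else
    sprintf("muscle%02d", seq_len(n_muscles))
  ML <- rlnorm(n_muscles, ml_meanlog, ml_sdlog)
  MV <- rlnorm(n_muscles, mv_meanlog, mv_sdlog)
  muscles <- data.frame(skull = skull, muscle = nm, ML_mm = ML, MV_mm3 = MV,
                        stringsAsFactors = FALSE)
  truth <- data.frame(muscle = nm, F_N = sigma * MV / (ML / 3),
                      stringsAsFactors = FALSE)
  list(muscles = muscles, S_mm2 = S_mm2, truth = truth)
}

#' Simulate a per-element stress field with known MWAM
#'
#' Emulates per-element solver output at reduced scale: element weights
#' (volumes) and von Mises stresses are log-normal (positive support, the
#' natural shape for element-size and stress distributions), optionally
#' constant, with an optional injection of artefact "spike" elements of
#' negligible weight and very high stress for robustness experiments.
#'
#' @inheritParams synth_muscle_set
#' @param n_elements Number of elements (default 1e4; full solver meshes of
#'   ~4e6 elements are summarised by the same code path).
#' @param stress_meanlog,stress_sdlog Log-normal parameters for stress, MPa.
#' @param weight_meanlog,weight_sdlog Log-normal parameters for element
#'   weight (volume, mm^3).
#' @param constant If non-NULL, all stresses equal this value.
#' @param n_spikes Number of artefact elements appended.
#' @param spike_value Stress of artefact elements, MPa.
#' @param spike_weight Weight of artefact elements (tiny).
#' @return List with `field` (data frame `element_id`, `weight`, `svm`) and
#'   `mwam_true` (the weighted mean implied by the drawn values).
#' @export
synth_stress_field <- function(seed, n_elements = 10000,
                               stress_meanlog = log(0.2), stress_sdlog = 1,
                               weight_meanlog = log(0.5), weight_sdlog = 0.3,
                               constant = NULL, n_spikes = 0,
                               spike_value = 1000, spike_weight = 1e-6) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_elements < 1) pj_stop("schema", "`n_elements` must be >= 1")
  set.seed(as.integer(seed))
  w <- rlnorm(n_elements, weight_meanlog, weight_sdlog)
  s <- if (is.null(constant)) rlnorm(n_elements, stress_meanlog, stress_sdlog)
       else rep(as.numeric(constant), n_elements)
  if (n_spikes > 0) {
    w <- c(w, rep(spike_weight, n_spikes))
    s <- c(s, rep(spike_value, n_spikes))
  }
  field <- data.frame(element_id = seq_along(w), weight = w, svm = s)
  list(field = field, mwam_true = sum(s * w) / sum(w))
}

#' Simulate Brownian motion along a calibrated tree
#'
#' Preorder walk adding independent Gaussian increments with variance
#' `sigma2 * branch duration`. Uses the current RNG state (seed it, or call
#' from a seeded generator).
#'
#' @param tree Calibrated `phylo` with branch durations in Myr.
#' @param sigma2 BM rate (trait variance per Myr), `>= 0`.
#' @param root_state Trait value at the root.
#' @return List with `tips` (named by tip label) and `nodes` (all node
#'   states, named by node number, root included).
#' @export
sim_bm <- function(tree, sigma2 = 0.01, root_state = 0) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), sigma2 >= 0)
  n <- ape::Ntip(tree)
  state <- numeric(n + tree$Nnode)
  state[n + 1L] <- root_state
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    state[ord$edge[i, 2]] <- state[ord$edge[i, 1]] +
      rnorm(1, 0, sqrt(sigma2 * ord$edge.length[i]))
  }
  list(tips = setNames(state[seq_len(n)], tree$tip.label),
       nodes = setNames(state[(n + 1L):(n + tree$Nnode)],
                        (n + 1L):(n + tree$Nnode)))
}

#' Simulate a comparative dataset: topology, ranges, traits, true states
#'
#' Generates a random binary topology, tip first/last appearances in a
#' stated window (with deliberate FAD ties so the "equal" calibration has
#' zero-length branches to repair), calibrates the tree, and evolves
#' anterior and posterior mechanical advantage by Brownian motion with
#' known rate and root states. True internal states are returned for
#' recovery tests.
#'
#' @inheritParams synth_muscle_set
#' @param n_tips Number of tips (default 24, the size of the packaged
#'   comparative sample).
#' @param fad_window Oldest/youngest allowed FAD, Ma.
#' @param tie_frac Fraction of tips whose FAD is copied from another tip to
#'   force zero-length branches before repair.
#' @param range_myr Min/max stratigraphic range duration, Myr.
#' @param sigma2 BM rate for both traits, per Myr.
#' @param root_ama,root_pma Root states for the two traits.
#' @param root_buffer Root extension passed to [equal_timescale()], Myr.
#' @return List with `topology` (uncalibrated `phylo`), `ranges`, `tree`
#'   (calibrated), `traits` (data frame `species`, `AMA`, `PMA`), and
#'   `true_states` (list of named node-state vectors `AMA`, `PMA`).
#' @export
synth_tree_traits <- function(seed, n_tips = 24, fad_window = c(170, 70),
                              tie_frac = 0.25, range_myr = c(1, 8),
                              sigma2 = 0.005, root_ama = 0.2, root_pma = 0.45,
                              root_buffer = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_tips < 3) pj_stop("schema", "`n_tips` must be >= 3")
  set.seed(as.integer(seed))
  topology <- ape::rtree(n_tips, br = NULL)
  topology$tip.label <- sprintf("taxon%02d", seq_len(n_tips))
  fad <- runif(n_tips, min(fad_window), max(fad_window))
  n_tie <- floor(tie_frac * n_tips)
  if (n_tie > 0) {
    to <- sample(n_tips, n_tie)
    from <- sample(setdiff(seq_len(n_tips), to), n_tie, replace = TRUE)
    fad[to] <- fad[from]
  }
  ranges <- data.frame(species = topology$tip.label, FAD_Ma = fad,
                       LAD_Ma = pmax(fad - runif(n_tips, range_myr[1], range_myr[2]), 0),
                       stringsAsFactors = FALSE)
  tree <- equal_timescale(topology, ranges, root_buffer = root_buffer)
  ama <- sim_bm(tree, sigma2, root_ama)
  pma <- sim_bm(tree, sigma2, root_pma)
  traits <- data.frame(species = tree$tip.label,
                       AMA = unname(ama$tips[tree$tip.label]),
                       PMA = unname(pma$tips[tree$tip.label]),
                       stringsAsFactors = FALSE)
  list(topology = topology, ranges = ranges, tree = tree, traits = traits,
       true_states = list(AMA = ama$nodes, PMA = pma$nodes))
}
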