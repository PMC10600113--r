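#' Anterior and posterior mechanical advantage from 2D lever measurements
#'
#' For macroevolutionary sampling, the in-lever is measured from the jaw
#' joint to the centre of the adductor insertion (dorsal outline of the
#' coronoid process) and the out-levers to the anterior and posterior ends
#' of the tooth row. Any consistent unit (mm or pixels) works: mechanical
#' advantage is unit-free.
#'
#' @param inlever In-lever length (positive, vectorised).
#' @param outlever_ant Out-lever to the anterior bite point (same unit).
#' @param outlever_post Out-lever to the posterior bite point (same unit).
#' @return Data frame with columns `AMA` and `PMA`. `PMA > AMA` whenever
#'   the posterior out-lever is the shorter one, as in mandibles.
#' @examples
#' ma_from_measurements(50, 250, 100) # AMA 0.2, PMA 0.5
#' @export
ma_from_measurements <- function(inlever, outlever_ant, outlever_post) {
  check_positive(inlever, "inlever")
  check_positive(outlever_ant, "outlever_ant")
  check_positive(outlever_post, "outlever_post")
  data.frame(AMA = inlever / outlever_ant, PMA = inlever / outlever_post)
}

# parent lookup for an ape phylo: par[k] = parent node of k (0 for root)
parent_vector <- function(tree) {
  par <- integer(ape::Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

#' Stratigraphic "equal" time-calibration of a cladogram
#'
#' Calibrates a rooted binary cladogram against tip first-appearance dates
#' (FADs, Ma). Each internal node is first dated to the oldest FAD among
#' its descendants and the root is pushed back by `root_buffer` Myr. Any
#' resulting zero-duration branch is then removed by the "equal" rule: the
#' duration of the first ancestral branch with positive length is shared
#' equally among itself and the zero-length branches on the path below it,
#' applied root-outward until every branch has positive duration.
#'
#' Tips terminate at their FAD (last appearances are kept only for optional
#' range display); node ages decrease monotonically from root to tips.
#'
#' @param tree A rooted, binary `phylo` cladogram (branch lengths, if any,
#'   are ignored). Polytomies are rejected rather than silently resolved.
#' @param ranges Data frame with columns `species`, `FAD_Ma`, `LAD_Ma`
#'   (ages in Ma, decreasing toward the present; `FAD_Ma >= LAD_Ma`).
#'   Every tip label must appear.
#' @param root_buffer Minimum root extension in Myr (positive). Default 1.
#' @return A `phylo` with branch durations in Myr and a `root.time` element
#'   (root age in Ma), as used by stratigraphic tree tools.
#' @seealso [tree_node_ages()]
#' @examples
#' tr <- ape::read.tree(text = "(A,B);")
#' rg <- data.frame(species = c("A", "B"), FAD_Ma = c(80, 75),
#'                  LAD_Ma = c(78, 73))
#' tt <- equal_timescale(tr, rg, root_buffer = 5)
#' tt$edge.length # 5 and 10 Myr
#' @export
equal_timescale <- function(tree, ranges, root_buffer = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) pj_stop("topology", "tree must be rooted")
  if (!ape::is.binary(tree)) {
    pj_stop("topology",
            "tree contains polytomies; resolve them explicitly before calibration")
  }
  need <- c("species", "FAD_Ma", "LAD_Ma")
  if (!is.data.frame(ranges) || !all(need %in% names(ranges))) {
    pj_stop("schema", paste("`ranges` needs columns:", paste(need, collapse = ", ")))
  }
  miss <- setdiff(tree$tip.label, ranges$species)
  if (length(miss)) {
    pj_stop("schema", paste("no stratigraphic range for tip(s):",
                            paste(miss, collapse = ", ")))
  }
  if (any(ranges$FAD_Ma < ranges$LAD_Ma)) {
    pj_stop("invalid_measurement",
            "FAD_Ma must be >= LAD_Ma (ages decrease toward the present)")
  }
  check_positive(root_buffer, "root_buffer")

  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  root <- n + 1L
  age <- numeric(N)
  age[seq_len(n)] <- ranges$FAD_Ma[match(tree$tip.label, ranges$species)]

  # oldest-descendant dating, children before parents
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    age[po[i, 1]] <- max(age[po[i, 1]], age[po[i, 2]])
  }
  age[root] <- age[root] + root_buffer

  par <- parent_vector(tree)
  eps <- 1e-9
  repeat {
    dur <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
    zero <- which(dur <= eps)
    if (!length(zero)) break
    # fix the zero branch closest to the root first
    e <- zero[which.max(age[tree$edge[zero, 1]])]
    child <- tree$edge[e, 2]
    # walk rootward collecting the chain of nodes at the same age
    chain <- integer(0)
    p <- tree$edge[e, 1]
    while (age[p] <= age[child] + eps) {
      chain <- c(chain, p)
      p <- par[p]
    }
    # p now has a strictly older age; space the chain evenly below it
    k <- length(chain) + 1L
    step <- (age[p] - age[child]) / k
    age[chain] <- age[child] + step * seq_along(chain)
  }

  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  out$root.time <- age[root]
  out
}

#' Node and tip ages of a calibrated tree
#'
#' @param tree A `phylo` with branch durations and a `root.time` element
#'   (as returned by [equal_timescale()]).
#' @return Numeric vector of ages in Ma, indexed by node number
#'   (tips `1..n`, then internal nodes).
#' @export
tree_node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (is.null(tree$root.time)) {
    pj_stop("schema", "tree has no `root.time`; calibrate it first")
  }
  tree$root.time - ape::node.depth.edgelength(tree)
}

#' Maximum-likelihood Brownian-motion ancestral states
#'
#' Fits a single-rate Brownian-motion model to a continuous trait on a
#' time-calibrated tree and returns the ML ancestral state at every
#' internal node, the ML rate, and conditional variances of the estimates.
#'
#' The ancestral state at a node is the generalized-least-squares mean of
#' the tip values on the tree re-rooted at that node (equivalently the
#' branch-length-weighted squared-change-parsimony solution, which is the
#' joint ML reconstruction under BM). The ML rate is
#' `sigma2 = (x - mu)' C^-1 (x - mu) / n` with `C` the BM tip covariance
#' and `mu` the GLS root state; note the classical `(n-1)/n` small-sample
#' bias of this estimator when the root state is estimated.
#'
#' @param tree A `phylo` with strictly positive branch durations (run
#'   [equal_timescale()] first; zero-length branches give a degenerate
#'   variance and are rejected).
#' @param trait Named numeric vector of tip values; names must cover every
#'   tip label.
#' @return A list of class `"paleojaw_asr"` with elements `ace` (named by
#'   internal node number), `var` (conditional variance of each estimate),
#'   `sig2` (ML rate), `root_state`, and `n_tips`. The root estimate always
#'   lies within the range of the tip values.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' bm_asr(tr, c(A = 1, B = 2, C = 3))
#' @export
bm_asr <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    pj_stop("degenerate_variance",
            "all branch durations must be positive; recalibrate the tree (see equal_timescale)")
  }
  n <- ape::Ntip(tree)
  if (is.null(names(trait)) || !all(tree$tip.label %in% names(trait))) {
    pj_stop("schema", "`trait` must be named and cover every tip")
  }
  x <- trait[tree$tip.label]
  check_finite(x, "trait")

  gls_mean <- function(phy) {
    C <- ape::vcv(phy)
    Ci <- solve(C)
    xx <- x[rownames(C)]
    denom <- sum(Ci)
    list(mu = sum(Ci %*% xx) / denom, denom = denom, Ci = Ci, xx = xx)
  }

  g <- gls_mean(tree)
  resid <- g$xx - g$mu
  sig2 <- as.numeric(t(resid) %*% g$Ci %*% resid) / n

  nodes <- (n + 1L):(n + tree$Nnode)
  ace <- vars <- setNames(numeric(length(nodes)), nodes)
  ace[1L] <- g$mu
  vars[1L] <- sig2 / g$denom
  for (i in seq_along(nodes)[-1L]) {
    rr <- ape::root(tree, node = nodes[i], resolve.root = TRUE)
    gi <- gls_mean(rr)
    ace[i] <- gi$mu
    vars[i] <- sig2 / gi$denom
  }
  structure(list(ace = ace, var = vars, sig2 = sig2,
                 root_state = g$mu, n_tips = n),
            class = "paleojaw_asr")
}

#' @export
print.paleojaw_asr <- function(x, ...) {
  cat(sprintf("BM ancestral states: %d tips, %d internal nodes\n",
              x$n_tips, length(x$ace)))
  cat(sprintf("  ML rate sigma^2: %.6g per Myr   root state: %.6g\n",
              x$sig2, x$root_state))
  invisible(x)
}

#' Phylomorphospace coordinates for two traits
#'
#' Places every tip at its observed (AMA, PMA) pair and every internal node
#' at its reconstructed pair, and returns the tree's edge list so the
#' scatter can be drawn with connecting branches. Tip coordinates are the
#' observed values exactly; no smoothing is applied.
#'
#' @param tree The calibrated `phylo` used for the reconstructions.
#' @param traits Data frame with columns `species`, `AMA`, `PMA` covering
#'   every tip.
#' @param asr_A,asr_P `"paleojaw_asr"` results for AMA and PMA on `tree`.
#' @return A list with `points` (data frame: `node`, `label`, `type`
#'   tip/node, `AMA`, `PMA`) and `edges` (data frame: `from`, `to` node
#'   numbers).
#' @export
phylomorphospace_coords <- function(tree, traits, asr_A, asr_P) {
  stopifnot(inherits(tree, "phylo"),
            inherits(asr_A, "paleojaw_asr"), inherits(asr_P, "paleojaw_asr"))
  n <- ape::Ntip(tree)
  need <- c("species", "AMA", "PMA")
  if (!is.data.frame(traits) || !all(need %in% names(traits))) {
    pj_stop("schema", paste("`traits` needs columns:", paste(need, collapse = ", ")))
  }
  miss <- setdiff(tree$tip.label, traits$species)
  if (length(miss)) {
    pj_stop("schema", paste("no trait row for tip(s):", paste(miss, collapse = ", ")))
  }
  nodes <- as.character((n + 1L):(n + tree$Nnode))
  if (!identical(names(asr_A$ace), nodes) || !identical(names(asr_P$ace), nodes)) {
    pj_stop("schema", "ASR node sets do not match the tree")
  }
  idx <- match(tree$tip.label, traits$species)
  points <- rbind(
    data.frame(node = seq_len(n), label = tree$tip.label, type = "tip",
               AMA = traits$AMA[idx], PMA = traits$PMA[idx],
               stringsAsFactors = FALSE),
    data.frame(node = as.integer(nodes), label = nodes, type = "node",
               AMA = unname(asr_A$ace), PMA = unname(asr_P$ace),
               stringsAsFactors = FALSE)
  )
  list(points = points,
       edges = data.frame(from = tree$edge[, 1], to = tree$edge[, 2]))
}
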