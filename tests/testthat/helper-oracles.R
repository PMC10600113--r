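# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package code it checks.

rel_diff <- function(x, ref) abs(x - ref) / abs(ref)

# Vector-mechanics oracle for the lever model: build the 3D unit vector of a
# muscle's line of action by rotating the vertical unit vector by alpha about
# the transverse axis and beta about the anteroposterior axis, project onto
# vertical, and apply the moment-arm ratio.
bite_force_oracle <- function(F_mus, alpha_deg, beta_deg, L_in, L_out) {
  a <- alpha_deg * pi / 180
  b <- beta_deg * pi / 180
  Ry <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), -sin(b), 0, sin(b), cos(b)), 3, 3)
  u <- Rx %*% Ry %*% c(0, 0, 1)
  F_mus * u[3] * L_in / L_out
}

# Streaming (incremental) weighted mean, one element at a time.
streaming_weighted_mean <- function(values, weights) {
  mean_acc <- 0
  w_acc <- 0
  for (i in seq_along(values)) {
    w_acc <- w_acc + weights[i]
    mean_acc <- mean_acc + (values[i] - mean_acc) * weights[i] / w_acc
  }
  mean_acc
}

# Brute-force joint-ML ancestral states under BM: numerically minimize the
# branch-length-weighted sum of squared changes over all internal states.
bm_joint_ml_oracle <- function(tree, x) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  tipvals <- x[tree$tip.label]
  objective <- function(a) {
    st <- c(tipvals, a)
    sum((st[tree$edge[, 1]] - st[tree$edge[, 2]])^2 / tree$edge.length)
  }
  o <- stats::optim(rep(mean(tipvals), m), objective, method = "BFGS",
                    control = list(maxit = 10000, reltol = 1e-15))
  stats::setNames(o$par, (n + 1):(n + m))
}

# Naive minimum-age calibration (no zero-branch repair): each node at the
# oldest descendant FAD, root pushed back by the buffer.
naive_timescale_ages <- function(tree, ranges, root_buffer) {
  n <- ape::Ntip(tree)
  age <- numeric(n + tree$Nnode)
  age[seq_len(n)] <- ranges$FAD_Ma[match(tree$tip.label, ranges$species)]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) age[po[i, 1]] <- max(age[po[i, 1]], age[po[i, 2]])
  age[n + 1] <- age[n + 1] + root_buffer
  age
}

euo_published_forces <- function() {
  df <- read.csv(ankylosaur_fixture("published_muscle_forces.csv"))
  df[df$skull == "Euoplocephalus", ]
}

pano_published_forces <- function() {
  df <- read.csv(ankylosaur_fixture("published_muscle_forces.csv"))
  df[df$skull == "Panoplosaurus", ]
}
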