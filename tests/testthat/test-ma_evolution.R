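test_that("mechanical advantage pairs follow directly from lever lengths", {
  r <- ma_from_measurements(50, 250, 100)
  expect_equal(r$AMA, 0.20)
  expect_equal(r$PMA, 0.50)
  expect_equal(unlist(ma_from_measurements(37, 37, 37)), c(AMA = 1, PMA = 1))
  # the 3D-lever analogue for the ankylosaurid skull rounds to the published pair
  r3 <- ma_from_measurements(55.30, 201.9, 101.0)
  expect_equal(round(r3$AMA, 2), 0.27)
  expect_equal(round(r3$PMA, 2), 0.55)
  expect_error(ma_from_measurements(0, 1, 1), class = "paleojaw_invalid_measurement")
})

test_that("equal calibration dates the minimal two-taxon case by hand", {
  tr <- ape::read.tree(text = "(A,B);")
  rg <- data.frame(species = c("A", "B"), FAD_Ma = c(80, 75), LAD_Ma = c(78, 73))
  tt <- equal_timescale(tr, rg, root_buffer = 5)
  expect_equal(tt$root.time, 85)
  durs <- setNames(tt$edge.length, tr$tip.label[tt$edge[, 2]])
  expect_equal(durs[["A"]], 5)
  expect_equal(durs[["B"]], 10)
})

test_that("equal calibration only lifts nodes that need repair", {
  # ((A,B),C): only the A branch is zero under minimum-age dating; the root
  # keeps its naive date and the cherry node is lifted midway (hand-derived)
  tr <- ape::read.tree(text = "((A,B),C);")
  rg <- data.frame(species = c("A", "B", "C"),
                   FAD_Ma = c(80, 70, 90), LAD_Ma = c(78, 68, 85))
  tt <- equal_timescale(tr, rg, root_buffer = 5)
  naive <- naive_timescale_ages(tr, rg, 5)
  age <- tree_node_ages(tt)
  expect_equal(unname(age[4]), unname(naive[4]))  # root untouched at 95
  expect_equal(unname(age[5]), 87.5)              # cherry lifted to midpoint
  # lifting is one-sided: equal never dates a node younger than naive
  for (seed in 1:10) {
    s <- synth_tree_traits(seed = seed, n_tips = 10, sigma2 = 0)
    expect_true(all(tree_node_ages(s$tree) >=
                      naive_timescale_ages(s$topology, s$ranges, 1) - 1e-9))
  }
})

test_that("zero-length branches are repaired by equal redistribution", {
  # two FAD ties: node(A,B) and node(A,B,C) both date to 90 Ma, and tip B
  # sits at its parent's age. Hand-executing the equal rule: the root branch
  # span (105 - 90) is halved across (root->ABC, ABC->AB), then the repaired
  # ABC->AB span (97.5 - 90) is halved again across (ABC->AB, AB->B).
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  rg <- data.frame(species = c("A", "B", "C", "D"),
                   FAD_Ma = c(80, 90, 90, 100), LAD_Ma = c(78, 88, 88, 95))
  tt <- equal_timescale(tr, rg, root_buffer = 5)
  age <- tree_node_ages(tt)
  expect_equal(unname(age[5:7]), c(105, 97.5, 93.75))
  expect_true(all(tt$edge.length > 0))
})

test_that("equal calibration yields positive durations and monotone ages", {
  for (seed in 1:40) {
    s <- synth_tree_traits(seed = seed, n_tips = 12, tie_frac = 0.4)
    tt <- s$tree
    expect_true(all(tt$edge.length > 0))
    age <- tree_node_ages(tt)
    expect_true(all(age[tt$edge[, 1]] > age[tt$edge[, 2]]))
    # tips terminate at their first appearance
    expect_equal(unname(age[seq_len(12)]),
                 s$ranges$FAD_Ma[match(tt$tip.label, s$ranges$species)],
                 tolerance = 1e-9)
  }
})

test_that("calibration rejects polytomies and incomplete ranges", {
  poly <- ape::read.tree(text = "(A,B,C);")
  rg <- data.frame(species = c("A", "B", "C"), FAD_Ma = c(80, 75, 70),
                   LAD_Ma = c(78, 73, 68))
  expect_error(equal_timescale(poly, rg), class = "paleojaw_topology")
  tr <- ape::read.tree(text = "((A,B),C);")
  expect_error(equal_timescale(tr, rg[-2, ]), "B", class = "paleojaw_schema")
  bad <- rg; bad$LAD_Ma[1] <- 99
  expect_error(equal_timescale(tr, bad), class = "paleojaw_invalid_measurement")
})

test_that("BM ancestral states solve the symmetric and two-tip cases", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2);")
  a <- bm_asr(star, c(A = 1, B = 2, C = 3))
  expect_equal(unname(a$root_state), 2)
  # precision-weighted mean: weights proportional to 1/branch duration
  two <- ape::read.tree(text = "(A:1,B:3);")
  a2 <- bm_asr(two, c(A = 0, B = 4))
  expect_equal(unname(a2$root_state), 1.0)
  expect_equal(unname(a2$sig2), {
    # profile ML by direct numerical maximization of the BM likelihood
    nll <- function(s2) {
      C <- s2 * diag(c(1, 3))
      r <- c(0, 4) - 1.0
      0.5 * (determinant(C)$modulus + t(r) %*% solve(C) %*% r + 2 * log(2 * pi))
    }
    stats::optimize(nll, c(1e-4, 100))$minimum
  }, tolerance = 1e-4)
})

test_that("BM states match the joint-likelihood optimizer and fastAnc", {
  set.seed(31)
  for (i in 1:3) {
    tr <- ape::rtree(8)
    x <- setNames(rnorm(8), tr$tip.label)
    a <- bm_asr(tr, x)
    expect_equal(unname(a$ace), unname(bm_joint_ml_oracle(tr, x)),
                 tolerance = 1e-6)
    fa <- phytools::fastAnc(tr, x)
    expect_equal(unname(a$ace), unname(as.numeric(fa)), tolerance = 1e-8)
  }
})

test_that("BM estimates are location- and scale-equivariant", {
  s <- synth_tree_traits(seed = 32, n_tips = 10)
  x <- setNames(s$traits$AMA, s$traits$species)
  a <- bm_asr(s$tree, x)
  b <- bm_asr(s$tree, x + 3.7)
  expect_equal(b$ace, a$ace + 3.7)
  expect_equal(b$sig2, a$sig2)
  cc <- bm_asr(s$tree, x * 2.5)
  expect_equal(cc$ace, a$ace * 2.5)
  expect_equal(cc$sig2, a$sig2 * 2.5^2)
  # root estimate bounded by the tip range; variances positive
  expect_gte(a$root_state, min(x))
  expect_lte(a$root_state, max(x))
  expect_true(all(a$var > 0))
})

test_that("BM fitting rejects degenerate branch durations", {
  tr <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  expect_error(bm_asr(tr, c(A = 1, B = 2, C = 3)),
               class = "paleojaw_degenerate_variance")
})

test_that("phylomorphospace places tips at observed values, nodes at estimates", {
  two <- ape::read.tree(text = "(A:1,B:3);")
  traits <- data.frame(species = c("A", "B"), AMA = c(0.2, 0.3),
                       PMA = c(0.5, 0.6))
  aa <- bm_asr(two, setNames(traits$AMA, traits$species))
  pp <- bm_asr(two, setNames(traits$PMA, traits$species))
  ps <- phylomorphospace_coords(two, traits, aa, pp)
  expect_equal(nrow(ps$points), 3)
  expect_equal(nrow(ps$edges), 2)
  expect_equal(ps$points$AMA[ps$points$type == "tip"], traits$AMA)
  expect_equal(ps$points$PMA[ps$points$type == "tip"], traits$PMA)

  # identical tip values collapse every point onto one coordinate
  flat <- data.frame(species = c("A", "B"), AMA = 0.25, PMA = 0.5)
  fa <- bm_asr(two, setNames(flat$AMA, flat$species))
  fp <- bm_asr(two, setNames(flat$PMA, flat$species))
  psf <- phylomorphospace_coords(two, flat, fa, fp)
  expect_true(all(psf$points$AMA == 0.25) && all(psf$points$PMA == 0.5))
})

test_that("ancestral-state error shrinks as the BM rate shrinks", {
  mse_at <- function(sigma2) {
    s <- synth_tree_traits(seed = 33, n_tips = 16, sigma2 = sigma2)
    a <- bm_asr(s$tree, setNames(s$traits$AMA, s$traits$species))
    mean((a$ace - s$true_states$AMA[names(a$ace)])^2)
  }
  expect_lt(mse_at(5e-4), mse_at(5e-2))
})
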