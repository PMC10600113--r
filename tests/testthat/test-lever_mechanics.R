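test_that("resultant force resolves sagittal and coronal deviation", {
  expect_equal(resultant_force(100, 0, 0), 100)
  expect_equal(resultant_force(232.6, 36, 5.3), 187.4, tolerance = 5e-4)
  # printed table value 121.87 carries the source's own rounding
  expect_lt(rel_diff(resultant_force(150.4, 36, 5), 121.87), 0.01)
  expect_error(resultant_force(10, 90, 0), class = "paleojaw_invalid_orientation")
  expect_error(resultant_force(10, 10, 95), class = "paleojaw_invalid_orientation")
  expect_error(resultant_force(-1, 10, 10), class = "paleojaw_invalid_measurement")
})

test_that("in-lever uses d*sin(q) with the supplementary-angle rule", {
  expect_equal(in_lever(59.60, 68.1), 55.30, tolerance = 1e-4)
  expect_equal(in_lever(12.3, 90), 12.3)
  # q past 90 degrees folds back: sin(180 - q)
  expect_equal(in_lever(49.10, 144.5), 49.10 * sin(35.5 * pi / 180))
  expect_equal(in_lever(49.10, 144.5), 28.51, tolerance = 1e-4)
  set.seed(7)
  for (i in 1:20) {
    d <- runif(1, 5, 100)
    q <- runif(1, 1, 179)
    expect_lte(in_lever(d, q), d)
    expect_gt(in_lever(d, q), 0)
  }
  expect_error(in_lever(10, 0), class = "paleojaw_invalid_orientation")
  expect_error(in_lever(10, 180), class = "paleojaw_invalid_orientation")
})

test_that("bite force reproduces published per-muscle contributions", {
  expect_lt(rel_diff(bite_force(307.3, 38, 9.7, 47.62, 270.5), 42.0), 0.01)
  expect_equal(bite_force(0, 12, 34, 10, 100), 0)
  # summing all seven muscles at the posterior bite point matches the table
  lev <- ankylosaur_levers("Euoplocephalus")
  pub <- euo_published_forces()
  F_mus <- pub$F_mus_N[match(lev$muscle, pub$muscle)]
  total_post <- sum(bite_force(F_mus, lev$alpha_deg, lev$beta_deg,
                               lev$L_in_mm, 101.0))
  expect_lt(rel_diff(total_post, 443.75), 0.005)
})

test_that("bite force agrees with a 3D vector-mechanics oracle", {
  set.seed(11)
  for (i in 1:30) {
    F <- runif(1, 10, 800)
    a <- runif(1, 0, 89)
    b <- runif(1, 0, 89)
    L_in <- runif(1, 5, 90)
    L_out <- runif(1, 50, 300)
    expect_equal(bite_force(F, a, b, L_in, L_out),
                 bite_force_oracle(F, a, b, L_in, L_out),
                 tolerance = 1e-12)
  }
})

test_that("bite force is monotone in each argument on its domain", {
  base <- c(F = 200, a = 30, b = 20, L_in = 40, L_out = 200)
  f <- function(F = base["F"], a = base["a"], b = base["b"],
                L_in = base["L_in"], L_out = base["L_out"]) {
    bite_force(F, a, b, L_in, L_out)
  }
  expect_gt(f(F = 250), f())
  expect_gt(f(L_in = 50), f())
  expect_lt(f(L_out = 250), f())
  expect_lt(f(a = 40), f())
  expect_lt(f(b = 30), f())
})

test_that("out-lever scaling of bite force is exact", {
  set.seed(12)
  for (i in 1:10) {
    F <- runif(1, 10, 500)
    a <- runif(1, 0, 80)
    b <- runif(1, 0, 80)
    L_in <- runif(1, 5, 80)
    expect_equal(bite_force(F, a, b, L_in, 270.5) / bite_force(F, a, b, L_in, 201.9),
                 201.9 / 270.5, tolerance = 1e-14)
  }
})

test_that("mechanical advantage is the lever ratio, below 1 for third-class jaws", {
  expect_equal(mechanical_advantage(55.30, 101.0), 0.548, tolerance = 1e-3)
  expect_equal(mechanical_advantage(14.46, 270.5), 0.053, tolerance = 2e-2)
  expect_equal(mechanical_advantage(64.2, 64.2), 1.0)
  # third-class lever: L_in < L_out forces MA < 1 and F_bite < F_res
  set.seed(13)
  for (i in 1:15) {
    L_in <- runif(1, 5, 90)
    L_out <- L_in + runif(1, 1, 200)
    F <- runif(1, 50, 500)
    a <- runif(1, 0, 80)
    b <- runif(1, 0, 80)
    expect_lt(mechanical_advantage(L_in, L_out), 1)
    expect_lt(bite_force(F, a, b, L_in, L_out), resultant_force(F, a, b))
  }
})

test_that("bite report assembles totals, honours L_in precedence and scaling", {
  forces <- muscle_force_table(ankylosaur_muscles("Euoplocephalus"))
  lev <- ankylosaur_levers("Euoplocephalus")
  sc <- ankylosaur_bite_points("Euoplocephalus")
  rep <- bite_report(forces, lev, sc)

  expect_s3_class(rep, "paleojaw_bite_report")
  expect_lt(rel_diff(rep$totals$F_bite_total_N[rep$totals$scenario == "muzzle"],
                     165.69), 0.01)
  # totals equal column sums
  for (s in rep$totals$scenario) {
    expect_equal(rep$totals$F_bite_total_N[rep$totals$scenario == s],
                 sum(rep$bite$F_bite_N[rep$bite$scenario == s]))
  }
  # supplied L_in wins over d*sin(q); NA entries are derived
  expect_equal(rep$per_muscle$L_in_mm[rep$per_muscle$muscle == "mAMP"], 31.40)
  lev2 <- lev
  lev2$L_in_mm[lev2$muscle == "mAMEP"] <- NA
  rep2 <- bite_report(forces, lev2, sc)
  expect_equal(rep2$per_muscle$L_in_mm[rep2$per_muscle$muscle == "mAMEP"],
               in_lever(59.60, 68.1))

  # single muscle, single scenario reduces to bite_force
  one <- bite_report(forces[1, ], lev, sc[1, ])
  expect_equal(one$totals$F_bite_total_N,
               bite_force(forces$F_mus_N[1], lev$alpha_deg[1], lev$beta_deg[1],
                          lev$L_in_mm[1], sc$L_out_mm[1]))

  # scaled forces propagate linearly through the whole report
  forces_s <- muscle_force_table(ankylosaur_muscles("Panoplosaurus"),
                                 S_mm2 = 615095, S_reference_mm2 = 867054)
  lev_p <- ankylosaur_levers("Panoplosaurus")
  sc_p <- ankylosaur_bite_points("Panoplosaurus")
  rep_o <- bite_report(forces_s, lev_p, sc_p)
  rep_s <- bite_report(forces_s, lev_p, sc_p, use_scaled = TRUE)
  expect_equal(rep_s$totals$F_bite_total_N,
               rep_o$totals$F_bite_total_N * 867054 / 615095)

  # a missing lever row is a schema error naming the muscle
  expect_error(bite_report(forces, lev[lev$muscle != "mPTd", ], sc),
               "mPTd", class = "paleojaw_schema")
  expect_error(bite_report(forces, lev, sc[0, ]), class = "paleojaw_empty_input")
})

test_that("flattened report has fixed column order and TOTAL rows", {
  forces <- muscle_force_table(ankylosaur_muscles("Euoplocephalus"))
  rep <- bite_report(forces, ankylosaur_levers("Euoplocephalus"),
                     ankylosaur_bite_points("Euoplocephalus"))
  df <- as.data.frame(rep)
  expect_identical(names(df), c("muscle", "scenario", "F_mus_N", "F_res_N",
                                "L_in_mm", "L_out_mm", "F_bite_N", "MA"))
  expect_equal(sum(df$muscle == "TOTAL"), 3)
  expect_equal(nrow(df), 7 * 3 + 3)
})
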