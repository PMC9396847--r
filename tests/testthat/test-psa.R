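test_that("distribution rules are mean-matched to the parameter table", {
  params <- implant_parameters()
  specs <- build_distributions(params)
  # beta mean-matching at concentration 100: alpha = 100 * 0.88
  eff <- specs[["effImplant"]]
  expect_equal(eff$family, "beta")
  expect_equal(eff$alpha, 88)
  expect_equal(eff$beta, 12)
  expect_equal(eff$alpha / (eff$alpha + eff$beta), 0.88)
  # normal costs: mean at base, sd from the 95%-interval rule
  ab <- specs[["cAntibiotics"]]
  expect_equal(ab$family, "normal")
  expect_equal(ab$mean, 10.20)
  expect_equal(ab$sd, (100 - 5) / 3.92)
  expect_equal(ab$lower, 0)
  # probabilities stay fixed by default
  expect_equal(specs[["pantsurv"]]$family, "fixed")
  expect_equal(specs[["pantsurv"]]$value, 0.9878)

  bad <- parameter_set(parameter("u", 0, 0, 1, "beta", "utility"))
  expect_error(build_distributions(bad, sampled = "u"), "outside \\(0, 1\\)")
  expect_error(build_distributions(params, sampled = "nope"),
               "unknown parameter")
})

test_that("sampling is seed-deterministic and respects support constraints", {
  specs <- build_distributions(implant_parameters())
  d1 <- sample_draws(specs, 500, seed = 7)
  d2 <- sample_draws(specs, 500, seed = 7)
  expect_identical(d1$draws, d2$draws)
  d3 <- sample_draws(specs, 500, seed = 8)
  expect_false(identical(d1$draws, d3$draws))

  # truncation: wide-sd costs never go negative
  expect_gte(min(d1$draws[, "cImplantReplacement"]), 0)
  expect_gte(min(d1$draws[, "cAntibiotics"]), 0)
  # beta support
  expect_true(all(d1$draws[, "effImplant"] > 0 & d1$draws[, "effImplant"] < 1))
  # fixed parameters equal the base value in every draw
  expect_true(all(d1$draws[, "pantsurv"] == 0.9878))
})

test_that("beta(88, 12) draws have mean 0.88 within 3 standard errors", {
  specs <- build_distributions(
    parameter_set(parameter("u", 0.88, 0.5, 0.9, "beta", "utility")))
  d <- sample_draws(specs, 10000, seed = 11)
  x <- d$draws[, "u"]
  se <- sqrt(0.88 * 0.12 / 101) / sqrt(10000)
  expect_lt(abs(mean(x) - 0.88), 3 * se)
})

test_that("zero-variance PSA reproduces the deterministic base case exactly", {
  tree <- build_implant_model("patient")
  specs <- build_distributions(tree$parameters, sampled = character(0))
  draws <- sample_draws(specs, 50, seed = 1)
  psa <- run_psa(tree, draws, specs)
  base <- rollback(tree)
  for (s in strategies(tree)) {
    expect_equal(unique(psa$cost[psa$strategy == s]),
                 base$expected_cost[base$strategy == s])
    expect_equal(unique(psa$effect[psa$strategy == s]),
                 base$expected_effect[base$strategy == s])
  }
  expect_identical(attr(psa, "n_resampled"), 0L)
})

test_that("the full PSA pipeline is bit-reproducible under a fixed seed", {
  tree <- build_implant_model("patient")
  specs <- build_distributions(tree$parameters)
  run <- function() {
    run_psa(tree, sample_draws(specs, 100, seed = 42), specs)
  }
  expect_identical(run(), run())
})

test_that("PSA scatter shows dispersion in both dimensions for both strategies", {
  tree <- build_implant_model("patient")
  specs <- build_distributions(tree$parameters)
  psa <- run_psa(tree, sample_draws(specs, 300, seed = 5), specs)
  for (s in strategies(tree)) {
    expect_gt(stats::var(psa$cost[psa$strategy == s]), 0)
    expect_gt(stats::var(psa$effect[psa$strategy == s]), 0)
  }
})

test_that("halving parameter uncertainty shrinks the PSA cost variance", {
  tree <- build_implant_model("patient")
  wide <- build_distributions(tree$parameters)
  narrow <- build_distributions(tree$parameters,
                                sd_rule = function(lo, hi) (hi - lo) / 7.84,
                                kappa = 400)
  v <- function(specs) {
    psa <- run_psa(tree, sample_draws(specs, 400, seed = 9), specs)
    stats::var(psa$cost[psa$strategy == "Antibiotics"])
  }
  expect_lt(v(narrow), v(wide))
})

test_that("CEAC probabilities are proportions summing to one at every WTP", {
  tree <- build_implant_model("patient")
  specs <- build_distributions(tree$parameters)
  psa <- run_psa(tree, sample_draws(specs, 200, seed = 3), specs)
  cc <- ceac(psa, seq(0, 10000, by = 500))
  sums <- as.numeric(tapply(cc$probability, cc$wtp, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
})

test_that("deterministic draws give a 0/1 CEAC stepping at the NMB crossing", {
  # A pays 10 more but gains 0.1 effect: preferred iff WTP > 100
  tree <- decision_tree(
    decision_node(A = terminal_node(payoff("cA", 0.2)),
                  B = terminal_node(payoff("cB", 0.1))),
    parameter_set(parameter("cA", 10, 0, 20, "fixed", "cost"),
                  parameter("cB", 0, 0, 20, "fixed", "cost"))
  )
  specs <- build_distributions(tree$parameters, sampled = character(0))
  psa <- run_psa(tree, sample_draws(specs, 25, seed = 1), specs)
  cc <- ceac(psa, c(0, 50, 100, 150, 200))
  pA <- cc$probability[cc$strategy == "A"]
  expect_equal(pA, c(0, 0, 0.5, 1, 1))  # exact tie at 100 splits the draw
  single <- ceac(psa[psa$strategy == "A", ], c(0, 100))
  expect_equal(single$probability, c(1, 1))
})

test_that("ICE summaries count quadrants exhaustively and prefer by strict NMB", {
  tree <- build_implant_model("patient")
  specs <- build_distributions(tree$parameters, sampled = character(0))
  psa <- run_psa(tree, sample_draws(specs, 40, seed = 2), specs)
  ice <- ice_summary(psa, 3000, "Antibiotics", "No Antibiotics")
  expect_equal(sum(ice$quadrant_counts), 40L)
  # fixed draws: every draw lands in the same quadrant (SE: cheaper, better)
  expect_equal(unname(ice$quadrant_counts["SE"]), 40L)
  expect_true(ice$n_preferred %in% c(0L, 40L))
  expect_equal(nrow(ice$deltas), 40L)
})

test_that("identical strategies split preference like a fair coin", {
  tree <- toy_two_param_tree()  # iid normal costs, equal effects
  specs <- build_distributions(tree$parameters)
  psa <- run_psa(tree, sample_draws(specs, 1000, seed = 77), specs)
  ice <- ice_summary(psa, 3000, "A", "B")
  # n_preferred ~ Binomial(1000, 1/2): assert within 3 sigma
  expect_lt(abs(ice$n_preferred - 500), 3 * sqrt(1000 * 0.25))
})

test_that("PSA tables write to CSV", {
  tree <- build_implant_model("patient")
  specs <- build_distributions(tree$parameters)
  psa <- run_psa(tree, sample_draws(specs, 30, seed = 4), specs)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_psa_csv(psa, p1)
  expect_equal(nrow(readr::read_csv(p1, show_col_types = FALSE)), 60L)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ceac_csv(ceac(psa, c(0, 3000)), p2)
  expect_true(file.exists(p2))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_ice_csv(ice_summary(psa, 3000, "Antibiotics", "No Antibiotics"), p3)
  expect_equal(nrow(readr::read_csv(p3, show_col_types = FALSE)), 30L)
})
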