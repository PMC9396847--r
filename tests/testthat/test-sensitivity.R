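test_that("one-way sweep reproduces the base case at the base value", {
  tree <- build_implant_model("healthcare")
  base <- rollback(tree)
  base_nmb <- nmb(base$expected_cost, base$expected_effect, 3000)
  # grid anchored at the base value so the first point is the base case
  curve <- one_way(tree, "cAntibiotics", wtp = 3000, n_points = 20,
                   range = c(10.20, 100))
  at_base <- curve[curve$value == 10.20, ]
  expect_equal(at_base$nmb[at_base$strategy == "Antibiotics"],
               base_nmb[base$strategy == "Antibiotics"], tolerance = 1e-9)
  expect_equal(at_base$nmb[at_base$strategy == "No Antibiotics"],
               base_nmb[base$strategy == "No Antibiotics"], tolerance = 1e-9)
})

test_that("antibiotic-cost sweep has analytic slope -1 on the treated arm only", {
  curve <- one_way(build_implant_model("patient"), "cAntibiotics",
                   wtp = 3000, n_points = 11)
  ab <- curve[curve$strategy == "Antibiotics", ]
  # the course cost enters every antibiotic-arm terminal once, so NMB falls
  # 1 EUR per EUR
  expect_equal(diff(ab$nmb) / diff(ab$value), rep(-1, 10), tolerance = 1e-9)
  noab <- curve[curve$strategy == "No Antibiotics", ]
  expect_equal(diff(noab$nmb), rep(0, 10))
})

test_that("sweeping a parameter the tree never references gives a flat curve", {
  # the patient perspective costs adverse events at a 10 EUR literal, so cAE
  # is declared but unreferenced
  curve <- one_way(build_implant_model("patient"), "cAE", wtp = 3000,
                   n_points = 7)
  for (s in unique(curve$strategy)) {
    expect_equal(diff(curve$nmb[curve$strategy == s]), rep(0, 6))
  }
})

test_that("degenerate ranges and grids are rejected", {
  tree <- build_implant_model("patient")
  expect_error(one_way(tree, "pantsurv", wtp = 3000,
                       range = c(0.9878, 0.9878)), "degenerate range")
  expect_error(one_way(tree, "nope", wtp = 3000), "unknown parameter")
})

test_that("threshold finding recovers a closed-form equality point", {
  # two certain strategies, identical except strategy A pays cA: NMBs are
  # equal exactly where cA equals B's cost of 50
  tree <- toy_two_param_tree()
  th <- find_threshold(tree, "cA", wtp = 3000, strategies = c("A", "B"),
                       bracket = c(0, 100))
  expect_equal(th$threshold, 50, tolerance = 1e-6)
  expect_lt(abs(th$dnmb), 1e-6)
})

test_that("replacement-cost threshold is bracketed, sign-verified and grid-stable", {
  tree <- build_implant_model("healthcare")
  th <- find_threshold(tree, "cImplantReplacement", wtp = 3000,
                       strategies = c("Antibiotics", "No Antibiotics"),
                       bracket = c(100, 1600))
  expect_lt(abs(th$dnmb), 1e-6)
  # sign flips across the root
  expect_lt(th$f(th$threshold - 1) * th$f(th$threshold + 1), 0)
  # a 10x finer bisection of a refined bracket moves the root below tolerance
  lo <- th$threshold - 5; hi <- th$threshold + 5
  grid <- seq(lo, hi, length.out = 1000)
  vals <- vapply(grid, th$f, numeric(1))
  flip <- which(diff(sign(vals)) != 0)[1]
  expect_lt(abs(grid[flip] - th$threshold), 0.02)
})

test_that("a dominance-preserving range reports no threshold", {
  tree <- build_implant_model("healthcare")
  expect_error(
    find_threshold(tree, "cAntibiotics", wtp = 3000,
                   strategies = c("Antibiotics", "No Antibiotics"),
                   bracket = c(5, 15)),
    "no threshold in range")
})

test_that("tornado spans equal |coefficient| x range width for linear payoffs", {
  tree <- toy_two_param_tree()
  torn <- tornado(tree, wtp = 3000, strategies = c("A", "B"))
  # dNMB(A - B) = cB - cA: both coefficients have magnitude 1, ranges 100 wide
  expect_equal(sort(torn$parameter), c("cA", "cB"))
  expect_equal(torn$span, c(100, 100))
  expect_error(tornado(tree, wtp = 3000, parameters = character(0)),
               "empty parameter list")
})

test_that("an unreferenced parameter has zero span and sinks to the tail", {
  torn <- tornado(build_implant_model("patient"), wtp = 3000)
  expect_equal(torn$span[torn$parameter == "cAE"], 0)
  # everything ranked at or below it is also zero-influence
  tail_spans <- torn$span[which(torn$parameter == "cAE"):nrow(torn)]
  expect_true(all(tail_spans <= 1e-9))
  expect_true(all(diff(torn$span) <= 0))
})

test_that("influence ranking surfaces the known drivers of the implant decision", {
  torn <- tornado(build_implant_model("healthcare"), wtp = 3000)
  top6 <- torn$parameter[1:6]
  expect_true(all(c("cAntibiotics", "cImplantReplacement", "pAE",
                    "pnoantsurv") %in% top6))
  # placement cost is paid identically in both arms: zero influence
  expect_equal(torn$span[torn$parameter == "cImplantPlacement"], 0,
               tolerance = 1e-9)
})

test_that("sensitivity tables write to CSV", {
  tree <- build_implant_model("healthcare")
  curve <- one_way(tree, "cAntibiotics", wtp = 3000, n_points = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  wide <- write_one_way_csv(curve, p1)
  expect_true(all(c("nmb_Antibiotics", "preferred") %in% names(wide)))

  th <- find_threshold(tree, "cAntibiotics", wtp = 3000,
                       strategies = c("Antibiotics", "No Antibiotics"))
  p2 <- withr::local_tempfile(fileext = ".csv")
  tab <- write_threshold_csv(th, p2)
  expect_equal(tab$threshold, th$threshold)

  p3 <- withr::local_tempfile(fileext = ".csv")
  write_tornado_csv(tornado(tree, wtp = 3000), p3)
  expect_true(file.exists(p3))
})
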