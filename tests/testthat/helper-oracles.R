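# Shared fixtures and independent oracles.

# Closed-form hand calculation of the implant case, independent of the tree
# engine: final survival probability is p + (1-p) * preplac * psurvsecond,
# the effect its utility-weighted mean, and costs accumulate placement,
# arm-specific adders and the reach-probability-weighted replacement cost.
implant_closed_form <- function(kind = "patient",
                                overrides = list()) {
  v <- list(cAE = 705, cAntibiotics = 10.20, cAntibioticResistance = 13.97,
            cImplantPlacement = 1002, cImplantReplacement = 1102,
            effImplant = 0.88, effNoImplant = 0.71, pAE = 0.000023,
            pantsurv = 0.9878, pnoantsurv = 0.9567, preplac = 0.85,
            psurvsecond = 0.89)
  v[names(overrides)] <- overrides
  ae_unit <- if (kind == "patient") 10 else v$cAE
  arm <- function(p, antibiotic) {
    p_final <- p + (1 - p) * v$preplac * v$psurvsecond
    effect <- p_final * v$effImplant + (1 - p_final) * v$effNoImplant
    cost <- v$cImplantPlacement +
      (1 - p) * v$preplac * v$cImplantReplacement
    if (antibiotic) {
      cost <- cost + v$cAntibiotics + v$pAE * ae_unit +
        if (kind == "healthcare") v$cAntibioticResistance else 0
    }
    list(p_final = p_final, cost = cost, effect = effect)
  }
  list(ab = arm(v$pantsurv, TRUE), noab = arm(v$pnoantsurv, FALSE))
}

# Exhaustive efficiency-frontier oracle: the preferred strategy as a function
# of WTP is piecewise constant with breakpoints at pairwise ICERs, so the
# frontier is exactly the union of max-NMB strategies over all candidate WTPs
# (0, each positive pairwise ICER nudged either way, and a value beyond the
# largest breakpoint).
frontier_oracle <- function(results) {
  cost <- results$expected_cost
  effect <- results$expected_effect
  n <- length(cost)
  icers <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      de <- effect[j] - effect[i]
      if (abs(de) > 1e-12) {
        r <- (cost[j] - cost[i]) / de
        if (r > 0) icers <- c(icers, r)
      }
    }
  }
  eps <- 1e-7
  cands <- unique(c(0, icers * (1 - eps), icers * (1 + eps),
                    if (length(icers)) max(icers) * 2 else 1))
  cands <- cands[cands >= 0]
  winners <- unique(unlist(lapply(cands, function(w) {
    b <- w * effect - cost
    results$strategy[b >= max(b) - 1e-9 * max(1, abs(max(b)))]
  })))
  sort(winners)
}

# Toy two-strategy tree over explicit parameters, used across modules:
# strategy A pays cost cA with utility eA, B likewise; both certain.
toy_two_param_tree <- function(eA = 0.5, eB = 0.5) {
  decision_tree(
    decision_node(
      A = terminal_node(payoff("cA", eA)),
      B = terminal_node(payoff("cB", eB))
    ),
    parameter_set(
      parameter("cA", 50, 0, 100, "normal", "cost"),
      parameter("cB", 50, 0, 100, "normal", "cost")
    )
  )
}
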