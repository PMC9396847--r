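# Random valid decision trees for property testing: engine invariants
# (rollback vs path enumeration, probability conservation, CEAC
# normalisation) are exercised on arbitrary trees, independent of any one
# case study. Generated payoffs are structural fixtures, not clinically
# meaningful values.

#' Specification for random tree generation
#'
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param max_depth Maximum chance-node depth below each strategy (>= 1).
#' @param branching Number of branches per chance node (>= 2).
#' @param n_strategies Number of decision alternatives (>= 2).
#' @param cost_range,effect_range Ranges for terminal payoffs;
#'   `effect_range` must lie inside \[0, 1\].
#' @return A list of class `tree_gen_spec`.
#' @export
tree_gen_spec <- function(seed, max_depth = 3, branching = 2,
                          n_strategies = 2, cost_range = c(0, 1000),
                          effect_range = c(0, 1)) {
  stopifnot(max_depth >= 1, branching >= 2, n_strategies >= 2,
            cost_range[1] <= cost_range[2], cost_range[1] >= 0,
            effect_range[1] <= effect_range[2],
            effect_range[1] >= 0, effect_range[2] <= 1)
  structure(list(seed = as.integer(seed), max_depth = max_depth,
                 branching = branching, n_strategies = n_strategies,
                 cost_range = cost_range, effect_range = effect_range),
            class = "tree_gen_spec")
}

# Simplex sampling via normalised independent uniforms; the last weight is
# set to the exact complement so the sum is 1 to the last bit.
simplex_probs <- function(k) {
  u <- stats::runif(k)
  p <- u / sum(u)
  p[k] <- 1 - sum(p[-k])
  p
}

#' Generate a random valid decision tree
#'
#' Every generated tree passes [validate_tree()]: chance-node probabilities
#' are drawn from the simplex (summing to one exactly), terminal costs and
#' effects fall in the spec's ranges, and the recursion stops at `max_depth`
#' (with probability 1/2 earlier at each level, so depths vary). With
#' `max_depth = 1` every strategy is a bare terminal.
#'
#' @param spec A [tree_gen_spec()].
#' @return A [decision_tree()] with no free parameters (all payoffs and
#'   probabilities are literals).
#' @export
random_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_gen_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  rand_terminal <- function() {
    terminal_node(payoff(
      cost = stats::runif(1, spec$cost_range[1], spec$cost_range[2]),
      effect = stats::runif(1, spec$effect_range[1], spec$effect_range[2])
    ))
  }
  grow <- function(depth) {
    if (depth >= spec$max_depth || stats::runif(1) < 0.5) {
      return(rand_terminal())
    }
    probs <- simplex_probs(spec$branching)
    chance_node(lapply(seq_len(spec$branching), function(i) {
      branch(p_lit(probs[i]), grow(depth + 1L))
    }))
  }
  alts <- lapply(seq_len(spec$n_strategies), function(i) {
    if (spec$max_depth == 1L) rand_terminal() else grow(1L)
  })
  names(alts) <- paste0("S", seq_len(spec$n_strategies))
  decision_tree(decision_node(alts))
}

#' Shift one parameter of a model
#'
#' Returns an evaluation environment with a single parameter moved by
#' `delta`, leaving the tree untouched — the workhorse for finite-difference
#' checks of sensitivity slopes.
#'
#' @param tree A [decision_tree()].
#' @param parameter Parameter name.
#' @param delta Shift added to the base value. The perturbed value must keep
#'   the tree valid (e.g. probabilities in \[0, 1\]).
#' @return A named numeric environment for [rollback()].
#' @export
perturb <- function(tree, parameter, delta) {
  par <- get_parameter(tree, parameter)
  value <- par$base + delta
  if (par$role %in% c("probability", "utility") && (value < 0 || value > 1)) {
    stop("perturbed ", parameter, " = ", value,
         " leaves the valid domain [0, 1]", call. = FALSE)
  }
  if (par$role == "cost" && value < 0) {
    stop("perturbed ", parameter, " = ", value, " is a negative cost",
         call. = FALSE)
  }
  env <- base_env(tree$parameters, stats::setNames(value, parameter))
  bad <- validate_tree(tree, env)
  if (length(bad)) {
    stop("perturbation leaves the valid domain: ", bad[1L], call. = FALSE)
  }
  env
}
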