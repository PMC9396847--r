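# Decision-tree data model and exact expected-value evaluation.
#
# A tree is: one Decision node at the root (one branch per strategy), Chance
# nodes whose branch probabilities must sum to one, and Terminal nodes holding
# a cost/effect payoff. Probabilities are expressions over the parameter set:
# a literal, a parameter, or the complement 1 - p of a parameter (failure
# branches are complements of survival probabilities, so that probability mass
# is conserved at every chance node by construction).

#' Probability expressions
#'
#' Branch probabilities at chance nodes are one of three expression kinds:
#' a numeric literal, a parameter reference, or the complement `1 - p` of a
#' parameter. `p_lit()`, `p_ref()` and `p_cpl()` construct them; `parse_prob()`
#' reads the string forms used in model-definition files (`"0.85"`,
#' `"preplac"`, `"1 - preplac"`); `deparse_prob()` writes them back.
#'
#' @param x Numeric literal in \[0, 1\] (for `p_lit`); string (for
#'   `parse_prob`); a `prob_expr` (for `deparse_prob`).
#' @param name Parameter name.
#' @return A `prob_expr` object; `deparse_prob()` returns a string.
#' @name prob_expr
NULL

#' @rdname prob_expr
#' @export
p_lit <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x <= 1)
  structure(list(kind = "literal", value = x), class = "prob_expr")
}

#' @rdname prob_expr
#' @export
p_ref <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "param", value = name), class = "prob_expr")
}

#' @rdname prob_expr
#' @export
p_cpl <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "complement", value = name), class = "prob_expr")
}

#' @rdname prob_expr
#' @export
parse_prob <- function(x) {
  if (inherits(x, "prob_expr")) return(x)
  if (is.numeric(x)) return(p_lit(x))
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub(" ", "", x)
  if (grepl("^1-", s)) return(p_cpl(substring(s, 3L)))
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(p_lit(num))
  p_ref(s)
}

#' @rdname prob_expr
#' @export
deparse_prob <- function(x) {
  stopifnot(inherits(x, "prob_expr"))
  switch(x$kind,
         literal = format(x$value, digits = 15),
         param = x$value,
         complement = paste0("1 - ", x$value))
}

eval_prob <- function(expr, env) {
  v <- switch(expr$kind,
              literal = expr$value,
              param = env_lookup(expr$value, env),
              complement = 1 - env_lookup(expr$value, env))
  if (is.na(v) || v < 0 || v > 1) {
    stop("probability expression '", deparse_prob(expr),
         "' evaluates to ", v, ", outside [0, 1]", call. = FALSE)
  }
  v
}

env_lookup <- function(name, env) {
  if (!name %in% names(env)) {
    stop("unbound parameter '", name, "'", call. = FALSE)
  }
  unname(env[[name]])
}

#' Terminal payoff
#'
#' A terminal node's payoff is a cost — the sum of terms, each a parameter
#' reference or numeric literal optionally weighted by a probability expression
#' (used e.g. for expected adverse-event medication cost, probability x unit
#' cost) — and an effect, a parameter reference or literal utility in \[0, 1\].
#'
#' @param cost A list of terms. Each term is either a parameter name, a number,
#'   or a `list(ref = <name or number>, weight = <prob expr, string or
#'   number>)`.
#' @param effect Parameter name or numeric utility.
#' @return A `terminal_payoff` object.
#' @export
#' @examples
#' payoff(cost = list("cImplantPlacement", "cAntibiotics",
#'                    list(ref = 10, weight = "pAE")),
#'        effect = "effImplant")
payoff <- function(cost, effect) {
  if (!is.list(cost)) cost <- list(cost)
  terms <- lapply(cost, function(term) {
    if (is.list(term)) {
      w <- term$weight
      if (!is.null(w) && !is.numeric(w)) w <- parse_prob(w)
      list(ref = term$ref, weight = if (is.null(w)) 1 else w)
    } else {
      list(ref = term, weight = 1)
    }
  })
  structure(list(cost_terms = terms, effect = effect),
            class = "terminal_payoff")
}

eval_payoff <- function(pay, env) {
  cost <- 0
  for (term in pay$cost_terms) {
    v <- if (is.character(term$ref)) env_lookup(term$ref, env) else term$ref
    w <- if (inherits(term$weight, "prob_expr")) {
      eval_prob(term$weight, env)
    } else {
      term$weight
    }
    cost <- cost + v * w
  }
  effect <- if (is.character(pay$effect)) {
    env_lookup(pay$effect, env)
  } else {
    pay$effect
  }
  list(cost = cost, effect = effect)
}

#' Tree node constructors
#'
#' @param payoff A [payoff()] object (terminal nodes).
#' @param label Node label.
#' @param ... For `decision_node()`: named arguments, one per strategy, each a
#'   node. For `chance_node()`: unnamed `branch()` objects.
#' @param prob A probability expression (or string/number coerced through
#'   [parse_prob()]).
#' @param node Child node.
#' @return A `tree_node` (subclass `decision_node`, `chance_node` or
#'   `terminal_node`); `branch()` returns a branch record.
#' @name tree_nodes
NULL

#' @rdname tree_nodes
#' @export
terminal_node <- function(payoff) {
  stopifnot(inherits(payoff, "terminal_payoff"))
  structure(list(payoff = payoff),
            class = c("terminal_node", "tree_node"))
}

#' @rdname tree_nodes
#' @export
branch <- function(prob, node) {
  stopifnot(inherits(node, "tree_node"))
  list(prob = parse_prob(prob), node = node)
}

#' @rdname tree_nodes
#' @export
chance_node <- function(..., label = "") {
  branches <- list(...)
  if (length(branches) == 1L && !("prob" %in% names(branches[[1L]]))) {
    branches <- branches[[1L]]
  }
  stopifnot(length(branches) >= 1L)
  structure(list(label = label, branches = branches),
            class = c("chance_node", "tree_node"))
}

#' @rdname tree_nodes
#' @export
decision_node <- function(..., label = "decision") {
  alts <- list(...)
  if (length(alts) == 1L && !inherits(alts[[1L]], "tree_node")) {
    alts <- alts[[1L]]
  }
  if (is.null(names(alts)) || any(!nzchar(names(alts)))) {
    stop("every strategy (decision alternative) must be named", call. = FALSE)
  }
  if (anyDuplicated(names(alts))) {
    stop("duplicate strategy names", call. = FALSE)
  }
  structure(list(label = label, alternatives = alts),
            class = c("decision_node", "tree_node"))
}

#' Assemble a decision tree
#'
#' Binds a root decision node to the parameter set its probability expressions
#' and payoffs reference.
#'
#' @param root A `decision_node`.
#' @param parameters A [parameter_set()].
#' @return A `decision_tree` object.
#' @export
decision_tree <- function(root, parameters = parameter_set(list())) {
  stopifnot(inherits(root, "decision_node"),
            inherits(parameters, "cea_parameter_set"))
  structure(list(root = root, parameters = parameters),
            class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  cat("<decision tree> strategies:",
      paste(strategies(x), collapse = ", "),
      "|", length(x$parameters), "parameters\n")
  invisible(x)
}

#' Strategy names of a tree
#' @param tree A `decision_tree`.
#' @return Character vector of strategy names, in tree order.
#' @export
strategies <- function(tree) {
  names(tree$root$alternatives)
}

# Tolerance for probability conservation at chance nodes: inputs are exact
# decimals, so anything beyond accumulated double rounding is a model error.
PROB_TOL <- 1e-9

#' Validate a decision tree
#'
#' Checks the structural invariants: exactly one decision node at the root
#' (enforced by construction), branch probabilities at every chance node
#' summing to one within `1e-9`, every referenced parameter declared, payoff
#' costs nonnegative and effects in \[0, 1\] at base values.
#'
#' @param tree A `decision_tree`.
#' @param env Evaluation environment; defaults to base values.
#' @return Character vector of violation descriptions; empty if the tree is
#'   valid. Unresolved parameter references are reported as violations, never
#'   raised as errors.
#' @export
validate_tree <- function(tree, env = base_env(tree$parameters)) {
  stopifnot(inherits(tree, "decision_tree"))
  violations <- character()
  note <- function(msg) violations <<- c(violations, msg)

  safe_prob <- function(expr, where) {
    tryCatch(eval_prob(expr, env), error = function(e) {
      if (grepl("unbound parameter", conditionMessage(e))) {
        note(paste0(where, ": unknown parameter in probability '",
                    deparse_prob(expr), "'"))
      } else {
        note(paste0(where, ": ", conditionMessage(e)))
      }
      NA_real_
    })
  }

  walk <- function(node, where) {
    if (inherits(node, "decision_node")) {
      if (where != "root") note(paste0(where, ": decision node below the root"))
      for (s in names(node$alternatives)) {
        walk(node$alternatives[[s]], paste0("strategy '", s, "'"))
      }
    } else if (inherits(node, "chance_node")) {
      here <- if (nzchar(node$label)) {
        paste0(where, " > chance '", node$label, "'")
      } else {
        paste0(where, " > chance")
      }
      probs <- vapply(node$branches, function(b) safe_prob(b$prob, here),
                      numeric(1))
      if (!anyNA(probs) && abs(sum(probs) - 1) > PROB_TOL) {
        note(sprintf("%s: probabilities sum to %.10g != 1", here, sum(probs)))
      }
      for (b in node$branches) walk(b$node, here)
    } else if (inherits(node, "terminal_node")) {
      res <- tryCatch(eval_payoff(node$payoff, env), error = function(e) {
        if (grepl("unbound parameter", conditionMessage(e))) {
          note(paste0(where, " > terminal: unknown parameter (",
                      conditionMessage(e), ")"))
        } else {
          note(paste0(where, " > terminal: ", conditionMessage(e)))
        }
        NULL
      })
      if (!is.null(res)) {
        if (res$cost < 0) {
          note(sprintf("%s > terminal: cost %.6g < 0", where, res$cost))
        }
        if (res$effect < 0 || res$effect > 1) {
          note(sprintf("%s > terminal: effect %.6g outside [0, 1]",
                       where, res$effect))
        }
      }
    }
  }
  walk(tree$root, "root")
  violations
}

#' Evaluate a tree by rollback
#'
#' Backward induction: expected cost and effect at a chance node are the
#' probability-weighted sums over its branches; a terminal contributes its
#' payoff. For each strategy this equals the sum over root-to-leaf paths of
#' path probability times path payoff (see [enumerate_paths()], the brute-force
#' oracle; the two differ only by floating-point association, well under 1e-9
#' on any sane tree).
#'
#' @param tree A `decision_tree`.
#' @param env Named numeric vector binding every referenced parameter; defaults
#'   to base values. Use `base_env(tree$parameters, overrides)` to shift
#'   parameters.
#' @return A tibble with columns `strategy`, `expected_cost`,
#'   `expected_effect`, one row per strategy.
#' @export
#' @examples
#' toy <- decision_tree(decision_node(
#'   a = terminal_node(payoff(7, 0.5)),
#'   b = chance_node(branch(0.5, terminal_node(payoff(10, 0))),
#'                   branch(0.5, terminal_node(payoff(20, 1))))
#' ))
#' rollback(toy)
rollback <- function(tree, env = base_env(tree$parameters)) {
  stopifnot(inherits(tree, "decision_tree"))
  eval_node <- function(node) {
    if (inherits(node, "terminal_node")) {
      eval_payoff(node$payoff, env)
    } else if (inherits(node, "chance_node")) {
      cost <- 0; effect <- 0
      for (b in node$branches) {
        p <- eval_prob(b$prob, env)
        sub <- eval_node(b$node)
        cost <- cost + p * sub$cost
        effect <- effect + p * sub$effect
      }
      list(cost = cost, effect = effect)
    } else {
      stop("decision node below the root", call. = FALSE)
    }
  }
  alts <- tree$root$alternatives
  res <- lapply(alts, eval_node)
  tibble::tibble(
    strategy = names(alts),
    expected_cost = unname(vapply(res, `[[`, numeric(1), "cost")),
    expected_effect = unname(vapply(res, `[[`, numeric(1), "effect"))
  )
}

#' Enumerate root-to-leaf paths
#'
#' The brute-force oracle for [rollback()]: lists every path from the decision
#' root to a terminal with its probability and payoff. Within each strategy
#' path probabilities sum to one, and the probability-weighted payoff sums
#' equal the rollback output to within 1e-9.
#'
#' @inheritParams rollback
#' @return A tibble with columns `strategy`, `probability`, `cost`, `effect`,
#'   one row per path.
#' @export
enumerate_paths <- function(tree, env = base_env(tree$parameters)) {
  stopifnot(inherits(tree, "decision_tree"))
  rows <- list()
  walk <- function(node, strategy, prob) {
    if (inherits(node, "terminal_node")) {
      pay <- eval_payoff(node$payoff, env)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        strategy = strategy, probability = prob,
        cost = pay$cost, effect = pay$effect)
    } else if (inherits(node, "chance_node")) {
      for (b in node$branches) {
        walk(b$node, strategy, prob * eval_prob(b$prob, env))
      }
    } else {
      stop("decision node below the root", call. = FALSE)
    }
  }
  for (s in strategies(tree)) {
    walk(tree$root$alternatives[[s]], s, 1)
  }
  dplyr::bind_rows(rows)
}
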