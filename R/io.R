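# Model-definition files: a YAML dialect holding the parameter table and the
# tree (nested node records; probabilities as the strings "p", "1 - p" or
# literals). read -> write -> read is the identity.

node_to_list <- function(node) {
  if (inherits(node, "terminal_node")) {
    pay <- node$payoff
    cost <- lapply(pay$cost_terms, function(term) {
      w <- term$weight
      if (is.numeric(w) && identical(unname(w), 1)) return(term$ref)
      list(ref = term$ref,
           weight = if (inherits(w, "prob_expr")) deparse_prob(w) else w)
    })
    list(kind = "terminal", cost = cost, effect = pay$effect)
  } else if (inherits(node, "chance_node")) {
    list(kind = "chance", label = node$label,
         branches = lapply(node$branches, function(b) {
           list(prob = deparse_prob(b$prob), node = node_to_list(b$node))
         }))
  } else {
    stop("unexpected node class", call. = FALSE)
  }
}

node_from_list <- function(x) {
  if (x$kind == "terminal") {
    cost <- lapply(x$cost, function(term) {
      if (is.list(term)) {
        w <- term$weight
        list(ref = num_or_chr(term$ref),
             weight = if (is.character(w)) parse_prob(w) else as.numeric(w))
      } else {
        num_or_chr(term)
      }
    })
    terminal_node(payoff(cost, num_or_chr(x$effect)))
  } else if (x$kind == "chance") {
    chance_node(lapply(x$branches, function(b) {
      branch(parse_prob(as.character(b$prob)), node_from_list(b$node))
    }), label = if (is.null(x$label)) "" else x$label)
  } else {
    stop("unknown node kind '", x$kind, "'", call. = FALSE)
  }
}

num_or_chr <- function(x) if (is.character(x)) x else as.numeric(x)

#' Read and write model-definition files
#'
#' A model-definition file is YAML with two sections: `parameters` (one
#' record per parameter: name, base, low, high, distribution, role,
#' description) and `tree` (the decision root: label plus one named strategy
#' record per alternative; chance nodes carry `branches` with probability
#' expression strings such as `"pantsurv"`, `"1 - pantsurv"` or `"0.5"`;
#' terminals carry `cost` term lists and an `effect`). Reading a written
#' model returns an identical object.
#'
#' @param tree A [decision_tree()] (for `write_model`).
#' @param path File path.
#' @return `read_model()` returns a [decision_tree()]; `write_model()`
#'   returns `path` invisibly.
#' @export
write_model <- function(tree, path) {
  stopifnot(inherits(tree, "decision_tree"))
  params <- lapply(unname(tree$parameters), function(p) {
    list(name = p$name, base = p$base, low = p$low, high = p$high,
         distribution = p$distribution, role = p$role,
         description = p$description)
  })
  strategies <- lapply(names(tree$root$alternatives), function(s) {
    list(name = s, node = node_to_list(tree$root$alternatives[[s]]))
  })
  doc <- list(parameters = params,
              tree = list(label = tree$root$label, strategies = strategies))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  params <- parameter_set(lapply(doc$parameters, function(p) {
    parameter(p$name, as.numeric(p$base), as.numeric(p$low),
              as.numeric(p$high), p$distribution, p$role,
              if (is.null(p$description)) "" else p$description)
  }))
  alts <- lapply(doc$tree$strategies, function(s) node_from_list(s$node))
  names(alts) <- vapply(doc$tree$strategies, `[[`, character(1), "name")
  decision_tree(decision_node(alts, label = doc$tree$label),
                parameters = params)
}
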