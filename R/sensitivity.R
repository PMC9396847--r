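# Deterministic sensitivity analysis: one-way sweeps over a parameter's
# tested range, NMB-equality threshold finding by a bracketing root solver,
# and tornado (influence) ranking across parameters.

#' One-way sensitivity sweep
#'
#' Re-evaluates the whole tree by [rollback()] at `n_points` equally spaced
#' values of one parameter across its tested range (all other parameters held
#' at base values) and records each strategy's net monetary benefit and the
#' preferred (max-NMB) strategy at each grid value.
#'
#' @param tree A [decision_tree()].
#' @param parameter Name of the parameter to sweep.
#' @param wtp Willingness to pay (EUR per unit effect).
#' @param n_points Grid size (>= 2); default 101.
#' @param range Optional `c(low, high)` overriding the parameter's tested
#'   range.
#' @return A tibble with columns `parameter`, `value`, `strategy`, `nmb`,
#'   `preferred` (the max-NMB strategy at that grid value). The grid always
#'   contains both range endpoints.
#' @export
one_way <- function(tree, parameter, wtp, n_points = 101, range = NULL) {
  par <- get_parameter(tree, parameter)
  if (is.null(range)) range <- c(par$low, par$high)
  if (!(range[1] < range[2])) {
    stop("degenerate range for parameter '", parameter, "'", call. = FALSE)
  }
  stopifnot(n_points >= 2)
  grid <- seq(range[1], range[2], length.out = n_points)
  rows <- lapply(grid, function(v) {
    res <- rollback(tree, base_env(tree$parameters, stats::setNames(v, parameter)))
    s_nmb <- nmb(res$expected_cost, res$expected_effect, wtp)
    tibble::tibble(parameter = parameter, value = v,
                   strategy = res$strategy, nmb = s_nmb,
                   preferred = res$strategy[which.max(s_nmb)])
  })
  dplyr::bind_rows(rows)
}

get_parameter <- function(tree, parameter) {
  if (!parameter %in% names(tree$parameters)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  tree$parameters[[parameter]]
}

#' Find the parameter value equalising two strategies
#'
#' Solves `NMB(intervention) - NMB(comparator) = 0` over one parameter with a
#' bracketing root solver ([stats::uniroot()], relative tolerance `1e-8`); the
#' NMB difference is continuous in any single parameter of a decision tree, so
#' a sign change across the bracket guarantees a root. Past the returned
#' threshold the preferred strategy switches.
#'
#' @param tree A [decision_tree()].
#' @param parameter Parameter to solve over.
#' @param wtp Willingness to pay.
#' @param strategies Length-2 character vector `c(intervention, comparator)`;
#'   defaults to the tree's first two strategies.
#' @param bracket `c(low, high)` interval to search; defaults to the
#'   parameter's tested range. The NMB difference must change sign across it.
#' @param tol Relative solver tolerance.
#' @return A list of class `threshold_result` with elements `parameter`,
#'   `threshold`, `wtp`, `bracket`, `dnmb` (the residual NMB difference at the
#'   threshold) and `f` (the ΔNMB function, for diagnostics).
#' @export
find_threshold <- function(tree, parameter, wtp,
                           strategies = NULL, bracket = NULL, tol = 1e-8) {
  par <- get_parameter(tree, parameter)
  if (is.null(bracket)) bracket <- c(par$low, par$high)
  if (is.null(strategies)) strategies <- utils::head(strategies(tree), 2L)
  stopifnot(length(strategies) == 2L)
  f <- function(v) {
    res <- rollback(tree, base_env(tree$parameters,
                                   stats::setNames(v, parameter)))
    s_nmb <- nmb(res$expected_cost, res$expected_effect, wtp)
    s_nmb[res$strategy == strategies[1L]] - s_nmb[res$strategy == strategies[2L]]
  }
  f_lo <- f(bracket[1]); f_hi <- f(bracket[2])
  if (sign(f_lo) * sign(f_hi) > 0) {
    stop("no threshold in range [", bracket[1], ", ", bracket[2],
         "]: NMB difference does not change sign (",
         strategies[1L], " remains ",
         if (f_lo > 0) "preferred" else "dominated",
         " across the bracket)", call. = FALSE)
  }
  root <- stats::uniroot(f, interval = bracket, f.lower = f_lo, f.upper = f_hi,
                         tol = tol * max(1, abs(bracket[2])), maxiter = 200)
  structure(
    list(parameter = parameter, threshold = root$root, wtp = wtp,
         bracket = bracket, dnmb = f(root$root), f = f),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold> %s = %.6g (WTP %g, bracket [%g, %g], residual dNMB %.3g)\n",
    x$parameter, x$threshold, x$wtp, x$bracket[1], x$bracket[2], x$dnmb))
  invisible(x)
}

#' Tornado (influence) analysis
#'
#' Evaluates a chosen output metric at each parameter's range endpoints, with
#' all other parameters at base values, and ranks parameters by the span of
#' the output — the standard tornado-diagram data. The default metric is the
#' incremental NMB of the intervention over the comparator; the ICER is
#' available but unstable when the effect difference is near zero.
#'
#' @param tree A [decision_tree()].
#' @param wtp Willingness to pay.
#' @param parameters Character vector of parameters to rank; defaults to all
#'   parameters with a non-degenerate tested range.
#' @param strategies Length-2 `c(intervention, comparator)`; defaults to the
#'   tree's first two strategies.
#' @param output `"incremental_nmb"` (default) or `"icer"`.
#' @return A tibble with columns `parameter`, `low`, `high`, `output_at_low`,
#'   `output_at_high`, `span`, sorted by decreasing span.
#' @export
tornado <- function(tree, wtp, parameters = NULL, strategies = NULL,
                    output = c("incremental_nmb", "icer")) {
  output <- match.arg(output)
  if (is.null(strategies)) strategies <- utils::head(strategies(tree), 2L)
  stopifnot(length(strategies) == 2L)
  if (is.null(parameters)) {
    all_p <- as_tibble_params(tree$parameters)
    parameters <- all_p$name[all_p$high > all_p$low]
  }
  if (!length(parameters)) stop("empty parameter list", call. = FALSE)

  metric <- function(env) {
    res <- rollback(tree, env)
    i <- res$strategy == strategies[1L]
    j <- res$strategy == strategies[2L]
    if (output == "incremental_nmb") {
      nmb(res$expected_cost[i], res$expected_effect[i], wtp) -
        nmb(res$expected_cost[j], res$expected_effect[j], wtp)
    } else {
      de <- res$expected_effect[i] - res$expected_effect[j]
      if (abs(de) < DELTA_E_TOL) NA_real_ else
        (res$expected_cost[i] - res$expected_cost[j]) / de
    }
  }
  rows <- lapply(parameters, function(pname) {
    par <- get_parameter(tree, pname)
    at <- function(v) metric(base_env(tree$parameters,
                                      stats::setNames(v, pname)))
    lo <- at(par$low); hi <- at(par$high)
    tibble::tibble(parameter = pname, low = par$low, high = par$high,
                   output_at_low = lo, output_at_high = hi,
                   span = abs(hi - lo))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$span))
}

#' Write deterministic-sensitivity tables to CSV
#'
#' `write_one_way_csv()` writes a one-way curve in wide form (one NMB column
#' per strategy plus the preferred strategy); `write_threshold_csv()` writes a
#' threshold table (one row per `threshold_result`); `write_tornado_csv()`
#' writes the tornado ranking as-is.
#'
#' @param curve Output of [one_way()].
#' @param thresholds A list of `threshold_result` objects.
#' @param tornado_table Output of [tornado()].
#' @param path File path.
#' @return The written tibble, invisibly.
#' @name sensitivity_csv
NULL

#' @rdname sensitivity_csv
#' @export
write_one_way_csv <- function(curve, path) {
  wide <- tidyr::pivot_wider(curve, names_from = "strategy",
                             values_from = "nmb", names_prefix = "nmb_")
  readr::write_csv(wide, path)
  invisible(wide)
}

#' @rdname sensitivity_csv
#' @export
write_threshold_csv <- function(thresholds, path) {
  if (inherits(thresholds, "threshold_result")) thresholds <- list(thresholds)
  tab <- dplyr::bind_rows(lapply(thresholds, function(t) {
    tibble::tibble(parameter = t$parameter, wtp = t$wtp,
                   range_low = t$bracket[1], range_high = t$bracket[2],
                   threshold = t$threshold)
  }))
  readr::write_csv(tab, path)
  invisible(tab)
}

#' @rdname sensitivity_csv
#' @export
write_tornado_csv <- function(tornado_table, path) {
  readr::write_csv(tornado_table, path)
  invisible(tornado_table)
}
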