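#' Define a model parameter
#'
#' A parameter is a named model input carrying a base-case value, the range
#' tested in deterministic sensitivity analysis, a distribution family used in
#' probabilistic sensitivity analysis, and a role that determines which
#' distribution rule applies to it.
#'
#' @param name Parameter name (a syntactic identifier, e.g. `"cAntibiotics"`).
#' @param base Base-case value.
#' @param low,high Tested range; must satisfy `low <= base <= high`. Default to
#'   `base` (a degenerate range, fine for parameters never swept).
#' @param distribution Distribution family for PSA: `"fixed"` (never sampled),
#'   `"normal"` (costs; truncated at zero) or `"beta"` (probabilities and
#'   utilities).
#' @param role What the parameter measures: `"cost"` (EUR, nonnegative),
#'   `"probability"` or `"utility"` (both constrained to \[0, 1\]), or
#'   `"other"`.
#' @param description Free-text description.
#'
#' @return An object of class `cea_parameter`.
#' @seealso [parameter_set()], [build_distributions()]
#' @export
#' @examples
#' parameter("cAntibiotics", 10.20, 5, 100, "normal", "cost",
#'           "Cost of a single antibiotic course")
parameter <- function(name, base, low = base, high = base,
                      distribution = c("fixed", "normal", "beta"),
                      role = c("other", "cost", "probability", "utility"),
                      description = "") {
  distribution <- match.arg(distribution)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(base), length(base) == 1L, is.finite(base))
  base <- as.numeric(base); low <- as.numeric(low); high <- as.numeric(high)
  if (!(low <= base && base <= high)) {
    stop("parameter '", name, "': requires low <= base <= high, got [",
         low, ", ", base, ", ", high, "]", call. = FALSE)
  }
  if (role %in% c("probability", "utility") &&
      (low < 0 || high > 1)) {
    stop("parameter '", name, "': ", role,
         " values must lie in [0, 1]", call. = FALSE)
  }
  if (role == "cost" && low < 0) {
    stop("parameter '", name, "': costs must be nonnegative", call. = FALSE)
  }
  structure(
    list(name = name, base = base, low = low, high = high,
         distribution = distribution, role = role,
         description = description),
    class = "cea_parameter"
  )
}

#' Bundle parameters into a set
#'
#' @param ... `cea_parameter` objects (or a single list of them).
#' @return A named list of parameters with class `cea_parameter_set`.
#' @export
parameter_set <- function(...) {
  params <- list(...)
  if (length(params) == 1L && !inherits(params[[1L]], "cea_parameter")) {
    params <- params[[1L]]
  }
  ok <- vapply(params, inherits, logical(1), "cea_parameter")
  if (!all(ok)) stop("all arguments must be cea_parameter objects", call. = FALSE)
  nm <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate parameter names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(params) <- nm
  structure(params, class = "cea_parameter_set")
}

#' @export
print.cea_parameter <- function(x, ...) {
  cat(sprintf("<parameter> %s = %g  [%g, %g]  (%s, %s)\n",
              x$name, x$base, x$low, x$high, x$distribution, x$role))
  invisible(x)
}

#' @export
print.cea_parameter_set <- function(x, ...) {
  cat("<parameter set> ", length(x), " parameters\n", sep = "")
  print(as_tibble_params(x))
  invisible(x)
}

#' Parameter set as a tibble
#'
#' @param params A `cea_parameter_set`.
#' @return A tibble with one row per parameter.
#' @export
as_tibble_params <- function(params) {
  stopifnot(inherits(params, "cea_parameter_set"))
  tibble::tibble(
    name = vapply(params, `[[`, character(1), "name"),
    base = vapply(params, `[[`, numeric(1), "base"),
    low = vapply(params, `[[`, numeric(1), "low"),
    high = vapply(params, `[[`, numeric(1), "high"),
    distribution = vapply(params, `[[`, character(1), "distribution"),
    role = vapply(params, `[[`, character(1), "role"),
    description = vapply(params, `[[`, character(1), "description")
  )
}

#' Base-value evaluation environment
#'
#' Collapses a parameter set to the named numeric vector of base values used by
#' [rollback()] and friends, optionally overriding some entries.
#'
#' @param params A `cea_parameter_set`.
#' @param overrides Named numeric vector or list of values replacing base
#'   values.
#' @return Named numeric vector.
#' @export
base_env <- function(params, overrides = NULL) {
  env <- vapply(params, `[[`, numeric(1), "base")
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(env))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    env[names(overrides)] <- overrides
  }
  env
}
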