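# Probabilistic sensitivity analysis: distribution assignment, seeded
# Monte Carlo sampling, per-draw rollback, CEAC and ICE-plane summaries.
#
# Hyperparameter rules. Published parameter tables rarely state distribution
# hyperparameters, only base values and tested ranges, so the defaults here
# derive them from the table: cost parameters get a normal distribution with
# mean = base and sd = (high - low)/3.92 (the tested range read as a central
# 95% interval), truncated at zero by rejection so draws stay nonnegative
# without distorting the retained shape; utility parameters get a
# mean-matched beta with concentration kappa = alpha + beta = 100
# (alpha = kappa * mean). Both rules are arguments, not constants.

#' Assign sampling distributions to parameters
#'
#' Builds one `DistributionSpec` per parameter: parameters named in `sampled`
#' get their family from their role (`cost` -> truncated normal, `utility` or
#' `probability` -> beta); everything else is held fixed at its base value.
#'
#' @param params A [parameter_set()].
#' @param sampled Character vector of parameter names to sample. Defaults to
#'   every parameter whose declared `distribution` is not `"fixed"`.
#' @param sd_rule Function `(low, high) -> sd` for normal specs; default
#'   `(high - low)/3.92`.
#' @param kappa Beta concentration (`alpha + beta`); mean is matched to the
#'   base value, so `alpha = kappa * base`.
#' @return A list of class `dist_specs`; each element has `parameter`,
#'   `family` (`"fixed"`, `"normal"`, `"beta"`) and family-specific fields
#'   (`mean`, `sd`, `lower` for normal; `alpha`, `beta` for beta; `value` for
#'   fixed).
#' @export
build_distributions <- function(params, sampled = NULL,
                                sd_rule = function(low, high) (high - low) / 3.92,
                                kappa = 100) {
  stopifnot(inherits(params, "cea_parameter_set"))
  if (is.null(sampled)) {
    sampled <- names(params)[vapply(params, function(p)
      p$distribution != "fixed", logical(1))]
  }
  unknown <- setdiff(sampled, names(params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  specs <- lapply(params, function(p) {
    if (!p$name %in% sampled) {
      return(list(parameter = p$name, family = "fixed", value = p$base))
    }
    family <- if (p$distribution != "fixed") p$distribution
              else if (p$role == "cost") "normal" else "beta"
    if (family == "beta") {
      if (p$base <= 0 || p$base >= 1) {
        stop("beta distribution requested for '", p$name,
             "' with base ", p$base, " outside (0, 1)", call. = FALSE)
      }
      list(parameter = p$name, family = "beta",
           alpha = kappa * p$base, beta = kappa * (1 - p$base))
    } else {
      sd <- sd_rule(p$low, p$high)
      if (!is.finite(sd) || sd <= 0) {
        stop("nonpositive sd for '", p$name, "'", call. = FALSE)
      }
      list(parameter = p$name, family = "normal",
           mean = p$base, sd = sd, lower = 0)
    }
  })
  names(specs) <- names(params)
  structure(specs, class = "dist_specs")
}

draw_one <- function(spec, n) {
  switch(spec$family,
    fixed = rep(spec$value, n),
    beta = stats::rbeta(n, spec$alpha, spec$beta),
    normal = {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      # rejection below the truncation bound preserves the conditional shape
      bad <- which(x < spec$lower)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), spec$mean, spec$sd)
        bad <- bad[x[bad] < spec$lower]
      }
      x
    },
    stop("unknown family '", spec$family, "'", call. = FALSE))
}

#' Draw a seeded Monte Carlo parameter sample
#'
#' Samples `n` independent draws per parameter under a fixed seed; the same
#' seed always regenerates the identical matrix. Support constraints (normal
#' truncation, beta in (0,1)) are enforced at draw time by rejection.
#'
#' @param specs A `dist_specs` from [build_distributions()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return An object of class `psa_draws`: list with `n`, `seed` and `draws`,
#'   an `n x p` matrix with one column per parameter.
#' @export
sample_draws <- function(specs, n, seed) {
  stopifnot(inherits(specs, "dist_specs"), n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draws <- vapply(specs, draw_one, numeric(n), n = n)
  if (n == 1L) draws <- matrix(draws, nrow = 1L,
                               dimnames = list(NULL, names(specs)))
  structure(list(n = n, seed = seed, draws = draws), class = "psa_draws")
}

#' @export
print.psa_draws <- function(x, ...) {
  cat(sprintf("<psa draws> n = %d, seed = %d, %d parameters\n",
              x$n, x$seed, ncol(x$draws)))
  invisible(x)
}

#' Run the probabilistic sensitivity analysis
#'
#' Rolls the tree back once per draw, binding sampled parameters to the
#' draw's values. A draw that breaks tree validity (a probability outside
#' \[0, 1\]) is resampled from the spec rather than clipped; the number of
#' resampled draws is recorded in the `n_resampled` attribute.
#'
#' @param tree A [decision_tree()].
#' @param draws A `psa_draws` (covering every sampled parameter) from
#'   [sample_draws()].
#' @param specs The `dist_specs` the draws came from (needed only to resample
#'   invalid draws; optional).
#' @return A tibble of class `psa_result` with columns `draw`, `strategy`,
#'   `cost`, `effect` — the per-draw CE scatter data.
#' @export
run_psa <- function(tree, draws, specs = NULL) {
  stopifnot(inherits(tree, "decision_tree"), inherits(draws, "psa_draws"))
  mat <- draws$draws
  out <- vector("list", draws$n)
  n_resampled <- 0L
  rng_saved <- FALSE
  old_seed <- NULL
  for (i in seq_len(draws$n)) {
    row <- mat[i, ]
    attempt <- 0L
    repeat {
      env <- base_env(tree$parameters, row)
      res <- tryCatch(rollback(tree, env), error = function(e) e)
      if (!inherits(res, "error")) break
      if (is.null(specs) || attempt >= 1000L) {
        stop("draw ", i, " violates tree validity: ",
             conditionMessage(res), call. = FALSE)
      }
      if (!rng_saved) {
        # resampling stream is seeded from the draws' seed so the full PSA
        # stays bit-reproducible; the caller's RNG state is untouched
        old_seed <- if (exists(".Random.seed", globalenv())) {
          get(".Random.seed", globalenv())
        }
        set.seed(draws$seed %% 2147483647L + 1L)
        rng_saved <- TRUE
      }
      row <- vapply(specs, draw_one, numeric(1), n = 1L)
      n_resampled <- n_resampled + 1L
      attempt <- attempt + 1L
    }
    out[[i]] <- tibble::tibble(draw = i, strategy = res$strategy,
                               cost = res$expected_cost,
                               effect = res$expected_effect)
  }
  if (rng_saved && !is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_resampled") <- n_resampled
  class(res) <- c("psa_result", class(res))
  res
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that a strategy is
#' optimal is the fraction of draws in which it attains the maximal net
#' monetary benefit; draws where `k` strategies tie at the maximum contribute
#' `1/k` to each, so probabilities sum to one exactly at every WTP.
#'
#' @param psa_results A `psa_result` from [run_psa()].
#' @param wtp_grid Nondecreasing, nonnegative WTP values; default 0 to 10,000
#'   in steps of 100.
#' @return A tibble with columns `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa_results, wtp_grid = seq(0, 10000, by = 100)) {
  stopifnot(nrow(psa_results) > 0,
            all(wtp_grid >= 0), !is.unsorted(wtp_grid))
  wide <- tidyr::pivot_wider(
    psa_results[c("draw", "strategy", "cost", "effect")],
    names_from = "strategy", values_from = c("cost", "effect"))
  strat <- unique(psa_results$strategy)
  n <- nrow(wide)
  cost <- as.matrix(wide[paste0("cost_", strat)])
  effect <- as.matrix(wide[paste0("effect_", strat)])
  rows <- lapply(wtp_grid, function(w) {
    b <- w * effect - cost
    mx <- do.call(pmax, as.data.frame(b))
    win <- b >= mx  # ties share the draw fractionally
    share <- win / rowSums(win)
    tibble::tibble(wtp = w, strategy = strat,
                   probability = unname(colSums(share)) / n)
  })
  dplyr::bind_rows(rows)
}

#' Incremental cost-effectiveness plane summary
#'
#' Per-draw incremental cost and effect of the intervention over the
#' comparator, with counts per quadrant of the CE plane and the number of
#' draws in which the intervention has strictly the higher net monetary
#' benefit at the given WTP. Quadrants are assigned deterministically:
#' `delta_effect > 0` goes east, `delta_cost > 0` goes north, and boundary
#' draws (a zero difference) go west/south respectively.
#'
#' @param psa_results A `psa_result` from [run_psa()].
#' @param wtp Willingness to pay.
#' @param intervention,comparator Strategy names.
#' @return A list of class `ice_summary`: `wtp`, `n`, `quadrant_counts`
#'   (named NE/NW/SW/SE), `n_preferred`, and `deltas`, a tibble with per-draw
#'   `delta_cost` and `delta_effect` (the ICE scatter data).
#' @export
ice_summary <- function(psa_results, wtp, intervention, comparator) {
  strat <- unique(psa_results$strategy)
  stopifnot(intervention %in% strat, comparator %in% strat)
  a <- psa_results[psa_results$strategy == intervention, ]
  b <- psa_results[psa_results$strategy == comparator, ]
  a <- a[order(a$draw), ]; b <- b[order(b$draw), ]
  dc <- a$cost - b$cost
  de <- a$effect - b$effect
  quad <- ifelse(de > 0,
                 ifelse(dc > 0, "NE", "SE"),
                 ifelse(dc > 0, "NW", "SW"))
  counts <- vapply(c("NE", "NW", "SW", "SE"),
                   function(q) sum(quad == q), integer(1))
  structure(
    list(wtp = wtp, n = length(dc),
         quadrant_counts = counts,
         n_preferred = sum(wtp * de - dc > 0),
         deltas = tibble::tibble(draw = a$draw, delta_cost = dc,
                                 delta_effect = de)),
    class = "ice_summary"
  )
}

#' @export
print.ice_summary <- function(x, ...) {
  cat(sprintf("<ICE summary> WTP %g: intervention preferred in %d/%d draws\n",
              x$wtp, x$n_preferred, x$n))
  print(x$quadrant_counts)
  invisible(x)
}

#' Write PSA tables to CSV
#'
#' `write_psa_csv()` writes the per-draw CE table, `write_ceac_csv()` the
#' acceptability curves, `write_ice_csv()` the per-draw incremental deltas.
#'
#' @param psa_results,ceac_table,ice An object from [run_psa()], [ceac()],
#'   [ice_summary()] respectively.
#' @param path File path.
#' @return The written tibble, invisibly.
#' @name psa_csv
NULL

#' @rdname psa_csv
#' @export
write_psa_csv <- function(psa_results, path) {
  readr::write_csv(tibble::as_tibble(psa_results), path)
  invisible(psa_results)
}

#' @rdname psa_csv
#' @export
write_ceac_csv <- function(ceac_table, path) {
  readr::write_csv(ceac_table, path)
  invisible(ceac_table)
}

#' @rdname psa_csv
#' @export
write_ice_csv <- function(ice, path) {
  readr::write_csv(ice$deltas, path)
  invisible(ice$deltas)
}
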