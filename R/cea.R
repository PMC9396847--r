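# Incremental cost-effectiveness metrics against a common baseline.

# Tolerance below which an effectiveness difference counts as a tie and the
# ICER is reported as undefined (NA) rather than a huge ratio.
DELTA_E_TOL <- 1e-12

#' Net monetary benefit
#'
#' `NMB = WTP x effect - cost`: the monetary value of a strategy's health
#' effect at a given willingness to pay, net of its cost. The strategy with
#' maximal NMB at a given WTP is preferred.
#'
#' @param cost Expected cost (EUR). Vectorised.
#' @param effect Expected effectiveness (utility). Vectorised.
#' @param wtp Willingness to pay, EUR per unit of effectiveness; must be
#'   nonnegative.
#' @return NMB in EUR.
#' @export
#' @examples
#' nmb(1023.64, 0.879495, 3000)  # ~ 1614.84
nmb <- function(cost, effect, wtp) {
  stopifnot(is.numeric(wtp), all(wtp >= 0))
  wtp * effect - cost
}

#' Incremental cost-effectiveness table
#'
#' For each strategy, computes cost and effect differences against a common
#' baseline, the ICER (incremental cost / incremental effect, signed; `NA`
#' when the effect difference is below `1e-12`), the net monetary benefit at
#' the given WTP, and a dominance label. A strategy is *absolutely dominated*
#' if some other strategy has strictly lower cost and strictly higher effect;
#' it is *extendedly dominated* if it is excluded from the efficiency
#' [frontier()] without being absolutely dominated.
#'
#' @param results A tibble as returned by [rollback()] (columns `strategy`,
#'   `expected_cost`, `expected_effect`).
#' @param baseline Name of the baseline strategy.
#' @param wtp Willingness to pay (EUR per unit effect).
#' @return A tibble with columns `strategy`, `cost`, `incr_cost`, `effect`,
#'   `incr_effect`, `icer`, `nmb`, `dominance`. The baseline row has zero
#'   increments and `NA` ICER.
#' @export
incremental_table <- function(results, baseline, wtp) {
  check_results(results)
  if (!baseline %in% results$strategy) {
    stop("baseline strategy '", baseline, "' not present", call. = FALSE)
  }
  base <- results[results$strategy == baseline, ]
  incr_cost <- results$expected_cost - base$expected_cost
  incr_effect <- results$expected_effect - base$expected_effect
  icer <- ifelse(abs(incr_effect) < DELTA_E_TOL, NA_real_,
                 incr_cost / incr_effect)
  icer[results$strategy == baseline] <- NA_real_
  tibble::tibble(
    strategy = results$strategy,
    cost = results$expected_cost,
    incr_cost = incr_cost,
    effect = results$expected_effect,
    incr_effect = incr_effect,
    icer = icer,
    nmb = nmb(results$expected_cost, results$expected_effect, wtp),
    dominance = dominance_labels(results)
  )
}

check_results <- function(results) {
  need <- c("strategy", "expected_cost", "expected_effect")
  if (!all(need %in% names(results))) {
    stop("results must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(results$strategy)) {
    stop("duplicate strategy names", call. = FALSE)
  }
  invisible(results)
}

dominance_labels <- function(results) {
  n <- nrow(results)
  cost <- results$expected_cost
  effect <- results$expected_effect
  abs_dom <- vapply(seq_len(n), function(i) {
    any(cost < cost[i] & effect > effect[i])
  }, logical(1))
  on_frontier <- results$strategy %in% frontier(results)$strategy
  labels <- rep("undominated", n)
  labels[!on_frontier] <- "extendedly_dominated"
  labels[abs_dom] <- "absolutely_dominated"
  labels
}

#' Efficiency frontier
#'
#' The subset of strategies that are optimal (maximise NMB) at some
#' nonnegative willingness to pay: strategies are ordered by increasing
#' effectiveness, absolutely dominated strategies removed, then strategies
#' whose removal restores a strictly increasing sequence of pairwise ICERs
#' (extendedly dominated) removed iteratively.
#'
#' @param results A tibble as returned by [rollback()].
#' @return The rows of `results` on the frontier, ordered by increasing
#'   effect.
#' @export
frontier <- function(results) {
  check_results(results)
  df <- results[order(results$expected_cost, -results$expected_effect), ]
  # strong dominance: walking up the cost ordering, keep only strategies that
  # strictly improve on the best effect seen so far (first at equal cost wins)
  keep <- logical(nrow(df))
  best_eff <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$expected_effect[i] > best_eff) {
      keep[i] <- TRUE
      best_eff <- df$expected_effect[i]
    }
  }
  df <- df[keep, ]
  # extended dominance: drop interior strategies until consecutive ICERs
  # strictly increase
  repeat {
    if (nrow(df) <= 2L) break
    icers <- diff(df$expected_cost) / diff(df$expected_effect)
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    df <- df[-(bad[1L] + 1L), ]
  }
  df[order(df$expected_effect), ]
}

#' ICER magnitude with dominance annotation
#'
#' Presentation helper: the signed ICER from [incremental_table()] is the
#' machine quantity; reports often print its magnitude together with the
#' dominance label (a negative ICER against a dominated comparator and the
#' positive ratio quoted in text are the same number).
#'
#' @param icer Signed ICER (vectorised).
#' @return `abs(icer)`.
#' @export
icer_magnitude <- function(icer) abs(icer)

#' Write an incremental table to CSV
#'
#' @param table Output of [incremental_table()] (optionally with extra
#'   columns such as `perspective`).
#' @param path File path.
#' @return `table`, invisibly.
#' @export
write_incremental_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(table)
}
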