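# Incremental cost-effectiveness analysis of two cohort traces. The ICER
# is the difference in expected discounted cost divided by the difference
# in expected discounted effect (QALY or LY), best practice minus basic.
# Dominance is classified before any ratio is reported, and
# cost-effectiveness at a willingness-to-pay threshold is judged by the
# sign of net monetary benefit, which remains well-defined in the
# southeast quadrant where a ratio misleads.

#' Incremental cost-effectiveness of two strategies
#'
#' Computes per-strategy expected discounted cost, QALY and LY, the
#' incrementals (best practice minus basic), the ICERs per QALY and per
#' LY, and the dominance classification. ICERs are reported only when the
#' comparison is a genuine trade-off (both incrementals positive, or both
#' negative); if the best-practice arm is cheaper and at least as
#' effective it dominates and no ratio is reported.
#'
#' @param trace_basic,trace_bp `cess_trace` objects from [run_cohort()]
#'   for the basic and best-practice arms, run under the same sex,
#'   horizon and settings.
#' @return A `cess_cea` object: list with `by_strategy` (tibble of totals
#'   per arm), `d_cost`, `d_qaly`, `d_ly`, `icer_qaly`, `icer_ly`
#'   (unrounded; `NA` when undefined or dominated), `dominance`
#'   (`"none"`, `"bp_dominant"`, `"bp_dominated"`), and `sex`.
#' @examples
#' ce <- compute_icer(run_cohort("basic", "male"),
#'                    run_cohort("best_practice", "male"))
#' glance(ce)
#' @export
compute_icer <- function(trace_basic, trace_bp) {
  if (!identical(attr(trace_basic, "sex"), attr(trace_bp, "sex")))
    abort("traces are for different sexes")
  if (nrow(trace_basic) != nrow(trace_bp))
    abort("traces have different horizons")
  a <- attr(trace_basic, "totals")
  b <- attr(trace_bp, "totals")
  d_cost <- b$cost - a$cost
  d_qaly <- b$qaly - a$qaly
  d_ly <- b$ly - a$ly

  dominance <- "none"
  if (d_cost <= 0 && d_qaly >= 0 && !(d_cost == 0 && d_qaly == 0))
    dominance <- "bp_dominant"
  else if (d_cost >= 0 && d_qaly <= 0 && !(d_cost == 0 && d_qaly == 0))
    dominance <- "bp_dominated"

  ratio_ok <- function(dc, de) {
    dominance == "none" && de != 0 && ((dc > 0 && de > 0) || (dc < 0 && de < 0))
  }
  icer_qaly <- if (ratio_ok(d_cost, d_qaly)) d_cost / d_qaly else NA_real_
  icer_ly <- if (dominance == "none" && d_ly != 0 &&
                 ((d_cost > 0 && d_ly > 0) || (d_cost < 0 && d_ly < 0)))
    d_cost / d_ly else NA_real_

  by_strategy <- bind_rows(glance(trace_basic), glance(trace_bp))
  structure(list(by_strategy = by_strategy,
                 d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
                 icer_qaly = icer_qaly, icer_ly = icer_ly,
                 dominance = dominance,
                 sex = attr(trace_basic, "sex")),
            class = "cess_cea")
}

#' Net monetary benefit
#'
#' `NMB = lambda * dQALY - dCost`; non-negative exactly when the
#' incremental comparison is cost-effective at willingness-to-pay
#' `lambda`.
#'
#' @param d_cost Incremental cost (CAD); vectorised.
#' @param d_qaly Incremental QALYs; vectorised.
#' @param lambda Willingness-to-pay threshold (CAD per QALY), >= 0.
#' @return Numeric NMB (CAD).
#' @examples
#' net_monetary_benefit(101, 0.03, 50000)
#' @export
net_monetary_benefit <- function(d_cost, d_qaly, lambda) {
  if (any(lambda < 0)) abort("lambda must be >= 0")
  lambda * d_qaly - d_cost
}

#' @export
print.cess_cea <- function(x, ...) {
  cat(sprintf("<cess_cea> best practice vs basic (%s)\n", x$sex))
  cat(sprintf("  dCost $%.2f, dQALY %.5f, dLY %.5f\n",
              x$d_cost, x$d_qaly, x$d_ly))
  if (x$dominance != "none") {
    cat("  dominance:", x$dominance, "\n")
  } else {
    cat(sprintf("  ICER: $%.0f/QALY, $%.0f/LY\n",
                round(x$icer_qaly), round(x$icer_ly)))
  }
  invisible(x)
}

#' Tidy a cost-effectiveness result
#'
#' @param x A `cess_cea`.
#' @param ... Unused.
#' @return A tibble mirroring the usual published layout: one row per
#'   strategy with discounted cost/QALY/LY, an `incremental` row, and an
#'   `ICER` row with the dollar-rounded ratios.
#' @export
tidy.cess_cea <- function(x, ...) {
  bind_rows(
    x$by_strategy %>% select("strategy", "cost", "qaly", "ly"),
    tibble(strategy = "incremental", cost = x$d_cost, qaly = x$d_qaly,
           ly = x$d_ly),
    tibble(strategy = "ICER", cost = NA_real_,
           qaly = if (is.na(x$icer_qaly)) NA_real_ else round(x$icer_qaly),
           ly = if (is.na(x$icer_ly)) NA_real_ else round(x$icer_ly)))
}

#' One-row summary of a cost-effectiveness result
#'
#' @param x A `cess_cea`.
#' @param ... Unused.
#' @return A tibble with the incrementals, unrounded ICERs, and dominance
#'   status.
#' @export
glance.cess_cea <- function(x, ...) {
  tibble(sex = x$sex, d_cost = x$d_cost, d_qaly = x$d_qaly, d_ly = x$d_ly,
         icer_qaly = x$icer_qaly, icer_ly = x$icer_ly,
         dominance = x$dominance)
}

#' Write a cost-effectiveness result as CSV
#'
#' @param cea A `cess_cea`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cea <- function(cea, path) {
  readr::write_csv(tidy(cea), path)
  invisible(path)
}
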