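# Yearly-cycle Markov cohort engine. Three clinical states — current
# smoker, former smoker, dead — with the former-smoker state expanded into
# one-year tunnel compartments so relapse can depend on years since
# quitting (bands 1-2, 3-4, 5-8, 9-10, 10+ years). Relapsers re-enter
# smoking through a separate compartment (S_rel) that is identical to S in
# mortality, cost and utility but is only ever eligible for self-quit:
# program-driven quitting is a one-time offer.
#
# Event order within a cycle is fixed: death first (by current age and
# status), then quit/relapse among survivors. Any fixed order conserves
# probability; this one makes every transition probability a simple
# product and keeps tests deterministic.

.states <- c("S", "S_rel",
             "F1_1", "F1_2", "F2_1", "F2_2",
             "F3_1", "F3_2", "F3_3", "F3_4",
             "F4_1", "F4_2", "F5", "D")
.f_states <- .states[3:13]

#' The expanded Markov state space
#'
#' @return A tibble describing each state: `state` (column order of the
#'   transition matrix), `kind` (`smoker`/`former`/`dead`), and for former
#'   compartments the relapse band and year-since-quit they encode.
#' @export
state_space <- function() {
  tibble(
    state = .states,
    kind = c("smoker", "smoker", rep("former", 11), "dead"),
    band = c(NA, NA, "1-2", "1-2", "3-4", "3-4", "5-8", "5-8", "5-8",
             "5-8", "9-10", "9-10", "10+", NA),
    years_since_quit = c(NA, NA, 1:10, NA, NA)
  ) %>% mutate(years_since_quit = replace(.data$years_since_quit,
                                          .data$state == "F5", 11))
}

# Annual relapse probability of each former-smoker tunnel compartment.
.relapse_vector <- function(params) {
  c(F1_1 = params$relapse_1_2, F1_2 = params$relapse_1_2,
    F2_1 = params$relapse_3_4, F2_2 = params$relapse_3_4,
    F3_1 = params$relapse_5_8, F3_2 = params$relapse_5_8,
    F3_3 = params$relapse_5_8, F3_4 = params$relapse_5_8,
    F4_1 = params$relapse_9_10, F4_2 = params$relapse_9_10,
    F5 = params$relapse_10plus)
}

# Probability that a surviving never-relapsed smoker quits this cycle.
.quit_prob <- function(strategy, cycle, params) {
  s <- params$settings
  if (strategy == "best_practice") {
    if (cycle == 1) params$abstinence_bp_y1
    else if (cycle == 2) params$program_quit_y2
    else params$self_quit
  } else {
    if (cycle == 1) params$abstinence_basic_y1
    else if (cycle == 2 && s$year2_program_quit_both_arms) params$program_quit_y2
    else params$self_quit
  }
}

.check_strategy <- function(strategy) {
  if (!strategy %in% c("basic", "best_practice"))
    abort("strategy must be 'basic' or 'best_practice'")
  strategy
}

#' Build the one-cycle transition matrix
#'
#' Explicit row-stochastic matrix over the expanded tunnel state space for
#' one cycle at a given age, strategy and cycle index. Death is applied
#' first from every living state using `p_death(age, status)`; among
#' survivors, smokers quit (entering the first former-smoker year) with
#' the strategy's schedule — the program abstinence rate at cycle 1, the
#' year-2 program quit rate at cycle 2 (best-practice arm), self-quit
#' thereafter — and former smokers relapse at their band's annual rate or
#' advance one tunnel year.
#'
#' @param age Attained age for the cycle (must be covered by `mort`).
#' @param sex `"male"` or `"female"` (matched against `mort`).
#' @param strategy `"basic"` or `"best_practice"`.
#' @param cycle 1-based cycle index.
#' @param params A `cess_params` object.
#' @param mort Adjusted-mortality tibble from
#'   [derive_adjusted_mortality()].
#' @return A 14 x 14 matrix with `dimnames` from [state_space()]; every
#'   row sums to 1.
#' @examples
#' mort <- derive_adjusted_mortality(make_life_table("male"),
#'                                   make_cause_split("male"))
#' M <- build_transition_matrix(65, "male", "best_practice", 1,
#'                              default_params(), mort)
#' M["S", c("S", "F1_1", "D")]
#' @export
build_transition_matrix <- function(age, sex, strategy, cycle, params, mort) {
  .check_strategy(strategy)
  if (cycle < 1) abort("cycle must be >= 1")
  sub <- mort[mort$sex == sex & mort$age == age, ]
  if (nrow(sub) == 0) abort("age not covered by the mortality table")
  pdS <- sub$p_death[sub$status == "current"]
  pdF <- sub$p_death[sub$status == "former"]

  qS <- .quit_prob(strategy, cycle, params)
  qR <- params$self_quit
  r <- .relapse_vector(params)

  n <- length(.states)
  M <- matrix(0, n, n, dimnames = list(.states, .states))
  M["S", "D"] <- pdS
  M["S", "F1_1"] <- (1 - pdS) * qS
  M["S", "S"] <- (1 - pdS) * (1 - qS)
  M["S_rel", "D"] <- pdS
  M["S_rel", "F1_1"] <- (1 - pdS) * qR
  M["S_rel", "S_rel"] <- (1 - pdS) * (1 - qR)
  succ <- c(.f_states[-1], "F5")  # next tunnel year; F5 self-loops
  for (i in seq_along(.f_states)) {
    st <- .f_states[i]
    M[st, "D"] <- pdF
    M[st, "S_rel"] <- (1 - pdF) * r[[st]]
    M[st, succ[i]] <- M[st, succ[i]] + (1 - pdF) * (1 - r[[st]])
  }
  M["D", "D"] <- 1
  M
}

#' Per-cycle payoff accrual
#'
#' Undiscounted cost, QALY and life-years accrued by an occupancy vector
#' over one cycle: annual cancer-care cost on the alive fraction (when
#' `include_cancer_cost`), smoking-attributable cost on current smokers,
#' the one-time program cost at cycle 1 (charged to the whole entering
#' cohort; basic arm: administration only; best-practice arm:
#' administration + nurse counseling fee + varenicline), utility by sex,
#' age band and status minus the cancer decrement, and the alive fraction
#' as life-years.
#'
#' The cohort runner discounts the recurring part of the cost and the
#' QALY/LY by `(1 + r)^-cycle`; the one-time program cost is charged
#' undiscounted at entry, so the discounted cost ledger is not simply this
#' function's cost times the discount factor at cycle 1.
#'
#' @param occupancy Named numeric vector over [state_space()] states
#'   (fractions of the cohort).
#' @param age Attained age for the cycle; must be within the utility
#'   bands (65-100).
#' @param sex,strategy,cycle,params As in [build_transition_matrix()].
#' @return A one-row tibble with columns `cost`, `qaly`, `ly`.
#' @examples
#' occ <- setNames(c(1, rep(0, 13)), state_space()$state)
#' accrue_cycle(occ, 70, "male", "best_practice", 2, default_params())
#' @export
accrue_cycle <- function(occupancy, age, sex, strategy, cycle, params) {
  .check_strategy(strategy)
  smokers <- occupancy[["S"]] + occupancy[["S_rel"]]
  formers <- sum(occupancy[.f_states])
  alive <- smokers + formers

  u_cur <- .utility_lookup(params, sex, age, "current") - params$cancer_decrement
  u_frm <- .utility_lookup(params, sex, age, "former") - params$cancer_decrement

  cost <- params$smoking_attrib_cost * smokers
  if (params$settings$include_cancer_cost)
    cost <- cost + params$annual_cancer_cost * alive
  if (cycle == 1) cost <- cost + .program_cost(strategy, params)

  tibble(cost = cost,
         qaly = smokers * u_cur + formers * u_frm,
         ly = alive)
}

.program_cost <- function(strategy, params) {
  if (strategy == "best_practice")
    params$bp_admin + params$nurse_fee + params$varenicline
  else params$basic_admin
}

#' Run the cohort simulation for one strategy
#'
#' Starts the whole cohort as 65-year-old current smokers and iterates the
#' yearly transition/accrual cycle to the horizon (`end_age - start_age`
#' cycles, 35 by default). Cycle `t` uses the transition matrix for age
#' `start_age + t - 1` and discounts payoffs by `(1 + r)^-t`; the one-time
#' program cost is charged undiscounted at entry. With
#' `half_cycle_correction = TRUE` payoffs are computed on the average of
#' the cycle's start and end occupancy.
#'
#' @param strategy `"basic"` or `"best_practice"`.
#' @param sex `"male"` or `"female"`.
#' @param params A `cess_params` object.
#' @param mort Adjusted mortality from [derive_adjusted_mortality()];
#'   defaults to the packaged synthetic inputs for `sex`.
#' @return A `cess_trace`: a tibble with one row per cycle (cycle, age,
#'   occupancy of every state, per-cycle and cumulative cost/QALY/LY,
#'   discounted and undiscounted), carrying the strategy, sex and
#'   discounted totals as attributes. [glance()] extracts the totals.
#' @examples
#' tr <- run_cohort("basic", "male")
#' glance(tr)
#' @export
run_cohort <- function(strategy, sex, params = default_params(),
                       mort = NULL) {
  .check_strategy(strategy)
  .check_sex(sex)
  if (is.null(mort))
    mort <- derive_adjusted_mortality(make_life_table(sex),
                                      make_cause_split(sex), params)
  s <- params$settings
  horizon <- as.integer(round((s$end_age - s$start_age) / s$cycle_length))
  pd <- .mortality_vectors(mort[mort$sex == sex, ], s$start_age, horizon)
  r <- .relapse_vector(params)
  qR <- params$self_quit
  disc <- (1 + s$discount_rate)^-(seq_len(horizon))

  occ <- setNames(numeric(length(.states)), .states)
  occ["S"] <- 1
  rows <- vector("list", horizon)

  for (t in seq_len(horizon)) {
    age <- s$start_age + t - 1
    pdS <- pd$current[t]; pdF <- pd$former[t]
    qS <- .quit_prob(strategy, t, params)
    occ_pre <- occ

    f <- occ[.f_states]
    surv_f <- f * (1 - pdF)
    relapse_in <- sum(surv_f * r)
    stay_f <- surv_f * (1 - r)
    new <- occ
    new["S"] <- occ[["S"]] * (1 - pdS) * (1 - qS)
    new["S_rel"] <- occ[["S_rel"]] * (1 - pdS) * (1 - qR) + relapse_in
    quit_in <- occ[["S"]] * (1 - pdS) * qS + occ[["S_rel"]] * (1 - pdS) * qR
    # advance tunnels: F1_1 -> F1_2 -> ... -> F4_2 -> F5 (absorbing band)
    new[.f_states] <- c(quit_in, stay_f[-length(stay_f)])
    new["F5"] <- new[["F5"]] + stay_f[["F5"]]
    new["D"] <- occ[["D"]] + pdS * (occ[["S"]] + occ[["S_rel"]]) + pdF * sum(f)
    occ <- new

    occ_pay <- if (s$half_cycle_correction) (occ_pre + occ) / 2 else occ
    pay <- accrue_cycle(occ_pay, age, sex, strategy, t, params)
    program <- if (t == 1) .program_cost(strategy, params) else 0
    recurring <- pay$cost - program

    rows[[t]] <- tibble(
      cycle = t, age = age, !!!as.list(occ),
      cost = pay$cost, qaly = pay$qaly, ly = pay$ly,
      cost_disc = recurring * disc[t] + program,
      qaly_disc = pay$qaly * disc[t],
      ly_disc = pay$ly * disc[t])
  }

  trace <- bind_rows(rows) %>%
    mutate(cum_cost = cumsum(.data$cost),
           cum_qaly = cumsum(.data$qaly),
           cum_ly = cumsum(.data$ly),
           cum_cost_disc = cumsum(.data$cost_disc),
           cum_qaly_disc = cumsum(.data$qaly_disc),
           cum_ly_disc = cumsum(.data$ly_disc))
  structure(trace,
            class = c("cess_trace", class(trace)),
            strategy = strategy, sex = sex,
            totals = list(
              cost = sum(trace$cost_disc), qaly = sum(trace$qaly_disc),
              ly = sum(trace$ly_disc), cost_undisc = sum(trace$cost),
              qaly_undisc = sum(trace$qaly), ly_undisc = sum(trace$ly)))
}

#' @export
print.cess_trace <- function(x, ...) {
  tt <- attr(x, "totals")
  cat(sprintf("<cess_trace> %s, %s: %d cycles\n", attr(x, "strategy"),
              attr(x, "sex"), nrow(x)))
  cat(sprintf("  discounted totals: cost $%.0f, %.3f QALY, %.3f LY\n",
              tt$cost, tt$qaly, tt$ly))
  NextMethod()
}

#' Tidy a cohort trace
#'
#' @param x A `cess_trace`.
#' @param ... Unused.
#' @return The per-cycle trace as a plain tibble (occupancy and ledgers).
#' @export
tidy.cess_trace <- function(x, ...) {
  as_tibble(unclass(x)[!names(unclass(x)) %in% character()])
}

#' One-row summary of a cohort trace
#'
#' @param x A `cess_trace`.
#' @param ... Unused.
#' @return A tibble with the strategy, sex, and total discounted and
#'   undiscounted cost, QALY and LY.
#' @export
glance.cess_trace <- function(x, ...) {
  tt <- attr(x, "totals")
  tibble(strategy = attr(x, "strategy"), sex = attr(x, "sex"),
         cost = tt$cost, qaly = tt$qaly, ly = tt$ly,
         cost_undisc = tt$cost_undisc, qaly_undisc = tt$qaly_undisc,
         ly_undisc = tt$ly_undisc)
}

#' Write a cohort trace as CSV
#'
#' @param trace A `cess_trace`.
#' @param path Output CSV path (one row per cycle).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tidy(trace), path)
  invisible(path)
}
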