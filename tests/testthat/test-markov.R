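default_mort <- function(sex = "male", params = default_params()) {
  derive_adjusted_mortality(make_life_table(sex), make_cause_split(sex),
                            params)
}

test_that("transition matrix encodes the quit schedule and relapse bands", {
  p <- default_params()
  zm <- zero_mortality()
  M1 <- build_transition_matrix(65, "male", "best_practice", 1, p, zm)
  expect_equal(M1["S", "F1_1"], 0.24)
  expect_equal(M1["S", "S"], 0.76)
  expect_equal(M1["F1_1", "S_rel"], 0.24)     # relapse band 1-2 years
  expect_equal(M1["F2_1", "S_rel"], 0.10)
  expect_equal(M1["F5", "S_rel"], 0.005)
  expect_equal(M1["F5", "F5"], 0.995)
  Mb <- build_transition_matrix(65, "male", "basic", 1, p, zm)
  expect_equal(Mb["S", "F1_1"], 0.04)
  # year 2: program quitting in the best-practice arm, self-quit in basic
  M2 <- build_transition_matrix(66, "male", "best_practice", 2, p, zm)
  expect_equal(M2["S", "F1_1"], 0.02)
  Mb2 <- build_transition_matrix(66, "male", "basic", 2, p, zm)
  expect_equal(Mb2["S", "F1_1"], 0.015)
  # year 3+: self-quit in both; relapsers only ever self-quit
  M3 <- build_transition_matrix(67, "male", "best_practice", 3, p, zm)
  expect_equal(M3["S", "F1_1"], 0.015)
  expect_equal(M2["S_rel", "F1_1"], 0.015)
})

test_that("death competes first and rows remain stochastic", {
  p <- default_params()
  mort <- dplyr::bind_rows(
    tibble::tibble(sex = "male", age = 65, status = "current", p_death = 0.1),
    tibble::tibble(sex = "male", age = 65, status = "former", p_death = 0.08))
  M <- build_transition_matrix(65, "male", "best_practice", 1, p, mort)
  expect_equal(M["S", "D"], 0.1)
  expect_equal(M["S", "F1_1"], 0.9 * 0.24)
  expect_equal(M["S", "S"], 0.9 * 0.76)
  expect_equal(M["F1_1", "D"], 0.08)
  expect_true(all(abs(rowSums(M) - 1) < 1e-12))
  expect_equal(M["D", ], setNames(c(rep(0, 13), 1), colnames(M)))
})

test_that("transition matrices are row-stochastic across ages, cycles and arms", {
  p <- default_params()
  mort <- default_mort()
  for (strategy in c("basic", "best_practice"))
    for (cycle in c(1, 2, 3, 20))
      for (age in c(65, 75, 99)) {
        M <- build_transition_matrix(age, "male", strategy, cycle, p, mort)
        expect_true(all(M >= 0 & M <= 1))
        expect_true(all(abs(rowSums(M) - 1) < 1e-12))
      }
  expect_error(build_transition_matrix(65, "male", "basic", 0, p, mort),
               "cycle")
  expect_error(build_transition_matrix(65, "male", "deluxe", 1, p, mort),
               "strategy")
  expect_error(build_transition_matrix(300, "male", "basic", 1, p, mort),
               "age")
})

test_that("a frozen cohort accrues the geometric-series discounted life-years", {
  p <- frozen_params()
  tr <- run_cohort("basic", "male", p, zero_mortality())
  occ <- tidy(tr)[, state_space()$state]
  expect_true(all(occ$S == 1))
  expect_true(all(occ[, setdiff(names(occ), "S")] == 0))
  tt <- attr(tr, "totals")
  expect_equal(tt$ly_undisc, 35)
  expect_equal(tt$ly, sum(1.05^-(1:35)), tolerance = 1e-9)
  expect_equal(tt$ly, 16.374, tolerance = 1e-3)
})

test_that("the engine matches an explicit matrix-power oracle", {
  p <- default_params()
  for (sex in c("male", "female")) {
    mort <- default_mort(sex)
    for (strategy in c("basic", "best_practice")) {
      tr <- run_cohort(strategy, sex, p, mort)
      oracle <- matrix_power_trace(strategy, sex, p, mort)
      got <- as.matrix(tidy(tr)[, state_space()$state])
      expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
    }
  }
})

test_that("trace invariants hold: conservation, monotone death, discounting, QALY <= LY", {
  p <- default_params()
  for (sex in c("male", "female")) for (st in c("basic", "best_practice")) {
    tr <- tidy(run_cohort(st, sex, p))
    expect_true(all(abs(rowSums(tr[, state_space()$state]) - 1) < 1e-12))
    expect_true(all(diff(tr$D) >= 0))
    expect_true(all(tr$cost_disc <= tr$cost + 1e-9))
    expect_true(all(tr$qaly_disc <= tr$qaly + 1e-12))
    expect_true(all(tr$ly_disc <= tr$ly + 1e-12))
    expect_true(all(tr$qaly <= tr$ly + 1e-12))
    expect_lte(dplyr::last(tr$cum_qaly_disc), dplyr::last(tr$cum_ly_disc))
  }
})

test_that("zero discounting collapses the two ledgers", {
  p <- default_params()
  p$settings$discount_rate <- 0
  tr <- tidy(run_cohort("best_practice", "male", p))
  expect_equal(tr$cost_disc, tr$cost, tolerance = 1e-12)
  expect_equal(tr$qaly_disc, tr$qaly, tolerance = 1e-12)
  expect_equal(tr$ly_disc, tr$ly, tolerance = 1e-12)
})

test_that("total cost is linear in the cost parameters", {
  p <- default_params()
  k <- 3.7
  pk <- p
  for (nm in c("nurse_fee", "bp_admin", "basic_admin", "varenicline",
               "annual_cancer_cost", "smoking_attrib_cost"))
    pk[[nm]] <- k * p[[nm]]
  mort <- default_mort()
  for (st in c("basic", "best_practice")) {
    t1 <- attr(run_cohort(st, "male", p, mort), "totals")
    tk <- attr(run_cohort(st, "male", pk, mort), "totals")
    expect_equal(tk$cost, k * t1$cost, tolerance = 1e-12)
    expect_equal(tk$qaly, t1$qaly, tolerance = 1e-12)
  }
})

test_that("equalising the arms makes their traces identical", {
  p <- default_params()
  p$abstinence_basic_y1 <- p$abstinence_bp_y1
  p$program_quit_y2 <- p$self_quit
  p$basic_admin <- p$bp_admin + p$nurse_fee + p$varenicline
  mort <- default_mort()
  tb <- tidy(run_cohort("basic", "male", p, mort))
  tp <- tidy(run_cohort("best_practice", "male", p, mort))
  expect_equal(tb, tp, tolerance = 1e-14)
})

test_that("the more intensive program never loses health", {
  p <- default_params()
  for (sex in c("male", "female")) {
    mort <- default_mort(sex)
    a <- attr(run_cohort("basic", sex, p, mort), "totals")
    b <- attr(run_cohort("best_practice", sex, p, mort), "totals")
    expect_gte(b$qaly, a$qaly)
    expect_gte(b$ly, a$ly)
  }
})

test_that("half-cycle correction averages start and end occupancy", {
  p <- frozen_params()
  p$settings$half_cycle_correction <- TRUE
  mort <- dplyr::bind_rows(
    tibble::tibble(sex = "male", age = 65:110, status = "current",
                   p_death = 0.5),
    tibble::tibble(sex = "male", age = 65:110, status = "former",
                   p_death = 0.5))
  tr <- tidy(run_cohort("basic", "male", p, mort))
  # alive halves each cycle; payoff uses the midpoint of start/end
  expect_equal(tr$ly[1], 0.75)
  expect_equal(tr$ly[2], 0.375)
})

test_that("cycle payoffs follow utilities, costs and state occupancy", {
  p <- default_params()
  states <- state_space()$state
  occ <- setNames(numeric(14), states)
  occ["S"] <- 1
  pay <- accrue_cycle(occ, 70, "male", "best_practice", 2, p)
  expect_equal(pay$qaly, 0.7551 - 0.12)
  expect_equal(pay$qaly, 0.6351)
  expect_equal(pay$ly, 1)
  expect_equal(pay$cost, 25058 + 403)
  # age band switch at 75
  expect_equal(accrue_cycle(occ, 75, "male", "best_practice", 2, p)$qaly,
               0.7089 - 0.12)
  # one-time program cost at cycle 1 on top of the recurring streams
  p0 <- p; p0$annual_cancer_cost <- 0; p0$smoking_attrib_cost <- 0
  expect_equal(accrue_cycle(occ, 70, "male", "best_practice", 1, p0)$cost,
               47 + 105 + 150)
  expect_equal(accrue_cycle(occ, 70, "male", "basic", 1, p0)$cost, 16)
  # former smokers drop the smoking-attributable cost
  occf <- setNames(numeric(14), states); occf["F2_1"] <- 1
  expect_equal(accrue_cycle(occf, 70, "male", "basic", 3, p)$cost, 25058)
  expect_equal(accrue_cycle(occf, 70, "male", "basic", 3, p)$qaly,
               0.7802 - 0.12)
  # the dead accrue nothing
  occd <- setNames(numeric(14), states); occd["D"] <- 1
  pay_d <- accrue_cycle(occd, 70, "male", "basic", 3, p)
  expect_equal(unlist(pay_d), c(cost = 0, qaly = 0, ly = 0))
  expect_error(accrue_cycle(occ, 101, "male", "basic", 3, p), "utility bands")
})

test_that("the year-2 program-quit flag can cover both arms", {
  p <- default_params()
  p$settings$year2_program_quit_both_arms <- TRUE
  M <- build_transition_matrix(66, "male", "basic", 2, p, zero_mortality())
  expect_equal(M["S", "F1_1"], p$program_quit_y2)
})

test_that("trace CSV export has one row per cycle", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(run_cohort("basic", "male"), f)
  df <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(df), 35)
  expect_true(all(c("cycle", "age", "S", "D", "cost_disc") %in% names(df)))
})
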