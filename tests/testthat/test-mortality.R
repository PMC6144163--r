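# Helpers building tiny hand-specified life tables for closed-form checks.
mini_lt <- function(q, ages = 65:(64 + length(q)), sex = "male") {
  tibble::tibble(sex = sex, age = ages, q = q)
}
mini_cs <- function(f, ages = 65:(64 + length(f)), sex = "male") {
  tibble::tibble(sex = sex, age = ages, f_cancer = f)
}

test_that("hazard decomposition matches the closed form", {
  hz <- split_mortality(mini_lt(0.02), mini_cs(0.5))
  m <- -log(0.98)
  expect_equal(m, 0.020203, tolerance = 1e-4)
  expect_equal(hz$hazard_cancer, m / 2, tolerance = 1e-12)
  expect_equal(hz$hazard_other, m / 2, tolerance = 1e-12)
  expect_equal(hz$hazard_cancer, 0.010101, tolerance = 1e-4)
})

test_that("degenerate splits behave", {
  hz0 <- split_mortality(mini_lt(0.02), mini_cs(0))
  expect_equal(hz0$hazard_cancer, 0)
  expect_equal(hz0$hazard_other, -log(0.98), tolerance = 1e-12)
  hzq0 <- split_mortality(mini_lt(0), mini_cs(0.5))
  expect_equal(hzq0$hazard_cancer, 0)
  expect_equal(hzq0$hazard_other, 0)
  expect_error(split_mortality(mini_lt(c(0.1, 0.2)), mini_cs(0.5)),
               "same ages")
})

test_that("hazard-ratio adjustment matches closed forms (both scopes agree at f_cancer = 0)", {
  # with f_cancer = 0 and multiplier 1 the baseline hazard is just m
  lt <- mini_lt(1 - exp(-0.02))  # m0 = 0.02
  cs <- mini_cs(0)
  for (scope in c("non_cancer", "all_cause")) {
    p <- default_params()
    p$settings$hr_scope <- scope
    p$settings$excess_cancer_multiplier <- 1
    mort <- derive_adjusted_mortality(lt, cs, p)
    expect_equal(mort$p_death[mort$status == "current"],
                 1 - exp(-1.5 * 0.02), tolerance = 1e-12)
    expect_equal(mort$p_death[mort$status == "current"], 0.029554,
                 tolerance = 1e-4)
    expect_equal(mort$p_death[mort$status == "former"],
                 1 - exp(-1.3 * 0.02), tolerance = 1e-12)
    expect_equal(mort$p_death[mort$status == "former"], 0.025665,
                 tolerance = 1e-4)
    p$hr_current_vs_never <- 1; p$hr_former_vs_never <- 1
    mort1 <- derive_adjusted_mortality(lt, cs, p)
    expect_equal(unique(mort1$p_death), 0.019801, tolerance = 1e-4)
  }
})

test_that("all-cause scope scales the full baseline hazard", {
  lt <- mini_lt(0.05); cs <- mini_cs(0.4)
  p <- default_params()
  p$settings$hr_scope <- "all_cause"
  mort <- derive_adjusted_mortality(lt, cs, p, excess_cancer_multiplier = 2)
  m <- -log(0.95)
  m0 <- m * 0.6 + 2 * m * 0.4
  expect_equal(mort$p_death[mort$status == "current"],
               1 - exp(-1.5 * m0), tolerance = 1e-12)
  # non-cancer scope leaves the cancer component unscaled by the HR
  p$settings$hr_scope <- "non_cancer"
  mort2 <- derive_adjusted_mortality(lt, cs, p, excess_cancer_multiplier = 2)
  expect_equal(mort2$p_death[mort2$status == "current"],
               1 - exp(-(1.5 * m * 0.6 + 2 * m * 0.4)), tolerance = 1e-12)
})

test_that("probability approximates HR times hazard for small hazards", {
  m0 <- c(1e-4, 1e-3, 5e-3, 9e-3)
  lt <- mini_lt(1 - exp(-m0))
  cs <- mini_cs(rep(0, 4))
  p <- default_params()
  p$settings$excess_cancer_multiplier <- 1
  mort <- derive_adjusted_mortality(lt, cs, p)
  for (st in c("current", "former")) {
    hr <- if (st == "current") p$hr_current_vs_never else p$hr_former_vs_never
    rel <- abs(mort$p_death[mort$status == st] / (hr * m0) - 1)
    expect_true(all(rel < 0.01))
  }
})

test_that("mortality is monotone in the hazard ratio and ordered by status", {
  lt <- mini_lt(0.03); cs <- mini_cs(0.5)
  hrs <- c(0.5, 1, 1.3, 1.5, 2, 3)
  ps <- sapply(hrs, function(h) {
    p <- default_params()
    p$hr_current_vs_never <- h
    derive_adjusted_mortality(lt, cs, p)$p_death[1]
  })
  expect_true(all(diff(ps) > 0))

  mort <- derive_adjusted_mortality(make_life_table("male"),
                                    make_cause_split("male"))
  wide <- tidyr::pivot_wider(mort, names_from = "status",
                             values_from = "p_death")
  expect_true(all(wide$current >= wide$former))  # hr_current >= hr_former
  expect_true(all(diff(wide$current) >= 0))      # monotone in age
  expect_true(all(mort$p_death >= 0 & mort$p_death <= 1))
})

test_that("identity settings reproduce the input life table", {
  lt <- make_life_table("female")
  cs <- make_cause_split("female", 0, 0)
  p <- default_params()
  p$hr_current_vs_never <- 1
  p$hr_former_vs_never <- 1
  mort <- derive_adjusted_mortality(lt, cs, p, excess_cancer_multiplier = 1)
  for (st in c("current", "former"))
    expect_equal(mort$p_death[mort$status == st], lt$q, tolerance = 1e-9)
})

test_that("invalid hazard ratios are rejected", {
  p <- default_params()
  p$hr_current_vs_never <- 0
  expect_error(
    derive_adjusted_mortality(make_life_table("male"),
                              make_cause_split("male"), p),
    "hazard ratios")
  expect_error(
    derive_adjusted_mortality(make_life_table("male"),
                              make_cause_split("male"),
                              excess_cancer_multiplier = 0.5),
    "multiplier")
})

test_that("adjusted mortality exports with the documented schema", {
  f <- withr::local_tempfile(fileext = ".csv")
  mort <- derive_adjusted_mortality(make_life_table("male"),
                                    make_cause_split("male"))
  write_adjusted_mortality(mort, f)
  df <- readr::read_csv(f, show_col_types = FALSE)
  expect_named(df, c("age", "status", "p_death"))
})
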