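# Shared fixtures: published input values re-keyed by hand (independent of
# the package's registry), degenerate model configurations, and a
# trace stub for exercising the incremental analysis with chosen totals.

# Hand-copied published parameter set (base, lower, upper) used to audit
# the packaged defaults field by field.
table1_fixture <- list(
  abstinence_bp_y1    = c(0.24, 0.14, 0.36),
  abstinence_basic_y1 = c(0.04, 0.03, 0.05),
  program_quit_y2     = c(0.02, 0.02, 0.03),
  self_quit           = c(0.015, 0.012, 0.018),
  relapse_1_2         = c(0.24, 0.19, 0.29),
  relapse_3_4         = c(0.10, 0.08, 0.12),
  relapse_5_8         = c(0.02, 0.016, 0.024),
  relapse_9_10        = c(0.021, 0.017, 0.025),
  relapse_10plus      = c(0.005, 0.004, 0.006),
  hr_current_vs_never = c(1.50, 1.07, 1.50),
  hr_former_vs_never  = c(1.30, 0.95, 1.81),
  nurse_fee           = c(105, 95, 116),
  bp_admin            = c(47, 33, 61),
  basic_admin         = c(16, 15, 18),
  varenicline         = c(150, 105, 195),
  annual_cancer_cost  = c(25058, 24897, 25219),
  smoking_attrib_cost = c(403, 262, 486),
  cancer_decrement    = c(0.12, 0.11, 0.13)
)

table1_utilities <- c(
  utility_male_current_65_74    = 0.7551,
  utility_male_current_75_100   = 0.7089,
  utility_male_former_65_74     = 0.7802,
  utility_male_former_75_100    = 0.7358,
  utility_female_current_65_74  = 0.7496,
  utility_female_current_75_100 = 0.6753,
  utility_female_former_65_74   = 0.7709,
  utility_female_former_75_100  = 0.6981
)

# Mortality surface with no deaths at any age.
zero_mortality <- function(sex = "male", ages = 65:110) {
  dplyr::bind_rows(
    tibble::tibble(sex = sex, age = ages, status = "current", p_death = 0),
    tibble::tibble(sex = sex, age = ages, status = "former", p_death = 0))
}

# Parameter set with every quit and relapse probability zeroed, so a
# cohort started in the smoker state never moves.
frozen_params <- function(params = default_params()) {
  for (nm in c("abstinence_bp_y1", "abstinence_basic_y1", "program_quit_y2",
               "self_quit", "relapse_1_2", "relapse_3_4", "relapse_5_8",
               "relapse_9_10", "relapse_10plus"))
    params[[nm]] <- 0
  params
}

# Minimal trace stub carrying chosen discounted totals, for driving
# compute_icer() with exact incrementals.
fake_trace <- function(cost, qaly, ly, sex = "male", strategy = "basic",
                       n_cycles = 35) {
  structure(tibble::tibble(cycle = seq_len(n_cycles)),
            class = c("cess_trace", "tbl_df", "tbl", "data.frame"),
            strategy = strategy, sex = sex,
            totals = list(cost = cost, qaly = qaly, ly = ly,
                          cost_undisc = cost, qaly_undisc = qaly,
                          ly_undisc = ly))
}

# Brute-force cohort evolution: explicit matrix products, one transition
# matrix per cycle, payoffs recomputed from first principles. Independent
# oracle for run_cohort()'s direct-update recurrences.
matrix_power_trace <- function(strategy, sex, params, mort) {
  s <- params$settings
  horizon <- s$end_age - s$start_age
  states <- state_space()$state
  occ <- stats::setNames(numeric(length(states)), states)
  occ["S"] <- 1
  out <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    age <- s$start_age + t - 1
    M <- build_transition_matrix(age, sex, strategy, t, params, mort)
    occ <- as.numeric(occ %*% M)
    names(occ) <- states
    out[[t]] <- occ
  }
  do.call(rbind, out)
}
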