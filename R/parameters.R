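# Model parameter set: base values, uncertainty ranges, and distribution
# kinds for every quantity driving the cohort model, plus the economic
# settings (discount rate, horizon, switches). The packaged defaults are the
# full published input set, so the pipeline runs with zero external files.

# Registry of uncertain/fixed parameters. `dist_kind` selects the PSA
# distribution family: beta for probabilities and utility decrements, gamma
# for costs, lognormal for hazard ratios, fixed for point values (the
# age/sex/status utilities have no published ranges).
.param_registry <- function() {
  tibble::tribble(
    ~name,                          ~base,   ~lower,  ~upper,  ~dist_kind,
    "abstinence_bp_y1",             0.24,    0.14,    0.36,    "beta",
    "abstinence_basic_y1",          0.04,    0.03,    0.05,    "beta",
    "program_quit_y2",              0.02,    0.02,    0.03,    "beta",
    "self_quit",                    0.015,   0.012,   0.018,   "beta",
    "relapse_1_2",                  0.24,    0.19,    0.29,    "beta",
    "relapse_3_4",                  0.10,    0.08,    0.12,    "beta",
    "relapse_5_8",                  0.02,    0.016,   0.024,   "beta",
    "relapse_9_10",                 0.021,   0.017,   0.025,   "beta",
    "relapse_10plus",               0.005,   0.004,   0.006,   "beta",
    "hr_current_vs_never",          1.50,    1.07,    1.50,    "lognormal",
    "hr_former_vs_never",           1.30,    0.95,    1.81,    "lognormal",
    "nurse_fee",                    105,     95,      116,     "gamma",
    "bp_admin",                     47,      33,      61,      "gamma",
    "basic_admin",                  16,      15,      18,      "gamma",
    "varenicline",                  150,     105,     195,     "gamma",
    "annual_cancer_cost",           25058,   24897,   25219,   "gamma",
    "smoking_attrib_cost",          403,     262,     486,     "gamma",
    "cancer_decrement",             0.12,    0.11,    0.13,    "beta",
    "utility_male_current_65_74",   0.7551,  0.7551,  0.7551,  "fixed",
    "utility_male_current_75_100",  0.7089,  0.7089,  0.7089,  "fixed",
    "utility_male_former_65_74",    0.7802,  0.7802,  0.7802,  "fixed",
    "utility_male_former_75_100",   0.7358,  0.7358,  0.7358,  "fixed",
    "utility_female_current_65_74", 0.7496,  0.7496,  0.7496,  "fixed",
    "utility_female_current_75_100",0.6753,  0.6753,  0.6753,  "fixed",
    "utility_female_former_65_74",  0.7709,  0.7709,  0.7709,  "fixed",
    "utility_female_former_75_100", 0.6981,  0.6981,  0.6981,  "fixed"
  )
}

.default_settings <- function() {
  list(
    discount_rate               = 0.05,
    start_age                   = 65,
    end_age                     = 100,
    cycle_length                = 1,
    include_cancer_cost         = TRUE,
    half_cycle_correction       = FALSE,
    year2_program_quit_both_arms = FALSE,
    excess_cancer_multiplier    = 1.25,
    hr_scope                    = "non_cancer"
  )
}

#' Default model parameter set
#'
#' Returns the packaged parameter set: annual quit and relapse
#' probabilities, mortality hazard ratios for current and former smokers
#' versus never smokers, one-time program costs and annual cost streams
#' (2015 CAD), EQ-5D utilities by sex, age band and smoking status, the
#' cancer utility decrement, and the economic settings (5\% annual discount
#' rate, cohort aged 65 to 100, yearly cycles).
#'
#' @return A `cess_params` object: a list with one element per parameter
#'   (named as in [param_table()]), a `settings` list, and a `ranges`
#'   tibble holding the lower/upper uncertainty bounds and distribution
#'   kind of each parameter.
#' @examples
#' p <- default_params()
#' p$abstinence_bp_y1
#' @export
default_params <- function() {
  reg <- .param_registry()
  values <- as.list(setNames(reg$base, reg$name))
  params <- c(values, list(settings = .default_settings(), ranges = reg))
  class(params) <- "cess_params"
  validate_params(params)
}

#' Validate a model parameter set
#'
#' Checks every structural constraint on a parameter set: probabilities and
#' utilities in \[0, 1\], costs non-negative, hazard ratios strictly
#' positive, the 10+ year relapse probability no larger than the 1-2 year
#' one, former-smoker utility at least the current-smoker utility within
#' each sex/age band, lower <= base <= upper for every ranged parameter,
#' and a discount rate in \[0, 1) with `end_age > start_age`.
#'
#' @param params A `cess_params` object.
#' @return `params`, invisibly unchanged, if every constraint holds.
#'   Otherwise an error naming the violated constraint.
#' @export
validate_params <- function(params) {
  reg <- params$ranges
  v <- function(name) params[[name]]

  fail <- function(msg) abort(paste0("invalid parameters: ", msg),
                              class = "cessim_validation_error")

  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    x <- v(nm)
    if (!is.numeric(x) || length(x) != 1 || is.na(x))
      fail(paste0(nm, " must be a single finite number"))
    kind <- reg$dist_kind[i]
    if (kind == "beta" && (x < 0 || x > 1))
      fail(paste0(nm, " is a probability and must lie in [0, 1], got ", x))
    if (kind == "gamma" && x < 0)
      fail(paste0(nm, " is a cost and must be >= 0, got ", x))
    if (kind == "lognormal" && x <= 0)
      fail(paste0(nm, " is a hazard ratio and must be > 0, got ", x))
    if (grepl("^utility_", nm) && (x < 0 || x > 1))
      fail(paste0(nm, " must lie in [0, 1], got ", x))
    if (!(reg$lower[i] <= reg$base[i] && reg$base[i] <= reg$upper[i]))
      fail(paste0(nm, ": range must satisfy lower <= base <= upper"))
  }

  if (v("relapse_10plus") > v("relapse_1_2"))
    fail("relapse_10plus must not exceed relapse_1_2 (relapse declines with quit duration)")

  for (sex in c("male", "female")) for (band in c("65_74", "75_100")) {
    cur <- v(paste0("utility_", sex, "_current_", band))
    frm <- v(paste0("utility_", sex, "_former_", band))
    if (frm < cur)
      fail(paste0("former-smoker utility must be >= current-smoker utility (",
                  sex, " ", band, ")"))
  }

  s <- params$settings
  if (s$discount_rate < 0 || s$discount_rate >= 1)
    fail("discount_rate must lie in [0, 1)")
  if (s$end_age <= s$start_age)
    fail("end_age must exceed start_age")
  if (s$excess_cancer_multiplier < 1)
    fail("excess_cancer_multiplier must be >= 1")
  if (!s$hr_scope %in% c("non_cancer", "all_cause"))
    fail("hr_scope must be 'non_cancer' or 'all_cause'")
  invisible(params)
}

#' Load a model parameter file
#'
#' Reads a flat key-value YAML file and merges it over the packaged
#' defaults, so a file only needs the keys it overrides; an empty or
#' missing-key file reproduces [default_params()] exactly. Keys are
#' parameter names as in [param_table()]; `<name>_lower` / `<name>_upper`
#' override a parameter's uncertainty bounds; settings keys
#' (`discount_rate`, `start_age`, `end_age`, `cycle_length`,
#' `include_cancer_cost`, `half_cycle_correction`,
#' `year2_program_quit_both_arms`, `excess_cancer_multiplier`,
#' `hr_scope`) override the economic settings.
#'
#' @param path Path to a YAML file of key-value overrides.
#' @return A validated `cess_params` object.
#' @seealso [save_params()], [param_table()]
#' @export
load_params <- function(path) {
  if (!file.exists(path))
    abort(paste0("parameter file not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(paste0(
                    "could not parse parameter file ", path, ": ",
                    conditionMessage(e))))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("parameter file must be a flat key-value mapping")

  params <- default_params()
  reg <- params$ranges
  known_values <- reg$name
  known_settings <- names(params$settings)

  for (key in names(raw)) {
    val <- raw[[key]]
    if (key %in% known_values) {
      if (!is.numeric(val) || length(val) != 1)
        abort(paste0("malformed value for key '", key, "': expected a number"))
      params[[key]] <- as.numeric(val)
      i <- params$ranges$name == key
      params$ranges$base[i] <- as.numeric(val)
      # an override outside the stored range widens the range to keep
      # lower <= base <= upper
      params$ranges$lower[i] <- pmin(params$ranges$lower[i], as.numeric(val))
      params$ranges$upper[i] <- pmax(params$ranges$upper[i], as.numeric(val))
    } else if (key %in% known_settings) {
      if (is.logical(params$settings[[key]])) {
        if (!is.logical(val) || length(val) != 1)
          abort(paste0("malformed value for key '", key, "': expected true/false"))
        params$settings[[key]] <- val
      } else if (is.character(params$settings[[key]])) {
        if (!is.character(val) || length(val) != 1)
          abort(paste0("malformed value for key '", key, "': expected a string"))
        params$settings[[key]] <- val
      } else {
        if (!is.numeric(val) || length(val) != 1)
          abort(paste0("malformed value for key '", key, "': expected a number"))
        params$settings[[key]] <- as.numeric(val)
      }
    } else if (grepl("_lower$", key) &&
               sub("_lower$", "", key) %in% known_values) {
      nm <- sub("_lower$", "", key)
      params$ranges$lower[params$ranges$name == nm] <- as.numeric(val)
    } else if (grepl("_upper$", key) &&
               sub("_upper$", "", key) %in% known_values) {
      nm <- sub("_upper$", "", key)
      params$ranges$upper[params$ranges$name == nm] <- as.numeric(val)
    } else {
      abort(paste0("unknown parameter key '", key, "'"))
    }
  }
  validate_params(params)
}

#' Save a model parameter set
#'
#' Writes the complete flat key-value representation (every parameter, its
#' `_lower`/`_upper` bounds, and all settings) as YAML. [load_params()] on
#' the written file reproduces the object exactly.
#'
#' @param params A `cess_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  reg <- params$ranges
  out <- list()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    out[[nm]] <- params[[nm]]
    out[[paste0(nm, "_lower")]] <- reg$lower[i]
    out[[paste0(nm, "_upper")]] <- reg$upper[i]
  }
  out <- c(out, params$settings)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Resolved parameter table
#'
#' @param params A `cess_params` object (default: packaged defaults).
#' @return A tibble with columns `name`, `base`, `lower`, `upper`,
#'   `dist_kind` — one row per model parameter, reflecting any overrides.
#' @examples
#' param_table()
#' @export
param_table <- function(params = default_params()) {
  params$ranges
}

#' Write the resolved parameter table as CSV
#'
#' @param params A `cess_params` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(params, path) {
  readr::write_csv(param_table(params), path)
  invisible(path)
}

# Utility weight for an alive state, net of nothing (the cancer decrement
# is applied by the accrual code so it can be varied in the PSA).
.utility_lookup <- function(params, sex, age, status) {
  band <- if (age < 75) "65_74" else "75_100"
  if (age > 100) abort("age outside utility bands (65-100)")
  params[[paste0("utility_", sex, "_", status, "_", band)]]
}

#' @export
print.cess_params <- function(x, ...) {
  cat("<cess_params> model parameter set\n")
  cat("  ", nrow(x$ranges), " parameters (",
      sum(x$ranges$dist_kind != "fixed"), " with uncertainty ranges)\n",
      sep = "")
  s <- x$settings
  cat(sprintf("  discount %.1f%%/yr, ages %d-%d, cycle %g yr\n",
              100 * s$discount_rate, s$start_age, s$end_age, s$cycle_length))
  cat(sprintf("  include_cancer_cost=%s, half_cycle_correction=%s\n",
              s$include_cancer_cost, s$half_cycle_correction))
  invisible(x)
}
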