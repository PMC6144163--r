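# Synthetic life tables and cause-of-death splits. These emulate the
# statistical shape of national statistical-agency inputs (smooth
# Gompertz-like mortality rising with age; cancer's share of deaths
# declining into extreme old age) so the whole pipeline is testable with
# no external data. A reader accepts real agency exports reshaped to the
# same two-column schema.

.lt_ages <- 65:110

.lt_defaults <- list(
  male   = list(a = 3e-5,   b = 0.085, f65 = 0.45, f_old = 0.15),
  female = list(a = 1.3e-5, b = 0.095, f65 = 0.40, f_old = 0.12)
)

.check_sex <- function(sex) {
  if (!sex %in% c("male", "female"))
    abort("sex must be 'male' or 'female'")
  sex
}

#' Generate a synthetic sex-specific life table
#'
#' Annual death probabilities follow a Gompertz hazard
#' `h(age) = a * exp(b * age)`, converted to a probability
#' `q = 1 - exp(-h)` and capped at 1. Age 110 is a closure row with
#' `q = 1`, so a cohort is always fully absorbed. When `seed` is given,
#' small multiplicative lognormal noise is applied and monotonicity in age
#' is restored by a cumulative maximum, mimicking the year-to-year
#' roughness of real tables.
#'
#' Defaults are calibrated so that the cohort model's basic-arm discounted
#' life expectancy at 65 lands near published cancer-cohort values
#' (roughly 11-13 discounted life-years for males); they are modelling
#' conveniences, not national estimates.
#'
#' @param sex `"male"` or `"female"`.
#' @param a Baseline hazard at age 0 (per year); must be > 0.
#' @param b Gompertz log-slope (per year of age); must be in \[0, 0.3).
#'   `b = 0` gives a constant death probability at all ages.
#' @param seed Optional integer; when given, adds seeded multiplicative
#'   noise (lognormal, sigma = `noise_sd`).
#' @param noise_sd Standard deviation of the log-noise (default 0.03).
#' @return A tibble with columns `sex`, `age` (65-110), `q` (annual death
#'   probability).
#' @examples
#' lt <- make_life_table("male")
#' head(lt)
#' @export
make_life_table <- function(sex, a = .lt_defaults[[sex]]$a,
                            b = .lt_defaults[[sex]]$b,
                            seed = NULL, noise_sd = 0.03) {
  .check_sex(sex)
  if (!is.numeric(a) || a <= 0) abort("baseline hazard a must be > 0")
  if (!is.numeric(b) || b < 0 || b >= 0.3)
    abort("Gompertz slope b must lie in [0, 0.3)")
  ages <- .lt_ages
  h <- a * exp(b * ages)
  q <- pmin(1 - exp(-h), 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    q <- pmin(q * exp(rnorm(length(q), 0, noise_sd)), 1)
    q <- cummax(q)  # real tables are graduated; keep q monotone
  }
  q[ages == max(ages)] <- 1  # closure: nobody survives past the last row
  tibble(sex = sex, age = ages, q = q)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cancer cause-of-death split
#'
#' The fraction of deaths attributable to cancer declines linearly with
#' age from `f65` at age 65 to `f_old` at age 110, reflecting the shift of
#' old-age mortality toward non-cancer causes.
#'
#' @param sex `"male"` or `"female"`.
#' @param f65 Cancer fraction of deaths at age 65, in \[0, 1\].
#' @param f_old Cancer fraction at age 110, in \[0, 1\].
#' @return A tibble with columns `sex`, `age` (65-110), `f_cancer`.
#' @examples
#' make_cause_split("male", 0.5, 0.1)
#' @export
make_cause_split <- function(sex, f65 = .lt_defaults[[sex]]$f65,
                             f_old = .lt_defaults[[sex]]$f_old) {
  .check_sex(sex)
  if (f65 < 0 || f65 > 1 || f_old < 0 || f_old > 1)
    abort("cancer fractions f65 and f_old must lie in [0, 1]")
  ages <- .lt_ages
  f <- f65 + (f_old - f65) * (ages - min(ages)) / (max(ages) - min(ages))
  tibble(sex = sex, age = ages, f_cancer = f)
}

#' Read / write life tables and cause splits
#'
#' CSV schemas: a life table has columns `age,q`; a cause split has
#' columns `age,f_cancer`. Real statistical-agency exports reshaped to
#' these columns load unchanged.
#'
#' @param path CSV path.
#' @param sex Sex label to attach to the rows.
#' @return A tibble in the same shape as [make_life_table()] /
#'   [make_cause_split()].
#' @export
read_life_table <- function(path, sex) {
  .check_sex(sex)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("age", "q") %in% names(df)))
    abort("life table CSV must have columns age,q")
  if (any(df$q < 0 | df$q > 1)) abort("life table q must lie in [0, 1]")
  tibble(sex = sex, age = as.integer(df$age), q = as.numeric(df$q))
}

#' @rdname read_life_table
#' @export
read_cause_split <- function(path, sex) {
  .check_sex(sex)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("age", "f_cancer") %in% names(df)))
    abort("cause split CSV must have columns age,f_cancer")
  if (any(df$f_cancer < 0 | df$f_cancer > 1))
    abort("f_cancer must lie in [0, 1]")
  tibble(sex = sex, age = as.integer(df$age),
         f_cancer = as.numeric(df$f_cancer))
}

#' @rdname read_life_table
#' @param lt,cs Tibbles as returned by the constructors above.
#' @export
write_life_table <- function(lt, path) {
  readr::write_csv(dplyr::select(lt, "age", "q"), path)
  invisible(path)
}

#' @rdname read_life_table
#' @export
write_cause_split <- function(cs, path) {
  readr::write_csv(dplyr::select(cs, "age", "f_cancer"), path)
  invisible(path)
}

#' Period life expectancy from a life table
#'
#' Undiscounted expected years lived from `from_age`, computed as the sum
#' of cumulative survival over the table's ages (curtate expectation).
#'
#' @param lt A life-table tibble (`age`, `q`).
#' @param from_age Starting age (default 65).
#' @return Expected remaining years (numeric scalar).
#' @export
life_expectancy <- function(lt, from_age = 65) {
  q <- lt$q[lt$age >= from_age]
  sum(cumprod(1 - q))
}
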