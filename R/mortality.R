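# Six-step derivation of annual death probabilities by age, sex, and
# smoking status for cancer patients:
#   1. age-specific probability of death q(age) from the life table;
#   2. age-specific cancer share of deaths f_cancer(age) from the cause
#      split;
#   3. decompose the total hazard m = -ln(1 - q) into cancer and
#      non-cancer components m * f and m * (1 - f);
#   4. form the never-smoker cancer-patient baseline hazard
#      m0 = non-cancer + multiplier * cancer (the multiplier carries the
#      excess cancer mortality of a diagnosed cohort over the general
#      population);
#   5. apply the status hazard ratio (current/former vs never smoker);
#   6. convert back to an annual probability p = 1 - exp(-HR * m0).
# HRs act on the hazard scale throughout, which keeps p <= 1 and matches
# the usual proportional-hazards reading of a published HR.

#' Split all-cause mortality into cancer and non-cancer hazards
#'
#' Converts each annual death probability to a hazard
#' `m = -log(1 - q)` and apportions it by the cancer fraction of deaths at
#' that age: cancer hazard `m * f_cancer`, non-cancer hazard
#' `m * (1 - f_cancer)`.
#'
#' @param lt Life-table tibble (`sex`, `age`, `q`).
#' @param cs Cause-split tibble (`sex`, `age`, `f_cancer`) covering the
#'   same sex and ages.
#' @return A tibble with columns `sex`, `age`, `hazard_cancer`,
#'   `hazard_other`. Rows with `q = 1` get a large capped hazard (with a
#'   warning) rather than infinity.
#' @examples
#' lt <- make_life_table("male")
#' cs <- make_cause_split("male")
#' split_mortality(lt, cs)
#' @export
split_mortality <- function(lt, cs) {
  if (!identical(lt$sex[1], cs$sex[1]))
    abort("life table and cause split are for different sexes")
  if (!identical(as.integer(lt$age), as.integer(cs$age)))
    abort("life table and cause split must cover the same ages")
  q <- lt$q
  capped <- q >= 1
  if (any(capped)) {
    # closure rows: finite capped hazard instead of Inf
    if (any(is.na(cs$f_cancer[capped])))
      warn("q = 1 with undefined f_cancer: hazard capped, split undefined")
    q <- pmin(q, 1 - 1e-12)
  }
  f <- dplyr::coalesce(cs$f_cancer, 0)
  m <- -log(1 - q)
  tibble(sex = lt$sex, age = lt$age,
         hazard_cancer = m * f,
         hazard_other  = m * (1 - f))
}

#' Derive smoking-status-adjusted mortality for cancer patients
#'
#' Builds the never-smoker cancer-patient hazard from the split
#' components, applies the status hazard ratio on the hazard scale, and
#' converts back to an annual probability. The scope of the smoking
#' adjustment is controlled by `params$settings$hr_scope`:
#'
#' * `"non_cancer"` (default): the HR scales the non-cancer hazard only —
#'   `p = 1 - exp(-(HR * hazard_other + mult * hazard_cancer))` — on the
#'   reading that published smoking-status HRs for a cancer cohort
#'   capture excess non-cancer (largely tobacco-related) mortality, while
#'   the cancer-death component is common to both statuses.
#' * `"all_cause"`: the HR scales the whole baseline hazard —
#'   `p = 1 - exp(-HR * (hazard_other + mult * hazard_cancer))`.
#'
#' The two coincide when `f_cancer = 0`. The general-population life
#' table stands in for the never-smoker baseline (no smoking-prevalence
#' deconvolution), and mortality depends on attained age but not on time
#' since diagnosis, because a single lifetime HR per status drives the
#' adjustment.
#'
#' @param lt Life-table tibble.
#' @param cs Cause-split tibble (same sex/ages).
#' @param params A `cess_params` object supplying `hr_current_vs_never`,
#'   `hr_former_vs_never`, the `hr_scope` setting, and (unless
#'   overridden) the multiplier.
#' @param excess_cancer_multiplier Multiplier (>= 1) on the cancer hazard
#'   component; defaults to the value in `params$settings`.
#' @return A tibble with columns `sex`, `age`, `status`
#'   (`"current"`/`"former"`), `p_death` — the adjusted-mortality surface
#'   used by the cohort engine.
#' @examples
#' mort <- derive_adjusted_mortality(make_life_table("male"),
#'                                   make_cause_split("male"))
#' head(mort)
#' @export
derive_adjusted_mortality <- function(lt, cs, params = default_params(),
                                      excess_cancer_multiplier =
                                        params$settings$excess_cancer_multiplier) {
  hr_c <- params$hr_current_vs_never
  hr_f <- params$hr_former_vs_never
  if (hr_c <= 0 || hr_f <= 0) abort("hazard ratios must be > 0")
  if (excess_cancer_multiplier < 1)
    abort("excess_cancer_multiplier must be >= 1")
  scope <- params$settings$hr_scope
  hz <- split_mortality(lt, cs)
  adj <- function(hr) {
    if (scope == "all_cause")
      hr * (hz$hazard_other + excess_cancer_multiplier * hz$hazard_cancer)
    else
      hr * hz$hazard_other + excess_cancer_multiplier * hz$hazard_cancer
  }
  bind_rows(
    tibble(sex = hz$sex, age = hz$age, status = "current",
           p_death = 1 - exp(-adj(hr_c))),
    tibble(sex = hz$sex, age = hz$age, status = "former",
           p_death = 1 - exp(-adj(hr_f)))) %>%
    arrange(.data$status, .data$age)
}

#' Write adjusted mortality as CSV
#'
#' @param mort Tibble from [derive_adjusted_mortality()].
#' @param path Output CSV path (columns `age,status,p_death`).
#' @return `path`, invisibly.
#' @export
write_adjusted_mortality <- function(mort, path) {
  readr::write_csv(dplyr::select(mort, "age", "status", "p_death"), path)
  invisible(path)
}

# Fast lookup: death probabilities as vectors indexed by age offset.
.mortality_vectors <- function(mort, start_age, horizon) {
  ages <- start_age + seq_len(horizon) - 1
  get1 <- function(st) {
    sub <- mort[mort$status == st, ]
    idx <- match(ages, sub$age)
    if (anyNA(idx)) abort("mortality table does not cover the run horizon")
    sub$p_death[idx]
  }
  list(current = get1("current"), former = get1("former"))
}
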