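# One-way deterministic sensitivity analysis: re-run the full base case
# with a single parameter pinned at its lower, then upper, bound — all
# other parameters at base — and record the ICER at each endpoint. The
# time horizon row is special: its "range" is a truncation of the run to
# 2 and 4 cycles.

.set_param <- function(params, name, value) {
  params[[name]] <- value
  i <- params$ranges$name == name
  params$ranges$base[i] <- value
  params$ranges$lower[i] <- pmin(params$ranges$lower[i], value)
  params$ranges$upper[i] <- pmax(params$ranges$upper[i], value)
  params
}

.icer_for <- function(params, sex, lt, cs) {
  mort <- derive_adjusted_mortality(lt, cs, params)
  ce <- compute_icer(run_cohort("basic", sex, params, mort),
                     run_cohort("best_practice", sex, params, mort))
  list(icer = ce$icer_qaly, dominance = ce$dominance)
}

#' One-way (tornado) sensitivity analysis
#'
#' For each listed parameter, re-runs the male base case at the
#' parameter's lower and upper bound and records the ICER ($/QALY) at
#' both endpoints; entries are sorted by swing (absolute difference of
#' the endpoint ICERs), the tornado ordering. An endpoint at which the
#' comparison is dominant/dominated gets `NA` for the ICER and a note.
#' The `time_horizon` entry truncates the run to 2 (lower) and 4 (upper)
#' yearly cycles.
#'
#' @param params A `cess_params` object.
#' @param sex Cohort sex; the conventional tornado uses the male cohort.
#' @param lt,cs Life table / cause split; default to the packaged
#'   synthetic inputs.
#' @param param_names Parameters to vary; default: every parameter with a
#'   non-degenerate range, plus `time_horizon`.
#' @return A `cess_tornado` tibble with columns `name`, `lower`, `upper`,
#'   `icer_at_lower`, `icer_at_upper`, `swing`, `note_lower`,
#'   `note_upper`, `brackets_base` (whether the base ICER lies between
#'   the endpoint ICERs), sorted by `swing` descending; the base-case
#'   ICER is attached as attribute `base_icer`.
#' @examples
#' \donttest{
#' tor <- one_way_tornado(param_names = c("bp_admin", "self_quit"))
#' tor
#' }
#' @export
one_way_tornado <- function(params = default_params(), sex = "male",
                            lt = NULL, cs = NULL, param_names = NULL) {
  .check_sex(sex)
  if (is.null(lt)) lt <- make_life_table(sex)
  if (is.null(cs)) cs <- make_cause_split(sex)
  reg <- params$ranges
  if (is.null(param_names)) {
    param_names <- c(reg$name[reg$dist_kind != "fixed" &
                                reg$lower < reg$upper], "time_horizon")
  }

  base <- .icer_for(params, sex, lt, cs)

  run_at <- function(name, bound) {
    if (name == "time_horizon") {
      p <- params
      p$settings$end_age <- p$settings$start_age +
        if (bound == "lower") 2 else 4
      return(.icer_for(p, sex, lt, cs))
    }
    i <- which(reg$name == name)
    if (length(i) != 1) abort(paste0("unknown tornado parameter '", name, "'"))
    value <- if (bound == "lower") reg$lower[i] else reg$upper[i]
    .icer_for(.set_param(params, name, value), sex, lt, cs)
  }

  rows <- purrr::map(param_names, function(nm) {
    lo <- run_at(nm, "lower")
    hi <- run_at(nm, "upper")
    i <- which(reg$name == nm)
    tibble(
      name = nm,
      lower = if (length(i)) reg$lower[i] else 2,
      upper = if (length(i)) reg$upper[i] else 4,
      icer_at_lower = lo$icer, icer_at_upper = hi$icer,
      swing = abs(hi$icer - lo$icer),
      note_lower = ifelse(lo$dominance == "none", NA_character_,
                          lo$dominance),
      note_upper = ifelse(hi$dominance == "none", NA_character_,
                          hi$dominance),
      brackets_base = !is.na(lo$icer) & !is.na(hi$icer) &
        base$icer >= pmin(lo$icer, hi$icer) - 1e-9 &
        base$icer <= pmax(lo$icer, hi$icer) + 1e-9)
  })

  out <- bind_rows(rows) %>% arrange(desc(.data$swing))
  structure(out, class = c("cess_tornado", class(out)),
            base_icer = base$icer)
}

#' Write a tornado table as CSV
#'
#' @param tornado A `cess_tornado` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(tornado, path) {
  readr::write_csv(as_tibble(unclass(tornado)), path)
  invisible(path)
}
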