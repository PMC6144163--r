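# Probabilistic sensitivity analysis: propagate the parameter
# distributions through both arms of the cohort model by Monte Carlo and
# summarise the incremental cloud on the cost-effectiveness plane and as
# an acceptability curve. The engine here is vectorised across draws —
# the cohort recurrences are identical to run_cohort()'s, applied to
# draw-long vectors — so ten thousand full model evaluations take
# seconds.

# One arm, all draws at once. `dp` is a list of draw-long parameter
# vectors; `m0` the baseline hazard components per cycle; utilities come
# from the (fixed) base parameter set.
.run_arm_vec <- function(strategy, dp, m0, params, sex) {
  s <- params$settings
  horizon <- length(m0$other)
  n <- length(dp$hr_current_vs_never)
  all_cause <- identical(s$hr_scope, "all_cause")
  disc <- (1 + s$discount_rate)^-(seq_len(horizon))

  u_cur <- c(.utility_lookup(params, sex, s$start_age, "current"),
             .utility_lookup(params, sex, 75, "current"))
  u_frm <- c(.utility_lookup(params, sex, s$start_age, "former"),
             .utility_lookup(params, sex, 75, "former"))

  rel <- list(dp$relapse_1_2, dp$relapse_1_2,
              dp$relapse_3_4, dp$relapse_3_4,
              dp$relapse_5_8, dp$relapse_5_8, dp$relapse_5_8, dp$relapse_5_8,
              dp$relapse_9_10, dp$relapse_9_10, dp$relapse_10plus)
  nf <- length(rel)

  ab1 <- if (strategy == "best_practice") dp$abstinence_bp_y1
         else dp$abstinence_basic_y1
  program <- if (strategy == "best_practice")
    dp$bp_admin + dp$nurse_fee + dp$varenicline else dp$basic_admin

  S <- rep(1, n); Sr <- rep(0, n)
  Fs <- replicate(nf, rep(0, n), simplify = FALSE)
  acc_cost <- program  # one-time cost, undiscounted at entry
  acc_qaly <- rep(0, n)
  acc_ly <- rep(0, n)

  for (t in seq_len(horizon)) {
    age <- s$start_age + t - 1
    if (all_cause) {
      pdS <- 1 - exp(-dp$hr_current_vs_never * (m0$other[t] + m0$cancer[t]))
      pdF <- 1 - exp(-dp$hr_former_vs_never * (m0$other[t] + m0$cancer[t]))
    } else {
      pdS <- 1 - exp(-(dp$hr_current_vs_never * m0$other[t] + m0$cancer[t]))
      pdF <- 1 - exp(-(dp$hr_former_vs_never * m0$other[t] + m0$cancer[t]))
    }
    qS <- if (t == 1) ab1
      else if (t == 2 && (strategy == "best_practice" ||
                          s$year2_program_quit_both_arms)) dp$program_quit_y2
      else dp$self_quit

    smokers_pre <- S + Sr
    formers_pre <- Reduce(`+`, Fs)

    survS <- S * (1 - pdS)
    survSr <- Sr * (1 - pdS)
    quit_in <- survS * qS + survSr * dp$self_quit
    surv_f <- lapply(Fs, function(f) f * (1 - pdF))
    relapse_in <- rep(0, n)
    stay <- vector("list", nf)
    for (k in seq_len(nf)) {
      relapse_in <- relapse_in + surv_f[[k]] * rel[[k]]
      stay[[k]] <- surv_f[[k]] * (1 - rel[[k]])
    }
    S <- survS * (1 - qS)
    Sr <- survSr * (1 - dp$self_quit) + relapse_in
    newF <- vector("list", nf)
    newF[[1]] <- quit_in
    for (k in 2:nf) newF[[k]] <- stay[[k - 1]]
    newF[[nf]] <- newF[[nf]] + stay[[nf]]
    Fs <- newF

    smokers <- S + Sr
    formers <- Reduce(`+`, Fs)
    if (s$half_cycle_correction) {
      smokers_pay <- (smokers + smokers_pre) / 2
      formers_pay <- (formers + formers_pre) / 2
    } else {
      smokers_pay <- smokers; formers_pay <- formers
    }
    alive <- smokers_pay + formers_pay

    band <- if (age < 75) 1L else 2L
    qaly_t <- smokers_pay * (u_cur[band] - dp$cancer_decrement) +
      formers_pay * (u_frm[band] - dp$cancer_decrement)
    cost_t <- dp$smoking_attrib_cost * smokers_pay
    if (s$include_cancer_cost)
      cost_t <- cost_t + dp$annual_cancer_cost * alive

    acc_cost <- acc_cost + cost_t * disc[t]
    acc_qaly <- acc_qaly + qaly_t * disc[t]
    acc_ly <- acc_ly + alive * disc[t]
  }
  list(cost = acc_cost, qaly = acc_qaly, ly = acc_ly)
}

# Baseline hazard components per cycle: non-cancer hazard and the
# multiplier-scaled cancer hazard, kept separate so the HR scope can be
# applied per draw.
.baseline_hazard <- function(lt, cs, params) {
  s <- params$settings
  horizon <- as.integer(round((s$end_age - s$start_age) / s$cycle_length))
  hz <- split_mortality(lt, cs)
  ages <- s$start_age + seq_len(horizon) - 1
  idx <- match(ages, hz$age)
  if (anyNA(idx)) abort("life table does not cover the run horizon")
  list(other = hz$hazard_other[idx],
       cancer = s$excess_cancer_multiplier * hz$hazard_cancer[idx])
}

.draw_valid <- function(dp, params) {
  probs <- c("abstinence_bp_y1", "abstinence_basic_y1", "program_quit_y2",
             "self_quit", "relapse_1_2", "relapse_3_4", "relapse_5_8",
             "relapse_9_10", "relapse_10plus", "cancer_decrement")
  ok <- rep(TRUE, length(dp[[1]]))
  for (p in probs) ok <- ok & dp[[p]] >= 0 & dp[[p]] <= 1
  ok <- ok & dp$hr_current_vs_never > 0 & dp$hr_former_vs_never > 0
  for (p in c("nurse_fee", "bp_admin", "basic_admin", "varenicline",
              "annual_cancer_cost", "smoking_attrib_cost"))
    ok <- ok & dp[[p]] >= 0
  ok
}

.sample_draws <- function(params, n, couple_hrs) {
  samplers <- .psa_samplers(params)
  dp <- list()
  if (couple_hrs && all(c("hr_current_vs_never", "hr_former_vs_never")
                        %in% names(samplers))) {
    u <- runif(n)  # one quantile drives both HRs (rank coupling)
    dp$hr_current_vs_never <- samplers$hr_current_vs_never$quantile(u)
    dp$hr_former_vs_never <- samplers$hr_former_vs_never$quantile(u)
    samplers <- samplers[setdiff(names(samplers),
                                 c("hr_current_vs_never",
                                   "hr_former_vs_never"))]
  }
  for (nm in names(samplers)) dp[[nm]] <- samplers[[nm]]$sample(n)
  # parameters with no samplers (all-fixed registries) fall back to base
  for (nm in c("abstinence_bp_y1", "abstinence_basic_y1", "program_quit_y2",
               "self_quit", "relapse_1_2", "relapse_3_4", "relapse_5_8",
               "relapse_9_10", "relapse_10plus", "cancer_decrement",
               "hr_current_vs_never", "hr_former_vs_never", "nurse_fee",
               "bp_admin", "basic_admin", "varenicline",
               "annual_cancer_cost", "smoking_attrib_cost"))
    if (is.null(dp[[nm]])) dp[[nm]] <- rep(params[[nm]], n)
  dp
}

#' Probabilistic sensitivity analysis
#'
#' Samples every parameter with an uncertainty range from its fitted
#' distribution ([fit_distribution()]; gamma for costs, beta for
#' probabilities and the cancer utility decrement, lognormal for the two
#' mortality hazard ratios), runs both strategy arms per draw, and records
#' the incremental cost and QALYs. Utilities without published ranges stay
#' fixed. With `couple_hrs = TRUE` (default) the two hazard ratios are
#' sampled from a single uniform quantile, preserving their ordering in
#' almost all draws.
#'
#' @param params A `cess_params` object.
#' @param sex Cohort sex (default `"male"`).
#' @param lt,cs Life table / cause split tibbles; default to the packaged
#'   synthetic inputs for `sex`.
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Optional integer seed; the result is fully reproducible
#'   given the seed.
#' @param wtp_grid Willingness-to-pay thresholds (CAD/QALY) for the
#'   acceptability curve.
#' @param couple_hrs Sample both hazard ratios from one quantile.
#' @return A `cess_psa`: list with `draws` (tibble: draw id, every sampled
#'   parameter, `d_cost`, `d_qaly`), `ceac` (tibble `lambda`, `prob_ce`),
#'   `quadrants` (NE/SE/NW/SW counts of the incremental cloud),
#'   `n_redrawn`, and the settings used.
#' @examples
#' psa <- run_psa(n_draws = 200, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(params = default_params(), sex = "male",
                    lt = NULL, cs = NULL, n_draws = 10000, seed = NULL,
                    wtp_grid = seq(0, 100000, by = 2500),
                    couple_hrs = TRUE) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  .check_sex(sex)
  if (is.null(lt)) lt <- make_life_table(sex)
  if (is.null(cs)) cs <- make_cause_split(sex)
  if (!is.null(seed)) set.seed(seed)

  dp <- .sample_draws(params, n_draws, couple_hrs)
  n_redrawn <- 0L
  repeat {
    bad <- which(!.draw_valid(dp, params))
    if (length(bad) == 0) break
    n_redrawn <- n_redrawn + length(bad)
    redo <- .sample_draws(params, length(bad), couple_hrs)
    for (nm in names(dp)) dp[[nm]][bad] <- redo[[nm]]
  }

  m0 <- .baseline_hazard(lt, cs, params)
  basic <- .run_arm_vec("basic", dp, m0, params, sex)
  bp <- .run_arm_vec("best_practice", dp, m0, params, sex)
  d_cost <- bp$cost - basic$cost
  d_qaly <- bp$qaly - basic$qaly

  draws <- as_tibble(dp) %>%
    mutate(draw = row_number(), d_cost = d_cost, d_qaly = d_qaly) %>%
    select("draw", dplyr::everything())

  quadrants <- c(NE = sum(d_qaly > 0 & d_cost > 0),
                 SE = sum(d_qaly > 0 & d_cost <= 0),
                 NW = sum(d_qaly <= 0 & d_cost > 0),
                 SW = sum(d_qaly <= 0 & d_cost <= 0))

  res <- structure(list(draws = draws, ceac = NULL, quadrants = quadrants,
                        n_redrawn = n_redrawn,
                        settings = list(n_draws = n_draws, seed = seed,
                                        wtp_grid = wtp_grid,
                                        couple_hrs = couple_hrs,
                                        sex = sex)),
                   class = "cess_psa")
  res$ceac <- ceac_curve(res, wtp_grid)
  res
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with non-negative net monetary benefit,
#' `lambda * dQALY - dCost >= 0`, at each willingness-to-pay threshold.
#'
#' @param psa A `cess_psa` object.
#' @param grid Non-empty numeric vector of thresholds (CAD/QALY, >= 0).
#' @return A tibble with columns `lambda`, `prob_ce`.
#' @export
ceac_curve <- function(psa, grid = psa$settings$wtp_grid) {
  if (length(grid) == 0) abort("wtp grid must be non-empty")
  if (any(grid < 0)) abort("wtp thresholds must be >= 0")
  d <- psa$draws
  tibble(lambda = grid,
         prob_ce = purrr::map_dbl(grid, function(l)
           mean(net_monetary_benefit(d$d_cost, d$d_qaly, l) >= 0)))
}

#' @export
print.cess_psa <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<cess_psa> %d draws (%s cohort, seed %s)\n", s$n_draws,
              s$sex, ifelse(is.null(s$seed), "none", s$seed)))
  cat("  quadrants:", paste(names(x$quadrants), x$quadrants,
                            collapse = ", ", sep = "="), "\n")
  at50 <- ceac_curve(x, 50000)$prob_ce
  cat(sprintf("  cost-effective at $50,000/QALY: %.1f%%\n", 100 * at50))
  invisible(x)
}

#' Tidy a PSA result
#'
#' @param x A `cess_psa`.
#' @param ... Unused.
#' @return The per-draw tibble (sampled parameters and incrementals).
#' @export
tidy.cess_psa <- function(x, ...) x$draws

#' One-row summary of a PSA result
#'
#' @param x A `cess_psa`.
#' @param ... Unused.
#' @return A tibble with draw count, mean incrementals, the probability
#'   cost-effective at $50,000/QALY, and quadrant fractions.
#' @export
glance.cess_psa <- function(x, ...) {
  q <- x$quadrants / sum(x$quadrants)
  tibble(n_draws = x$settings$n_draws,
         mean_d_cost = mean(x$draws$d_cost),
         mean_d_qaly = mean(x$draws$d_qaly),
         prob_ce_50k = ceac_curve(x, 50000)$prob_ce,
         frac_ne = q[["NE"]], frac_se = q[["SE"]],
         frac_nw = q[["NW"]], frac_sw = q[["SW"]],
         n_redrawn = x$n_redrawn)
}

#' Write PSA outputs as CSV
#'
#' @param psa A `cess_psa`.
#' @param draws_path,ceac_path Output CSV paths (either may be `NULL` to
#'   skip).
#' @return `psa`, invisibly.
#' @export
write_psa <- function(psa, draws_path = NULL, ceac_path = NULL) {
  if (!is.null(draws_path)) readr::write_csv(psa$draws, draws_path)
  if (!is.null(ceac_path)) readr::write_csv(psa$ceac, ceac_path)
  invisible(psa)
}
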