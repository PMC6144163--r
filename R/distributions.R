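# Fitting sampling distributions to (base, lower, upper) triples for the
# probabilistic sensitivity analysis. Ranges are read as 95% confidence
# bounds, so SE = (upper - lower) / (2 * 1.96) throughout. Costs get
# gamma distributions (skewed, non-negative) moment-matched so the mean
# equals the base value; probabilities and the utility decrement get beta
# distributions moment-matched the same way; hazard ratios get lognormals
# with mu = log(base) — the base value is the median, the standard
# reading of an HR with a published CI.

#' Fit a sampling distribution to one parameter
#'
#' @param spec A one-row data frame (or list) with elements `name`,
#'   `base`, `lower`, `upper`, `dist_kind` — one row of [param_table()].
#' @return A `cess_sampler`: list with `name`, `kind`, `pars` (fitted
#'   parameters), `mean` (closed-form mean of the fitted distribution),
#'   `sample(n)` and `quantile(p)` functions. A degenerate range
#'   (`lower == upper`) or `dist_kind = "fixed"` yields a point mass at
#'   the base value. A beta fit whose implied variance is infeasible
#'   (`SE^2 >= base * (1 - base)`) falls back to a point mass with a
#'   warning.
#' @examples
#' s <- fit_distribution(list(name = "hr_former_vs_never", base = 1.30,
#'                            lower = 0.95, upper = 1.81,
#'                            dist_kind = "lognormal"))
#' s$pars
#' @export
fit_distribution <- function(spec) {
  name <- spec$name
  base <- spec$base
  lower <- spec$lower
  upper <- spec$upper
  kind <- spec$dist_kind
  se <- (upper - lower) / (2 * 1.96)

  point_mass <- function() {
    structure(list(name = name, kind = "fixed",
                   pars = list(value = base), mean = base,
                   sample = function(n) rep(base, n),
                   quantile = function(p) rep(base, length(p))),
              class = "cess_sampler")
  }
  if (kind == "fixed" || se == 0) return(point_mass())

  if (kind == "gamma") {
    if (base <= 0) abort(paste0(name, ": gamma fit needs base > 0"))
    shape <- base^2 / se^2
    scale <- se^2 / base
    structure(list(name = name, kind = "gamma",
                   pars = list(shape = shape, scale = scale), mean = base,
                   sample = function(n) rgamma(n, shape = shape, scale = scale),
                   quantile = function(p) qgamma(p, shape = shape, scale = scale)),
              class = "cess_sampler")
  } else if (kind == "beta") {
    if (base <= 0 || base >= 1)
      abort(paste0(name, ": beta fit needs base in (0, 1)"))
    v <- se^2
    if (v >= base * (1 - base)) {
      warn(paste0(name, ": implied variance infeasible for a beta; ",
                  "falling back to a point mass"))
      return(point_mass())
    }
    k <- base * (1 - base) / v - 1
    alpha <- base * k
    beta <- (1 - base) * k
    structure(list(name = name, kind = "beta",
                   pars = list(alpha = alpha, beta = beta), mean = base,
                   sample = function(n) rbeta(n, alpha, beta),
                   quantile = function(p) qbeta(p, alpha, beta)),
              class = "cess_sampler")
  } else if (kind == "lognormal") {
    if (lower <= 0 || upper <= 0 || base <= 0)
      abort(paste0(name, ": lognormal fit needs positive base and bounds"))
    mu <- log(base)
    sigma <- (log(upper) - log(lower)) / (2 * 1.96)
    structure(list(name = name, kind = "lognormal",
                   pars = list(mu = mu, sigma = sigma),
                   mean = exp(mu + sigma^2 / 2),  # median, not mean, is base
                   sample = function(n) rlnorm(n, mu, sigma),
                   quantile = function(p) qlnorm(p, mu, sigma)),
              class = "cess_sampler")
  } else {
    abort(paste0("unknown dist_kind '", kind, "' for ", name))
  }
}

#' @export
print.cess_sampler <- function(x, ...) {
  cat(sprintf("<cess_sampler> %s: %s(%s)\n", x$name, x$kind,
              paste(sprintf("%s=%.5g", names(x$pars), unlist(x$pars)),
                    collapse = ", ")))
  invisible(x)
}

# Samplers for every non-fixed parameter in a parameter set.
.psa_samplers <- function(params) {
  reg <- params$ranges %>% filter(.data$dist_kind != "fixed")
  samplers <- purrr::map(seq_len(nrow(reg)), function(i) {
    fit_distribution(reg[i, ])
  })
  setNames(samplers, reg$name)
}
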