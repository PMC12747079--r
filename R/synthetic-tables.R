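# Synthetic CARD-FISH survey tables and flagellate growth curves, the
# tabular counterparts of the sequence generators.

default_env_vars <- function() {
  list(
    temperature  = list(mean = 15,  sd = 6,   coupling = 0),
    ph           = list(mean = 7.6, sd = 0.8, coupling = 0),
    chlorophyll  = list(mean = 12,  sd = 8,   coupling = 0),
    conductivity = list(mean = 250, sd = 120, coupling = 0)
  )
}

#' Generate a synthetic CARD-FISH survey table
#'
#' Per-sample total heterotrophic nanoflagellate (HNF) densities are
#' log-normal around `hnf_mean`; the fraction of HNF belonging to the focal
#' lineage is Beta(`a`, `b`); environmental covariates are Gaussian and
#' independent of the lineage fraction unless a per-covariate `coupling`
#' (correlation on the normal-scores scale) is set.
#'
#' The default Beta(0.73, 3.69) gives a mean fraction of 16.5% with a
#' standard deviation near 16 percentage points, emulating the dispersion
#' seen in large lake surveys of this lineage.
#'
#' @param n_samples Number of samples (rows).
#' @param hnf_mean Mean HNF density, cells per ml.
#' @param cry1a_beta Two-element `(a, b)` shape vector of the Beta law for
#'   the lineage fraction.
#' @param env_vars Named list of covariate specs, each a list with `mean`,
#'   `sd` and optional `coupling` in (-1, 1).
#' @param hnf_sdlog Log-scale SD of the HNF density.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `site`, `date`, `depth_class`,
#'   `hnf_count`, `cry1a_count`, `cry1a_pct` and one `env_*` column per
#'   covariate.
#' @export
gen_survey <- function(n_samples = 263L, hnf_mean = 1500,
                       cry1a_beta = c(0.73, 3.69),
                       env_vars = default_env_vars(),
                       hnf_sdlog = 0.8, seed = 1L) {
  a <- cry1a_beta[1]; b <- cry1a_beta[2]
  if (a <= 0 || b <= 0) abort("Beta shapes must be positive")
  set.seed(seed)
  frac <- pmin(1, pmax(0, rbeta(n_samples, a, b)))
  hnf <- round(rlnorm(n_samples, log(hnf_mean) - hnf_sdlog^2 / 2, hnf_sdlog))
  hnf <- pmax(hnf, 1)
  cry <- round(frac * hnf)
  # normal scores of the fraction drive any requested covariate coupling
  z <- qnorm(pmin(1 - 1e-9, pmax(1e-9, stats::pbeta(frac, a, b))))
  out <- tibble(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    site = sprintf("lake%02d", sample.int(max(2L, ceiling(n_samples / 3)),
                                          n_samples, replace = TRUE)),
    date = as.Date("2022-01-01") + sample.int(720, n_samples, replace = TRUE),
    depth_class = sample(c("epilimnion", "mid", "hypolimnion"), n_samples,
                         replace = TRUE, prob = c(0.5, 0.25, 0.25)),
    hnf_count = as.numeric(hnf),
    cry1a_count = as.numeric(cry),
    cry1a_pct = 100 * cry / hnf)
  for (nm in names(env_vars)) {
    sp <- env_vars[[nm]]
    rho <- sp$coupling %||% 0
    e <- rho * z + sqrt(1 - rho^2) * rnorm(n_samples)
    out[[paste0("env_", nm)]] <- sp$mean + sp$sd * e
  }
  out
}

#' Generate a synthetic growth-curve series
#'
#' Piecewise model: density stays at `inoculum` during the lag, grows
#' exponentially at rate `mu` afterwards, and is multiplied by
#' `(1 - collapse_frac)` from `t_collapse` onwards (a catastrophic
#' population collapse, as seen in virus-infected flagellate cultures).
#' Multiplicative log-normal noise with coefficient of variation `cv` is
#' applied to every observation.
#'
#' @param inoculum Starting density, cells per ml.
#' @param lag Lag-phase duration in hours.
#' @param mu Exponential growth rate per hour (doubling time `log(2)/mu`).
#' @param t_collapse Collapse time in hours (`Inf` for none).
#' @param collapse_frac Fraction of the population lost at collapse, in
#'   `[0, 1)`.
#' @param cv Observation coefficient of variation (0 = noiseless).
#' @param timepoints Sampling times in hours, strictly increasing.
#' @param replicate_id Label for the replicate.
#' @param seed Integer seed.
#' @return A tibble `replicate_id`, `time_h`, `count` with the generating
#'   parameters attached as attribute `"growth_params"`.
#' @export
gen_growth <- function(inoculum = 200, lag = 168, mu = log(2) / 29,
                       t_collapse = Inf, collapse_frac = 0, cv = 0.1,
                       timepoints = seq(0, 600, by = 24),
                       replicate_id = "rep1", seed = 1L) {
  if (mu <= 0) abort("mu must be positive")
  if (collapse_frac < 0 || collapse_frac >= 1) {
    abort("collapse_frac must lie in [0, 1)")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  set.seed(seed)
  expect <- ifelse(timepoints < lag, inoculum,
                   inoculum * exp(mu * (timepoints - lag)))
  expect <- ifelse(timepoints >= t_collapse, expect * (1 - collapse_frac),
                   expect)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- exp(rnorm(length(timepoints), -sdlog^2 / 2, sdlog))
  } else {
    noise <- 1
  }
  out <- tibble(replicate_id = replicate_id, time_h = as.numeric(timepoints),
                count = expect * noise)
  attr(out, "growth_params") <- list(inoculum = inoculum, lag = lag, mu = mu,
                                     t_collapse = t_collapse,
                                     collapse_frac = collapse_frac, cv = cv)
  out
}
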