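# CARD-FISH survey statistics: lineage relative abundance summaries,
# abundance-category counts, environmental correlation screens, and in-situ
# doubling times from abundance time series.

#' Summarise lineage relative abundance across a survey
#'
#' Computes the per-sample lineage percentage of total heterotrophic
#' nanoflagellates (`100 * cry1a_count / hnf_count`, or an existing
#' `cry1a_pct` column) and summarises it. Samples without an HNF count
#' (zero or missing) are excluded and counted separately, never imputed.
#' Category counts use strict inequalities (> 10%, < 1%).
#'
#' @param samples Survey tibble with `hnf_count` and `cry1a_count` (or
#'   `cry1a_pct`).
#' @return A one-row tibble: `n`, `mean`, `median`, `sd`, `min`, `max`,
#'   `n_above_10pct`, `n_below_1pct`, `n_excluded`. `sd` is the sample
#'   (n-1) standard deviation, `NA` for a single sample.
#' @export
summarize_survey <- function(samples) {
  samples <- as_tibble(samples)
  if (!"cry1a_pct" %in% names(samples)) {
    samples$cry1a_pct <- 100 * samples$cry1a_count / samples$hnf_count
  }
  excl <- if ("hnf_count" %in% names(samples)) {
    is.na(samples$hnf_count) | samples$hnf_count <= 0
  } else {
    is.na(samples$cry1a_pct)
  }
  pct <- samples$cry1a_pct[!excl]
  if (!length(pct)) abort("no samples with usable HNF counts")
  tibble(n = length(pct), mean = mean(pct), median = median(pct),
         sd = if (length(pct) > 1) sd(pct) else NA_real_,
         min = min(pct), max = max(pct),
         n_above_10pct = sum(pct > 10), n_below_1pct = sum(pct < 1),
         n_excluded = sum(excl))
}

#' Screen environmental covariates for correlation with lineage abundance
#'
#' Both Pearson and Spearman coefficients are computed on pairwise-complete
#' observations; a covariate is flagged when either absolute coefficient
#' exceeds `threshold`. Constant covariates yield `NA` coefficients, are
#' never flagged, and attach a warning.
#'
#' @param samples Survey tibble with a `cry1a_pct` (or counts to derive it)
#'   and covariate columns.
#' @param covariates Covariate column names; defaults to every `env_*`
#'   column.
#' @param threshold Flagging threshold on |r|.
#' @return A tibble: `covariate`, `pearson_r`, `spearman_r`, `n_pairs`,
#'   `flagged`.
#' @export
correlation_screen <- function(samples, covariates = NULL, threshold = 0.5) {
  samples <- as_tibble(samples)
  if (!"cry1a_pct" %in% names(samples)) {
    samples$cry1a_pct <- 100 * samples$cry1a_count / samples$hnf_count
  }
  covariates <- covariates %||% grep("^env_", names(samples), value = TRUE)
  if (!length(covariates)) abort("no covariates to screen")
  y <- samples$cry1a_pct
  out <- map_dfr(covariates, function(cv) {
    x <- samples[[cv]]
    ok <- complete.cases(x, y)
    n_pairs <- sum(ok)
    if (n_pairs < 3) abort(paste0("covariate '", cv, "' has < 3 complete pairs"))
    if (sd(x[ok]) == 0) {
      warn(paste0("covariate '", cv, "' is constant; coefficients undefined"))
      return(tibble(covariate = cv, pearson_r = NA_real_,
                    spearman_r = NA_real_, n_pairs = n_pairs,
                    flagged = FALSE))
    }
    pr <- cor(x[ok], y[ok], method = "pearson")
    sr <- cor(x[ok], y[ok], method = "spearman")
    tibble(covariate = cv, pearson_r = pr, spearman_r = sr,
           n_pairs = n_pairs,
           flagged = abs(pr) > threshold | abs(sr) > threshold)
  })
  out
}

#' Fastest in-situ doubling time from an abundance time series
#'
#' Over consecutive pairs with increasing abundance, the doubling time is
#' `(t2 - t1) * log(2) / log(N2 / N1)`; the minimum over pairs is reported.
#'
#' @param series Tibble with `time_h` and `abundance` (or two numeric
#'   vectors `time_h`, `abundance`).
#' @param time_h,abundance Optional column names when `series` uses other
#'   names.
#' @return A one-row tibble: `fastest_doubling_h` (`NA` when no increasing
#'   pair exists), `t_start`, `t_end`, `n_increasing_pairs`.
#' @export
insitu_doubling <- function(series, time_h = "time_h",
                            abundance = "abundance") {
  series <- as_tibble(series)
  t <- series[[time_h]]; n <- series[[abundance]]
  if (length(t) < 2) abort("need at least two timepoints")
  if (is.unsorted(t, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  if (any(n <= 0)) abort("abundances must be positive")
  dt <- diff(t)
  ratio <- n[-1] / n[-length(n)]
  inc <- ratio > 1
  if (!any(inc)) {
    return(tibble(fastest_doubling_h = NA_real_, t_start = NA_real_,
                  t_end = NA_real_, n_increasing_pairs = 0L))
  }
  dbl <- dt * log(2) / log(ratio)
  dbl[!inc] <- Inf
  k <- which.min(dbl)
  tibble(fastest_doubling_h = dbl[k], t_start = t[k], t_end = t[k + 1],
         n_increasing_pairs = sum(inc))
}
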