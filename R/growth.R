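# Growth-curve kinetics: exponential-phase fitting by windowed log-linear
# regression with an R^2-maximising window rule, and collapse detection
# against the running maximum.

#' Fit exponential growth to one count series
#'
#' Among all contiguous windows of at least `min_points` timepoints with a
#' positive slope of `log(count)` vs time and an observed fold-change of at
#' least `min_fold` (last over first count), the window maximising R^2 is
#' selected; ties go to more points, then to the earlier start. Windows
#' containing zero counts are excluded. The growth rate `mu` is the
#' least-squares slope and the doubling time is `log(2)/mu`.
#'
#' @param series Tibble with `time_h` and `count` for one replicate.
#' @param min_points Minimum window size in timepoints.
#' @param min_fold Minimum observed fold-change across the window.
#' @return An object of class `growth_fit` (list with `mu`, `doubling_h`,
#'   `r2`, `window`, `n_points`, `series`, `model`). When no window
#'   qualifies the fit fields are `NA` (a missing fit, not an error).
#' @export
fit_exponential <- function(series, min_points = 4L, min_fold = 2) {
  series <- as_tibble(series)
  t <- series$time_h; y <- series$count
  if (length(t) < 3) abort("need at least three timepoints")
  if (is.unsorted(t, strictly = TRUE)) abort("times must be strictly increasing")
  n <- length(t)
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      yy <- y[i:j]
      if (any(yy <= 0)) next
      if (yy[length(yy)] / yy[1] < min_fold) next
      fit <- lm(log(yy) ~ t[i:j])
      mu <- unname(coef(fit)[2])
      if (!is.finite(mu) || mu <= 0) next
      # noiseless series trip lm's perfect-fit warning; R^2 itself is fine
      r2 <- suppressWarnings(summary(fit)$r.squared)
      npt <- j - i + 1L
      better <- is.null(best) || r2 > best$r2 + 1e-12 ||
        (abs(r2 - best$r2) <= 1e-12 &&
           (npt > best$n_points ||
              (npt == best$n_points && t[i] < best$window[1])))
      if (better) {
        best <- list(mu = mu, r2 = r2, n_points = npt,
                     window = c(t[i], t[j]), model = fit)
      }
    }
  }
  if (is.null(best)) {
    best <- list(mu = NA_real_, r2 = NA_real_, n_points = NA_integer_,
                 window = c(NA_real_, NA_real_), model = NULL)
  }
  structure(list(mu = best$mu, doubling_h = log(2) / best$mu, r2 = best$r2,
                 window = best$window, n_points = best$n_points,
                 series = series, model = best$model),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (is.na(x$mu)) {
    cat("<growth_fit> no qualifying exponential window\n")
  } else {
    cat(sprintf(
      "<growth_fit> mu = %.4f /h, doubling = %.1f h, R^2 = %.4f, window [%g, %g] h (%d points)\n",
      x$mu, x$doubling_h, x$r2, x$window[1], x$window[2], x$n_points))
  }
  invisible(x)
}

#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble(term = c("log_intercept", "mu"), estimate = NA_real_,
                  std.error = NA_real_))
  }
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = c("log_intercept", "mu"),
         estimate = unname(s[, "Estimate"]),
         std.error = unname(s[, "Std. Error"]))
}

#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(mu = x$mu, doubling_h = x$doubling_h, r2 = x$r2,
         t_start = x$window[1], t_end = x$window[2], n_points = x$n_points)
}

#' Fit exponential growth per replicate
#'
#' @param data Tibble with `replicate_id`, `time_h`, `count`.
#' @param ... Passed to [fit_exponential()].
#' @return A tibble with one [glance()] row per replicate.
#' @export
fit_growth_curves <- function(data, ...) {
  data <- as_tibble(data)
  map_dfr(split(data, data$replicate_id), function(d) {
    g <- glance(fit_exponential(d, ...))
    g$replicate_id <- d$replicate_id[1]
    g[, c("replicate_id", setdiff(names(g), "replicate_id"))]
  })
}

#' Detect population collapses in a count series
#'
#' An event is emitted when a count falls by at least `drop_frac` (inclusive
#' bound) relative to the running maximum, provided that maximum was
#' attained within the last `horizon` sampling intervals. The fractional
#' drop is reported against the running maximum. Zero counts participate
#' (they are only excluded from log-linear growth fits).
#'
#' @param series Tibble with `time_h` and `count`.
#' @param drop_frac Minimum fractional drop.
#' @param horizon Maximum number of sampling intervals between the peak and
#'   the drop.
#' @return A tibble `time_h`, `drop`, `peak_time_h`, `peak_count` (zero rows
#'   when no collapse occurs).
#' @export
detect_collapse <- function(series, drop_frac = 0.5, horizon = 2L) {
  series <- as_tibble(series)
  t <- series$time_h; y <- series$count
  out <- list()
  for (i in seq_along(y)[-1]) {
    prior <- y[seq_len(i - 1L)]
    m <- max(prior)
    peak_last <- max(which(prior == m))  # most recent attainment of the max
    if (i - peak_last > horizon) next
    if (y[i] <= (1 - drop_frac) * m) {
      out[[length(out) + 1L]] <- tibble(
        time_h = t[i], drop = 1 - y[i] / m,
        peak_time_h = t[peak_last], peak_count = m)
    }
  }
  if (!length(out)) {
    return(tibble(time_h = double(), drop = double(),
                  peak_time_h = double(), peak_count = double()))
  }
  bind_rows(out)
}
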