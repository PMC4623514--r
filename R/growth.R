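#' Domain-growth series from a quench ensemble
#'
#' Computes the ensemble correlation profile at each snapshot time and the
#' half-height characteristic length `L(t)`, giving the `(t, L)` series
#' whose power law `L(t) ~ t^phi` is the growth law of the coarsening
#' dynamics.
#'
#' @param ensemble A [run_quench()] result.
#' @param times Snapshot times to use (default: all positive scheduled
#'   times).
#' @param level Decay fraction defining `L(t)` (default one half).
#' @return A tibble of class `growth_series` with columns `t` and `L`,
#'   carrying the ensemble config as attribute `config`.
#' @export
growth_series <- function(ensemble, times = NULL, level = 0.5) {
  stopifnot(inherits(ensemble, "quench_ensemble"))
  if (is.null(times)) {
    times <- ensemble$config$snapshot_times
    times <- times[times > 0]
  }
  L <- vapply(times, function(t) {
    domain_length(correlation_function(snapshot_ensemble(ensemble, t), t = t),
                  level = level)
  }, 0)
  structure(tibble(t = as.numeric(times), L = L),
    class = c("growth_series", class(tibble())),
    config = ensemble$config, level = level
  )
}

#' Fit the growth exponent by log-log least squares
#'
#' Ordinary least squares of `log L` on `log t` over a fit window, giving
#' the growth exponent `phi` of `L(t) ~ t^phi` and its standard error.
#' Curvature-driven nonconserved coarsening follows the Cahn-Allen law
#' `phi = 1/2`.
#'
#' @param series A tibble with columns `t` and `L` (e.g. [growth_series()]).
#' @param fit_window Optional `c(t_min, t_max)` restricting the fit; at
#'   least 4 points must remain.
#' @return An object of class `growth_fit` with components `phi`, `stderr`,
#'   `prefactor` (with `prefactor_stderr`), `fit` (the `lm`), and `data`.
#'   Supports [tidy()], [glance()], and [autoplot()].
#' @examples
#' s <- tibble::tibble(t = c(50, 100, 200, 400, 800), L = 3 * sqrt(c(50, 100, 200, 400, 800)))
#' growth_exponent(s)$phi  # 0.5
#' @export
growth_exponent <- function(series, fit_window = NULL) {
  if (!all(c("t", "L") %in% names(series))) {
    abort("`series` needs columns `t` and `L`.")
  }
  d <- tibble(t = as.numeric(series$t), L = as.numeric(series$L))
  if (!is.null(fit_window)) {
    d <- d[d$t >= fit_window[1] & d$t <= fit_window[2], ]
  }
  if (any(d$t <= 0) || any(d$L <= 0)) {
    abort("Times and lengths must be positive for a log-log fit.")
  }
  if (nrow(d) < 4) abort("Need at least 4 points in the fit window.")
  fit <- lm(log(L) ~ log(t), data = d)
  sm <- summary(fit)$coefficients
  structure(list(
    phi = unname(coef(fit)[2]), stderr = sm[2, 2],
    prefactor = exp(unname(coef(fit)[1])), prefactor_stderr = sm[1, 2],
    fit = fit, data = d
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> phi = %.4f +/- %.4f, prefactor = %.4f (%d points)\n",
    x$phi, x$stderr, x$prefactor, nrow(x$data)
  ))
  invisible(x)
}

#' @rdname growth_exponent
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("log_prefactor", "phi"),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
}

#' @rdname growth_exponent
#' @export
glance.growth_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    phi = x$phi, std.error = x$stderr, prefactor = x$prefactor,
    r.squared = sm$r.squared, nobs = nrow(x$data)
  )
}

#' Log-log tail slope of the structure factor
#'
#' Least-squares slope of `log S` versus `log k` over a tail window. Sharp
#' domain interfaces produce Porod's law `S(k) ~ k^-(d+1)`, i.e. a slope of
#' `-3` in two dimensions.
#'
#' @param profile A [structure_factor()] result (or tibble with `k`, `S`).
#' @param tail_window `c(k_min, k_max)` selecting the tail; at least 4 bins
#'   with `S > 0` must remain.
#' @return A list with `slope` and `stderr`.
#' @export
porod_tail_slope <- function(profile, tail_window) {
  if (!all(c("k", "S") %in% names(profile))) {
    abort("`profile` needs columns `k` and `S`.")
  }
  d <- profile[profile$k >= tail_window[1] & profile$k <= tail_window[2] &
                 profile$k > 0, c("k", "S")]
  if (nrow(d) < 4) abort("Need at least 4 bins in the tail window.")
  if (any(d$S <= 0)) abort("Structure factor must be positive in the window.")
  fit <- lm(log(S) ~ log(k), data = d)
  list(
    slope = unname(coef(fit)[2]),
    stderr = summary(fit)$coefficients[2, 2]
  )
}
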