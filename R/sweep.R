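#' Magnetization curve and susceptibility-peak critical point
#'
#' Summarises per-temperature equilibrium magnetization samples into
#' `<|m|>` and the susceptibility `chi = N * beta * (<m^2> - <|m|>^2)`, and
#' estimates the empirical critical temperature as the susceptibility-peak
#' temperature. The absolute value `|m|` is used because a finite system
#' below criticality breaks symmetry toward either sign.
#'
#' @param samples A tibble with columns `temp` (temperature of the block)
#'   and `m` (one magnetization measurement per row).
#' @param n_sites Number of lattice sites `N` entering `chi`.
#' @return A tibble of class `magnetization_curve` with columns `temp`,
#'   `m_abs`, `m2`, `chi`, and `n_samples`, sorted by temperature, with the
#'   susceptibility-peak estimate in attribute `T_c`.
#' @export
magnetization_curve <- function(samples, n_sites) {
  if (!all(c("temp", "m") %in% names(samples))) {
    abort("`samples` needs columns `temp` and `m`.")
  }
  out <- samples |>
    dplyr::group_by(.data$temp) |>
    dplyr::summarise(
      m_abs = mean(abs(.data$m)),
      m2 = mean(.data$m^2),
      n_samples = dplyr::n()
    ) |>
    dplyr::arrange(.data$temp) |>
    dplyr::mutate(chi = n_sites / .data$temp * (.data$m2 - .data$m_abs^2))
  T_c <- out$temp[which.max(out$chi)]
  structure(out,
    class = c("magnetization_curve", class(tibble())),
    T_c = T_c, n_sites = n_sites
  )
}

#' Temperature sweep of the equilibrium magnetization
#'
#' Anneals a lattice downward through a temperature grid (reusing the final
#' state of the previous temperature to shorten equilibration), discards
#' the first half of the Monte Carlo steps at each temperature, and samples
#' the magnetization every `measure_every` MCS thereafter. The result feeds
#' [magnetization_curve()], whose susceptibility peak locates the empirical
#' critical temperature of the truncated-kernel model.
#'
#' @param n Coupling decay exponent.
#' @param L_s Even linear lattice size.
#' @param temps Temperature grid (any order; annealing proceeds from the
#'   highest down).
#' @param mcs_per_temp Monte Carlo steps spent at each temperature (half
#'   equilibration, half measurement).
#' @param measure_every Sampling stride in MCS within the measurement half.
#' @param seed Integer seed.
#' @param J,cutoff Passed to [coupling_kernel()].
#' @return A list of class `sweep_result` with `samples` (tibble `temp`,
#'   `m`), `curve` (a [magnetization_curve()]), `T_c`, and the sweep
#'   parameters.
#' @export
temperature_sweep <- function(n, L_s, temps, mcs_per_temp = 600,
                              measure_every = 5, seed = 1L,
                              J = 1, cutoff = NULL) {
  if (length(temps) < 2) abort("`temps` needs at least 2 temperatures.")
  if (any(temps <= 0)) abort("Temperatures must be positive.")
  kernel <- coupling_kernel(n, J, cutoff)
  check_kernel_fits(kernel, L_s)
  temps_desc <- sort(unique(temps), decreasing = TRUE)
  set.seed(as.integer(seed))
  spins <- lattice_fixture("balanced_random", L_s)
  keep <- seq(ceiling(mcs_per_temp / 2) + 1, mcs_per_temp)
  keep <- keep[(keep - keep[1]) %% measure_every == 0]
  samples <- purrr::map_dfr(temps_desc, function(temp) {
    res <- mc_sweep(spins, kernel, 1 / temp, mcs_per_temp)
    spins <<- res$spins
    tibble(temp = temp, m = res$magnetization[keep])
  })
  curve <- magnetization_curve(samples, n_sites = L_s^2)
  structure(list(
    samples = samples, curve = curve, T_c = attr(curve, "T_c"),
    n = n, L_s = L_s, temps = temps_desc, mcs_per_temp = mcs_per_temp,
    measure_every = measure_every, seed = as.integer(seed)
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> n = %g, L_s = %d, %d temperatures; susceptibility-peak T_c = %g\n",
    x$n, x$L_s, length(x$temps), x$T_c
  ))
  invisible(x)
}
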