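#' Closed-form interaction potential per spin
#'
#' Continuum approximation of the per-site interaction energy
#' `U(n) = (1/N) sum_{i != j} J / r_ij^n` on an `N`-site square lattice of
#' linear size `sqrt(N)`, obtained from the radial integral
#' `J * integral_1^sqrt(N) r^(3-n) dr` with pair-distribution `g(r) ~ 1`.
#' The three branches are
#' \describe{
#'   \item{`n = 4`}{`U = (J/2) ln N` (logarithmic growth with size),}
#'   \item{`n > 4`}{`U = J/(n-4) * (1 - N^(2 - n/2))`, finite as
#'     `N -> Inf`,}
#'   \item{`0 < n < 4`}{`U = J/(4-n) * N^(2 - n/2)`, diverging with size
#'     (long-range regime).}
#' }
#'
#' @param n Positive decay exponent.
#' @param N Number of lattice sites (`>= 4`), or `Inf`.
#' @param J Coupling strength.
#' @return A one-row tibble with columns `n`, `N`, `branch`, and `U`
#'   (units of `J`). For `n <= 4` and `N = Inf`, `U` is `Inf`.
#' @examples
#' potential_closed_form(6, Inf)   # U = J / 2
#' @export
potential_closed_form <- function(n, N, J = 1) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    abort("`n` must be a single positive number.")
  }
  if (!is.numeric(N) || length(N) != 1 || (is.finite(N) && N < 4)) {
    abort("`N` must be a single value >= 4 (or Inf).")
  }
  branch <- if (n == 4) "n_eq_4" else if (n > 4) "n_gt_4" else "n_lt_4"
  U <- switch(branch,
    n_eq_4 = J / 2 * log(N),
    n_gt_4 = J / (n - 4) * (1 - N^(2 - n / 2)),
    n_lt_4 = if (is.finite(N)) J / (4 - n) * N^(2 - n / 2) else Inf
  )
  tibble(n = n, N = N, branch = branch, U = U)
}

#' Mean-field critical temperature of the power-law Ising model
#'
#' Leading-order estimate `T_c ~ U(n, N) / k_B` from the closed-form
#' potential, with `k_B = 1` by convention. For short-range couplings
#' (`n > 4`) the critical temperature is finite in the thermodynamic limit,
#' `T_c = J / (k_B (n - 4))`; for `n = 4` it diverges logarithmically,
#' `T_c = J ln(N) / (2 k_B)`; for long-range couplings (`0 < n < 4`) it
#' diverges as a power of the system size,
#' `T_c = (J/k_B) N^(2 - n/2) / (4 - n)`.
#'
#' @inheritParams potential_closed_form
#' @param k_B Boltzmann constant (default 1).
#' @return A one-row tibble with columns `n`, `N`, `branch`, `T_c` (units of
#'   `J/k_B`), and `diverging` (`TRUE` when `n <= 4` with `N = Inf`, where
#'   `T_c` is `Inf`).
#' @examples
#' critical_temperature(6, Inf)   # T_c = 0.5
#' @export
critical_temperature <- function(n, N, J = 1, k_B = 1) {
  p <- potential_closed_form(n, N, J)
  diverging <- n <= 4 && !is.finite(N)
  tibble(
    n = n, N = N, branch = p$branch,
    T_c = if (diverging) Inf else p$U / k_B,
    diverging = diverging
  )
}

#' Theory table over a grid of (n, N)
#'
#' Tabulates the closed-form potential, the critical-temperature estimate,
#' and the second-moment lattice sum `f_2` of the truncated kernel for each
#' requested exponent and system size.
#'
#' @param n Vector of decay exponents.
#' @param N Vector of site counts (recycled against `n` via a full grid).
#' @inheritParams critical_temperature
#' @return A tibble with one row per `(n, N)` combination: columns `n`, `N`,
#'   `branch`, `U`, `T_c`, `diverging`, `f_2`, `r_c`, `n_offsets`.
#' @export
theory_table <- function(n, N = Inf, J = 1, k_B = 1) {
  grid <- expand.grid(n = n, N = N)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    ni <- grid$n[i]; Ni <- grid$N[i]
    p <- potential_closed_form(ni, Ni, J)
    tc <- critical_temperature(ni, Ni, J, k_B)
    k <- coupling_kernel(ni, J)
    tibble(
      n = ni, N = Ni, branch = p$branch, U = p$U,
      T_c = tc$T_c, diverging = tc$diverging,
      f_2 = f2_lattice_sum(k), r_c = attr(k, "r_c"), n_offsets = nrow(k)
    )
  })
}
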