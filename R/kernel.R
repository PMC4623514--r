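#' Build the power-law coupling kernel
#'
#' Enumerates every integer lattice offset `(di, dj) != (0, 0)` whose
#' Euclidean length satisfies `0 < r <= r_c` and attaches the ferromagnetic
#' coupling weight `J / r^n`. The default cutoff is `r_c = 2.5^(6/n)`, which
#' keeps roughly the same interaction energy truncated at every `n`: short
#' ranges (`n = 12`) interact with 8 neighbours, while `n = 2` couples each
#' spin to 768 neighbours. The cutoff boundary is inclusive, so the `n = 6`
#' kernel keeps the `r = sqrt(5)` shell and the `n = 12` kernel keeps
#' `r = sqrt(2)`.
#'
#' @param n Positive real; decay exponent of the coupling `J / r^n`.
#' @param J Positive real; coupling strength at `r = 1` (energy units).
#' @param cutoff Optional positive real overriding the default cutoff.
#' @return A tibble of class `coupling_kernel` with columns `di`, `dj`
#'   (integer offsets), `r` (Euclidean length), and `w` (coupling weight),
#'   carrying attributes `n`, `J`, and `r_c`.
#' @examples
#' k <- coupling_kernel(6)
#' nrow(k)      # 20 offsets within r_c = 2.5
#' @export
coupling_kernel <- function(n, J = 1, cutoff = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    abort("`n` must be a single positive number.")
  }
  if (!is.numeric(J) || length(J) != 1 || J <= 0) {
    abort("`J` must be a single positive number.")
  }
  r_c <- if (is.null(cutoff)) 2.5^(6 / n) else cutoff
  if (!is.numeric(r_c) || length(r_c) != 1 || r_c <= 0) {
    abort("`cutoff` must be a single positive number.")
  }
  half <- ceiling(r_c)
  g <- expand.grid(di = -half:half, dj = -half:half)
  g$r <- sqrt(g$di^2 + g$dj^2)
  # inclusive boundary; tiny epsilon guards sqrt() representation of shells
  g <- g[g$r > 0 & g$r <= r_c * (1 + 1e-12), , drop = FALSE]
  out <- tibble(
    di = as.integer(g$di), dj = as.integer(g$dj),
    r = g$r, w = J / g$r^n
  )
  out <- out[order(out$r, out$di, out$dj), ]
  structure(out,
    class = c("coupling_kernel", class(tibble())),
    n = n, J = J, r_c = r_c
  )
}

#' Per-site second moment of the couplings
#'
#' Returns `sum(w^2)` over all kernel offsets, the lattice sum entering the
#' second-order correction to the mean-field critical-point condition. It is
#' diagnostic only: the critical-temperature formulas use the leading-order
#' approximation.
#'
#' @param kernel A [coupling_kernel()].
#' @return A single number, `sum_offsets w^2`.
#' @examples
#' f2_lattice_sum(coupling_kernel(12))  # 4 + 4/64^2
#' @export
f2_lattice_sum <- function(kernel) {
  stopifnot(inherits(kernel, "coupling_kernel"))
  sum(kernel$w^2)
}

#' @export
print.coupling_kernel <- function(x, ...) {
  cat(sprintf(
    "<coupling_kernel> n = %g, J = %g, r_c = %g, %d offsets\n",
    attr(x, "n"), attr(x, "J"), attr(x, "r_c"), nrow(x)
  ))
  NextMethod()
}

# Kernel must fit inside half the box so every pair has a unique
# minimum-image separation; refuse ambiguous configurations.
check_kernel_fits <- function(kernel, L_s) {
  if (attr(kernel, "r_c") >= L_s / 2) {
    abort(sprintf(
      "Kernel cutoff r_c = %g must be < L_s/2 = %g (minimum-image convention).",
      attr(kernel, "r_c"), L_s / 2
    ))
  }
  invisible(kernel)
}
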