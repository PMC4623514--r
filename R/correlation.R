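# Ensemble-averaged 2D correlation field under periodic wrap.
# For each lattice the full circular autocorrelation
#   A(d) = (1/N) sum_i s_i s_{i+d}
# is computed by FFT; the ensemble mean magnetization (one scalar — the
# system is translationally invariant) is squared and subtracted, and the
# field is normalized so the zero-separation value is exactly 1.
corr_field <- function(lattices) {
  if (length(lattices) < 1) abort("Need at least one lattice.")
  L <- nrow(lattices[[1]])
  for (s in lattices) {
    check_lattice(s)
    if (nrow(s) != L) abort("All lattices must share the same L_s.")
  }
  N <- as.numeric(L)^2
  A <- Reduce(`+`, lapply(lattices, function(s) {
    F <- fft(s)
    Re(fft(F * Conj(F), inverse = TRUE)) / (N * N)
  })) / length(lattices)
  m_bar <- mean(vapply(lattices, mean, 0))
  # normalize by the measured zero-separation value (A(0) = 1 for +/-1
  # spins up to FFT rounding) so that C(0) = 1 holds exactly
  var0 <- A[1, 1] - m_bar^2
  if (var0 <= .Machine$double.eps^0.5) {
    abort("Degenerate ensemble: zero spin variance, normalization undefined.")
  }
  field <- (A - m_bar^2) / var0
  attr(field, "L_s") <- L
  field
}

# Minimum-image component displacements for FFT index 0..L-1.
min_image <- function(L) {
  d <- 0:(L - 1)
  ifelse(d > L / 2, d - L, d)
}

#' Spherically averaged equal-time correlation function
#'
#' Computes `C(r, t) = <s_i s_j> - <s_i><s_j>` over all site pairs and the
#' supplied ensemble of same-time snapshots (via the full 2D periodic
#' autocorrelation), subtracts the squared ensemble mean magnetization,
#' normalizes so `C(0) = 1`, and spherically averages into radial bins of
#' width 1 lattice unit centered on the integers (minimum-image
#' separations).
#'
#' @param lattices A list of spin matrices (an ensemble at equal time), or a
#'   single spin matrix.
#' @param t Optional MCS time stored as metadata.
#' @param bins `"integer"` (default) averages into unit-width bins centered
#'   on the integers, the convention used for coarsening profiles;
#'   `"exact"` keeps every distinct separation length as its own shell,
#'   which resolves e.g. the `r = 1` and `r = sqrt(2)` shells of a
#'   checkerboard.
#' @return A tibble of class `correlation_profile` with columns `r` (bin
#'   center), `C`, and `n_pairs` (offsets contributing to the bin), plus
#'   attributes `t`, `L_s`, `n_lattices`, and the unbinned 2D `field`.
#' @examples
#' cb <- lattice_fixture("checkerboard", 8)
#' correlation_function(list(cb), bins = "exact")  # C(1) = -1, C(sqrt 2) = +1
#' @export
correlation_function <- function(lattices, t = NA_real_,
                                 bins = c("integer", "exact")) {
  bins <- match.arg(bins)
  if (is.matrix(lattices)) lattices <- list(lattices)
  field <- corr_field(lattices)
  L <- attr(field, "L_s")
  d <- min_image(L)
  r <- sqrt(outer(d^2, d^2, `+`))
  bin <- if (bins == "integer") round(r) else round(r, 9)
  df <- tibble(bin = as.vector(bin), C = as.vector(field)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(C = mean(.data$C), n_pairs = dplyr::n()) |>
    dplyr::arrange(.data$bin)
  out <- tibble(r = as.numeric(df$bin), C = df$C, n_pairs = df$n_pairs)
  structure(out,
    class = c("correlation_profile", class(tibble())),
    t = t, L_s = L, n_lattices = length(lattices), field = field
  )
}

#' Spherically averaged structure factor
#'
#' Discrete Fourier transform `S(k, t) = sum_r C(r, t) exp(i k . r)` of the
#' unbinned 2D correlation field, spherically averaged over shells of width
#' one grid mode (`k = 2 pi s / L_s` for integer shell `s`). Under this
#' convention Parseval's identity holds exactly: the sum of the full 2D
#' spectrum equals `N * C(0) = N`.
#'
#' @inheritParams correlation_function
#' @return A tibble of class `structure_profile` with columns `k`
#'   (wavenumber, units `2*pi/L_s` per mode), `S`, and `n_modes`, plus
#'   attributes `t`, `L_s`, and the full 2D `spectrum`.
#' @export
structure_factor <- function(lattices, t = NA_real_) {
  if (is.matrix(lattices)) lattices <- list(lattices)
  field <- corr_field(lattices)
  L <- attr(field, "L_s")
  spec <- Re(fft(field)) # field is even under negation => real spectrum
  s_mode <- min_image(L)
  shell <- round(sqrt(outer(s_mode^2, s_mode^2, `+`)))
  df <- tibble(shell = as.vector(shell), S = as.vector(spec)) |>
    dplyr::group_by(.data$shell) |>
    dplyr::summarise(S = mean(.data$S), n_modes = dplyr::n()) |>
    dplyr::arrange(.data$shell)
  out <- tibble(k = 2 * pi * df$shell / L, S = df$S, n_modes = df$n_modes)
  structure(out,
    class = c("structure_profile", class(tibble())),
    t = t, L_s = L, n_lattices = length(lattices), spectrum = spec
  )
}

#' Characteristic domain length from the correlation function
#'
#' The domain scale `L(t)` is the distance at which `C(r, t)` first decays
#' (downward) through `level` times its maximum `C(0) = 1`, linearly
#' interpolated between adjacent radial bins.
#'
#' @param profile A [correlation_function()] result.
#' @param level Decay fraction, default one half.
#' @return The crossing distance in lattice units.
#' @examples
#' p <- correlation_function(list(lattice_fixture("slab", 16)))
#' domain_length(p)
#' @export
domain_length <- function(profile, level = 0.5) {
  stopifnot(inherits(profile, "correlation_profile"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).")
  }
  r <- profile$r
  C <- profile$C
  if (abs(C[1] - 1) > 1e-8) abort("Profile must be normalized to C(0) = 1.")
  below <- which(C < level)
  if (length(below) == 0) {
    abort(paste(
      "Correlation never decays below the level within the box:",
      "domains are comparable to the system size; enlarge L_s."
    ))
  }
  j <- below[1]
  i <- j - 1
  r[i] + (C[i] - level) / (C[i] - C[j]) * (r[j] - r[i])
}

#' Ohta-Jasnow-Kawasaki scaled correlation function
#'
#' The analytic scaling function `(2/pi) * asin(exp(-x^2))` for the
#' equal-time correlation of a nonconserved scalar order parameter, with
#' `x = r / L(t)`.
#'
#' @param x Nonnegative scaled separation(s).
#' @return `C` values in `[0, 1]`.
#' @examples
#' ojk_correlation(0)  # 1
#' @export
ojk_correlation <- function(x) {
  if (any(x < 0)) abort("`x` must be nonnegative.")
  (2 / pi) * asin(exp(-x^2))
}
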