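# Independent oracles and small utilities shared across tests.

# Brute-force Hamiltonian: enumerate every unordered pair once via the
# offset star, in plain R, independent of the compiled path.
brute_energy <- function(spins, kernel) {
  L <- nrow(spins)
  e <- 0
  for (a in seq_len(nrow(kernel))) {
    di <- kernel$di[a]; dj <- kernel$dj[a]; w <- kernel$w[a]
    for (i in seq_len(L)) for (j in seq_len(L)) {
      ii <- (i - 1 + di) %% L + 1
      jj <- (j - 1 + dj) %% L + 1
      e <- e + w * spins[i, j] * spins[ii, jj]
    }
  }
  -e / 2
}

# O(N^2) pair enumeration of the spherically averaged correlation function
# on one lattice, with ensemble-mean subtraction and C(0) = 1 normalization
# (integer bins, minimum image).
brute_correlation <- function(spins) {
  L <- nrow(spins)
  m <- mean(spins)
  acc <- list()
  for (di in 0:(L - 1)) for (dj in 0:(L - 1)) {
    dmi <- if (di > L / 2) di - L else di
    dmj <- if (dj > L / 2) dj - L else dj
    b <- as.character(round(sqrt(dmi^2 + dmj^2)))
    s <- mean(spins * spins[((seq_len(L) - 1 + di) %% L) + 1,
                            ((seq_len(L) - 1 + dj) %% L) + 1, drop = FALSE])
    if (is.null(acc[[b]])) acc[[b]] <- c(0, 0)
    acc[[b]] <- acc[[b]] + c(s, 1)
  }
  bins <- sort(as.numeric(names(acc)))
  C <- vapply(as.character(bins), function(b) acc[[b]][1] / acc[[b]][2], 0)
  data.frame(r = bins, C = (C - m^2) / (1 - m^2))
}

# First radial bin at which C drops below `level`; Inf when it never does
# within the box.
decay_range <- function(profile, level = 0.1) {
  b <- which(profile$C < level)
  if (length(b) == 0) Inf else profile$r[b[1]]
}

# Synthetic correlation profile with an analytic shape, for tests of the
# profile-consuming operations.
synthetic_profile <- function(r, C, t = NA_real_) {
  structure(tibble::tibble(r = r, C = C, n_pairs = 1L),
    class = c("correlation_profile", class(tibble::tibble())),
    t = t, L_s = NA_integer_, n_lattices = 1L
  )
}
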