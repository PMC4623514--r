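test_that("correlation of a checkerboard resolves the alternating shells", {
  p <- correlation_function(lattice_fixture("checkerboard", 8), bins = "exact")
  expect_equal(p$C[p$r == 0], 1)
  expect_equal(p$C[p$r == 1], -1)
  expect_equal(p$C[abs(p$r - sqrt(2)) < 1e-6], 1)
  expect_equal(p$C[p$r == 2], 1)
})

test_that("profiles are normalized to C(0) = 1 with bounded values", {
  set.seed(3)
  lat <- replicate(3, lattice_fixture("balanced_random", 32), simplify = FALSE)
  cfg <- quench_config(32, 6, 1, snapshot_times = 30, seed = 5, n_runs = 3)
  coars <- snapshot_ensemble(run_quench(cfg), 30)
  for (ens in list(lat, coars)) {
    p <- correlation_function(ens)
    expect_equal(p$C[p$r == 0], 1)
    expect_true(all(abs(p$C) <= 1 + 1e-9))
  }
})

test_that("a single random lattice is uncorrelated beyond r = 0", {
  p <- correlation_function(lattice_fixture("balanced_random", 128, seed = 1))
  expect_true(all(abs(p$C[p$r >= 1]) < 0.05))
})

test_that("correlation matches the O(N^2) pair-enumeration oracle", {
  for (seed in c(1, 2)) {
    s <- lattice_fixture("balanced_random", 8, seed = seed)
    p <- correlation_function(s)
    oracle <- brute_correlation(s)
    expect_equal(p$r, oracle$r)
    expect_equal(p$C, oracle$C, tolerance = 1e-12)
  }
})

test_that("uniform ensembles are rejected as degenerate", {
  expect_error(correlation_function(lattice_fixture("uniform_up", 8)),
               "Degenerate")
  expect_error(structure_factor(list(lattice_fixture("uniform_down", 8),
                                     lattice_fixture("uniform_down", 8))),
               "Degenerate")
})

test_that("Parseval's identity holds exactly for the 2D spectrum", {
  for (seed in 1:2) {
    cfg <- quench_config(32, 6, 1, snapshot_times = 20, seed = seed, n_runs = 2)
    ens <- snapshot_ensemble(run_quench(cfg), 20)
    s <- structure_factor(ens)
    spec <- attr(s, "spectrum")
    # sum over all modes = N * C(0) = N under this transform convention
    expect_equal(sum(spec), 32^2, tolerance = 1e-9)
  }
})

test_that("white noise has a flat spectrum and a checkerboard peaks at (pi, pi)", {
  set.seed(7)
  ens <- replicate(24, lattice_fixture("balanced_random", 32), simplify = FALSE)
  s <- structure_factor(ens)
  # E[S] = 1 at every k for uncorrelated spins; shell averages at finite
  # sample size scatter around it
  expect_true(all(abs(s$S[s$k > 0] - 1) < 0.5))
  expect_equal(mean(s$S[s$k > 0]), 1, tolerance = 0.05)

  cb <- structure_factor(lattice_fixture("checkerboard", 8))
  spec <- attr(cb, "spectrum")
  corner <- which(spec == max(spec), arr.ind = TRUE)
  expect_equal(unname(corner[1, ]), c(5, 5)) # mode (L/2, L/2) <=> (pi, pi)
})

test_that("domain length inverts analytic profiles", {
  r <- 0:40
  # exponential: crossing at 5 ln 2
  p_exp <- synthetic_profile(r, exp(-r / 5))
  expect_equal(domain_length(p_exp), 5 * log(2), tolerance = 0.03)
  # OJK shape with scale 10: half height at 5.887
  p_ojk <- synthetic_profile(r, ojk_correlation(r / 10))
  expect_equal(domain_length(p_ojk), 5.887, tolerance = 0.02)
  # no crossing within the box
  expect_error(domain_length(synthetic_profile(r, rep(1, length(r)))),
               "never decays|normalized")
  expect_error(domain_length(synthetic_profile(r, 0.9 - 0.001 * r)),
               "normalized")
})

test_that("domain length scales with the r axis and is monotone in level", {
  r <- 0:60
  p1 <- synthetic_profile(r, ojk_correlation(r / 8))
  p2 <- synthetic_profile(3 * r, ojk_correlation(r / 8)) # both axes stretched
  expect_equal(domain_length(p2), 3 * domain_length(p1), tolerance = 1e-6)
  levels <- c(0.7, 0.5, 0.3)
  Ls <- vapply(levels, function(l) domain_length(p1, level = l), 0)
  expect_true(all(diff(Ls) > 0)) # lower level crossed farther out
})

test_that("the OJK scaling function has its closed-form values", {
  expect_equal(ojk_correlation(0), 1)
  expect_equal(ojk_correlation(1), (2 / pi) * asin(exp(-1)))
  expect_equal(ojk_correlation(1), 0.2398, tolerance = 1e-3)
  expect_lt(ojk_correlation(6), 1e-9)
  expect_error(ojk_correlation(-0.1), "nonnegative")
})

test_that("growth exponent recovers exact power laws", {
  t <- c(50, 100, 200, 400, 800)
  f_half <- suppressWarnings(growth_exponent(tibble::tibble(t = t, L = 3 * t^0.5)))
  expect_equal(f_half$phi, 0.5, tolerance = 1e-12)
  expect_equal(f_half$prefactor, 3, tolerance = 1e-10)
  f_lin <- suppressWarnings(growth_exponent(tibble::tibble(t = t, L = 2 * t)))
  expect_equal(f_lin$phi, 1, tolerance = 1e-12)
  # fit window restricts the points
  f_win <- suppressWarnings(growth_exponent(tibble::tibble(t = t, L = 3 * t^0.5),
                                            fit_window = c(100, 800)))
  expect_identical(nrow(f_win$data), 4L)
  expect_error(growth_exponent(tibble::tibble(t = t[1:3], L = t[1:3])), "4 points")
  expect_error(growth_exponent(tibble::tibble(t = t, L = -t)), "positive")
})

test_that("tidy and glance expose the growth fit", {
  t <- c(50, 100, 200, 400, 800)
  f <- growth_exponent(tibble::tibble(t = t, L = 3 * t^0.5 * exp(rnorm(5, 0, 0.01))))
  td <- tidy(f)
  expect_identical(td$term, c("log_prefactor", "phi"))
  expect_equal(td$estimate[2], f$phi)
  gl <- glance(f)
  expect_identical(names(gl), c("phi", "std.error", "prefactor", "r.squared", "nobs"))
  expect_gt(gl$r.squared, 0.99)
})

test_that("Porod fit recovers synthetic power-law tails", {
  k <- seq(0.2, 2, by = 0.05)
  prof <- tibble::tibble(k = k, S = k^-3)
  exact <- suppressWarnings(porod_tail_slope(prof, c(0.2, 2)))
  expect_equal(exact$slope, -3, tolerance = 1e-12)
  set.seed(2)
  noisy <- tibble::tibble(k = k, S = k^-3 * (1 + 0.01 * rnorm(length(k))))
  expect_equal(porod_tail_slope(noisy, c(0.2, 2))$slope, -3, tolerance = 0.05)
  expect_error(porod_tail_slope(prof, c(1.9, 2)), "4 bins")
  bad <- tibble::tibble(k = k, S = c(-1, (k^-3)[-1]))
  expect_error(porod_tail_slope(bad, c(0.2, 2)), "positive")
})

test_that("analytically self-similar profiles collapse exactly", {
  r <- 0:80
  profs <- lapply(c(5, 10, 20), function(Lam) {
    synthetic_profile(r, ojk_correlation(r / Lam))
  })
  col <- scaling_collapse(profs)
  expect_lt(max(col$rms_pairwise), 0.01)
  expect_lt(max(col$rms_ojk), 0.01)
  expect_error(scaling_collapse(profs[1]), "at least 2")
})

test_that("structure-factor collapse uses the d = 2 rescaling", {
  # build two profiles from the same scaling function f(kL) = exp(-kL):
  # S(k) = L^2 f(kL) collapses exactly; without the L^2 factor it cannot
  mk <- function(Lam) {
    k <- seq(0.05, 4, by = 0.05)
    structure(tibble::tibble(k = k, S = Lam^2 * exp(-k * Lam), n_modes = 1L),
      class = c("structure_profile", class(tibble::tibble())),
      t = NA_real_, L_s = NA_integer_
    )
  }
  col <- scaling_collapse(list(mk(5), mk(10)), lengths = c(5, 10))
  expect_lt(max(col$rms_pairwise), 0.02) # linear-interpolation error only
  expect_error(scaling_collapse(list(mk(5), mk(10))), "lengths")
  gl <- glance(col)
  expect_identical(gl$type, "structure")
  expect_true(is.na(gl$rms_ojk_max))
})

test_that("magnetization curve locates the susceptibility peak", {
  # synthetic sigmoid transition with a variance bump at T = 2
  set.seed(6)
  samples <- purrr::map_dfr(seq(1, 3, by = 0.25), function(T) {
    base <- 1 / (1 + exp(8 * (T - 2)))
    spread <- 0.02 + 0.3 * exp(-8 * (T - 2)^2)
    tibble::tibble(temp = T, m = base + rnorm(60, 0, spread))
  })
  curve <- magnetization_curve(samples, n_sites = 64^2)
  expect_equal(attr(curve, "T_c"), 2, tolerance = 0.3)
  expect_true(all(diff(curve$temp) > 0))
  expect_error(magnetization_curve(tibble::tibble(x = 1), 10), "temp")
})
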