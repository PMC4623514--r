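#' Metropolis acceptance rule
#'
#' Accepts a proposed spin flip with probability `min(1, exp(-beta * dH))`:
#' always when the move lowers (or keeps) the energy, and with probability
#' `exp(-beta * dH)` otherwise, decided against the supplied uniform draw.
#'
#' @param delta_H Energy change of the proposed flip.
#' @param beta Inverse temperature `1 / (k_B T)`, positive.
#' @param u A uniform draw on `[0, 1)` supplied by the caller.
#' @return `TRUE` if the flip is accepted.
#' @examples
#' metropolis_accept(-2, beta = 1, u = 0.99)   # TRUE: energy-lowering
#' metropolis_accept(log(2), beta = 1, u = 0.49)  # TRUE: u < 1/2
#' @export
metropolis_accept <- function(delta_H, beta, u) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
  delta_H <= 0 | u < exp(-beta * delta_H)
}

#' Run Monte Carlo sweeps of spin-flip dynamics
#'
#' Performs `n_mcs` Monte Carlo steps of nonconserved (Glauber) single
#' spin-flip dynamics with Metropolis acceptance. One MCS consists of `N`
#' attempted flips (N = number of sites), each at an independently,
#' uniformly chosen site; updates are sequential, so each attempt sees all
#' previously accepted flips. Randomness comes from R's RNG stream, so
#' `set.seed()` makes trajectories reproducible.
#'
#' @param spins A spin matrix.
#' @param kernel A [coupling_kernel()] with `r_c < L_s / 2`.
#' @param beta Inverse temperature (positive; use a large value for a deep
#'   quench limit).
#' @param n_mcs Number of Monte Carlo steps.
#' @return A list with `spins` (final lattice), `accepted` (integer vector of
#'   accepted flips per MCS), and `magnetization` (numeric vector of `m`
#'   after each MCS).
#' @export
mc_sweep <- function(spins, kernel, beta, n_mcs = 1L) {
  check_lattice(spins)
  check_kernel_fits(kernel, nrow(spins))
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0) {
    abort("`beta` must be a single nonnegative number.")
  }
  storage.mode(spins) <- "integer"
  run_mcs_cpp(spins, beta, as.integer(n_mcs), kernel$di, kernel$dj, kernel$w)
}

#' Quench configuration
#'
#' Bundles and validates the parameters of a quench experiment: an `L_s^2`
#' periodic lattice with coupling `J / r^n`, instantaneously cooled to
#' temperature `T` (units of `J/k_B`, `k_B = 1`) from a balanced random
#' initial state, evolved for `n_mcs` Monte Carlo steps, with lattice
#' snapshots recorded at `snapshot_times`. `n_runs` independent runs are
#' simulated for ensemble averaging; run `i` uses the derived seed
#' `seed + 1009 * (i - 1)` so runs are reproducible and independent of
#' evaluation order.
#'
#' @param L_s Even linear lattice size.
#' @param n Coupling decay exponent.
#' @param temp Quench temperature `T > 0` in units of `J/k_B`.
#' @param n_mcs Total Monte Carlo steps (defaults to the largest snapshot
#'   time).
#' @param snapshot_times Sorted integer MCS times at which snapshots are
#'   kept; time 0 is the initial state.
#' @param seed Master integer seed.
#' @param n_runs Number of independent runs (the study default is 10;
#'   scaled-down analyses typically use 5).
#' @param J Coupling strength.
#' @param cutoff Optional kernel cutoff override.
#' @return A list of class `quench_config`.
#' @export
quench_config <- function(L_s, n, temp, snapshot_times,
                          n_mcs = max(snapshot_times), seed = 1L,
                          n_runs = 10L, J = 1, cutoff = NULL) {
  snapshot_times <- sort(unique(as.integer(snapshot_times)))
  if (any(snapshot_times < 0)) abort("`snapshot_times` must be >= 0.")
  if (!is.numeric(temp) || temp <= 0) abort("`temp` must be positive.")
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  if (n_mcs < max(snapshot_times)) {
    abort("`snapshot_times` may not exceed `n_mcs`.")
  }
  structure(list(
    L_s = as.integer(L_s), n = n, J = J, temp = temp,
    n_mcs = as.integer(n_mcs), snapshot_times = snapshot_times,
    seed = as.integer(seed), n_runs = as.integer(n_runs), cutoff = cutoff
  ), class = "quench_config")
}

run_seed <- function(master, i) as.integer((master + 1009 * (i - 1)) %% 2^31)

#' Simulate an ensemble of quench trajectories
#'
#' Runs `n_runs` independent quenches described by a [quench_config()]. Each
#' run starts from a fresh balanced random lattice (exactly half up, half
#' down, magnetization 0) and evolves under spin-flip Metropolis dynamics at
#' inverse temperature `1 / temp`, recording lattice snapshots at the
#' scheduled MCS times together with per-MCS magnetization and acceptance
#' series.
#'
#' @param config A [quench_config()].
#' @return A list of class `quench_ensemble` with elements `config`,
#'   `kernel`, `snapshots` (list over runs; each a named list of spin
#'   matrices keyed by MCS time), and `series` (tibble with columns `run`,
#'   `t`, `m`, `accepted`).
#' @examples
#' cfg <- quench_config(32, n = 6, temp = 1, snapshot_times = c(0, 10),
#'                      seed = 1, n_runs = 2)
#' qe <- run_quench(cfg)
#' dplyr::glimpse(qe$series)
#' @export
run_quench <- function(config) {
  stopifnot(inherits(config, "quench_config"))
  kernel <- coupling_kernel(config$n, config$J, config$cutoff)
  check_kernel_fits(kernel, config$L_s)
  beta <- 1 / config$temp
  times <- config$snapshot_times

  runs <- purrr::map(seq_len(config$n_runs), function(i) {
    set.seed(run_seed(config$seed, i))
    spins <- lattice_fixture("balanced_random", config$L_s)
    snaps <- list()
    ms <- numeric(0)
    accs <- integer(0)
    if (0L %in% times) snaps[["0"]] <- spins
    t_now <- 0L
    horizon <- max(config$n_mcs, times)
    stops <- sort(unique(c(times[times > 0L], horizon)))
    for (t_next in stops) {
      res <- mc_sweep(spins, kernel, beta, t_next - t_now)
      spins <- res$spins
      ms <- c(ms, res$magnetization)
      accs <- c(accs, res$accepted)
      t_now <- t_next
      if (t_next %in% times) snaps[[as.character(t_next)]] <- spins
    }
    list(snapshots = snaps, m = ms, accepted = accs)
  })

  series <- purrr::map_dfr(seq_along(runs), function(i) {
    tibble(
      run = i, t = seq_along(runs[[i]]$m),
      m = runs[[i]]$m, accepted = runs[[i]]$accepted
    )
  })
  structure(list(
    config = config, kernel = kernel,
    snapshots = purrr::map(runs, "snapshots"),
    series = series
  ), class = "quench_ensemble")
}

#' Extract the snapshot ensemble at one time
#'
#' @param ensemble A [run_quench()] result.
#' @param t Snapshot MCS time present in the schedule.
#' @return List of spin matrices, one per run.
#' @export
snapshot_ensemble <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "quench_ensemble"))
  key <- as.character(t)
  out <- purrr::map(ensemble$snapshots, key)
  if (any(vapply(out, is.null, TRUE))) {
    abort(sprintf("No snapshot recorded at t = %s.", key))
  }
  out
}

#' @export
print.quench_ensemble <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<quench_ensemble> L_s = %d, n = %g, T = %g, %d runs, %d MCS; snapshots at %s\n",
    cfg$L_s, cfg$n, cfg$temp, cfg$n_runs, cfg$n_mcs,
    paste(cfg$snapshot_times, collapse = ", ")
  ))
  invisible(x)
}
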