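test_that("quench experiments are deterministic end to end", {
  cfg <- quench_config(32, 6, 1, snapshot_times = c(10, 20, 30, 40),
                       seed = 3, n_runs = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  e1 <- experiment_quench(cfg, out_dir = d1)
  e2 <- experiment_quench(cfg, out_dir = d2)
  expect_identical(e1$growth$L, e2$growth$L)
  expect_identical(e1$fit$phi, e2$fit$phi)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("experiment artifacts carry provenance metadata", {
  cfg <- quench_config(32, 6, 1, snapshot_times = c(10, 20), seed = 5,
                       n_runs = 2)
  d <- withr::local_tempdir()
  experiment_quench(cfg, out_dir = d)
  files <- list.files(d)
  expect_true(all(c("corr_t10.csv", "sfac_t20.csv", "growth.csv",
                    "series.csv") %in% files))
  growth <- read_table_csv(file.path(d, "growth.csv"))
  meta <- attr(growth, "meta")
  expect_equal(meta$seed, 5)
  expect_equal(meta$L_s, 32)
  expect_match(meta$package, "spinquench")
  # snapshots of the final time are written per run
  snap <- read_snapshot(file.path(d, "snapshot_run1_t20.txt"))
  expect_identical(dim(snap), c(32L, 32L))
})

test_that("the n = 12 sweep locates T_c near the nearest-neighbour value", {
  # the n = 12 kernel is nearest-neighbour dominated (diagonal weight 1/64),
  # so the exact square-lattice value 2/ln(1 + sqrt 2) = 2.269 anchors it
  sw <- experiment_sweep(12, 64, temps = seq(1.5, 3.3, by = 0.15),
                         mcs_per_temp = 600, seed = 1)
  expect_lt(abs(sw$T_c - 2.269) / 2.269, 0.15)
  curve <- sw$curve
  # sigmoid-like drop: ordered at the cold end, near-zero at the hot end
  expect_gt(curve$m_abs[1], 0.9)
  expect_lt(curve$m_abs[nrow(curve)], 0.15)
})

test_that("empirical T_c decreases with the interaction exponent", {
  grids <- list(`2` = seq(4, 20, 1), `3` = seq(2, 9, 0.5),
                `6` = seq(1.5, 4.5, 0.25))
  tcs <- vapply(c(2, 3, 6), function(n) {
    temperature_sweep(n, 48, temps = grids[[as.character(n)]],
                      mcs_per_temp = 500, seed = 1)$T_c
  }, 0)
  expect_true(all(diff(tcs) < 0))
})

test_that("near-critical quenches order weakly compared to deep quenches", {
  deep <- run_quench(quench_config(64, 6, 1, snapshot_times = 500,
                                   seed = 1, n_runs = 4))
  m_deep <- mean(abs(vapply(snapshot_ensemble(deep, 500), mean, 0)))
  near <- experiment_near_critical(6, 64, snapshot_times = 500,
                                   n_runs = 4, seed = 1)
  expect_lt(near$mean_abs_m, m_deep)
  expect_gt(m_deep, 0.7) # deep quench on a small box orders globally
  expect_lt(near$mean_abs_m, 0.65)
})

test_that("near-critical correlations decay over a longer range for n = 2", {
  # 5 runs so the ensemble mixes magnetization signs; with fewer runs an
  # all-same-sign draw cancels the long-range plateau of the connected C
  sweep_args <- list(L_s = 64L, mcs_per_temp = 400)
  e2 <- experiment_near_critical(2, 256, snapshot_times = 500, n_runs = 5,
                                 seed = 1, sweep_args = sweep_args)
  e6 <- experiment_near_critical(6, 256, snapshot_times = 500, n_runs = 5,
                                 seed = 1, sweep_args = sweep_args)
  r2 <- decay_range(e2$correlations[["500"]])
  r6 <- decay_range(e6$correlations[["500"]])
  expect_gt(r2, r6)
  expect_lt(r6, 64) # short-range correlations stay well inside the box
})

test_that("theory experiment tabulates the closed forms over a grid", {
  d <- withr::local_tempdir()
  tab <- experiment_theory(c(3, 4, 6), N = c(1e2, 1e4, Inf), out_dir = d)
  expect_equal(tab$T_c[tab$n == 6 & is.infinite(tab$N)], 0.5)
  # marginal case grows as ln(N)/2
  t4 <- tab[tab$n == 4 & is.finite(tab$N), ]
  expect_equal(t4$T_c, log(t4$N) / 2)
  # n = 3 grows as sqrt(N)
  t3 <- tab[tab$n == 3 & is.finite(tab$N), ]
  expect_equal(t3$T_c[t3$N == 1e4] / t3$T_c[t3$N == 1e2], 10)
  expect_true(file.exists(file.path(d, "theory.csv")))
})

test_that("the reference configuration mirrors the study protocol", {
  cfg <- reference_quench_config(6)
  expect_identical(cfg$L_s, 512L)
  expect_identical(cfg$n_runs, 10L)
  expect_equal(cfg$temp, 1)
  expect_true(all(c(100, 200, 500) %in% cfg$snapshot_times))
})

test_that("the command-line driver runs the theory and analyze subcommands", {
  cli <- system.file("cli", "spinquench.R", package = "spinquench")
  expect_true(nzchar(cli))
  d <- withr::local_tempdir()

  out <- system2("Rscript", c(cli, "theory", "--n", "3,6", "--N", "1e4,Inf",
                              "--out", d), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(d, "theory.csv")))
  tab <- read_table_csv(file.path(d, "theory.csv"))
  expect_equal(tab$T_c[tab$n == 6 & is.infinite(tab$N)], 0.5)

  # standalone analysis of snapshot files
  s1 <- lattice_fixture("balanced_random", 32, seed = 1)
  s2 <- lattice_fixture("balanced_random", 32, seed = 2)
  f1 <- file.path(d, "s1.txt"); f2 <- file.path(d, "s2.txt")
  write_snapshot(s1, f1); write_snapshot(s2, f2)
  adir <- file.path(d, "analyzed")
  system2("Rscript", c(cli, "analyze", f1, f2, "--out", adir),
          stdout = TRUE, stderr = TRUE)
  corr <- read_table_csv(file.path(adir, "corr.csv"))
  expect_equal(corr$C[corr$r == 0], 1)
  expect_true(file.exists(file.path(adir, "sfac.csv")))
})
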