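# Deep-quench ensembles shared across test blocks, built once per session.
.ens_cache <- new.env(parent = emptyenv())

deep_quench <- function(n, L_s, times, n_runs = 5L, seed = 42L, temp = 1) {
  key <- paste("q", n, L_s, paste(times, collapse = "."), n_runs, seed, temp,
               sep = "_")
  if (is.null(.ens_cache[[key]])) {
    cfg <- quench_config(L_s, n, temp, snapshot_times = times,
                         seed = seed, n_runs = n_runs)
    .ens_cache[[key]] <- run_quench(cfg)
  }
  .ens_cache[[key]]
}

corr_at <- function(ensemble, t) {
  correlation_function(snapshot_ensemble(ensemble, t), t = t)
}
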