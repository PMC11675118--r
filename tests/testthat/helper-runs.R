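# Shared heavy simulation runs for the acceptance-level tests: computed
# lazily once per test session and reused across test blocks (the crowded
# c = 0.28, d = 0.70 ensemble feeds both the trapped-fraction and the
# position-autocorrelation checks).

.run_cache <- new.env(parent = emptyenv())

crowded_ensemble <- function() {
  if (is.null(.run_cache$crowded)) {
    trajs <- lapply(1:4, function(k) {
      st <- initialize_system(64, c = 0.28, d = 0.70, seed = 52400 + k)
      set.seed(62400 + k)
      run_trajectory(st, 3e5)
    })
    .run_cache$crowded <- trajs
  }
  .run_cache$crowded
}

free_dimer_ensemble <- function() {
  if (is.null(.run_cache$free)) {
    trajs <- lapply(1:8, function(k) {
      st <- initialize_system(64, c = 0, d = 0.5, seed = 73100 + k)
      set.seed(83100 + k)
      run_trajectory(st, 1e5)
    })
    .run_cache$free <- trajs
  }
  .run_cache$free
}
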