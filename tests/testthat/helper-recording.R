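# Build a synthetic recording with known ground truth for recovery tests.
make_test_recording <- function(n = 2000, sigma = 150, seed = 1,
                                cell_args = list()) {
  cell <- do.call(make_cell, c(list(seed = seed), cell_args))
  n_el <- nrow(cell$array$positions)
  ens <- sample_white_noise(n, n_el, sigma, mask = cell$array$mask,
                            seed = seed + 1000L)
  rec <- simulate_responses(cell, ens, seed = seed + 2000L)
  list(cell = cell, ens = ens, rec = rec,
       ste = spike_triggered_ensemble(ens, rec$responses))
}

cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
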