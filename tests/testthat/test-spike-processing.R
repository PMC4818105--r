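
# Construct a 25 kHz trace with triangular spikes and rectangular artefact
# pulses at the stimulus onsets.
build_trace <- function(spike_ms, onset_ms, duration_ms = 50,
                        rate = 25000, baseline = -60, spike_amp = 20,
                        artefact_amp = 60, blank_ms = 2) {
  n <- round(duration_ms / 1000 * rate)
  v <- rep(baseline, n)
  half <- 10  # samples on each flank of a spike
  for (t in spike_ms) {
    pk <- round(t / 1000 * rate) + 1
    idx <- (pk - half):(pk + half)
    # triangular waveform rising from baseline to a peak at +spike_amp mV
    v[idx] <- baseline + (spike_amp - baseline) *
      (1 - abs(seq(-half, half)) / half)
  }
  for (t in onset_ms) {
    # the amplifier artefact develops a couple of samples after the
    # stimulus onset, so the blank-start sample still sits at baseline
    i0 <- round(t / 1000 * rate) + 3
    v[i0:(i0 + round(blank_ms / 2000 * rate))] <- artefact_amp
  }
  membrane_trace(v, rate, stimulus_onsets = onset_ms / 1000,
                 blank_duration = blank_ms / 1000)
}

test_that("spike detection blanks artefacts and finds inserted peaks", {
  flat <- membrane_trace(rep(-60, 1000), 25000)
  expect_length(detect_spikes(flat, 0), 0)

  tr <- build_trace(spike_ms = c(10, 20, 30), onset_ms = c(5, 15, 25))
  spikes <- detect_spikes(tr, 0)
  expect_length(spikes, 3)
  expect_equal(as.numeric(spikes) * 1000, c(10, 20, 30),
               tolerance = 1 / 25)  # within one sample

  # artefacts only: blanking removes them for any threshold above baseline
  tr2 <- build_trace(spike_ms = numeric(0), onset_ms = c(5, 15, 25))
  expect_length(detect_spikes(tr2, 0), 0)
})

test_that("a supra-threshold plateau yields one spike at its first sample", {
  v <- rep(-60, 200)
  v[100:104] <- 10
  tr <- membrane_trace(v, 25000)
  spikes <- detect_spikes(tr, 0)
  expect_length(spikes, 1)
  expect_equal(as.numeric(spikes), 99 / 25000)
})

test_that("latencies attach each spike to the preceding offset", {
  res <- compute_latencies(c(0.002, 0.1019), c(0, 0.1))
  expect_equal(res$latencies[[1]], 2.0)
  expect_equal(res$latencies[[2]], 1.9)
  expect_equal(res$n_dropped, 0)

  # boundary: a spike exactly at an offset has latency 0 at that offset
  res2 <- compute_latencies(c(0.1), c(0, 0.1))
  expect_equal(res2$latencies[[2]], 0)

  # spikes before the first offset are dropped and counted
  res3 <- compute_latencies(c(-0.01, 0.05), c(0, 0.1))
  expect_equal(res3$n_dropped, 1)
})

test_that("latency assignment matches a brute-force all-pairs oracle", {
  withr::with_seed(99, {
    offsets <- sort(runif(50, 0, 10))
    spikes <- sort(runif(1000, 0, 10.5))
  })
  res <- compute_latencies(spikes, offsets)
  oracle <- lapply(seq_along(offsets), function(j) numeric(0))
  dropped <- 0
  for (s in spikes) {
    elig <- which(offsets <= s)
    if (length(elig) == 0) { dropped <- dropped + 1; next }
    j <- max(elig)
    oracle[[j]] <- c(oracle[[j]], (s - offsets[j]) * 1000)
  }
  expect_equal(res$latencies, oracle)
  expect_equal(res$n_dropped, dropped)
})

test_that("latency clustering separates short and long modes", {
  lat <- withr::with_seed(11, c(rnorm(500, 1.95, 0.3), rnorm(500, 12, 2)))
  lat <- abs(lat)
  cl <- cluster_latencies(lat, k = 2)
  expect_equal(cl$k, 2)
  expect_lt(abs(cl$means[1] - 1.95), 0.15)
  expect_lt(abs(cl$means[2] - 12), 0.5)
  truth <- rep(1:2, each = 500)
  expect_lt(mean(cl$assignments != truth), 0.01)
  # window = shortest-cluster mean +/- 2 SD
  expect_equal(cl$short_window,
               c(max(0, cl$means[1] - 2 * cl$sds[1]),
                 cl$means[1] + 2 * cl$sds[1]))
})

test_that("degenerate and exact clusterings are handled", {
  cl1 <- cluster_latencies(rep(2.5, 20), k = 1)
  expect_equal(cl1$means, 2.5)
  expect_equal(cl1$sds, 0)
  expect_equal(cl1$short_window, c(2.5, 2.5))

  cl2 <- cluster_latencies(c(1, 1, 1, 10, 10, 10), k = 2, fallback = FALSE)
  expect_equal(cl2$means, c(1, 10))
  expect_equal(cl2$assignments, rep(1:2, each = 3))

  expect_error(kmeans_1d(c(1, 1, 1), 2), "degenerate")
})

test_that("clustering is invariant to input order", {
  lat <- withr::with_seed(12, c(rnorm(200, 2, 0.3), rnorm(200, 11, 2)))
  lat <- abs(lat)
  cl_a <- cluster_latencies(lat, k = 2)
  cl_b <- cluster_latencies(withr::with_seed(13, sample(lat)), k = 2)
  expect_equal(cl_a$means, cl_b$means, tolerance = 1e-8)
  expect_equal(cl_a$short_window, cl_b$short_window, tolerance = 1e-8)
})

test_that("response labelling applies the latency windows", {
  cl <- structure(list(k = 2L, means = c(1.95, 8), sds = c(0.525, 1),
                       n_sd = 2, assignments = integer(0),
                       short_window = c(0.9, 3.0), silhouette = NA),
                  class = "latency_clusters")
  rv <- label_responses(list(c(1.8), c(7.9), c(1.8, 7.9), numeric(0)), cl)
  expect_equal(rv$short, c(1L, 0L, 1L, 0L))
  expect_equal(rv$long, c(0L, 1L, 1L, 0L))

  # duplicate latencies do not change the label (idempotence)
  rv2 <- label_responses(list(c(1.8, 1.8, 1.8)), cl)
  expect_equal(rv2$short, 1L)

  cl1 <- cluster_latencies(c(1, 2, 1.5, 2.5), k = 1)
  expect_error(label_responses(list(1.5), cl1, long = TRUE),
               "not available")
})
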