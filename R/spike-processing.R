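#' Membrane-potential trace
#'
#' Container for an intracellular voltage recording with the stimulus timing
#' needed for artefact blanking.
#'
#' @param samples voltage samples in mV.
#' @param sample_rate sampling rate in Hz (default 25000).
#' @param stimulus_onsets stimulus onset times in seconds, strictly
#'   increasing.
#' @param blank_duration duration in seconds for which the trace is replaced
#'   by a constant after each onset (artefact blanking).
#' @return an object of class `membrane_trace`.
#' @export
membrane_trace <- function(samples, sample_rate = 25000,
                           stimulus_onsets = numeric(0),
                           blank_duration = 0) {
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  if (blank_duration < 0) stop("blank_duration must be >= 0", call. = FALSE)
  if (is.unsorted(stimulus_onsets, strictly = TRUE)) {
    stop("stimulus onsets must be strictly increasing", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 stimulus_onsets = stimulus_onsets,
                 blank_duration = blank_duration),
            class = "membrane_trace")
}

#' Detect spikes in a blanked membrane trace
#'
#' Stimulation artefacts are removed by setting the trace to a constant value
#' (the sample at the start of each blank window) for `blank_duration` after
#' each stimulus onset. Spikes are then detected as local maxima of the
#' blanked trace crossing `threshold`: one spike per contiguous
#' supra-threshold excursion, timed at the peak sample (first sample of the
#' maximal run if the peak is a plateau).
#'
#' @param trace a [membrane_trace()].
#' @param threshold detection threshold in mV.
#' @return numeric vector of spike times in seconds (class `spike_train`).
#' @export
detect_spikes <- function(trace, threshold) {
  stopifnot(inherits(trace, "membrane_trace"))
  v <- trace$samples
  n <- length(v)
  if (trace$blank_duration > 0) {
    for (on in trace$stimulus_onsets) {
      i0 <- max(1L, floor(on * trace$sample_rate) + 1L)
      i1 <- min(n, floor((on + trace$blank_duration) * trace$sample_rate) + 1L)
      if (i0 <= n) v[i0:i1] <- v[i0]
    }
  }
  above <- v > threshold
  if (!any(above)) return(structure(numeric(0), class = "spike_train"))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  peaks <- vapply(seq_along(starts), function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(v[seg])]  # which.max: first sample of a maximal plateau
  }, integer(1))
  times <- (peaks - 1) / trace$sample_rate
  duration <- n / trace$sample_rate
  if (length(times) / duration > 200) {
    warning("spike rate exceeds 200 Hz; threshold may be below baseline",
            call. = FALSE)
  }
  structure(times, class = "spike_train")
}

#' Spike latencies from stimulus offsets
#'
#' Assigns each spike to the latest stimulus offset at or before it and
#' returns the latency (spike time minus offset) in milliseconds, as one
#' list element per stimulus. Spikes occurring before the first offset are
#' dropped and counted.
#'
#' @param spike_times spike times in seconds.
#' @param stimulus_offsets stimulus offset times in seconds, strictly
#'   increasing (see [pulse_offsets()] when only onsets are recorded).
#' @return list with `latencies` (list of ms latencies per stimulus) and
#'   `n_dropped` (spikes before the first offset).
#' @export
compute_latencies <- function(spike_times, stimulus_offsets) {
  if (is.unsorted(stimulus_offsets, strictly = TRUE)) {
    stop("stimulus offsets must be strictly increasing", call. = FALSE)
  }
  spike_times <- sort(as.numeric(spike_times))
  idx <- findInterval(spike_times, stimulus_offsets)
  n_dropped <- sum(idx == 0L)
  keep <- idx > 0L
  lat_ms <- (spike_times[keep] - stimulus_offsets[idx[keep]]) * 1000
  out <- vector("list", length(stimulus_offsets))
  for (j in seq_along(out)) out[[j]] <- numeric(0)
  if (any(keep)) {
    sp <- split(lat_ms, idx[keep])
    out[as.integer(names(sp))] <- sp
  }
  list(latencies = out, n_dropped = n_dropped)
}

#' Cluster spike latencies
#'
#' 1-D k-means on spike latencies (multiple restarts under a fixed seed),
#' used to separate short-latency (direct, electrically evoked) from
#' long-latency (network-mediated) responses. Clusters are relabelled by
#' ascending mean and the short-latency acceptance window is the shortest
#' cluster's mean +/- `n_sd` standard deviations, clamped at 0.
#'
#' By default `k = 2` with an automatic fallback to `k = 1` when the mean
#' silhouette width of the 2-cluster solution is below 0.5 (a heuristic for
#' recordings with no long-latency component; disable with
#' `fallback = FALSE` or force `k` directly).
#'
#' @param latencies spike latencies in ms.
#' @param k number of clusters (default 2).
#' @param n_sd half-width of the latency windows in SDs (default 2).
#' @param fallback drop to k = 1 when the k = 2 silhouette is weak.
#' @param seed,n_restarts k-means seeding controls.
#' @return an object of class `latency_clusters` with `k`, `means`, `sds`,
#'   `assignments`, `short_window`, `silhouette`.
#' @export
cluster_latencies <- function(latencies, k = 2L, n_sd = 2, fallback = TRUE,
                              seed = 1L, n_restarts = 10L) {
  latencies <- as.numeric(latencies)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1 || length(unique(latencies)) == 1) {
    m <- mean(latencies)
    s <- if (length(latencies) > 1 && length(unique(latencies)) > 1)
      stats::sd(latencies) else 0
    fit <- list(k = 1L, means = m, sds = s,
                assignments = rep(1L, length(latencies)))
    sil <- NA_real_
  } else {
    fit <- kmeans_1d(latencies, k, seed = seed, n_restarts = n_restarts)
    sil <- silhouette_1d(latencies, fit$assignments)
    if (fallback && k == 2 && is.finite(sil) && sil < 0.5) {
      return(cluster_latencies(latencies, k = 1L, n_sd = n_sd, seed = seed))
    }
  }
  win <- c(max(0, fit$means[1] - n_sd * fit$sds[1]),
           fit$means[1] + n_sd * fit$sds[1])
  structure(list(k = fit$k, means = fit$means, sds = fit$sds,
                 assignments = fit$assignments, n_sd = n_sd,
                 short_window = win, silhouette = sil),
            class = "latency_clusters")
}

#' @export
print.latency_clusters <- function(x, ...) {
  cat(sprintf("Latency clusters (k = %d)\n", x$k))
  for (j in seq_len(x$k)) {
    cat(sprintf("  cluster %d: %.2f ms (SD %.2f), n = %d\n", j, x$means[j],
                x$sds[j], sum(x$assignments == j)))
  }
  cat(sprintf("  short-latency window: [%.2f, %.2f] ms\n",
              x$short_window[1], x$short_window[2]))
  invisible(x)
}

#' Label presentations with short- and long-latency responses
#'
#' A presentation is labelled `short = 1` when any of its spike latencies
#' falls within the short-latency window (shortest cluster mean +/- 2 SD) and
#' `long = 1` when any latency falls within the second cluster's mean +/- 2
#' SD. With overlapping clusters both labels can be 1 for the same
#' presentation; this is reported, not resolved.
#'
#' @param latency_lists list of per-presentation latency vectors (ms).
#' @param clusters a [cluster_latencies()] result.
#' @param long compute long-latency labels (requires `k >= 2`).
#' @return an object of class `response_vector` with binary `short`,
#'   optional binary `long`, and the input `latencies`.
#' @export
label_responses <- function(latency_lists, clusters, long = clusters$k >= 2) {
  stopifnot(inherits(clusters, "latency_clusters"))
  if (long && clusters$k < 2) {
    stop("long-latency labels not available: only one latency cluster",
         call. = FALSE)
  }
  win_s <- clusters$short_window
  short <- vapply(latency_lists, function(l) {
    as.integer(any(l >= win_s[1] & l <= win_s[2]))
  }, integer(1))
  long_lab <- NULL
  if (long) {
    win_l <- c(clusters$means[2] - clusters$n_sd * clusters$sds[2],
               clusters$means[2] + clusters$n_sd * clusters$sds[2])
    long_lab <- vapply(latency_lists, function(l) {
      as.integer(any(l >= win_l[1] & l <= win_l[2]))
    }, integer(1))
  }
  response_vector(short, long_lab, latency_lists)
}

#' Per-presentation response labels
#'
#' @param short binary short-latency response per presentation.
#' @param long optional binary long-latency response per presentation.
#' @param latencies optional list of per-presentation latencies (ms).
#' @return an object of class `response_vector`.
#' @export
response_vector <- function(short, long = NULL, latencies = NULL) {
  short <- as.integer(short)
  if (!all(short %in% c(0L, 1L))) {
    stop("short responses must be binary", call. = FALSE)
  }
  if (!is.null(long)) {
    long <- as.integer(long)
    if (length(long) != length(short) || !all(long %in% c(0L, 1L))) {
      stop("long responses must be binary and match length", call. = FALSE)
    }
  }
  if (!is.null(latencies) && length(latencies) != length(short)) {
    stop("latency list length must match number of presentations",
         call. = FALSE)
  }
  structure(list(short = short, long = long, latencies = latencies),
            class = "response_vector")
}

#' @export
print.response_vector <- function(x, ...) {
  cat(sprintf("Response vector: %d presentations, %d short-latency responses",
              length(x$short), sum(x$short)))
  if (!is.null(x$long)) cat(sprintf(", %d long-latency", sum(x$long)))
  cat("\n")
  invisible(x)
}
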