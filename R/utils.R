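# Internal helpers shared across modules.

# Run code under a temporary RNG seed; NULL seed leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

clip01 <- function(x) pmin(1, pmax(0, x))

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / nv
}

# Extract the amplitude matrix from a stim_ensemble or pass a matrix through.
amplitude_matrix <- function(x) {
  if (inherits(x, "stim_ensemble")) return(x$amplitudes)
  if (inherits(x, "ste")) return(x$S_T)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop("expected a stim_ensemble, matrix or data.frame of amplitudes",
       call. = FALSE)
}

# 1-D k-means with deterministic seeding, clusters relabelled by ascending
# mean. Shared by latency clustering and stratum detection.
kmeans_1d <- function(x, k, seed = 1L, n_restarts = 10L) {
  if (length(unique(x)) < k) {
    stop("degenerate clustering: fewer than k = ", k, " distinct values",
         call. = FALSE)
  }
  fit <- with_seed(seed, stats::kmeans(x, centers = k, nstart = n_restarts))
  ord <- order(fit$centers[, 1])
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[fit$cluster]
  means <- as.numeric(fit$centers[ord, 1])
  sds <- vapply(seq_len(k), function(j) {
    xs <- x[assignments == j]
    if (length(xs) > 1) stats::sd(xs) else 0
  }, numeric(1))
  list(k = k, means = means, sds = sds, assignments = assignments)
}

# Mean silhouette width of a 1-D clustering (used for the k = 2 -> k = 1
# fallback heuristic).
silhouette_1d <- function(x, assignments) {
  if (length(unique(assignments)) < 2) return(NA_real_)
  sil <- cluster::silhouette(assignments, stats::dist(x))
  mean(sil[, "sil_width"])
}
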