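# Dendritic stratification depth within the inner plexiform layer (IPL)
# and the ON / OFF / ON-OFF classification rule.

#' Stratification depth as a percentage of the IPL
#'
#' `s(x) = 100 (L_s - x) / (L_s - L_e)`, where `x` is the instrument-frame
#' depth of a terminal dendrite, `L_s` the IPL-GCL border and `L_e` the
#' INL-side border. `s = 0` at the ganglion-cell-layer border and 100 at
#' the inner-nuclear-layer border; the formula is invariant to shifting
#' all three depths by a constant.
#'
#' @param terminal_depths depths of terminal dendrites (um, instrument
#'   frame).
#' @param L_s depth of the IPL-GCL border (um).
#' @param L_e depth of the INL-side border (um).
#' @return percentage depths.
#' @export
stratification_depth <- function(terminal_depths, L_s, L_e) {
  if (L_s == L_e) {
    stop("division error: IPL borders coincide (L_s == L_e)", call. = FALSE)
  }
  100 * (L_s - terminal_depths) / (L_s - L_e)
}

#' Classify a cell as ON, OFF or ON-OFF from stratification depths
#'
#' Detects one or two dendritic strata in the depth distribution (1-D
#' k-means with k chosen by silhouette, mirroring the latency-cluster
#' heuristic) and classifies by stratum means: OFF when all strata lie at
#' <= 40 percent, ON when all lie at >= 60 percent, ON-OFF when distinct
#' strata fall in both bands, otherwise unclassified.
#'
#' @param depths percentage depths from [stratification_depth()].
#' @param k number of strata; `NULL` (default) chooses 1 or 2
#'   automatically.
#' @param seed k-means seed.
#' @return list with `class` (one of `"ON"`, `"OFF"`, `"ON-OFF"`,
#'   `"unclassified"`), `stratum_means` and `assignments`.
#' @export
classify_cell <- function(depths, k = NULL, seed = 1L) {
  depths <- as.numeric(depths)
  if (length(depths) == 0) stop("depths must be nonempty", call. = FALSE)
  if (is.null(k)) {
    k <- 1L
    if (length(unique(depths)) >= 2) {
      two <- kmeans_1d(depths, 2L, seed = seed)
      sil <- silhouette_1d(depths, two$assignments)
      if (is.finite(sil) && sil >= 0.5) k <- 2L
    }
  }
  if (k == 1L || length(unique(depths)) < 2) {
    means <- mean(depths)
    assignments <- rep(1L, length(depths))
  } else {
    fit <- kmeans_1d(depths, k, seed = seed)
    means <- fit$means
    assignments <- fit$assignments
  }
  cls <- if (all(means <= 40)) {
    "OFF"
  } else if (all(means >= 60)) {
    "ON"
  } else if (any(means <= 40) && any(means >= 60)) {
    "ON-OFF"
  } else {
    "unclassified"
  }
  list(class = cls, stratum_means = means, assignments = assignments)
}
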