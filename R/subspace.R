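#' Spike-triggered ensemble
#'
#' Pairs the full stimulus matrix with the binary response vector; the
#' spike-triggered subset (rows with a response) is derived on demand.
#'
#' @param stimuli a [sample_white_noise()] ensemble or a presentations x
#'   electrodes amplitude matrix (microamperes).
#' @param response binary response per presentation (a vector or a
#'   [response_vector()], whose `short` labels are used).
#' @param mask logical vector of operational electrodes; taken from the
#'   ensemble when available.
#' @param stim_id optional distinct-stimulus index per presentation (used by
#'   [split_data()] to keep repeats together); taken from the ensemble when
#'   available.
#' @return an object of class `ste` with fields `S_T`, `response`, `mask`,
#'   `stim_id`.
#' @export
spike_triggered_ensemble <- function(stimuli, response, mask = NULL,
                                     stim_id = NULL) {
  S <- amplitude_matrix(stimuli)
  if (inherits(response, "response_vector")) response <- response$short
  response <- as.integer(response)
  if (length(response) != nrow(S)) {
    stop("response length (", length(response),
         ") must equal number of presentations (", nrow(S), ")",
         call. = FALSE)
  }
  if (!all(response %in% c(0L, 1L))) {
    stop("response must be binary", call. = FALSE)
  }
  if (is.null(mask) && inherits(stimuli, "stim_ensemble")) mask <- stimuli$mask
  if (is.null(mask)) mask <- rep(TRUE, ncol(S))
  if (is.null(stim_id) && inherits(stimuli, "stim_ensemble")) {
    stim_id <- stimuli$stim_id
  }
  if (is.null(stim_id)) stim_id <- seq_len(nrow(S))
  structure(list(S_T = S, response = response, mask = mask,
                 stim_id = stim_id),
            class = "ste")
}

#' @export
print.ste <- function(x, ...) {
  cat(sprintf("Spike-triggered ensemble: %d presentations, %d spikes, %d/%d electrodes operational\n",
              nrow(x$S_T), sum(x$response), sum(x$mask), length(x$mask)))
  invisible(x)
}

# Spike-eliciting subset restricted to operational electrodes.
spike_subset <- function(ens) {
  ens$S_T[ens$response == 1L, ens$mask, drop = FALSE]
}

#' Spike-triggered covariance eigenspectrum
#'
#' Computes the covariance (unbiased, n - 1 denominator) of the
#' spike-eliciting stimuli about their own mean, restricted to operational
#' electrodes, and its eigendecomposition. Because the raw ensemble is white
#' with variance ~ sigma^2 in every direction, eigenvalues well above
#' (below) sigma^2 mark stimulus-space directions along which spiking
#' increased (suppressed) the stimulus variance.
#'
#' @param ens a [spike_triggered_ensemble()].
#' @return an object of class `eigen_spectrum` with descending `eigenvalues`
#'   (uA^2), orthonormal `eigenvectors` (columns, in the operational
#'   subspace), `eigenvectors_full` (masked electrodes re-inserted as
#'   zeros), `sigma2` (mean per-electrode variance of the raw ensemble) and
#'   `normalized` (eigenvalues / sigma2).
#' @export
spike_triggered_cov <- function(ens) {
  stopifnot(inherits(ens, "ste"))
  SD <- spike_subset(ens)
  if (nrow(SD) < 2) {
    stop("insufficient spikes: need >= 2 spike-eliciting stimuli",
         call. = FALSE)
  }
  if (ncol(SD) < 2) {
    stop("need >= 2 operational electrodes", call. = FALSE)
  }
  Cs <- stats::cov(SD)
  eg <- eigen(Cs, symmetric = TRUE)
  ST <- ens$S_T[, ens$mask, drop = FALSE]
  sigma2 <- mean(apply(ST, 2, stats::var))
  full <- matrix(0, length(ens$mask), ncol(SD))
  full[ens$mask, ] <- eg$vectors
  structure(list(eigenvalues = eg$values, eigenvectors = eg$vectors,
                 eigenvectors_full = full, sigma2 = sigma2,
                 normalized = eg$values / sigma2, mask = ens$mask),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("Spike-triggered covariance spectrum (%d components)\n",
              length(x$eigenvalues)))
  cat("  normalized eigenvalues:",
      paste(signif(x$normalized, 3), collapse = " "), "\n")
  invisible(x)
}

# Fix an eigenvector's sign so its largest-magnitude component is positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# Extreme eigenvalues (and optionally first eigenvectors) of the
# spike-triggered covariance under circular shifts of the response vector.
shift_null <- function(S, spike_pos, n, offsets, keep_vectors = FALSE) {
  m <- length(offsets)
  p <- ncol(S)
  null_max <- null_min <- numeric(m)
  eig_sum <- 0
  v1 <- if (keep_vectors) matrix(0, p, m) else NULL
  for (j in seq_len(m)) {
    idx <- ((spike_pos + offsets[j] - 1L) %% n) + 1L
    eg <- eigen(stats::cov(S[idx, , drop = FALSE]), symmetric = TRUE,
                only.values = !keep_vectors)
    null_max[j] <- eg$values[1]
    null_min[j] <- eg$values[p]
    eig_sum <- eig_sum + sum(eg$values)
    if (keep_vectors) v1[, j] <- fix_sign(eg$vectors[, 1])
  }
  list(max = null_max, min = null_min,
       mean_all = eig_sum / (m * p), v1 = v1)
}

#' Significant-subspace identification by a time-shift null
#'
#' Tests how many spike-triggered covariance eigenvalues differ from chance.
#' The null distribution is built by circularly shifting the binary response
#' vector relative to the stimulus sequence by a uniform random offset
#' (>= 1 presentation), which preserves both the spike count and the
#' stimulus statistics, and recording the largest and smallest eigenvalue of
#' each shuffled spike-triggered covariance. If the observed largest
#' (smallest) eigenvalue exceeds (falls below) the null mean
#' `+/- n_sd x SD` of the corresponding extreme, the axis is recorded as
#' excitatory (suppressive), the data are projected onto its orthogonal
#' complement, the null is regenerated on the deflated data, and the test
#' repeats until no extreme is outside its interval.
#'
#' The strength ratio `G = |e1 - e_rnd| / |e2 - e_rnd|` compares the two
#' eigenvalues most separated from the first iteration's null mean `e_rnd`;
#' `G >> 1` indicates an effectively one-dimensional cell (linear electrode
#' interactions).
#'
#' @param ens a [spike_triggered_ensemble()].
#' @param n_shuffles shuffles per iteration (default 1000, minimum 100).
#' @param n_sd half-width of the confidence interval in null SDs (default 2,
#'   approximately a 95 percent interval).
#' @param seed integer seed for the shuffle offsets.
#' @return an object of class `stc_significance`: `significant` (list of
#'   records with `axis` in full electrode space, `eigenvalue`, `label`),
#'   `n_excitatory`, `n_suppressive`, `G`, `null_mean` (`e_rnd`),
#'   `ci_low`/`ci_high` per iteration, `spectrum` (first-iteration
#'   [spike_triggered_cov()]), and first-iteration shuffle data
#'   (`null_offsets`, `null_v1`) consumed by [electrode_significance()].
#' @export
significance_test <- function(ens, n_shuffles = 1000L, n_sd = 2,
                              seed = NULL) {
  stopifnot(inherits(ens, "ste"))
  if (n_shuffles < 100) stop("n_shuffles must be >= 100", call. = FALSE)
  if (n_sd <= 0) stop("n_sd must be > 0", call. = FALSE)
  r <- ens$response
  n <- length(r)
  if (sum(r) == 0L || sum(r) == n) {
    stop("degenerate response: all-zero or all-one response vector",
         call. = FALSE)
  }
  spectrum <- spike_triggered_cov(ens)
  S0 <- ens$S_T[, ens$mask, drop = FALSE]
  spike_pos <- which(r == 1L)

  with_seed(seed, {
    S <- S0
    basis <- diag(ncol(S0))      # current subspace -> operational space
    significant <- list()
    ci_low <- ci_high <- numeric(0)
    first <- NULL
    repeat {
      p <- ncol(S)
      if (p < 1) break
      eo <- eigen(stats::cov(S[spike_pos, , drop = FALSE]), symmetric = TRUE)
      offsets <- sample.int(n - 1L, n_shuffles, replace = TRUE)
      nul <- shift_null(S, spike_pos, n, offsets,
                        keep_vectors = is.null(first))
      hi <- mean(nul$max) + n_sd * stats::sd(nul$max)
      lo <- mean(nul$min) - n_sd * stats::sd(nul$min)
      ci_high <- c(ci_high, hi)
      ci_low <- c(ci_low, lo)
      if (is.null(first)) {
        first <- list(values = eo$values, null_mean = nul$mean_all,
                      offsets = offsets, v1 = nul$v1)
      }
      exc_dev <- eo$values[1] - hi
      sup_dev <- lo - eo$values[p]
      if (exc_dev <= 0 && sup_dev <= 0) break
      pick <- if (exc_dev >= sup_dev) 1L else p
      label <- if (pick == 1L) "excitatory" else "suppressive"
      v <- eo$vectors[, pick]
      axis_op <- fix_sign(as.numeric(basis %*% v))
      axis_full <- numeric(length(ens$mask))
      axis_full[ens$mask] <- axis_op
      significant[[length(significant) + 1L]] <-
        list(axis = axis_full, eigenvalue = eo$values[pick], label = label)
      if (p == 1L) break
      # deflate: orthonormal complement of v within the current subspace
      Q <- qr.Q(qr(cbind(v, diag(p))))[, 2:p, drop = FALSE]
      S <- S %*% Q
      basis <- basis %*% Q
    }

    dev <- abs(first$values - first$null_mean)
    ord <- order(dev, decreasing = TRUE)
    G <- if (length(dev) >= 2 && dev[ord[2]] > 0) {
      dev[ord[1]] / dev[ord[2]]
    } else {
      Inf
    }
    labels <- vapply(significant, `[[`, character(1), "label")
    structure(
      list(significant = significant,
           n_excitatory = sum(labels == "excitatory"),
           n_suppressive = sum(labels == "suppressive"),
           G = G, null_mean = first$null_mean,
           e1 = first$values[ord[1]], e2 = first$values[ord[2]],
           ci_low = ci_low, ci_high = ci_high,
           n_shuffles = as.integer(n_shuffles), n_sd = n_sd, seed = seed,
           spectrum = spectrum,
           null_offsets = first$offsets, null_v1 = first$v1,
           mask = ens$mask),
      class = "stc_significance")
  })
}

#' @export
print.stc_significance <- function(x, ...) {
  cat(sprintf("STC significance test (%d shuffles, +/- %.1f SD)\n",
              x$n_shuffles, x$n_sd))
  cat(sprintf("  %d excitatory, %d suppressive significant component(s)\n",
              x$n_excitatory, x$n_suppressive))
  cat(sprintf("  strength ratio G = %.2f (null mean %.1f uA^2)\n",
              x$G, x$null_mean))
  invisible(x)
}

#' Strength ratio between the two most significant eigenvalues
#'
#' `G = |e1 - e_rnd| / |e2 - e_rnd|`: the separation of the dominant
#' eigenvalue from the shuffle-null mean relative to that of the next most
#' significant eigenvalue.
#'
#' @param e1,e2 the two eigenvalues most separated from the null mean.
#' @param e_rnd mean of the null eigenvalue distribution (first iteration).
#' @return the dimensionless ratio G.
#' @export
strength_ratio <- function(e1, e2, e_rnd) {
  abs(e1 - e_rnd) / abs(e2 - e_rnd)
}

#' Polarity-split electrical receptive fields
#'
#' Splits the spike-eliciting stimuli by the sign of their projection onto
#' the first principal axis `v1` into net anodic-first (positive projection;
#' zero projections count as positive) and net cathodic-first (negative)
#' subsets, and averages each subset. The two means are the polarity-resolved
#' analogues of the spike-triggered average: the positive and negative
#' electrical receptive fields `w+` and `w-`. Their Pearson correlation over
#' operational electrodes is near -1 when the same electrodes drive the cell
#' under both polarities. A side with no spike-eliciting stimuli (a cell
#' driven by one polarity only) is flagged absent.
#'
#' @param ens a [spike_triggered_ensemble()].
#' @param v1 first principal axis, full electrode length or operational
#'   subspace length; its sign is fixed so the largest-magnitude component
#'   is positive.
#' @return an object of class `erf_pair` with full-length `w_plus`,
#'   `w_minus` (zeros at masked electrodes), presence flags, counts, `v1`
#'   and `corr`.
#' @export
estimate_erfs <- function(ens, v1) {
  stopifnot(inherits(ens, "ste"))
  mask <- ens$mask
  if (length(v1) == length(mask)) {
    v1m <- v1[mask]
  } else if (length(v1) == sum(mask)) {
    v1m <- v1
  } else {
    stop("v1 length matches neither electrode count nor operational count",
         call. = FALSE)
  }
  v1m <- fix_sign(unit_vector(v1m))
  SD <- spike_subset(ens)
  if (nrow(SD) == 0) {
    stop("insufficient spikes: no spike-eliciting stimuli", call. = FALSE)
  }
  proj <- as.numeric(SD %*% v1m)
  plus <- proj >= 0
  n_el <- length(mask)
  w_plus <- w_minus <- numeric(n_el)
  has_plus <- any(plus)
  has_minus <- any(!plus)
  if (has_plus) w_plus[mask] <- colMeans(SD[plus, , drop = FALSE])
  if (has_minus) w_minus[mask] <- colMeans(SD[!plus, , drop = FALSE])
  corr <- if (has_plus && has_minus) {
    stats::cor(w_plus[mask], w_minus[mask])
  } else {
    NA_real_
  }
  v1_full <- numeric(n_el)
  v1_full[mask] <- v1m
  structure(list(w_plus = w_plus, w_minus = w_minus,
                 has_plus = has_plus, has_minus = has_minus,
                 n_plus = sum(plus), n_minus = sum(!plus),
                 corr = corr, v1 = v1_full, mask = mask,
                 sig_plus = NULL, sig_minus = NULL,
                 rms_bound_plus = NULL, rms_bound_minus = NULL,
                 D_plus = NA_real_, D_minus = NA_real_),
            class = "erf_pair")
}

#' @export
print.erf_pair <- function(x, ...) {
  cat("Electrical receptive field pair\n")
  if (x$has_plus) {
    cat(sprintf("  w+: %d spike-eliciting stimuli", x$n_plus))
    if (!is.null(x$sig_plus)) {
      cat(sprintf(", significant electrodes: %s",
                  paste(which(x$sig_plus), collapse = " ")))
    }
    cat("\n")
  } else cat("  w+: absent (no net anodic-first spikes)\n")
  if (x$has_minus) {
    cat(sprintf("  w-: %d spike-eliciting stimuli", x$n_minus))
    if (!is.null(x$sig_minus)) {
      cat(sprintf(", significant electrodes: %s",
                  paste(which(x$sig_minus), collapse = " ")))
    }
    cat("\n")
  } else cat("  w-: absent (no net cathodic-first spikes)\n")
  if (is.finite(x$corr)) cat(sprintf("  corr(w+, w-) = %.3f\n", x$corr))
  invisible(x)
}

#' Electrode significance by shuffle RMS bounds
#'
#' Recomputes `w+` and `w-` for each first-iteration shuffle of the
#' significance test, splitting that shuffle's spike-triggered stimuli on
#' its own first eigenvector, and takes the per-electrode root-mean-square
#' of the resulting null receptive fields as the significance bound. An
#' electrode is significant when its true weight exceeds the bound in
#' magnitude.
#'
#' @param ens a [spike_triggered_ensemble()].
#' @param sig a [significance_test()] result on the same ensemble.
#' @param erf an [estimate_erfs()] result to annotate.
#' @return the `erf_pair` with `rms_bound_plus`, `rms_bound_minus` and
#'   logical `sig_plus`, `sig_minus` filled in (FALSE at masked electrodes).
#' @export
electrode_significance <- function(ens, sig, erf) {
  stopifnot(inherits(ens, "ste"), inherits(sig, "stc_significance"),
            inherits(erf, "erf_pair"))
  S <- ens$S_T[, ens$mask, drop = FALSE]
  n <- nrow(S)
  spike_pos <- which(ens$response == 1L)
  m <- length(sig$null_offsets)
  p <- ncol(S)
  wp <- wm <- matrix(NA_real_, p, m)
  for (j in seq_len(m)) {
    idx <- ((spike_pos + sig$null_offsets[j] - 1L) %% n) + 1L
    Sd <- S[idx, , drop = FALSE]
    pr <- as.numeric(Sd %*% sig$null_v1[, j])
    pos <- pr >= 0
    if (any(pos)) wp[, j] <- colMeans(Sd[pos, , drop = FALSE])
    if (any(!pos)) wm[, j] <- colMeans(Sd[!pos, , drop = FALSE])
  }
  rms <- function(x) sqrt(rowMeans(x^2, na.rm = TRUE))
  n_el <- length(ens$mask)
  bound_p <- bound_m <- rep(NA_real_, n_el)
  bound_p[ens$mask] <- rms(wp)
  bound_m[ens$mask] <- rms(wm)
  sig_p <- sig_m <- rep(FALSE, n_el)
  if (erf$has_plus) sig_p[ens$mask] <- abs(erf$w_plus[ens$mask]) > bound_p[ens$mask]
  if (erf$has_minus) sig_m[ens$mask] <- abs(erf$w_minus[ens$mask]) > bound_m[ens$mask]
  erf$rms_bound_plus <- bound_p
  erf$rms_bound_minus <- bound_m
  erf$sig_plus <- sig_p
  erf$sig_minus <- sig_m
  erf
}

#' Weighted spatial extent of a receptive field
#'
#' Weighted mean of the cell-to-electrode distances, weighted by the
#' magnitude of each electrode's receptive-field weight. Absolute weights
#' are used so the extent is a nonnegative spatial spread even for the
#' signed cathodic field.
#'
#' @param weights receptive-field weights per electrode (uA).
#' @param distances cell-to-electrode distances (mm), same length, >= 0.
#' @return the extent in mm.
#' @export
erf_extent <- function(weights, distances) {
  if (length(weights) != length(distances)) {
    stop("weights and distances must have equal length", call. = FALSE)
  }
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  w <- abs(weights)
  if (sum(w) == 0) {
    stop("undefined extent: all weights are zero", call. = FALSE)
  }
  sum(w * distances) / sum(w)
}
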