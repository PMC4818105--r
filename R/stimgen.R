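#' Biphasic pulse parameters
#'
#' Carries the timing constants of the charge-balanced biphasic current
#' pulses. The model itself operates on per-pulse amplitude vectors only, so
#' these are metadata: the phase duration and interphase gap matter downstream
#' only for converting stimulus onset times to offset times (the reference
#' point for spike latencies).
#'
#' @param phase_duration duration of each phase in microseconds.
#' @param interphase_gap gap between the two phases in microseconds.
#' @param pulse_rate stimulation frequency in Hz.
#' @param amplitude_limit hardware compliance limit in microamperes; samples
#'   beyond +/- this value are rejected and redrawn.
#' @return an object of class `pulse_params`.
#' @export
pulse_params <- function(phase_duration = 500, interphase_gap = 50,
                         pulse_rate = 10, amplitude_limit = 300) {
  vals <- c(phase_duration = phase_duration, interphase_gap = interphase_gap,
            pulse_rate = pulse_rate, amplitude_limit = amplitude_limit)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all pulse parameters must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "pulse_params")
}

#' Stimulus offset times implied by pulse timing
#'
#' Spike latencies are measured from the stimulus *offset*; when only onsets
#' are recorded the offset is onset + 2 x phase duration + interphase gap.
#'
#' @param onsets stimulus onset times in seconds.
#' @param pulse a [pulse_params()] object.
#' @return offset times in seconds.
#' @export
pulse_offsets <- function(onsets, pulse = pulse_params()) {
  onsets + (2 * pulse$phase_duration + pulse$interphase_gap) * 1e-6
}

#' Sample a truncated-Gaussian white-noise stimulus ensemble
#'
#' Draws `n_stimuli` independent stimulus vectors, one signed current
#' amplitude per electrode (positive = anodic-first), from a zero-mean
#' Gaussian with standard deviation `sigma`. Amplitudes beyond `+/- limit`
#' are rejected and redrawn (not clipped), preserving the Gaussian shape of
#' the ensemble within the compliance limits, which the spike-triggered
#' covariance analysis relies on. Each distinct stimulus is repeated
#' `repeats` times consecutively in the presentation sequence; masked
#' (non-operational) electrodes carry amplitude 0.
#'
#' @param n_stimuli number of distinct stimulus vectors.
#' @param n_electrodes number of electrodes.
#' @param sigma Gaussian standard deviation in microamperes.
#' @param limit rejection bound in microamperes (default 300).
#' @param mask logical vector, `TRUE` for operational electrodes.
#' @param repeats presentations per distinct stimulus (>= 1).
#' @param seed integer seed; identical seeds give bit-identical ensembles.
#' @param pulse a [pulse_params()] object.
#' @return an object of class `stim_ensemble` with fields `amplitudes`
#'   (presentations x electrodes matrix), `stim_id` (distinct-stimulus index
#'   per presentation), `sigma`, `repeats`, `seed`, `mask`, `pulse`.
#' @export
sample_white_noise <- function(n_stimuli, n_electrodes, sigma, limit = 300,
                               mask = NULL, repeats = 1L, seed = NULL,
                               pulse = pulse_params(amplitude_limit = limit)) {
  if (!is.finite(sigma) || sigma < 0) {
    stop("invalid parameter: sigma must be >= 0", call. = FALSE)
  }
  if (!is.finite(limit) || limit <= 0) {
    stop("invalid parameter: limit must be > 0", call. = FALSE)
  }
  if (n_electrodes < 1) stop("need at least one electrode", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n_electrodes)
  if (length(mask) != n_electrodes) {
    stop("mask length must equal n_electrodes", call. = FALSE)
  }
  if (!any(mask)) {
    stop("degenerate design: mask excludes all electrodes", call. = FALSE)
  }

  distinct <- with_seed(seed, {
    a <- matrix(0, n_stimuli, n_electrodes)
    n_active <- sum(mask)
    x <- stats::rnorm(n_stimuli * n_active, 0, sigma)
    bad <- abs(x) > limit
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), 0, sigma)
      bad <- abs(x) > limit
    }
    a[, mask] <- x
    a
  })

  idx <- rep(seq_len(n_stimuli), each = repeats)
  structure(
    list(amplitudes = distinct[idx, , drop = FALSE],
         stim_id = idx,
         n_distinct = as.integer(n_stimuli),
         sigma = sigma, repeats = as.integer(repeats),
         seed = seed, mask = mask, pulse = pulse),
    class = "stim_ensemble")
}

#' @export
print.stim_ensemble <- function(x, ...) {
  cat("White-noise stimulus ensemble\n")
  cat(sprintf("  %d presentations (%d distinct x %d repeats), %d electrodes (%d operational)\n",
              nrow(x$amplitudes), x$n_distinct, x$repeats,
              length(x$mask), sum(x$mask)))
  cat(sprintf("  sigma = %.1f uA, limit = %.0f uA\n",
              x$sigma, x$pulse$amplitude_limit))
  invisible(x)
}

#' Standard deviation of a symmetrically truncated normal
#'
#' Closed form for the SD of a N(0, sigma^2) variable conditioned on
#' |x| <= limit; used to check the rejection sampler against theory.
#'
#' @param sigma nominal standard deviation.
#' @param limit truncation bound.
#' @return the truncated SD.
#' @export
truncated_normal_sd <- function(sigma, limit) {
  if (sigma == 0) return(0)
  a <- limit / sigma
  z <- 2 * stats::pnorm(a) - 1
  sigma * sqrt(1 - 2 * a * stats::dnorm(a) / z)
}

#' Calibrate the white-noise amplitude from a response-probability curve
#'
#' Fits a saturating sigmoid `p(sigma) = max / (1 + exp(-gain (sigma - mid)))`
#' to response probability measured at a grid of noise amplitudes, and
#' returns the sigma at which the fitted curve reaches
#' `target_fraction x max` (default one half of the saturating response).
#' This is the per-cell calibration that keeps the working stimulus ensemble
#' near the steep part of the cell's response curve.
#'
#' @param sigma_grid noise SDs tested, in microamperes (>= 3 points).
#' @param response_prob observed response probabilities in `[0, 1]`.
#' @param target_fraction fraction of the fitted saturation at which to read
#'   off the chosen sigma (default 0.5).
#' @return an object of class `sigma_calibration` with the fitted
#'   `(max, gain, mid)`, the `chosen_sigma`, and an `extrapolated` flag set
#'   when the chosen sigma lies outside the tested grid.
#' @export
calibrate_sigma <- function(sigma_grid, response_prob, target_fraction = 0.5) {
  if (length(sigma_grid) != length(response_prob) || length(sigma_grid) < 3) {
    stop("sigma_grid and response_prob must have equal length >= 3",
         call. = FALSE)
  }
  if (any(response_prob < 0 | response_prob > 1)) {
    stop("response probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must lie in (0, 1)", call. = FALSE)
  }
  df <- data.frame(s = sigma_grid, p = response_prob)
  span <- diff(range(sigma_grid))
  start <- list(pmax = max(response_prob),
                gain = 4 / span,
                mid = sigma_grid[which.min(abs(response_prob -
                                                 max(response_prob) / 2))])
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ pmax / (1 + exp(-gain * (s - mid))),
                      data = df, start = start,
                      lower = c(pmax = 1e-6, gain = 1e-9, mid = -Inf),
                      upper = c(pmax = 1, gain = Inf, mid = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("calibration failure: sigmoid fit did not converge (",
         conditionMessage(fit), "); response range [",
         paste(signif(range(response_prob), 3), collapse = ", "), "]",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  # p = target * max  =>  sigma = mid - log(1/target - 1) / gain
  chosen <- unname(cf["mid"] - log(1 / target_fraction - 1) / cf["gain"])
  structure(
    list(sigma_grid = sigma_grid, response_prob = response_prob,
         sigmoid_params = c(max = unname(cf["pmax"]),
                            gain = unname(cf["gain"]),
                            mid = unname(cf["mid"])),
         chosen_sigma = chosen, target_prob = target_fraction * cf[["pmax"]],
         target_fraction = target_fraction,
         extrapolated = chosen < min(sigma_grid) | chosen > max(sigma_grid),
         fit = fit),
    class = "sigma_calibration")
}

#' @export
print.sigma_calibration <- function(x, ...) {
  p <- x$sigmoid_params
  cat(sprintf("Sigma calibration: chosen sigma = %.1f uA%s\n", x$chosen_sigma,
              if (x$extrapolated) " (extrapolated beyond grid)" else ""))
  cat(sprintf("  fitted max = %.3f, gain = %.4f /uA, mid = %.1f uA\n",
              p["max"], p["gain"], p["mid"]))
  invisible(x)
}
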