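# Ground-truth synthetic retinal ganglion cell: a generative
# linear-nonlinear cell with known receptive fields, nonlinearity and
# latency statistics, so that every estimation stage can be tested by
# parameter recovery.

#' Default stimulating-electrode array geometry
#'
#' A 20-electrode staggered grid: 5 columns, 4 electrodes per column with
#' 1 mm vertical center-to-center pitch, alternate columns offset by 0.5 mm,
#' 400 um electrode discs, covering roughly 3.5 x 3.5 mm.
#'
#' @return an object of class `electrode_array` with `positions`
#'   (20 x 2 matrix, mm), `diameter` (mm) and logical `mask`.
#' @export
default_array <- function() {
  xs <- seq(0, 3.5, length.out = 5)
  ys <- 0:3
  pos <- do.call(rbind, lapply(seq_along(xs), function(i) {
    cbind(x = xs[i], y = ys + ifelse(i %% 2 == 0, 0.5, 0))
  }))
  structure(list(positions = pos, diameter = 0.4,
                 mask = rep(TRUE, nrow(pos))),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("Electrode array: %d electrodes (%d operational), %.0f um discs\n",
              nrow(x$positions), sum(x$mask), x$diameter * 1000))
  invisible(x)
}

#' Construct a ground-truth linear-nonlinear cell
#'
#' Places positive receptive-field weight on the `n_significant` electrodes
#' nearest `position`, with magnitudes decaying exponentially in distance
#' (space constant `lambda`) and a small seed-controlled jitter. By default
#' the cell is polarity-symmetric (`w- = -w+`) with double-sigmoid
#' parameters a = 0.9, b = 0.03 per uA and thresholds c+ = 150 uA,
#' c- = -150 uA; asymmetric thresholds can be requested to probe the
#' estimator under mis-specification. Latency statistics default to the
#' short/long means observed for directly and synaptically activated
#' cells (about 1.75 ms and 11 ms).
#'
#' @param array an [default_array()] geometry.
#' @param position length-2 cell position (mm); default is offset slightly
#'   from the electrode nearest the array center.
#' @param n_significant number of electrodes carrying true weight (1-3
#'   typical).
#' @param seed integer seed for the weight jitter.
#' @param a,b saturation and gain (1/uA) of both sigmoids.
#' @param c_plus,c_minus anodic and cathodic thresholds (uA; `c_minus`
#'   defaults to `-c_plus`).
#' @param baseline spontaneous-response probability offset.
#' @param lambda distance decay constant of the weights (mm).
#' @param latency_short,latency_long `(mean, sd)` of the latency
#'   distributions in ms.
#' @param p_long probability of an (independent) long-latency response.
#' @param suppressive_axis optional list `(vector, strength, width)` adding
#'   a second, suppressive stimulus dimension: the spike probability is
#'   multiplied by `(1 - strength) + strength * exp(-x2^2 / (2 width^2))`
#'   where `x2` is the projection onto the unit `vector`, so stimuli far
#'   from zero along that axis are suppressed.
#' @return an object of class `rgc_cell`.
#' @export
make_cell <- function(array = default_array(), position = NULL,
                      n_significant = 3L, seed = NULL,
                      a = 0.9, b = 0.03, c_plus = 150, c_minus = -c_plus,
                      baseline = 0, lambda = 1.0,
                      latency_short = c(1.75, 0.35),
                      latency_long = c(11, 2.6),
                      p_long = 0.2, suppressive_axis = NULL) {
  stopifnot(inherits(array, "electrode_array"))
  n_el <- nrow(array$positions)
  if (n_significant < 1 || n_significant > n_el) {
    stop("n_significant must lie between 1 and the electrode count",
         call. = FALSE)
  }
  if (is.null(position)) {
    center <- colMeans(array$positions)
    d0 <- sqrt(rowSums(sweep(array$positions, 2, center)^2))
    position <- array$positions[which.min(d0), ] + c(0.3, 0.2)
  }
  d <- sqrt((array$positions[, 1] - position[1])^2 +
              (array$positions[, 2] - position[2])^2)
  hull <- apply(array$positions, 2, range)
  if (position[1] < hull[1, 1] || position[1] > hull[2, 1] ||
      position[2] < hull[1, 2] || position[2] > hull[2, 2]) {
    warning("cell position lies outside the array hull", call. = FALSE)
  }
  ord <- order(d, seq_len(n_el))
  sig_idx <- ord[seq_len(n_significant)]
  w <- numeric(n_el)
  w[sig_idx] <- exp(-d[sig_idx] / lambda)
  w[sig_idx] <- w[sig_idx] *
    with_seed(seed, stats::runif(n_significant, 0.9, 1.1))
  w <- 100 * w / max(w)
  structure(
    list(w_true_plus = w, w_true_minus = -w,
         sigmoid = list(a_plus = a, b_plus = b, c_plus = c_plus,
                        a_minus = a, b_minus = b, c_minus = c_minus),
         baseline = baseline, position = as.numeric(position),
         significant_electrodes = sort(sig_idx),
         latency_short = latency_short, latency_long = latency_long,
         p_long = p_long, suppressive_axis = suppressive_axis,
         array = array, seed = seed),
    class = "rgc_cell")
}

#' @export
print.rgc_cell <- function(x, ...) {
  cat("Ground-truth LN cell\n")
  cat(sprintf("  position (%.2f, %.2f) mm; significant electrodes: %s\n",
              x$position[1], x$position[2],
              paste(x$significant_electrodes, collapse = " ")))
  cat(sprintf("  sigmoid: a = %.2f, b = %.3f /uA, c+ = %.0f uA, c- = %.0f uA\n",
              x$sigmoid$a_plus, x$sigmoid$b_plus, x$sigmoid$c_plus,
              x$sigmoid$c_minus))
  if (!is.null(x$suppressive_axis)) cat("  suppressive second axis present\n")
  invisible(x)
}

#' True spike probability of a ground-truth cell
#'
#' Evaluates the cell's generative nonlinearity (sum of the two one-sided
#' sigmoids plus baseline, times the optional suppressive-axis penalty,
#' clipped to `[0, 1]`) for each stimulus.
#'
#' @param cell an [make_cell()] cell.
#' @param stimuli ensemble, matrix, or single amplitude vector.
#' @return vector of spike probabilities.
#' @export
true_probability <- function(cell, stimuli) {
  S <- if (is.numeric(stimuli) && is.null(dim(stimuli))) {
    matrix(stimuli, nrow = 1)
  } else {
    amplitude_matrix(stimuli)
  }
  u_plus <- unit_vector(cell$w_true_plus)
  u_minus <- -unit_vector(cell$w_true_minus)
  sg <- cell$sigmoid
  xp <- as.numeric(S %*% u_plus)
  xm <- as.numeric(S %*% u_minus)
  p <- sigmoid_pos(xp, sg$a_plus, sg$b_plus, sg$c_plus) +
    sigmoid_neg(xm, sg$a_minus, sg$b_minus, sg$c_minus) + cell$baseline
  if (!is.null(cell$suppressive_axis)) {
    sup <- cell$suppressive_axis
    x2 <- as.numeric(S %*% unit_vector(sup$vector))
    p <- p * ((1 - sup$strength) +
                sup$strength * exp(-x2^2 / (2 * sup$width^2)))
  }
  clip01(p)
}

#' Simulate per-presentation responses of a ground-truth cell
#'
#' Each presentation elicits a short-latency response with the cell's true
#' spike probability (one Bernoulli trial per presentation); responding
#' presentations receive a latency drawn from the short-latency normal
#' truncated at 0. Long-latency responses are phenomenological: independent
#' Bernoulli draws with their own latency distribution, sufficient to
#' exercise latency clustering and re-running the pipeline on long-latency
#' labels.
#'
#' @param cell an [make_cell()] cell.
#' @param ensemble a [sample_white_noise()] ensemble.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return an object of class `sim_recording` with `ensemble`, `responses`
#'   (a [response_vector()]), `probability` (true per-presentation
#'   probability), `truth` (the cell) and `seed`.
#' @export
simulate_responses <- function(cell, ensemble, seed = NULL) {
  stopifnot(inherits(cell, "rgc_cell"))
  S <- amplitude_matrix(ensemble)
  if (ncol(S) != length(cell$w_true_plus)) {
    stop("ensemble electrode count does not match the cell", call. = FALSE)
  }
  p <- true_probability(cell, S)
  n <- nrow(S)
  rec <- with_seed(seed, {
    short <- stats::rbinom(n, 1L, p)
    long <- stats::rbinom(n, 1L, cell$p_long)
    rtnorm <- function(k, mu, sd) {
      x <- stats::rnorm(k, mu, sd)
      while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, sd)
      x
    }
    lat <- vector("list", n)
    for (j in seq_len(n)) lat[[j]] <- numeric(0)
    ns <- sum(short)
    if (ns > 0) {
      ls <- rtnorm(ns, cell$latency_short[1], cell$latency_short[2])
      lat[short == 1L] <- as.list(ls)
    }
    nl <- sum(long)
    if (nl > 0) {
      ll <- rtnorm(nl, cell$latency_long[1], cell$latency_long[2])
      which_long <- which(long == 1L)
      for (k in seq_along(which_long)) {
        j <- which_long[k]
        lat[[j]] <- c(lat[[j]], ll[k])
      }
    }
    list(short = short, long = long, lat = lat)
  })
  structure(list(ensemble = ensemble,
                 responses = response_vector(rec$short, rec$long, rec$lat),
                 probability = p, truth = cell, seed = seed),
            class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf("Simulated recording: %d presentations, %d short-latency responses (rate %.3f)\n",
              length(x$responses$short), sum(x$responses$short),
              mean(x$responses$short)))
  invisible(x)
}

#' Ground-truth cell as a fitted model object
#'
#' Wraps a cell's true receptive fields and sigmoid parameters in an
#' [ln_model()], i.e. the correctly specified 1-D model. Useful as a
#' reference predictor in validation studies (the optional suppressive
#' axis is outside the 1-D model and is ignored).
#'
#' @param cell an [make_cell()] cell.
#' @return an [ln_model()].
#' @export
true_ln_model <- function(cell) {
  stopifnot(inherits(cell, "rgc_cell"))
  mask <- cell$array$mask
  v1 <- numeric(length(mask))
  v1[mask] <- fix_sign(unit_vector(cell$w_true_plus[mask]))
  erf <- structure(
    list(w_plus = cell$w_true_plus, w_minus = cell$w_true_minus,
         has_plus = TRUE, has_minus = TRUE,
         n_plus = NA_integer_, n_minus = NA_integer_,
         corr = stats::cor(cell$w_true_plus[mask], cell$w_true_minus[mask]),
         v1 = v1, mask = mask, sig_plus = NULL, sig_minus = NULL,
         rms_bound_plus = NULL, rms_bound_minus = NULL,
         D_plus = NA_real_, D_minus = NA_real_),
    class = "erf_pair")
  sg <- structure(c(cell$sigmoid, list(r2 = NA_real_)),
                  class = "double_sigmoid")
  ln_model(erf, sg, baseline = cell$baseline)
}

#' Simulate the noise-amplitude calibration experiment
#'
#' Presents short white-noise trains at each sigma in `sigma_grid` to the
#' ground-truth cell and records the response probability, emulating the
#' per-cell calibration sweep that precedes the main experiment.
#'
#' @param cell an [make_cell()] cell.
#' @param sigma_grid noise SDs to test (default 50-250 uA in steps of 50).
#' @param n_pulses pulses per train (default 500).
#' @param limit rejection bound (uA).
#' @param seed integer seed.
#' @return list with `sigma_grid` and `response_prob`, ready for
#'   [calibrate_sigma()].
#' @export
simulate_calibration <- function(cell, sigma_grid = seq(50, 250, by = 50),
                                 n_pulses = 500L, limit = 300, seed = NULL) {
  stopifnot(inherits(cell, "rgc_cell"))
  n_el <- length(cell$w_true_plus)
  probs <- with_seed(seed, {
    vapply(sigma_grid, function(s) {
      ens <- sample_white_noise(n_pulses, n_el, s, limit = limit,
                                mask = cell$array$mask)
      mean(simulate_responses(cell, ens)$responses$short)
    }, numeric(1))
  })
  list(sigma_grid = sigma_grid, response_prob = probs)
}
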