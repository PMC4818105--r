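# Static-nonlinearity estimation: equal-spike binning, double-sigmoid fit,
# the polarity-split 1-D predictor, and the 2-D surface model.

# Orientation convention for the projection axes: both axes point in the net
# anodic-first direction. The anodic axis is the unit w+; the cathodic axis
# is the *negated* unit w-, so that net cathodic-first stimuli map to
# negative projection values and the fitted cathodic threshold c- comes out
# negative (thresholds are in uA and comparable across cells).
erf_axes <- function(erf) {
  list(
    plus = if (erf$has_plus) unit_vector(erf$w_plus) else NULL,
    minus = if (erf$has_minus) -unit_vector(erf$w_minus) else NULL
  )
}

# Equal-spike bin edges from the sorted spike-eliciting projections.
equal_spike_edges <- function(x_spike, n_bins) {
  xs <- sort(x_spike)
  n <- length(xs)
  counts <- diff(round(seq(0, n, length.out = n_bins + 1)))
  cum <- cumsum(counts)
  inner <- vapply(cum[-n_bins], function(k) (xs[k] + xs[k + 1]) / 2,
                  numeric(1))
  c(-Inf, inner, Inf)
}

bin_one_side <- function(x_all, spike, n_bins, side, axis_full) {
  n_spk <- sum(spike)
  if (length(unique(x_all)) == 1) {
    return(structure(list(bin_centers = x_all[1],
                          probabilities = mean(spike),
                          n_stimuli = length(x_all), n_spikes = n_spk,
                          side = side, axis = axis_full,
                          edges = c(-Inf, Inf)),
                     class = "binned_probability"))
  }
  if (n_spk < n_bins) {
    warning("side '", side, "' has only ", n_spk,
            " spikes; reducing to ", max(1L, n_spk), " bins", call. = FALSE)
    n_bins <- max(1L, n_spk)
  }
  edges <- equal_spike_edges(x_all[spike], n_bins)
  bin <- findInterval(x_all, edges[-c(1, length(edges))]) + 1L
  n_stim <- tabulate(bin, n_bins)
  n_spikes <- tabulate(bin[spike], n_bins)
  centers <- rep(NA_real_, n_bins)
  centers[sort(unique(bin))] <- as.numeric(tapply(x_all, bin, mean))
  keep <- n_stim > 0  # all bins hold >= 1 spike stimulus by construction
  structure(list(bin_centers = centers[keep],
                 probabilities = (n_spikes / pmax(n_stim, 1))[keep],
                 n_stimuli = n_stim[keep], n_spikes = n_spikes[keep],
                 side = side, axis = axis_full, edges = edges),
            class = "binned_probability")
}

#' Binned spike probability along the receptive-field axes
#'
#' Projects every stimulus onto the unit positive and (negated) unit
#' negative receptive fields, segments each polarity side into
#' `n_bins_per_side` bins containing equal numbers of spike-eliciting
#' stimuli (quantile edges of the spike projections), and estimates the
#' spike probability per bin as the ratio of spike-eliciting to total
#' stimuli falling in it. Side membership (net anodic-first vs net
#' cathodic-first) is the sign of the projection onto the first principal
#' axis, as in [estimate_erfs()].
#'
#' @param ens a [spike_triggered_ensemble()].
#' @param erf an [estimate_erfs()] result.
#' @param n_bins_per_side bins per polarity side (default 15, i.e. 30 in
#'   total for a two-sided cell).
#' @return a list of class `binned_pair` with elements `pos` and `neg`
#'   (each a `binned_probability` or NULL for an absent side).
#' @export
bin_projections <- function(ens, erf, n_bins_per_side = 15L) {
  stopifnot(inherits(ens, "ste"), inherits(erf, "erf_pair"))
  if (n_bins_per_side < 2) stop("n_bins_per_side must be >= 2", call. = FALSE)
  axes <- erf_axes(erf)
  S <- ens$S_T[, ens$mask, drop = FALSE]
  v1proj <- as.numeric(S %*% erf$v1[ens$mask])
  spike <- ens$response == 1L
  out <- list(pos = NULL, neg = NULL)
  if (erf$has_plus) {
    side <- v1proj >= 0
    x <- as.numeric(S %*% axes$plus[ens$mask])
    out$pos <- bin_one_side(x[side], spike[side], n_bins_per_side,
                            "positive", axes$plus)
  }
  if (erf$has_minus) {
    side <- v1proj < 0
    x <- as.numeric(S %*% axes$minus[ens$mask])
    out$neg <- bin_one_side(x[side], spike[side], n_bins_per_side,
                            "negative", axes$minus)
  }
  structure(out, class = "binned_pair")
}

#' The anodic-side sigmoid
#'
#' `N+(x) = a / (1 + exp(-b (x - c)))`: nondecreasing, saturating at `a`,
#' with threshold `c` at half saturation.
#'
#' @param x projection onto the unit positive receptive field (uA).
#' @param a,b,c saturation, gain (1/uA) and threshold (uA).
#' @return spike probability contribution.
#' @export
sigmoid_pos <- function(x, a, b, c) a / (1 + exp(-b * (x - c)))

#' The cathodic-side sigmoid
#'
#' `N-(x) = a - a / (1 + exp(-b (x - c)))`: nonincreasing in `x`,
#' saturating at `a` for strongly net-cathodic (negative) projections, with
#' threshold `c` (typically negative) at half saturation.
#'
#' @inheritParams sigmoid_pos
#' @return spike probability contribution.
#' @export
sigmoid_neg <- function(x, a, b, c) a - a / (1 + exp(-b * (x - c)))

fit_one_sigmoid <- function(x, p, weights = NULL, negative = FALSE) {
  a0 <- max(p)
  if (a0 <= 0) stop("fit failure: all bin probabilities are zero",
                    call. = FALSE)
  c0 <- x[which.min(abs(p - a0 / 2))]
  span <- diff(range(x))
  if (span == 0) stop("fit failure: degenerate projection range",
                      call. = FALSE)
  b0 <- 4 * a0 / span
  form <- if (negative) p ~ a - a / (1 + exp(-b * (x - c)))
          else p ~ a / (1 + exp(-b * (x - c)))
  df <- data.frame(x = x, p = p)
  best <- NULL
  for (mult in c(1, 0.25, 4, 0.05, 20)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df,
                        start = list(a = min(a0, 1), b = b0 * mult, c = c0),
                        lower = c(a = 1e-6, b = 1e-9, c = -Inf),
                        upper = c(a = 1, b = Inf, c = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("fit failure: sigmoid did not converge after multi-start; ",
         "probability range [", paste(signif(range(p), 3), collapse = ", "),
         "]", call. = FALSE)
  }
  stats::coef(best$fit)
}

#' Fit the double sigmoid to binned probabilities
#'
#' Independent nonlinear least squares of the anodic sigmoid
#' ([sigmoid_pos()]) to the positive-side bins and of the cathodic sigmoid
#' ([sigmoid_neg()]) to the negative-side bins (the six parameters never
#' interact across sides). The coefficient of determination `r2` is
#' computed jointly over all bins.
#'
#' @param binned a [bin_projections()] result.
#' @return an object of class `double_sigmoid` with `a_plus`, `b_plus`,
#'   `c_plus`, `a_minus`, `b_minus`, `c_minus` (absent sides are NA) and
#'   `r2`.
#' @export
fit_double_sigmoid <- function(binned) {
  stopifnot(inherits(binned, "binned_pair"))
  cf_p <- cf_m <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  pred <- obs <- numeric(0)
  if (!is.null(binned$pos)) {
    if (length(binned$pos$bin_centers) < 4) {
      stop("need >= 4 bins on the positive side", call. = FALSE)
    }
    cf_p <- fit_one_sigmoid(binned$pos$bin_centers,
                            binned$pos$probabilities, negative = FALSE)
    pred <- c(pred, sigmoid_pos(binned$pos$bin_centers, cf_p["a"],
                                cf_p["b"], cf_p["c"]))
    obs <- c(obs, binned$pos$probabilities)
  }
  if (!is.null(binned$neg)) {
    if (length(binned$neg$bin_centers) < 4) {
      stop("need >= 4 bins on the negative side", call. = FALSE)
    }
    cf_m <- fit_one_sigmoid(binned$neg$bin_centers,
                            binned$neg$probabilities, negative = TRUE)
    pred <- c(pred, sigmoid_neg(binned$neg$bin_centers, cf_m["a"],
                                cf_m["b"], cf_m["c"]))
    obs <- c(obs, binned$neg$probabilities)
  }
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - sum((obs - pred)^2) / ss_tot else NA_real_
  structure(list(a_plus = unname(cf_p["a"]), b_plus = unname(cf_p["b"]),
                 c_plus = unname(cf_p["c"]), a_minus = unname(cf_m["a"]),
                 b_minus = unname(cf_m["b"]), c_minus = unname(cf_m["c"]),
                 r2 = r2),
            class = "double_sigmoid")
}

#' @export
print.double_sigmoid <- function(x, ...) {
  cat("Double-sigmoid nonlinearity\n")
  if (is.finite(x$a_plus)) {
    cat(sprintf("  N+: a = %.3f, b = %.4f /uA, c = %.1f uA\n",
                x$a_plus, x$b_plus, x$c_plus))
  }
  if (is.finite(x$a_minus)) {
    cat(sprintf("  N-: a = %.3f, b = %.4f /uA, c = %.1f uA\n",
                x$a_minus, x$b_minus, x$c_minus))
  }
  cat(sprintf("  r2 = %.4f\n", x$r2))
  invisible(x)
}

#' Assemble a 1-D linear-nonlinear model
#'
#' Bundles the polarity-split receptive fields and the fitted double
#' sigmoid into a predictor: the spike probability for a stimulus is
#' `N+(x+) + N-(x-) + baseline`, clipped to `[0, 1]`, where `x+` and `x-`
#' are the projections onto the unit positive and negated unit negative
#' receptive fields.
#'
#' @param erf an [estimate_erfs()] result.
#' @param sigmoid a [fit_double_sigmoid()] result.
#' @param baseline spontaneous-rate probability offset (default 0).
#' @return an object of class `ln_model`.
#' @export
ln_model <- function(erf, sigmoid, baseline = 0) {
  stopifnot(inherits(erf, "erf_pair"), inherits(sigmoid, "double_sigmoid"))
  if (baseline < 0) stop("baseline must be >= 0", call. = FALSE)
  structure(list(erf = erf, sigmoid = sigmoid, baseline = baseline,
                 axes = erf_axes(erf), mask = erf$mask, v1 = erf$v1),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat("Linear-nonlinear model (1-D, polarity-split)\n")
  print(x$sigmoid)
  if (x$baseline > 0) cat(sprintf("  baseline = %.4f\n", x$baseline))
  invisible(x)
}

#' Predict spike probability from a fitted model
#'
#' @param object an [ln_model()].
#' @param stimuli a stimulus ensemble, matrix, or single amplitude vector.
#' @param mode `"sum"` evaluates both sigmoid terms for every stimulus (the
#'   additive form; the off-side term sits near its floor); `"piecewise"`
#'   evaluates only the term for the stimulus's own polarity side.
#' @param ... unused.
#' @return vector of spike probabilities in `[0, 1]`.
#' @export
predict.ln_model <- function(object, stimuli, mode = c("sum", "piecewise"),
                             ...) {
  mode <- match.arg(mode)
  S <- if (is.numeric(stimuli) && is.null(dim(stimuli))) {
    matrix(stimuli, nrow = 1)
  } else {
    amplitude_matrix(stimuli)
  }
  if (ncol(S) != length(object$mask)) {
    stop("stimulus dimension (", ncol(S), ") does not match model (",
         length(object$mask), ")", call. = FALSE)
  }
  Sm <- S[, object$mask, drop = FALSE]
  sg <- object$sigmoid
  n_plus <- rep(0, nrow(Sm))
  n_minus <- rep(0, nrow(Sm))
  if (!is.null(object$axes$plus) && is.finite(sg$a_plus)) {
    xp <- as.numeric(Sm %*% object$axes$plus[object$mask])
    n_plus <- sigmoid_pos(xp, sg$a_plus, sg$b_plus, sg$c_plus)
  }
  if (!is.null(object$axes$minus) && is.finite(sg$a_minus)) {
    xm <- as.numeric(Sm %*% object$axes$minus[object$mask])
    n_minus <- sigmoid_neg(xm, sg$a_minus, sg$b_minus, sg$c_minus)
  }
  if (mode == "piecewise") {
    v1p <- as.numeric(Sm %*% object$v1[object$mask])
    pos <- v1p >= 0
    n_plus[!pos] <- 0
    n_minus[pos] <- 0
  }
  clip01(n_plus + n_minus + object$baseline)
}

#' Fit a two-dimensional nonlinearity surface
#'
#' Estimates the spike probability jointly over the projections onto two
#' significant axes as a 2-D histogram (equal-width grid over the training
#' projection range), with cells containing fewer than `min_count` training
#' stimuli flagged unsupported. Predictions interpolate bilinearly between
#' supported cell centers (reproducing the binned value exactly at a grid
#' node); queries outside the grid or next to unsupported cells return NA
#' so callers can fall back to the 1-D model or omit them.
#'
#' @param ens a training [spike_triggered_ensemble()].
#' @param v1,v2 the two axes (full electrode length or operational length).
#' @param grid_resolution cells per axis (default 15, minimum 5).
#' @param min_count minimum training stimuli per supported cell (default 20).
#' @return an object of class `ln_model_2d`.
#' @export
fit_2d <- function(ens, v1, v2, grid_resolution = 15L, min_count = 20L) {
  stopifnot(inherits(ens, "ste"))
  if (grid_resolution < 5) stop("grid_resolution must be >= 5", call. = FALSE)
  mask <- ens$mask
  pick <- function(v) {
    if (length(v) == length(mask)) v[mask]
    else if (length(v) == sum(mask)) v
    else stop("axis length mismatch", call. = FALSE)
  }
  u1 <- fix_sign(unit_vector(pick(v1)))
  u2 <- unit_vector(pick(v2))
  S <- ens$S_T[, mask, drop = FALSE]
  x1 <- as.numeric(S %*% u1)
  x2 <- as.numeric(S %*% u2)
  spike <- ens$response == 1L
  e1 <- seq(min(x1), max(x1), length.out = grid_resolution + 1)
  e2 <- seq(min(x2), max(x2), length.out = grid_resolution + 1)
  b1 <- pmin(pmax(findInterval(x1, e1, rightmost.closed = TRUE), 1L),
             grid_resolution)
  b2 <- pmin(pmax(findInterval(x2, e2, rightmost.closed = TRUE), 1L),
             grid_resolution)
  idx <- (b2 - 1L) * grid_resolution + b1
  counts <- tabulate(idx, grid_resolution^2)
  spikes <- tabulate(idx[spike], grid_resolution^2)
  prob <- matrix(spikes / pmax(counts, 1), grid_resolution, grid_resolution)
  supported <- matrix(counts >= min_count, grid_resolution, grid_resolution)
  prob[!supported] <- NA_real_
  if (sum(supported) < 4) {
    stop("insufficient support: fewer than 4 supported grid cells",
         call. = FALSE)
  }
  c1 <- (e1[-1] + e1[-length(e1)]) / 2
  c2 <- (e2[-1] + e2[-length(e2)]) / 2
  u1f <- numeric(length(mask)); u1f[mask] <- u1
  u2f <- numeric(length(mask)); u2f[mask] <- u2
  structure(list(v1 = u1f, v2 = u2f, centers1 = c1, centers2 = c2,
                 surface = prob, supported = supported,
                 grid_resolution = as.integer(grid_resolution),
                 min_count = as.integer(min_count), mask = mask),
            class = "ln_model_2d")
}

# Bilinear interpolation over cell centers; NA outside or next to
# unsupported cells.
interp_bilinear <- function(model, x1, x2) {
  c1 <- model$centers1; c2 <- model$centers2
  K <- length(c1)
  out <- rep(NA_real_, length(x1))
  inside <- x1 >= c1[1] & x1 <= c1[K] & x2 >= c2[1] & x2 <= c2[K]
  if (!any(inside)) return(out)
  i <- pmin(pmax(findInterval(x1[inside], c1), 1L), K - 1L)
  j <- pmin(pmax(findInterval(x2[inside], c2), 1L), K - 1L)
  tx <- (x1[inside] - c1[i]) / (c1[i + 1] - c1[i])
  ty <- (x2[inside] - c2[j]) / (c2[j + 1] - c2[j])
  f <- function(ii, jj) model$surface[cbind(ii, jj)]
  z <- (1 - tx) * (1 - ty) * f(i, j) + tx * (1 - ty) * f(i + 1, j) +
    (1 - tx) * ty * f(i, j + 1) + tx * ty * f(i + 1, j + 1)
  out[inside] <- z
  out
}

#' @rdname fit_2d
#' @param object an `ln_model_2d`.
#' @param stimuli stimulus ensemble, matrix, or single vector.
#' @param ... unused.
#' @return for `predict`: spike probabilities, NA where the surface is
#'   unsupported.
#' @export
predict.ln_model_2d <- function(object, stimuli, ...) {
  S <- if (is.numeric(stimuli) && is.null(dim(stimuli))) {
    matrix(stimuli, nrow = 1)
  } else {
    amplitude_matrix(stimuli)
  }
  Sm <- S[, object$mask, drop = FALSE]
  x1 <- as.numeric(Sm %*% object$v1[object$mask])
  x2 <- as.numeric(Sm %*% object$v2[object$mask])
  clip01(interp_bilinear(object, x1, x2))
}
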