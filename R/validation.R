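# Held-out model validation: train/test split at the distinct-stimulus
# level and binned calibration error.

#' Split an ensemble into training and validation sets
#'
#' Splits at the distinct-stimulus level so that all repeats of one
#' stimulus stay in the same partition (repeats of a stimulus are
#' statistically dependent and would otherwise leak across the split).
#'
#' @param ens a [spike_triggered_ensemble()].
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with `train` and `test` ensembles.
#' @export
split_data <- function(ens, fraction = 0.8, seed = NULL) {
  stopifnot(inherits(ens, "ste"))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  ids <- unique(ens$stim_id)
  n_train <- round(fraction * length(ids))
  if (n_train < 1 || n_train >= length(ids)) {
    stop("split error: too few distinct stimuli for a nonempty train and test set",
         call. = FALSE)
  }
  train_ids <- with_seed(seed, sample(ids, n_train))
  take <- function(rows) {
    spike_triggered_ensemble(ens$S_T[rows, , drop = FALSE],
                             ens$response[rows], mask = ens$mask,
                             stim_id = ens$stim_id[rows])
  }
  in_train <- ens$stim_id %in% train_ids
  list(train = take(which(in_train)), test = take(which(!in_train)))
}

#' Binned calibration error on held-out data
#'
#' Assigns every test presentation its model-predicted spike probability,
#' bins predictions into `B` equal-width bins on `[0, 1]`, and compares the
#' mean predicted probability per bin with the empirical response fraction.
#' The mean squared error over non-empty bins and its square root are the
#' model's calibration errors; empty bins are omitted and counted. For 2-D
#' models, presentations falling in unsupported surface regions (NA
#' predictions) are omitted before binning.
#'
#' @param model an [ln_model()] or [fit_2d()] model, or a function mapping
#'   a test ensemble to a vector of predicted probabilities (useful for
#'   evaluating a known generative model).
#' @param test a held-out [spike_triggered_ensemble()].
#' @param B number of probability bins (default 10).
#' @param ... passed to the model's `predict` method.
#' @return an object of class `validation_report` with per-bin `predicted`,
#'   `actual`, `counts`, plus `e_ms`, `e_rms`, `omitted_bins`,
#'   `omitted_points`, `n_test`.
#' @export
validation_error <- function(model, test, B = 10L, ...) {
  stopifnot(inherits(test, "ste"))
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  pred <- if (is.function(model)) model(test) else predict(model, test, ...)
  resp <- test$response
  ok <- !is.na(pred)
  omitted_points <- sum(!ok)
  pred <- pred[ok]
  resp <- resp[ok]
  if (length(pred) == 0) {
    stop("validation error: no supported test presentations", call. = FALSE)
  }
  edges <- seq(0, 1, length.out = B + 1)
  bin <- pmin(pmax(findInterval(pred, edges, rightmost.closed = TRUE), 1L),
              B)
  counts <- tabulate(bin, B)
  keep <- counts > 0
  if (!any(keep)) stop("validation error: all bins empty", call. = FALSE)
  p_hat <- rep(NA_real_, B)
  p_act <- rep(NA_real_, B)
  occ <- sort(unique(bin))
  p_hat[occ] <- as.numeric(tapply(pred, bin, mean))
  p_act[occ] <- as.numeric(tapply(resp, bin, mean))
  e_ms <- mean((p_hat[keep] - p_act[keep])^2)
  structure(list(B = as.integer(B), predicted = p_hat, actual = p_act,
                 counts = counts, e_ms = e_ms, e_rms = sqrt(e_ms),
                 omitted_bins = sum(!keep),
                 omitted_points = omitted_points,
                 n_test = length(pred)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (B = %d, %d test presentations)\n",
              x$B, x$n_test))
  cat(sprintf("  E_MS = %.5f, E_RMS = %.4f (%d empty bins omitted",
              x$e_ms, x$e_rms, x$omitted_bins))
  if (x$omitted_points > 0) {
    cat(sprintf(", %d unsupported points omitted", x$omitted_points))
  }
  cat(")\n")
  invisible(x)
}

#' Compare 1-D and 2-D validation errors
#'
#' @param report_1d,report_2d [validation_error()] reports computed on the
#'   same test set.
#' @return list with `e_rms_1d`, `e_rms_2d` and `difference`
#'   (`e_rms_2d - e_rms_1d`; negative means the 2-D model validated
#'   better).
#' @export
compare_1d_2d <- function(report_1d, report_2d) {
  stopifnot(inherits(report_1d, "validation_report"),
            inherits(report_2d, "validation_report"))
  if (report_1d$n_test + report_1d$omitted_points !=
      report_2d$n_test + report_2d$omitted_points) {
    stop("comparison error: reports computed on different test sets",
         call. = FALSE)
  }
  list(e_rms_1d = report_1d$e_rms, e_rms_2d = report_2d$e_rms,
       difference = report_2d$e_rms - report_1d$e_rms)
}
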