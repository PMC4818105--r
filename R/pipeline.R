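# End-to-end estimation pipeline: subspace -> receptive fields ->
# nonlinearity -> validation.

#' Run the full estimation pipeline
#'
#' Splits the data 80/20 at the distinct-stimulus level, identifies the
#' significant stimulus subspace on the training set, estimates the
#' polarity-split receptive fields with electrode significance, fits the
#' double-sigmoid nonlinearity on equal-spike bins, and computes the binned
#' calibration error on the held-out set. When the significance test finds
#' two or more components (and `config$fit_2d` is not FALSE), a 2-D surface
#' model over the two most significant axes is fitted and validated on the
#' same test set.
#'
#' @param stimuli a [sample_white_noise()] ensemble (or amplitude matrix),
#'   or a `dataset` from [read_dataset()] (in which case `responses` is
#'   ignored).
#' @param responses a [response_vector()] or binary vector.
#' @param config named list of stage parameters; recognized entries (with
#'   defaults): `split_fraction` (0.8), `split_seed` (1), `n_shuffles`
#'   (1000), `n_sd` (2), `shuffle_seed` (1), `bins_per_side` (15), `B`
#'   (10), `baseline` (0), `fit_2d` (TRUE), `grid_resolution` (15),
#'   `min_count` (20).
#' @param verbose log each stage with its parameters and seeds.
#' @return list of class `pipeline_result` with `split`, `spectrum`,
#'   `significance`, `erf`, `binned`, `sigmoid`, `model`, `validation`,
#'   and (when fitted) `model_2d`, `validation_2d`, `comparison`, plus the
#'   resolved `config`.
#' @export
run_pipeline <- function(stimuli, responses = NULL, config = list(),
                         verbose = FALSE) {
  if (inherits(stimuli, "dataset")) {
    responses <- stimuli$responses
    stimuli <- stimuli$ensemble
  }
  defaults <- list(split_fraction = 0.8, split_seed = 1L,
                   n_shuffles = 1000L, n_sd = 2, shuffle_seed = 1L,
                   bins_per_side = 15L, B = 10L, baseline = 0,
                   fit_2d = TRUE, grid_resolution = 15L, min_count = 20L)
  config <- utils::modifyList(defaults, config)
  say <- function(...) if (verbose) message(sprintf(...))

  ens <- spike_triggered_ensemble(stimuli, responses)
  say("split: fraction %.2f, seed %d", config$split_fraction,
      config$split_seed)
  split <- split_data(ens, config$split_fraction, seed = config$split_seed)
  train <- split$train

  say("subspace: %d shuffles, +/- %.1f SD, seed %d", config$n_shuffles,
      config$n_sd, config$shuffle_seed)
  sig <- significance_test(train, n_shuffles = config$n_shuffles,
                           n_sd = config$n_sd, seed = config$shuffle_seed)
  axes <- lapply(sig$significant, `[[`, "axis")
  v1 <- if (length(axes) >= 1) axes[[1]] else sig$spectrum$eigenvectors_full[, 1]

  erf <- estimate_erfs(train, v1)
  erf <- electrode_significance(train, sig, erf)
  say("erf: %d/%d spike stimuli net anodic-first, corr = %.3f", erf$n_plus,
      erf$n_plus + erf$n_minus, erf$corr)

  binned <- bin_projections(train, erf, config$bins_per_side)
  sigmoid <- fit_double_sigmoid(binned)
  model <- ln_model(erf, sigmoid, baseline = config$baseline)
  say("nonlinearity: r2 = %.3f, c+ = %.1f, c- = %.1f", sigmoid$r2,
      sigmoid$c_plus, sigmoid$c_minus)

  report <- validation_error(model, split$test, B = config$B)
  say("validation: E_RMS = %.4f over %d test presentations", report$e_rms,
      report$n_test)

  out <- list(split = split, spectrum = sig$spectrum, significance = sig,
              erf = erf, binned = binned, sigmoid = sigmoid, model = model,
              validation = report, config = config)

  if (isTRUE(config$fit_2d) && length(axes) >= 2) {
    m2 <- tryCatch(
      fit_2d(train, axes[[1]], axes[[2]],
             grid_resolution = config$grid_resolution,
             min_count = config$min_count),
      error = function(e) NULL)
    if (!is.null(m2)) {
      r2d <- validation_error(m2, split$test, B = config$B)
      out$model_2d <- m2
      out$validation_2d <- r2d
      out$comparison <- compare_1d_2d(report, r2d)
      say("2-D model: E_RMS = %.4f (1-D %.4f)", r2d$e_rms, report$e_rms)
    }
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  significant components: %d excitatory, %d suppressive (G = %.2f)\n",
              x$significance$n_excitatory, x$significance$n_suppressive,
              x$significance$G))
  cat(sprintf("  nonlinearity r2 = %.3f; validation E_RMS = %.4f\n",
              x$sigmoid$r2, x$validation$e_rms))
  if (!is.null(x$comparison)) {
    cat(sprintf("  2-D model E_RMS = %.4f (difference %+.4f)\n",
                x$comparison$e_rms_2d, x$comparison$difference))
  }
  invisible(x)
}

#' Serialize pipeline results to JSON
#'
#' Writes the eigenspectrum, significant axes, receptive fields with
#' significance flags, sigmoid parameters, validation report and shuffle
#' metadata to `subspace.json`, `model.json` and `validation.json` in
#' `dir`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- result$significance
  sub <- list(
    eigenvalues = sig$spectrum$eigenvalues,
    normalized_eigenvalues = sig$spectrum$normalized,
    sigma2 = sig$spectrum$sigma2,
    significant = lapply(sig$significant, function(s) {
      list(axis = s$axis, eigenvalue = s$eigenvalue, label = s$label)
    }),
    G = sig$G, null_mean = sig$null_mean,
    n_shuffles = sig$n_shuffles, n_sd = sig$n_sd, seed = sig$seed)
  erf <- result$erf
  model <- list(
    w_plus = erf$w_plus, w_minus = erf$w_minus,
    sig_plus = erf$sig_plus, sig_minus = erf$sig_minus,
    rms_bound_plus = erf$rms_bound_plus,
    rms_bound_minus = erf$rms_bound_minus,
    corr = erf$corr, sigmoid = unclass(result$sigmoid),
    baseline = result$model$baseline)
  val <- list(B = result$validation$B,
              predicted = result$validation$predicted,
              actual = result$validation$actual,
              counts = result$validation$counts,
              e_ms = result$validation$e_ms,
              e_rms = result$validation$e_rms,
              omitted_bins = result$validation$omitted_bins)
  if (!is.null(result$comparison)) val$comparison <- result$comparison
  jsonlite::write_json(sub, file.path(dir, "subspace.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(val, file.path(dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
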