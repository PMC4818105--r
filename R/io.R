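# Dataset readers and writers. Tables are CSV, metadata and model results
# are JSON, so fixtures stay inspectable.

#' Write a dataset to a directory
#'
#' Writes `ensemble.csv` (stim_id column plus one amplitude column per
#' electrode, uA, one row per presentation), `responses.csv`
#' (presentation, short, long, semicolon-joined latency list in ms) and
#' `meta.json` (sigma, seed, mask, pulse parameters, repeats, optional
#' geometry and free-form metadata).
#'
#' @param ensemble a [sample_white_noise()] ensemble.
#' @param responses a [response_vector()].
#' @param dir output directory (created if missing).
#' @param geometry optional [default_array()] geometry.
#' @param metadata optional named list of free-form metadata.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ensemble, responses, dir, geometry = NULL,
                          metadata = list()) {
  stopifnot(inherits(ensemble, "stim_ensemble"),
            inherits(responses, "response_vector"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  amp <- as.data.frame(ensemble$amplitudes)
  names(amp) <- sprintf("E%02d", seq_len(ncol(amp)))
  utils::write.csv(cbind(stim_id = ensemble$stim_id, amp),
                   file.path(dir, "ensemble.csv"), row.names = FALSE)
  lat <- if (is.null(responses$latencies)) {
    rep("", length(responses$short))
  } else {
    vapply(responses$latencies,
           function(l) paste(format(l, trim = TRUE), collapse = ";"),
           character(1))
  }
  utils::write.csv(
    data.frame(presentation = seq_along(responses$short),
               short = responses$short,
               long = if (is.null(responses$long)) NA else responses$long,
               latencies = lat),
    file.path(dir, "responses.csv"), row.names = FALSE)
  meta <- list(sigma = ensemble$sigma, seed = ensemble$seed,
               repeats = ensemble$repeats, mask = ensemble$mask,
               pulse = unclass(ensemble$pulse),
               n_distinct = ensemble$n_distinct,
               metadata = metadata)
  if (!is.null(geometry)) {
    meta$geometry <- list(positions = unname(as.matrix(geometry$positions)),
                          diameter = geometry$diameter,
                          mask = geometry$mask)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates cross-field consistency on load: amplitude columns must be
#' numeric, response and ensemble row counts must match, and no amplitude
#' may exceed the declared limit; violations raise errors naming the
#' offending row or column.
#'
#' @param dir directory containing `ensemble.csv`, `responses.csv`,
#'   `meta.json`.
#' @return list of class `dataset` with `ensemble`, `responses`,
#'   `geometry` (or NULL) and `metadata`.
#' @export
read_dataset <- function(dir) {
  ens_path <- file.path(dir, "ensemble.csv")
  resp_path <- file.path(dir, "responses.csv")
  meta_path <- file.path(dir, "meta.json")
  for (p in c(ens_path, resp_path, meta_path)) {
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tab <- utils::read.csv(ens_path, check.names = FALSE)
  stim_id <- tab[["stim_id"]]
  amp_cols <- setdiff(names(tab), "stim_id")
  for (cn in amp_cols) {
    if (!is.numeric(tab[[cn]])) {
      stop("non-numeric amplitude in column '", cn, "'", call. = FALSE)
    }
  }
  A <- as.matrix(tab[amp_cols])
  limit <- meta$pulse$amplitude_limit
  over <- which(abs(A) > limit, arr.ind = TRUE)
  if (nrow(over) > 0) {
    stop("amplitude ", signif(A[over[1, , drop = FALSE]], 6), " uA at row ",
         over[1, 1], ", column '", amp_cols[over[1, 2]],
         "' exceeds declared limit ", limit, " uA", call. = FALSE)
  }
  resp <- utils::read.csv(resp_path)
  if (nrow(resp) != nrow(A)) {
    stop("length mismatch: ", nrow(A), " ensemble rows but ", nrow(resp),
         " response rows", call. = FALSE)
  }
  lat <- lapply(as.character(resp$latencies), function(s) {
    if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ";")[[1]])
  })
  long <- if (all(is.na(resp$long))) NULL else as.integer(resp$long)
  pulse <- do.call(pulse_params, meta$pulse)
  ensemble <- structure(
    list(amplitudes = unname(A), stim_id = stim_id,
         n_distinct = meta$n_distinct, sigma = meta$sigma,
         repeats = meta$repeats, seed = meta$seed,
         mask = as.logical(meta$mask), pulse = pulse),
    class = "stim_ensemble")
  geometry <- NULL
  if (!is.null(meta$geometry)) {
    geometry <- structure(
      list(positions = matrix(unlist(meta$geometry$positions),
                              ncol = 2, byrow = FALSE,
                              dimnames = list(NULL, c("x", "y"))),
           diameter = meta$geometry$diameter,
           mask = as.logical(meta$geometry$mask)),
      class = "electrode_array")
  }
  structure(list(ensemble = ensemble,
                 responses = response_vector(resp$short, long, lat),
                 geometry = geometry, metadata = meta$metadata),
            class = "dataset")
}
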