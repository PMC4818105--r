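# Fixed-power stimulation-efficiency analysis: thresholds of naive
# equal-amplitude strategies vs stimulation proportional to the positive
# electrical receptive field, compared at constant stimulus-vector norm
# (equivalent to constant power for identical electrode geometries).

#' Build naive and ERF-proportional stimulation strategies
#'
#' A naive `k`-electrode strategy puts equal positive (anodic-first)
#' amplitudes on the `k` electrodes nearest the cell, at unit Euclidean
#' norm; the ERF strategy stimulates proportionally to the positive
#' receptive field, `w+ / ||w+||`. Distance ties are broken by electrode
#' index.
#'
#' @param erf an [estimate_erfs()] result with a defined positive side.
#' @param electrode_positions electrodes x 2 matrix of (x, y) positions in
#'   mm (e.g. `default_array()$positions`).
#' @param cell_position length-2 cell position in mm.
#' @param k_max largest naive electrode count (default 3).
#' @return list of `stim_strategy` objects labelled `naive-1` ...
#'   `naive-k_max` and `erf`, each with a unit `direction` vector.
#' @export
make_strategies <- function(erf, electrode_positions, cell_position,
                            k_max = 3L) {
  stopifnot(inherits(erf, "erf_pair"))
  if (!erf$has_plus) {
    stop("positive receptive field is absent; no ERF strategy defined",
         call. = FALSE)
  }
  n_el <- nrow(electrode_positions)
  d <- sqrt((electrode_positions[, 1] - cell_position[1])^2 +
              (electrode_positions[, 2] - cell_position[2])^2)
  ord <- order(d, seq_len(n_el))
  strategies <- list()
  for (k in seq_len(k_max)) {
    u <- numeric(n_el)
    u[ord[seq_len(k)]] <- 1 / sqrt(k)
    strategies[[paste0("naive-", k)]] <-
      structure(list(direction = u, label = paste0("naive-", k)),
                class = "stim_strategy")
  }
  strategies[["erf"]] <-
    structure(list(direction = unit_vector(erf$w_plus), label = "erf"),
              class = "stim_strategy")
  strategies
}

#' Stimulation threshold at fixed power along a strategy direction
#'
#' The threshold is the smallest scale `t > 0` at which the predicted
#' probability of the anodic sigmoid reaches half its fitted saturation
#' when stimulating with `t x u` for a unit-norm direction `u`. For the
#' pure anodic sigmoid this is analytic: `t = c+ / (u . w+/||w+||)` (the
#' projection threshold divided by the cosine between the strategy and the
#' receptive field). A bisection solver is available for cross-checking
#' and for models with a baseline offset.
#'
#' @param model an [ln_model()].
#' @param strategy a `stim_strategy` from [make_strategies()].
#' @param method `"analytic"` (default) or `"bisection"`.
#' @param tol relative tolerance of the bisection solver.
#' @return the threshold scale in microamperes.
#' @export
threshold_at_fixed_power <- function(model, strategy,
                                     method = c("analytic", "bisection"),
                                     tol = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(model, "ln_model"))
  u <- strategy$direction
  w_hat <- unit_vector(model$erf$w_plus)
  cosine <- sum(u * w_hat)
  if (cosine <= 0) {
    stop("unreachable threshold: strategy direction has non-positive ",
         "projection onto w+", call. = FALSE)
  }
  sg <- model$sigmoid
  if (method == "analytic") {
    return(sg$c_plus / cosine)
  }
  target <- sg$a_plus / 2
  g <- function(t) sigmoid_pos(t * cosine, sg$a_plus, sg$b_plus,
                               sg$c_plus) - target
  hi <- abs(sg$c_plus) / cosine + 1
  while (g(hi) < 0) hi <- hi * 2
  lo <- 0
  stats::uniroot(g, c(lo, hi), tol = tol * max(1, abs(sg$c_plus)))$root
}

#' Compare stimulation strategies at fixed power
#'
#' Computes the threshold of every strategy and the ratio of the
#' ERF-proportional threshold to the best (lowest-threshold) naive
#' strategy. By Cauchy-Schwarz the ratio never exceeds 1: at fixed norm no
#' direction projects onto the receptive field more strongly than the
#' receptive field itself, with equality only when the best naive
#' direction is parallel to `w+`.
#'
#' @param model an [ln_model()].
#' @param strategies list from [make_strategies()], containing at least one
#'   naive strategy and the `erf` strategy.
#' @param ... passed to [threshold_at_fixed_power()].
#' @return an object of class `threshold_comparison` with per-strategy
#'   `thresholds`, `best_naive` label, and `ratio`.
#' @export
compare_strategies <- function(model, strategies, ...) {
  labels <- vapply(strategies, `[[`, character(1), "label")
  if (!"erf" %in% labels || length(strategies) < 2) {
    stop("need at least one naive strategy and the erf strategy",
         call. = FALSE)
  }
  thresholds <- vapply(strategies, function(s) {
    tryCatch(threshold_at_fixed_power(model, s, ...),
             error = function(e) NA_real_)
  }, numeric(1))
  naive <- thresholds[labels != "erf"]
  if (all(is.na(naive))) {
    stop("comparison error: all naive strategies unreachable", call. = FALSE)
  }
  best <- names(naive)[which.min(naive)]
  ratio <- thresholds[["erf"]] / min(naive, na.rm = TRUE)
  structure(list(thresholds = thresholds, best_naive = best, ratio = ratio),
            class = "threshold_comparison")
}

#' @export
print.threshold_comparison <- function(x, ...) {
  cat("Fixed-power threshold comparison\n")
  for (nm in names(x$thresholds)) {
    cat(sprintf("  %-8s %8.2f uA\n", nm, x$thresholds[[nm]]))
  }
  cat(sprintf("  ratio erf / best naive (%s) = %.3f\n", x$best_naive,
              x$ratio))
  invisible(x)
}
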