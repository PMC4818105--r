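
mk_binned <- function(x, p, side = "positive", n = 1000) {
  structure(list(bin_centers = x, probabilities = p,
                 n_stimuli = rep(n, length(x)), n_spikes = round(p * n),
                 side = side, axis = NULL, edges = NULL),
            class = "binned_probability")
}
mk_pair <- function(pos = NULL, neg = NULL) {
  structure(list(pos = pos, neg = neg), class = "binned_pair")
}

test_that("equal-spike binning puts the same number of spikes in every bin", {
  # 30 spikes evenly spread over the projection axis, 15 bins -> 2 per bin
  tr <- make_test_recording(n = 3000, seed = 41)
  v1 <- spike_triggered_cov(tr$ste)$eigenvectors_full[, 1]
  erf <- estimate_erfs(tr$ste, v1)
  binned <- bin_projections(tr$ste, erf, n_bins_per_side = 15)
  for (side in list(binned$pos, binned$neg)) {
    expect_true(max(side$n_spikes) - min(side$n_spikes) <= 1)
    expect_equal(side$probabilities, side$n_spikes / side$n_stimuli)
  }

  # an exactly even toy: 30 spikes at distinct projections, 15 bins -> 2 each
  S <- cbind(seq(10, 300, by = 10), 0)
  ste <- spike_triggered_ensemble(S, rep(1, 30))
  erf2 <- estimate_erfs(ste, c(1, 0))
  b2 <- bin_projections(ste, erf2, 15)
  expect_null(b2$neg)
  expect_true(all(b2$pos$n_spikes == 2))
})

test_that("identical projections collapse to one bin at the overall rate", {
  S <- matrix(rep(c(50, 0), each = 40), ncol = 2)
  ste <- spike_triggered_ensemble(S, rep(c(1, 0), 20))
  erf <- estimate_erfs(ste, c(1, 0))
  b <- bin_projections(ste, erf, 15)
  expect_length(b$pos$probabilities, 1)
  expect_equal(b$pos$probabilities, 0.5)
})

test_that("noiseless double-sigmoid samples are recovered to three significant figures", {
  x_pos <- seq(20, 300, length.out = 15)
  p_pos <- sigmoid_pos(x_pos, 0.9, 0.03, 150)
  x_neg <- seq(-300, -20, length.out = 15)
  p_neg <- sigmoid_neg(x_neg, 0.85, 0.025, -140)
  fit <- fit_double_sigmoid(mk_pair(mk_binned(x_pos, p_pos),
                                    mk_binned(x_neg, p_neg, "negative")))
  expect_equal(fit$a_plus, 0.9, tolerance = 1e-3)
  expect_equal(fit$b_plus, 0.03, tolerance = 1e-3)
  expect_equal(fit$c_plus, 150, tolerance = 1e-3)
  expect_equal(fit$a_minus, 0.85, tolerance = 1e-3)
  expect_equal(fit$c_minus, -140, tolerance = 1e-3)
  expect_gte(fit$r2, 0.999)
})

test_that("the sigmoid reaches half saturation exactly at its threshold", {
  expect_equal(sigmoid_pos(150, 0.8, 0.03, 150), 0.4)
  expect_equal(sigmoid_neg(-120, 0.6, 0.05, -120), 0.3)
})

test_that("fitted nonlinearities are monotone over the observed range", {
  tr <- make_test_recording(n = 4000, seed = 42)
  v1 <- spike_triggered_cov(tr$ste)$eigenvectors_full[, 1]
  erf <- estimate_erfs(tr$ste, v1)
  fit <- fit_double_sigmoid(bin_projections(tr$ste, erf))
  grid <- seq(-400, 400, length.out = 400)
  np <- sigmoid_pos(grid, fit$a_plus, fit$b_plus, fit$c_plus)
  nm <- sigmoid_neg(grid, fit$a_minus, fit$b_minus, fit$c_minus)
  expect_true(all(diff(np) >= 0))
  expect_true(all(diff(nm) <= 0))
})

test_that("prediction evaluates the additive double sigmoid and clips", {
  cell <- make_cell(seed = 43)
  model <- true_ln_model(cell)
  # stimulus orthogonal to both receptive fields
  w <- cell$w_true_plus
  orth <- numeric(20)
  orth[cell$significant_electrodes[1:2]] <-
    c(-w[cell$significant_electrodes[2]], w[cell$significant_electrodes[1]])
  expect_lt(abs(sum(orth * w)), 1e-9)
  sg <- cell$sigmoid
  expect_equal(predict(model, orth),
               sigmoid_pos(0, sg$a_plus, sg$b_plus, sg$c_plus) +
                 sigmoid_neg(0, sg$a_minus, sg$b_minus, sg$c_minus))

  # projection at threshold with a negligible off-side term: half saturation
  cell2 <- make_cell(seed = 44, a = 0.8)
  m2 <- true_ln_model(cell2)
  s_thr <- unit_vector(cell2$w_true_plus) * cell2$sigmoid$c_plus
  expect_equal(predict(m2, s_thr), 0.40, tolerance = 1e-3)

  # piecewise mode drops the off-side term
  p_sum <- predict(m2, s_thr)
  p_pw <- predict(m2, s_thr, mode = "piecewise")
  expect_lte(p_pw, p_sum)
  expect_equal(p_pw, 0.40, tolerance = 1e-6)
})

test_that("mean predicted probability matches the empirical spike rate", {
  tr <- make_test_recording(n = 6000, seed = 45)
  model <- true_ln_model(tr$cell)
  pred <- predict(model, tr$ens)
  rate <- mean(tr$rec$responses$short)
  se <- sqrt(mean(pred * (1 - pred)) / 6000)
  expect_lt(abs(mean(pred) - rate), 2 * se + 1e-12)
})

test_that("probabilities are invariant to a joint rescaling of stimuli and parameters", {
  cell <- make_cell(seed = 46)
  m <- true_ln_model(cell)
  S <- sample_white_noise(200, 20, 150, seed = 47)$amplitudes
  p1 <- predict(m, S)
  k <- 2.5
  cell2 <- make_cell(seed = 46, b = cell$sigmoid$b_plus / k,
                     c_plus = cell$sigmoid$c_plus * k)
  p2 <- predict(true_ln_model(cell2), S * k)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("binned-fit r2 approaches one as bin noise vanishes", {
  x <- seq(10, 300, length.out = 15)
  p_true <- sigmoid_pos(x, 0.9, 0.03, 150)
  r2s <- vapply(c(0.05, 0.01, 0), function(noise) {
    p <- pmin(1, pmax(0, p_true + withr::with_seed(48, rnorm(15, 0, noise))))
    fit_double_sigmoid(mk_pair(mk_binned(x, p)))$r2
  }, numeric(1))
  expect_true(all(diff(r2s) >= 0))
  expect_gte(r2s[3], 0.999)
})

test_that("the 2-D surface reproduces its grid nodes exactly", {
  tr <- make_test_recording(n = 8000, seed = 51)
  v1 <- unit_vector(tr$cell$w_true_plus)
  v2 <- numeric(20)
  v2[tr$cell$significant_electrodes[1:2]] <-
    c(-v1[tr$cell$significant_electrodes[2]],
      v1[tr$cell$significant_electrodes[1]])
  v2 <- unit_vector(v2)
  m2 <- fit_2d(tr$ste, v1, v2, grid_resolution = 7, min_count = 20)
  sup <- which(m2$supported, arr.ind = TRUE)
  mid <- sup[which.min(rowSums(abs(sweep(sup, 2, c(4, 4))))), ]
  node <- m2$v1 * m2$centers1[mid[1]] + m2$v2 * m2$centers2[mid[2]]
  expect_equal(predict(m2, node), m2$surface[mid[1], mid[2]],
               tolerance = 1e-10)
})

test_that("a separable cell gives a surface flat along the second axis", {
  tr <- make_test_recording(n = 20000, seed = 52)
  v1 <- unit_vector(tr$cell$w_true_plus)
  v2 <- numeric(20)
  v2[tr$cell$significant_electrodes[1:2]] <-
    c(-v1[tr$cell$significant_electrodes[2]],
      v1[tr$cell$significant_electrodes[1]])
  v2 <- unit_vector(v2)
  m2 <- fit_2d(tr$ste, v1, v2, grid_resolution = 5, min_count = 500)
  # per-x1-row spread across supported x2 cells stays within sampling noise
  spreads <- apply(m2$surface, 1, function(row) {
    row <- row[!is.na(row)]
    if (length(row) >= 2) diff(range(row)) else 0
  })
  expect_lt(max(spreads), 0.1)
})

test_that("the 2-D surface recovers a suppressive second axis", {
  # spiking is suppressed away from x2 = 0: at strong x1 drive, the fitted
  # surface must fall from the x2 center toward the x2 edges
  v2 <- numeric(20)
  base <- make_cell(seed = 61)
  v2[base$significant_electrodes[1:2]] <-
    c(-base$w_true_plus[base$significant_electrodes[2]],
      base$w_true_plus[base$significant_electrodes[1]])
  v2 <- unit_vector(v2)
  cell <- make_cell(seed = 61,
                    suppressive_axis = list(vector = v2, strength = 0.9,
                                            width = 80))
  ens <- sample_white_noise(20000, 20, 150, seed = 161)
  rec <- simulate_responses(cell, ens, seed = 261)
  ste <- spike_triggered_ensemble(ens, rec$responses)
  m2 <- fit_2d(ste, unit_vector(cell$w_true_plus), v2,
               grid_resolution = 9, min_count = 50)
  mid2 <- which.min(abs(m2$centers2))
  strong <- which(abs(m2$centers1) > 250)
  drop_seen <- vapply(strong, function(i) {
    row <- m2$surface[i, ]
    sup <- which(!is.na(row))
    if (!(mid2 %in% sup) || length(sup) < 3) return(NA_real_)
    row[mid2] - max(row[setdiff(sup, mid2)])
  }, numeric(1))
  drop_seen <- drop_seen[!is.na(drop_seen)]
  expect_gte(length(drop_seen), 2)
  expect_true(all(drop_seen > 0.1))

  # and the suppressive axis shows up as a low extreme eigenvalue
  spec <- spike_triggered_cov(ste)
  expect_lt(min(spec$normalized), 0.8)
})

test_that("for a 1-D cell the 2-D model adds no predictive power", {
  # the surface estimate carries a small discretization bias, so the 2-D
  # error may sit slightly above the 1-D error but never far from it
  diffs <- vapply(1:5, function(s) {
    cell <- make_cell(seed = 60 + s)
    ens <- sample_white_noise(10000, 20, 150, seed = 160 + s)
    rec <- simulate_responses(cell, ens, seed = 260 + s)
    ste <- spike_triggered_ensemble(ens, rec$responses)
    sp <- split_data(ste, 0.8, seed = 360 + s)
    spec <- spike_triggered_cov(sp$train)
    v1 <- spec$eigenvectors_full[, 1]
    erf <- estimate_erfs(sp$train, v1)
    m1 <- ln_model(erf, fit_double_sigmoid(bin_projections(sp$train, erf)))
    m2 <- fit_2d(sp$train, v1, spec$eigenvectors_full[, 2],
                 grid_resolution = 9, min_count = 50)
    compare_1d_2d(validation_error(m1, sp$test),
                  validation_error(m2, sp$test))$difference
  }, numeric(1))
  expect_lt(median(abs(diffs)), 0.05)
})
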