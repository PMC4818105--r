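test_that("spike-triggered covariance matches hand and brute-force results", {
  # two spike-eliciting stimuli on a 2-electrode array
  S <- rbind(c(1, 0), c(-1, 0), c(0, 0.1), c(0, -0.1))
  ens <- spike_triggered_ensemble(S, c(1, 1, 0, 0))
  spec <- spike_triggered_cov(ens)
  expect_equal(spec$eigenvalues, c(2, 0))
  expect_equal(abs(spec$eigenvectors[, 1]), c(1, 0))

  # brute-force covariance from the definitional sum on a random ensemble
  SD <- withr::with_seed(3, matrix(rnorm(500 * 5, 0, 120), 500, 5))
  ens2 <- spike_triggered_ensemble(SD, rep(1, 500))
  expect_error(spike_triggered_cov(ens2), NA)
  spec2 <- spike_triggered_cov(
    spike_triggered_ensemble(rbind(SD, matrix(0, 5, 5)),
                             c(rep(1, 500), rep(0, 5))))
  mu <- colMeans(SD)
  Cbf <- matrix(0, 5, 5)
  for (i in seq_len(500)) Cbf <- Cbf + tcrossprod(SD[i, ] - mu)
  Cbf <- Cbf / 499
  eg <- eigen(Cbf, symmetric = TRUE)
  expect_equal(spec2$eigenvalues, eg$values, tolerance = 1e-10)
  expect_equal(abs(spec2$eigenvectors), abs(eg$vectors), tolerance = 1e-8)

  # eigenvalue sum equals the covariance trace
  expect_equal(sum(spec2$eigenvalues), sum(diag(Cbf)), tolerance = 1e-10)
})

test_that("when every stimulus elicits a spike the normalized spectrum is flat", {
  ens <- sample_white_noise(10000, 20, 150, seed = 5)
  ste <- spike_triggered_ensemble(ens, rep(1, 10000))
  spec <- spike_triggered_cov(ste)
  expect_true(all(spec$normalized > 0.88 & spec$normalized < 1.12))
})

test_that("first eigenvector matches a 1-degree grid search over directions", {
  # 2-electrode toys: maximize projected variance of the spike subset
  for (s in 1:5) {
    SD <- withr::with_seed(s, {
      z <- matrix(rnorm(400 * 2), 400, 2)
      ang <- runif(1, 0, pi)
      R <- cbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
      z %*% diag(c(80, 20)) %*% t(R)
    })
    ste <- spike_triggered_ensemble(rbind(SD, matrix(0, 2, 2)),
                                    c(rep(1, 400), 0, 0))
    v1 <- spike_triggered_cov(ste)$eigenvectors[, 1]
    thetas <- (0:179) * pi / 180
    vars <- vapply(thetas, function(th) {
      var(SD %*% c(cos(th), sin(th)))
    }, numeric(1))
    best <- thetas[which.max(vars)]
    ang_v1 <- atan2(v1[2], v1[1]) %% pi
    d <- abs(ang_v1 - best) %% pi
    expect_lt(min(d, pi - d), pi / 180)
  }
})

test_that("significance test rejects degenerate responses and is invariant to joint permutation", {
  ens <- sample_white_noise(500, 6, 100, seed = 1)
  expect_error(significance_test(spike_triggered_ensemble(ens, rep(0, 500))),
               "degenerate")
  expect_error(significance_test(spike_triggered_ensemble(ens, rep(1, 500))),
               "degenerate")
  expect_error(
    significance_test(
      spike_triggered_ensemble(ens,
                               c(1, rep(0, 499))), n_shuffles = 50),
    "n_shuffles")

  # jointly permuting stimuli and responses leaves the spectrum unchanged
  r <- withr::with_seed(2, rbinom(500, 1, 0.3))
  ste_a <- spike_triggered_ensemble(ens, r)
  perm <- withr::with_seed(3, sample(500))
  ste_b <- spike_triggered_ensemble(ens$amplitudes[perm, ], r[perm])
  expect_equal(spike_triggered_cov(ste_a)$eigenvalues,
               spike_triggered_cov(ste_b)$eigenvalues, tolerance = 1e-10)
})

test_that("strength ratio follows its definition", {
  expect_equal(strength_ratio(13, 2, 1), 12)
})

test_that("polarity-split receptive fields average each projection side", {
  S <- rbind(c(2, 0), c(4, 0), c(-3, 0), c(0, 50))
  ste <- spike_triggered_ensemble(S, c(1, 1, 1, 0))
  erf <- estimate_erfs(ste, c(1, 0))
  expect_equal(erf$w_plus, c(3, 0))
  expect_equal(erf$w_minus, c(-3, 0))
  expect_equal(erf$corr, -1)
  # every spike-eliciting stimulus contributes to exactly one side
  expect_equal(erf$n_plus + erf$n_minus, 3)

  # one-sided cell: all spike-eliciting projections negative
  S2 <- rbind(c(-2, 0), c(-4, 0), c(5, 0))
  erf2 <- estimate_erfs(spike_triggered_ensemble(S2, c(1, 1, 0)), c(1, 0))
  expect_false(erf2$has_plus)
  expect_true(erf2$has_minus)
  expect_true(is.na(erf2$corr))
})

test_that("a symmetric cell yields strongly anticorrelated receptive fields", {
  tr <- make_test_recording(n = 6000, seed = 21)
  v1 <- spike_triggered_cov(tr$ste)$eigenvectors_full[, 1]
  erf <- estimate_erfs(tr$ste, v1)
  expect_lt(erf$corr, -0.9)
  expect_gt(cosine_sim(erf$w_plus, tr$cell$w_true_plus), 0.95)
})

test_that("electrode significance recovers the true support and stays quiet under the null", {
  # sensitivity: three true electrodes at n = 4000
  tr <- make_test_recording(n = 4000, seed = 31)
  sig <- significance_test(tr$ste, n_shuffles = 300, seed = 131)
  erf <- estimate_erfs(tr$ste, sig$significant[[1]]$axis)
  erf <- electrode_significance(tr$ste, sig, erf)
  expect_equal(which(erf$sig_plus), tr$cell$significant_electrodes)
  expect_equal(which(erf$sig_minus), tr$cell$significant_electrodes)

  # specificity: with stimulus-independent spiking the observed receptive
  # fields are draws from the same distribution as the shuffle nulls, so
  # the RMS rule flags electrodes only at its chance level (about
  # P(|z| > 1), i.e. roughly a third of electrodes), never the
  # concentrated low-count support characteristic of a real cell
  flagged <- vapply(1:5, function(s) {
    ens <- sample_white_noise(3000, 20, 150, seed = 500 + s)
    r <- withr::with_seed(600 + s, rbinom(3000, 1, 0.3))
    ste <- spike_triggered_ensemble(ens, r)
    sg <- significance_test(ste, n_shuffles = 300, seed = 700 + s)
    v1 <- sg$spectrum$eigenvectors_full[, 1]
    e <- electrode_significance(ste, sg, estimate_erfs(ste, v1))
    (sum(e$sig_plus) + sum(e$sig_minus)) / 2
  }, numeric(1))
  expect_lt(mean(flagged), 10)
  expect_gt(mean(flagged), 2)  # chance level, not spuriously tight bounds
})

test_that("receptive-field extent is the absolute-weighted mean distance", {
  expect_equal(erf_extent(c(0, 5, 0), c(1, 2.5, 4)), 2.5)
  expect_equal(erf_extent(c(1, 1, 1), c(1, 2, 6)), 3)
  expect_equal(erf_extent(c(2, 1), c(1, 4)), 2)
  expect_equal(erf_extent(c(-2, 1), c(1, 4)), 2)  # signs do not matter
  expect_error(erf_extent(c(0, 0), c(1, 2)), "undefined")
  expect_error(erf_extent(c(1, 1), c(1, -2)))
})
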