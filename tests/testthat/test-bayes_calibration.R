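test_that("posterior mean is the printed convex blend", {
  expect_equal(posterior_mean(0.5, 0.7, 0, 0.812), 0.7)    # zero variance
  expect_equal(posterior_mean(0.5, 0.5, 1.3, 0.812), 0.5)  # fixed point
  expect_equal(posterior_mean(0.5, 0.7, 0.812, 0.812), 0.6) # equal weights
  # always between prior and sample mean
  grid <- expand.grid(theta = c(-1, 0.2, 2), var = c(0, 0.1, 5),
                      w = c(0.05, 0.812, 10))
  for (i in seq_len(nrow(grid))) {
    e <- posterior_mean(0.5, grid$theta[i], grid$var[i], grid$w[i])
    expect_gte(e, min(0.5, grid$theta[i]) - 1e-12)
    expect_lte(e, max(0.5, grid$theta[i]) + 1e-12)
  }
  # weight limits: w -> Inf trusts the data, w -> 0 keeps the prior
  expect_equal(posterior_mean(0.5, 0.7, 1.3, 1e12), 0.7, tolerance = 1e-9)
  expect_equal(posterior_mean(0.5, 0.7, 1.3, 1e-12), 0.5, tolerance = 1e-9)
})

test_that("daily coefficient samples invert the model exactly", {
  driver <- c(0.5, 1, 2, 4, 0.01)
  a_true <- 0.15; b_true <- 0.74
  pm <- a_true + b_true * driver
  s <- daily_coefficient_samples(pm, driver, a = a_true, b = 0.5)
  expect_equal(s$b_samples, rep(b_true, 4)) # 0.01-driver day excluded
  expect_equal(s$n_excluded, 1L)
  s2 <- daily_coefficient_samples(pm, driver, a = 0, b = b_true)
  expect_equal(s2$a_samples, rep(a_true, 4))
  expect_error(daily_coefficient_samples(pm, rep(0.001, 5), 0.18, 0.5),
               "all days excluded")
})

test_that("noisy coefficient samples centre on the truth", {
  w <- synthetic_year(seed = 23)
  driver <- fr_driver(w)
  truth <- generate_fr_truth(w, a_true = 0.15, b_true = 0.74,
                             noise_sd = 0.1, seed = 23)
  s <- daily_coefficient_samples(truth$et0_mm, driver, a = 0.15, b = 0.74)
  se <- sd(s$b_samples) / sqrt(s$n_used)
  expect_lt(abs(mean(s$b_samples) - 0.74), 4 * se)
})

test_that("calibration shrinks toward the truth per the blend formula", {
  w <- synthetic_year(seed = 29)
  # noise-free planted truth: the run converges and agrees with the
  # independent oracle exactly. Note the fixed point is NOT the planted
  # truth: a mismatched intercept keeps spread in the per-day b samples,
  # so the variance term in the blend never vanishes and the alternation
  # settles where prior anchoring balances the induced spread.
  truth0 <- generate_fr_truth(w, a_true = 0.15, b_true = 0.74, noise_sd = 0)
  res0 <- calibrate_fr(w, standard = truth0)
  expect_true(res0$converged)
  orc0 <- oracle_calibrate(truth0$et0_mm, fr_driver(w))
  expect_equal(res0$a_post, orc0$a, tolerance = 1e-8)
  expect_equal(res0$b_post, orc0$b, tolerance = 1e-8)
  # a perfectly specified prior is a fixed point: starting at the truth
  # with zero noise, every sample equals the prior and nothing moves
  res_fix <- calibrate_fr(w, calibration_config(prior_a = 0.15,
                                                prior_b = 0.74),
                          standard = truth0)
  expect_equal(res_fix$a_post, 0.15, tolerance = 1e-9)
  expect_equal(res_fix$b_post, 0.74, tolerance = 1e-9)

  # tiny prior weight keeps the priors
  truth <- generate_fr_truth(w, a_true = 0.15, b_true = 0.74,
                             noise_sd = 0.3, seed = 31)
  res_p <- calibrate_fr(w, calibration_config(prior_weight = 1e-9),
                        standard = truth)
  expect_equal(res_p$a_post, 0.18, tolerance = 1e-3)
  expect_equal(res_p$b_post, 0.50, tolerance = 1e-3)

  # defaults agree with the independent straight-line oracle
  res <- calibrate_fr(w, standard = truth)
  orc <- oracle_calibrate(truth$et0_mm, fr_driver(w))
  expect_equal(res$a_post, orc$a, tolerance = 1e-8)
  expect_equal(res$b_post, orc$b, tolerance = 1e-8)
  expect_equal(res$iterations, orc$iterations)
  expect_lte(res$iterations, res$config$max_iter)
  expect_equal(nrow(res$trace), res$iterations)
})

test_that("a destabilising prior weight is reported, not hidden", {
  # with an overwhelming data weight the alternation amplifies the
  # intercept error by mean(d) * mean(1/d) >= 1 each cycle and need not
  # converge; the run still returns, flagged, matching the oracle
  w <- synthetic_year(seed = 29)
  truth <- generate_fr_truth(w, a_true = 0.15, b_true = 0.74,
                             noise_sd = 0.3, seed = 31)
  res_w <- calibrate_fr(w, calibration_config(prior_weight = 1e9),
                        standard = truth)
  orc_w <- oracle_calibrate(truth$et0_mm, fr_driver(w), w = 1e9)
  expect_equal(res_w$a_post, orc_w$a, tolerance = 1e-6)
  expect_equal(res_w$b_post, orc_w$b, tolerance = 1e-6)
})

test_that("every iteration's blend lies between prior and sample mean", {
  w <- synthetic_year(seed = 37)
  truth <- generate_fr_truth(w, 0.15, 0.74, noise_sd = 0.3, seed = 37)
  res <- calibrate_fr(w, standard = truth)
  tr <- res$trace
  for (i in seq_len(nrow(tr))) {
    expect_gte(tr$b[i], min(0.50, tr$theta_b[i]) - 1e-12)
    expect_lte(tr$b[i], max(0.50, tr$theta_b[i]) + 1e-12)
    expect_gte(tr$a[i], min(0.18, tr$theta_a[i]) - 1e-12)
    expect_lte(tr$a[i], max(0.18, tr$theta_a[i]) + 1e-12)
  }
})

test_that("calibration improves training RMSE and leaves R2 unchanged", {
  w <- synthetic_year(seed = 41)
  truth <- generate_fr_truth(w, 0.15, 0.74, noise_sd = 0.3, seed = 43)
  res <- calibrate_fr(w, standard = truth)
  fr0 <- compute_et0(w, "FR")
  fr1 <- compute_et0(w, "FR", res$params)
  m0 <- agreement_metrics(fr0, truth)
  m1 <- agreement_metrics(fr1, truth)
  expect_lte(m1$rmse, m0$rmse)
  # affine recalibration cannot change the squared correlation
  expect_equal(m0$r2, m1$r2, tolerance = 1e-12)
})
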