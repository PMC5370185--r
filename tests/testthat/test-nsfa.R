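test_that("decay variance spans peak to 10% of peak and nulls for identical events", {
  mod <- default_channel(sigma_b = 0)
  sw <- gen_channel_events(mod, 25, seed = 1)
  mat <- ideal_matrix(sw)
  # replace rows with the identical ensemble mean: zero variance everywhere
  mu <- colMeans(mat)
  mat_id <- matrix(rep(mu, each = 25), nrow = 25)
  attr(mat_id, "dt") <- sw$dt
  pts <- decay_variance(mat_id, min_events = 20)
  expect_true(all(pts$var_pA2 == 0))
  expect_equal(pts$mean_pA[1], max(mu))
  expect_lte(tail(pts$mean_pA, 1), 0.11 * max(mu))
  expect_error(decay_variance(mat_id[1:10, ], min_events = 20),
               "at least 20 successful events")
})

test_that("equal-width binning averages within bins and drops empty ones", {
  pts <- data.frame(mean_pA = seq(1, 15, length.out = 150),
                    var_pA2 = rep(2, 150))
  b <- bin_variance(pts, n_bins = 15)
  expect_equal(nrow(b), 15L)
  expect_true(all(b$n == 10))
  b1 <- bin_variance(pts, n_bins = 1)
  expect_equal(b1$mean_pA, mean(pts$mean_pA))
  expect_error(bin_variance(data.frame(mean_pA = rep(3, 5), var_pA2 = 1)),
               "degenerate")
})

test_that("parabola fit inverts analytically generated bins to machine precision", {
  for (par in list(c(-1.5, 30, 4), c(-0.7, 80, 1.2), c(-2.5, 12, 0.5))) {
    bins <- analytic_bins(par[1], par[2], par[3])
    f <- fit_parabola(bins)
    expect_equal(f$i, par[1], tolerance = 1e-9)
    expect_equal(f$n_channels, par[2], tolerance = 1e-7)
    expect_equal(f$sigma_b2, par[3], tolerance = 1e-9)
    expect_lt(f$rss, 1e-18)
  }
  expect_error(fit_parabola(analytic_bins()[1:2, ]), "at least 3")
})

test_that("flat variance yields near-zero single-channel current", {
  bins <- data.frame(mean_pA = seq(-25, -2, length.out = 15), var_pA2 = 4)
  f <- fit_parabola(bins)
  expect_equal(f$i, 0, tolerance = 1e-8)
  expect_equal(f$sigma_b2, 4, tolerance = 1e-6)
})

test_that("conductance converts pA and mV to pS, with guards", {
  expect_equal(conductance(-1.524, -60, 0), 25.4)
  expect_equal(conductance(0, -60, 0), 0)
  expect_equal(conductance(-3.048, -60, 0), 2 * conductance(-1.524, -60, 0))
  expect_error(conductance(1, -60, -60), "differ")
})

test_that("binned and unbinned parabola fits agree on dense synthetic data", {
  mod <- default_channel()
  sw <- gen_channel_events(mod, 400, seed = 5)
  mat <- ideal_matrix(sw)
  sc <- peak_scale(mat)
  attr(sc, "dt") <- sw$dt
  pts <- decay_variance(sc)
  pts_signed <- data.frame(mean_pA = -pts$mean_pA, var_pA2 = pts$var_pA2)
  f_binned <- fit_parabola(bin_variance(pts_signed, 15))
  f_unbinned <- fit_parabola(pts_signed)
  expect_equal(f_binned$i, f_unbinned$i, tolerance = 0.03)
})

test_that("the full pipeline recovers single-channel current from synthetic events", {
  mod <- default_channel()           # gamma 25.4 pS, i = -1.524 pA
  sw <- gen_channel_events(mod, 300, seed = 77)
  fit <- nsfa(sw, config = run_config())
  expect_s3_class(fit, "nsfa")
  expect_equal(coef(fit)[["i"]], mod$i, tolerance = 0.1)
  expect_equal(fit$gamma_pS, attr(sw, "truth")$gamma_pS, tolerance = 0.1)
  expect_gte(fit$n_events_used, 20)
  # methods are coherent
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), fit$bins$var_pA2 - fitted(fit))
  expect_output(print(fit), "gamma")
  expect_output(print(summary(fit)), "variance bins")
})

test_that("recovery error does not grow with more events", {
  mod <- default_channel()
  med_err <- vapply(c(30, 150, 500), function(ne) {
    errs <- vapply(1:5, function(k) {
      f <- nsfa(gen_channel_events(mod, ne, seed = 100 + k),
                config = run_config(min_events = 20))
      abs(f$gamma_pS - 25.4) / 25.4
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0.005))
})

test_that("peak scaling removes receptor-number variance at the peak", {
  m1 <- channel_model(n_channels = 18, i = -1.524, p_peak = 0.6, sigma_b = 1)
  m2 <- channel_model(n_channels = 42, i = -1.524, p_peak = 0.6, sigma_b = 1)
  mat <- rbind(ideal_matrix(gen_channel_events(m1, 120, seed = 7)),
               ideal_matrix(gen_channel_events(m2, 120, seed = 8)))
  attr(mat, "dt") <- 1e-5
  pk_col <- which.max(colMeans(mat))
  v_unscaled <- var(mat[, pk_col])
  v_scaled <- var(peak_scale(mat)[, pk_col])
  # analytic gating variance of the homogeneous average ensemble
  v_homog <- 1.524^2 * 30 * 0.6 * 0.4 + 1
  expect_gt(v_unscaled, 2 * v_homog)
  expect_lt(v_scaled, 2 * v_homog)
})

test_that("NSFA refuses cells below the minimum event count, citing the rule", {
  mod <- default_channel()
  sw <- gen_channel_events(mod, 10, seed = 3)
  expect_error(nsfa(sw, config = run_config(min_events = 20)),
               "at least 20 successful events")
})
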