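test_that("generators are deterministic given model and seed", {
  mod <- default_channel()
  a <- gen_channel_events(mod, 5, seed = 3)
  b <- gen_channel_events(mod, 5, seed = 3)
  expect_identical(lapply(a$sweeps, `[[`, "samples"),
                   lapply(b$sweeps, `[[`, "samples"))
  mt <- mini_train_model(duration_s = 5)
  expect_identical(gen_mini_recording(mt, seed = 4)$samples,
                   gen_mini_recording(mt, seed = 4)$samples)
  fm <- frap_model()
  expect_identical(gen_frap_trace(fm, seed = 5)$bleached$samples,
                   gen_frap_trace(fm, seed = 5)$bleached$samples)
})

test_that("channel-model edge cases behave analytically", {
  null <- channel_model(n_channels = 5, i = 0, p_peak = 0.5, sigma_b = 0)
  sw <- gen_channel_events(null, 3, seed = 1)
  expect_true(all(vapply(sw$sweeps, function(s) all(s$samples == 0), logical(1))))
  one <- channel_model(n_channels = 1, i = -2, p_peak = 1, sigma_b = 0)
  sw1 <- gen_channel_events(one, 5, seed = 2)
  expect_true(all(vapply(sw1$sweeps, function(s) min(s$samples) == -2, logical(1))))
  expect_error(channel_model(p_peak = 1.2), "p_peak")
  expect_error(channel_model(tau_rise_ms = 10, tau_decay_ms = 9), "tau_rise")
})

test_that("simulated ensemble matches the binomial mean and variance", {
  mod <- default_channel(sigma_b = 2)
  n_ev <- 5000
  sw <- gen_channel_events(mod, n_ev, dt = 2e-4, seed = 10, sweep_s = 0.04,
                           onset_s = 0.004)
  mat <- t(vapply(sw$sweeps, `[[`, numeric(200), "samples"))
  t_ms <- (0:199) * 0.2 - 4
  p <- mod$p_peak * biexp_waveform(t_ms, mod$tau_rise_ms, mod$tau_decay_ms)
  cols <- round(seq(25, 195, length.out = 20))
  for (j in cols) {
    mu_th <- mod$i * mod$n_channels * p[j]
    v_th <- mod$i^2 * mod$n_channels * p[j] * (1 - p[j]) + mod$sigma_b^2
    se_mu <- sqrt(v_th / n_ev)
    z_mu <- abs(mean(mat[, j]) - mu_th) / se_mu
    # variance of the sample variance ~ 2 v^2 / (n - 1) for near-normal sums
    z_v <- abs(var(mat[, j]) - v_th) / sqrt(2 * v_th^2 / (n_ev - 1))
    expect_lt(z_mu, 4)
    expect_lt(z_v, 4)
  }
})

test_that("mini-train ground truth matches the Poisson rate", {
  m <- mini_train_model(rate = 2, duration_s = 20, dt = 1e-3, noise_sd = 0.5)
  counts <- vapply(1:50, function(s) nrow(attr(gen_mini_recording(m, seed = s),
                                               "truth")), numeric(1))
  lambda <- m$rate * m$duration_s
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 50))
  m0 <- mini_train_model(rate = 0, duration_s = 2, noise_sd = 1)
  rec0 <- gen_mini_recording(m0, seed = 1)
  expect_equal(nrow(attr(rec0, "truth")), 0L)
  expect_equal(length(rec0), 20000L)
})

test_that("FRAP generator honours its construction identities", {
  full <- frap_model(plateau = 1, k_acq = 1, noise_sd = 0, f_post = 0.05)
  tr <- gen_frap_trace(full, n_frames = 40, bleach_frame = 5, seed = 1)
  expect_equal(tail(tr$bleached$samples, 1), full$f_pre, tolerance = 0.01)
  immob <- frap_model(plateau = 0, f_post = 0, k_acq = 1, noise_sd = 0)
  tri <- gen_frap_trace(immob, n_frames = 20, bleach_frame = 5, seed = 1)
  expect_true(all(tri$bleached$samples[5:20] == 0))
  geo <- gen_frap_trace(frap_model(k_acq = 0.999, noise_sd = 0),
                        n_frames = 15, bleach_frame = 5, seed = 1)
  ref <- geo$reference$samples
  expect_equal(ref[-1] / ref[-15], rep(0.999, 14))
  expect_error(gen_frap_trace(frap_model(), n_frames = 10, bleach_frame = 12),
               "bleach_frame")
})

test_that("I/V family reproduces ohmic ratios and full block", {
  fam <- gen_iv_family(iv_model(g = 2, erev = 0, block = FALSE))
  expect_equal(unname(fam$currents), c(-120, 0, 80))
  blocked <- iv_model(g = 2, v_half = -200, slope = 1)  # block ~ total at +40
  expect_equal(gen_iv_family(blocked)$currents[["40"]], 0, tolerance = 1e-10)
  expect_error(gen_iv_family(iv_model(), potentials = numeric(0)), "non-empty")
  # ramp agrees with pointwise model evaluation
  fam2 <- gen_iv_family(iv_model(g = 1.5), ramp = TRUE)
  v <- seq(-100, 100, length.out = length(fam2$ramp$samples))
  j <- which.min(abs(v + 60))
  expect_equal(fam2$ramp$samples[j], fam2$currents[["-60"]], tolerance = 1e-3)
})

test_that("evoked-pair generator encodes its inputs exactly when noiseless", {
  p <- gen_evoked_pair(ampar_peak = 80, nmdar_peak = 30, ppr = 1, noise_sd = 0)
  x <- -p$paired$samples
  i1 <- round(p$truth$onset_s / p$paired$dt) + 1L
  i2 <- i1 + round(0.05 / p$paired$dt)
  expect_equal(max(x[i1:(i2 - 1)]), 80, tolerance = 1e-6)
  expect_error(gen_evoked_pair(ppr = -1), "ppr")
  j100 <- i1 + round(0.1 / p$plus40$dt)
  expect_equal(p$plus40$samples[j100], 30, tolerance = 0.02)
})
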