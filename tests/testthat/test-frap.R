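test_that("reference correction + normalization exactly inverts acquisition bleaching", {
  m <- frap_model(plateau = 0.63, tau_rec_s = 197.3, k_acq = 0.995, noise_sd = 0)
  tr <- gen_frap_trace(m, n_frames = 26, bleach_frame = 6, seed = 1)
  norm <- normalize_prebleach(bleach_correct(tr$bleached, tr$reference, 6), 6)
  m1 <- frap_model(plateau = 0.63, tau_rec_s = 197.3, k_acq = 1, noise_sd = 0)
  ideal <- gen_frap_trace(m1, n_frames = 26, bleach_frame = 6, seed = 1)
  expect_equal(norm$samples, ideal$bleached$samples / m1$f_pre,
               tolerance = 1e-12)
})

test_that("constant reference is an identity correction", {
  b <- sweep_trace(c(1, 1, 0.2, 0.5, 0.7, 0.8), dt = 30,
                   signal_kind = "fluorescence")
  ref <- sweep_trace(rep(2, 6), dt = 30, signal_kind = "fluorescence")
  expect_equal(bleach_correct(b, ref, 3)$samples, b$samples)
  ref0 <- sweep_trace(c(2, 2, 0, 2, 2, 2), dt = 30, signal_kind = "fluorescence")
  expect_error(bleach_correct(b, ref0, 3), "zero intensity")
})

test_that("pre-bleach normalization pins the pre-bleach mean at one", {
  set.seed(9)
  s <- sweep_trace(runif(20, 0.5, 2), dt = 30, signal_kind = "fluorescence")
  n <- normalize_prebleach(s, bleach_frame = 8)
  expect_equal(mean(n$samples[1:7]), 1)
  expect_error(normalize_prebleach(s, bleach_frame = 2), "at least 2")
})

test_that("noiseless recovery fits reproduce the generating curve", {
  m <- frap_model(plateau = 0.8, tau_rec_s = 100, f_post = 0.1,
                  k_acq = 1, noise_sd = 0)
  tr <- gen_frap_trace(m, n_frames = 26, bleach_frame = 6, seed = 1)
  fit <- frap(tr$bleached, tr$reference, bleach_frame = 6)
  expect_equal(fit$tau_rec_s, 100, tolerance = 1e-5)
  expect_equal(fit$plateau, 0.8, tolerance = 1e-6)
  expect_equal(fit$immobile_fraction, 0.2, tolerance = 1e-6)
  # full-recovery model converges to the pre-bleach level
  mf <- frap_model(plateau = 1, tau_rec_s = 60, k_acq = 1, noise_sd = 0)
  trf <- gen_frap_trace(mf, n_frames = 40, bleach_frame = 6, seed = 1)
  ff <- frap(trf$bleached, trf$reference, bleach_frame = 6)
  expect_equal(ff$plateau, 1, tolerance = 1e-4)
})

test_that("an immobile trace is flagged as tau-unidentifiable", {
  m <- frap_model(plateau = 0.049, f_post = 0.05, tau_rec_s = 100,
                  k_acq = 1, noise_sd = 0)
  tr <- gen_frap_trace(m, n_frames = 20, bleach_frame = 6, seed = 1)
  fit <- frap(tr$bleached, tr$reference, bleach_frame = 6)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$tau_rec_s))
})

test_that("bleach correction is unbiased under noise", {
  m <- frap_model(plateau = 0.7, tau_rec_s = 150, k_acq = 0.995, noise_sd = 0.03)
  ideal <- ampafluct:::frap_ideal(m, (0:25) * 30, 5 * 30)
  errs <- vapply(1:50, function(s) {
    tr <- gen_frap_trace(m, n_frames = 26, bleach_frame = 6, seed = s)
    norm <- normalize_prebleach(bleach_correct(tr$bleached, tr$reference, 6), 6)
    mean(norm$samples[10:26] - ideal[10:26])
  }, numeric(1))
  # Monte-Carlo SE of the mean error
  expect_lt(abs(mean(errs)), 4 * sd(errs) / sqrt(50))
})

test_that("recovered tau is unbiased across seeds when well sampled", {
  m <- frap_model(plateau = 0.8, tau_rec_s = 90, frame_interval_s = 30,
                  noise_sd = 0.02)
  taus <- vapply(1:50, function(s) {
    tr <- gen_frap_trace(m, n_frames = 26, bleach_frame = 6, seed = s)
    frap(tr$bleached, tr$reference, bleach_frame = 6)$tau_rec_s
  }, numeric(1))
  expect_lt(abs(median(taus) - 90) / 90, 0.10)
})

test_that("frap_fit methods are coherent", {
  m <- frap_model(noise_sd = 0.02)
  tr <- gen_frap_trace(m, seed = 4)
  fit <- frap(tr$bleached, tr$reference, bleach_frame = 6)
  expect_named(coef(fit), c("tau_rec_s", "plateau", "f0"))
  expect_length(predict(fit, c(0, 600)), 2L)
  expect_equal(length(residuals(fit)), length(fit$t_post))
  expect_output(print(fit), "tau")
  expect_output(print(summary(fit)), "residual SD")
})
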