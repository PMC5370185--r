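test_that("template matches its invariants", {
  tpl <- mepsc_template(0.5, 9, dt = 1e-4)
  expect_equal(max(tpl$samples), 1)
  expect_gte(length(tpl$samples) * 1e-4 * 1000, 5 * 9)
  expect_error(mepsc_template(0.5, 9, dt = 1e-4, length_ms = 20),
               "5 decay time constants")
})

test_that("noiseless injected events are detected with full recall and precision", {
  sw <- noiseless_mini_sweep(n_events = 5, amp = 20)
  tpl <- mepsc_template(dt = sw$dt)
  ev <- detect_events(sw, tpl, threshold = 4)
  expect_equal(nrow(ev), 5L)
  expect_equal(ev$onset_s, attr(sw, "onsets"), tolerance = 2 * sw$dt)
  expect_equal(ev$amplitude_pA, rep(20, 5), tolerance = 0.02)
})

test_that("pure-noise sweeps yield a negligible false-positive rate", {
  tpl <- mepsc_template(dt = 1e-4)
  total_fp <- 0
  for (s in 1:5) {
    set.seed(s)
    noise <- sweep_trace(rnorm(2e5, 0, 2), dt = 1e-4, signal_kind = "current")
    total_fp <- total_fp + nrow(detect_events(noise, tpl, threshold = 4))
  }
  expect_lt(total_fp / (5 * 20), 0.1)   # Hz over 5 x 20 s
})

test_that("detection-criterion threshold sets the amplitude detection limit", {
  set.seed(21)
  noise <- sweep_trace(rnorm(5e4, 0, 2), dt = 1e-4, signal_kind = "current")
  ev <- detect_events(noise, mepsc_template(dt = 1e-4), threshold = 4)
  expect_equal(attr(ev, "detection_limit_pA"), 8, tolerance = 0.5)
})

test_that("rise time is the interpolated 10-90% interval", {
  # linear ramp 0 -> peak over exactly 1 ms then plateau
  dt <- 1e-5
  ramp <- c(seq(0, 10, length.out = 101), rep(10, 50))
  expect_equal(rise_time_10_90(ramp, dt, peak_idx = 101), 0.8, tolerance = 1e-6)
  w <- biexp_waveform((0:4000) * dt * 1000, 0.5, 9)
  r <- rise_time_10_90(w, dt)
  expect_gt(r, 0.5); expect_lt(r, 0.9)
})

test_that("decay fitting recovers exponential time constants", {
  dt <- 1e-5
  y <- c(rep(0, 10), 10 * exp(-(0:3000) * dt * 1000 / 9))
  expect_equal(decay_tau(y, dt, peak_idx = 11), 9, tolerance = 0.05)
  wav <- 15 * biexp_waveform((0:3500) * dt * 1000, 0.3, 9)
  expect_equal(decay_tau(wav, dt), 9, tolerance = 0.45)
})

test_that("QC implements the rise-time cutoff and the 20-event rule", {
  ev <- data.frame(event_id = 1:3, sweep_id = "s",
                   onset_s = c(0.5, 1.5, 2.5), peak_s = c(0.51, 1.51, 2.51),
                   steepest_idx = 1:3, amplitude_pA = c(10, 12, 14),
                   rise_10_90_ms = c(0.5, 1.0, 0.85),
                   decay_tau_ms = c(9, 9, 9), score = 5, qc_pass = TRUE)
  q <- qc_filter(ev, rise_cutoff_ms = 0.9, min_events = 20)
  expect_equal(q$events$event_id, c(1L, 3L))   # 1.0 ms event excluded
  expect_false(q$cell_pass)                    # 2 < 20
  ev19 <- ev[rep(1, 19), ]; ev19$onset_s <- seq(1, 19) * 0.5
  expect_false(qc_filter(ev19, min_events = 20)$cell_pass)
  ev20 <- ev[rep(1, 20), ]; ev20$onset_s <- seq(1, 20) * 0.5
  expect_true(qc_filter(ev20, min_events = 20)$cell_pass)
  # overlapping neighbours are excluded
  evo <- ev[rep(1, 3), ]; evo$onset_s <- c(0.5, 0.52, 2)
  expect_equal(nrow(qc_filter(evo, overlap_ms = 90, min_events = 1)$events), 1L)
})

test_that("alignment of identical noiseless events nulls column variance", {
  sw <- noiseless_mini_sweep(n_events = 6, amp = 20)
  tpl <- mepsc_template(dt = sw$dt)
  ev <- detect_events(sw, tpl)
  mat <- align_events(sw, ev, pre_ms = 2, post_ms = 30)
  expect_equal(nrow(mat), 6L)
  expect_lt(max(apply(mat, 2, var)), 1e-12)
  # empty event list
  m0 <- align_events(sw, ev[0, ])
  expect_equal(nrow(m0), 0L)
})

test_that("alignment recovers deliberately jittered event timing", {
  dt <- 1e-4
  wav_len <- round(8 * 9 / 1000 / dt)
  wav <- biexp_waveform((seq_len(wav_len) - 1) * dt * 1000, 0.5, 9)
  n <- round(4 / dt)
  x <- numeric(n)
  jit <- c(-3, 2, 0, 3, -2, 1)
  onsets0 <- round(seq(0.5, 3, length.out = 6) / dt) + 1L
  for (k in seq_along(jit)) {
    i0 <- onsets0[k] + jit[k]
    x[i0:(i0 + wav_len - 1L)] <- x[i0:(i0 + wav_len - 1L)] - 20 * wav
  }
  sw <- sweep_trace(x, dt = dt, signal_kind = "current")
  ev <- detect_events(sw, mepsc_template(dt = dt))
  mat <- align_events(sw, ev)
  expect_equal(nrow(mat), 6L)
  # cross-correlation of each aligned row with the first peaks at zero lag
  ref <- mat[1, ] - mean(mat[1, ])
  for (r in 2:6) {
    cc <- ccf(mat[r, ], mat[1, ], lag.max = 5, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("peak scaling equalizes peaks, is idempotent, preserves peak time", {
  m <- rbind(c(0, 5, 10, 4, 1), c(0, 10, 20, 8, 2))
  s <- peak_scale(m)
  expect_equal(apply(s, 1, max), c(15, 15))
  expect_equal(unname(apply(s, 1, which.max)), c(3, 3))
  expect_equal(peak_scale(s), s, ignore_attr = TRUE)
  expect_equal(var(s[, 3]), 0)
  # zero-amplitude event dropped
  s2 <- peak_scale(rbind(m, 0))
  expect_equal(nrow(s2), 2L)
})

test_that("mini summaries and the equal-count pooled ECDF are correct", {
  ev <- data.frame(amplitude_pA = rnorm(30, 15), decay_tau_ms = 9)
  s <- summarize_minis(ev, duration_s = 60)
  expect_equal(s$frequency_hz, 0.5)
  expect_error(summarize_minis(ev, duration_s = 0), "positive")
  cells <- list(a = data.frame(amplitude_pA = rnorm(50, 10)),
                b = data.frame(amplitude_pA = rnorm(80, 20)),
                c = data.frame(amplitude_pA = rnorm(120, 30)))
  p <- pooled_ecdf(cells, seed = 1)
  expect_equal(p$n_per_cell, 50L)
  expect_length(p$amplitudes, 150L)
  single <- pooled_ecdf(cells["a"], seed = 1)
  expect_equal(sort(single$amplitudes), sort(cells$a$amplitude_pA))
})
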