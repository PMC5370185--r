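test_that("rectification index follows its defining ratio", {
  g <- 1.5
  ohmic <- holding_measurements(-60 * g, 0, 40 * g)
  expect_equal(rectification_index(ohmic), 2 / 3)
  blocked <- holding_measurements(-60 * g, 0, 0)
  expect_equal(rectification_index(blocked), 0)
  expect_error(rectification_index(holding_measurements(5, 5, 1)), "undefined")
})

test_that("rectification index is invariant to uniform current scaling", {
  h1 <- holding_measurements(-90, -2, 12)
  h2 <- holding_measurements(-90 * 7.3, -2 * 7.3, 12 * 7.3)
  expect_equal(rectification_index(h1), rectification_index(h2))
})

test_that("ohmic models give RI = 2/3 for any conductance; block depresses it", {
  for (g in c(0.2, 1, 5)) {
    fam <- gen_iv_family(iv_model(g = g, erev = 0, block = FALSE))
    expect_equal(rectification_index(fam$holding), 2 / 3)
  }
  ri_blocked <- rectification_index(gen_iv_family(iv_model())$holding)
  expect_gt(ri_blocked, 0.1)
  expect_lt(ri_blocked, 0.2)
})

test_that("ramp I/V with background subtraction matches the step protocol", {
  mod <- iv_model(g = 1.5)
  fam <- gen_iv_family(mod, ramp = TRUE)
  blank <- sweep_trace(rep(0, length(fam$ramp$samples)), dt = fam$ramp$dt,
                       signal_kind = "current",
                       meta = list(v_start = -100, v_end = 100))
  riv <- ramp_iv(fam$ramp, blank)
  expect_equal(riv$ri, rectification_index(fam$holding), tolerance = 0.02)
  # blank == glu cancels exactly
  zero <- ramp_iv(fam$ramp, fam$ramp)
  expect_true(all(zero$i == 0))
  # ohmic ramp: extracted I(-60)/I(+40) = -1.5
  fam_o <- gen_iv_family(iv_model(g = 2, block = FALSE), ramp = TRUE)
  riv_o <- ramp_iv(fam_o$ramp, blank)
  expect_equal(riv_o$holding$i_minus60 / riv_o$holding$i_plus40, -1.5,
               tolerance = 0.01)
  short <- sweep_trace(1:10, dt = fam$ramp$dt, signal_kind = "current")
  expect_error(ramp_iv(fam$ramp, short), "share length")
})

test_that("KA/Glu ratio is a guarded ratio of magnitudes", {
  expect_equal(ka_glu_ratio(50, 50), 1)
  expect_equal(ka_glu_ratio(0, 80), 0)
  expect_equal(ka_glu_ratio(-48, -100), 0.48)
  expect_error(ka_glu_ratio(10, 0), "undefined")
})

test_that("AMPAR/NMDAR ratio recovers generator inputs", {
  p <- gen_evoked_pair(ampar_peak = 107.2, nmdar_peak = 40, ppr = 1, noise_sd = 0)
  an <- ampar_nmdar_ratio(p$minus60, p$plus40, onset_s = p$truth$onset_s)
  expect_equal(an$ratio, 2.68, tolerance = 0.01)
  # AMPAR-null cell (Cre-like): ratio 0
  p0 <- gen_evoked_pair(ampar_peak = 0, nmdar_peak = 40, noise_sd = 0)
  an0 <- ampar_nmdar_ratio(p0$minus60, p0$plus40, onset_s = p0$truth$onset_s)
  expect_equal(an0$ratio, 0, tolerance = 1e-6)
  # NMDAR-null: flagged undefined
  pn <- gen_evoked_pair(ampar_peak = 100, nmdar_peak = 0, noise_sd = 0)
  ann <- ampar_nmdar_ratio(pn$minus60, pn$plus40, onset_s = pn$truth$onset_s)
  expect_false(ann$defined)
  expect_true(is.na(ann$ratio))
})

test_that("paired-pulse ratio uses tail extrapolation under the second pulse", {
  for (ppr_true in c(0.5, 1, 2)) {
    p <- gen_evoked_pair(ampar_peak = 100, ppr = ppr_true, noise_sd = 0)
    r <- paired_pulse_ratio(p$paired, p$truth$onset_s + c(0, 0.05))
    expect_equal(r$ppr, ppr_true, tolerance = 0.02 * max(ppr_true, 1))
  }
  p0 <- gen_evoked_pair(ampar_peak = 100, ppr = 0, noise_sd = 0)
  r0 <- paired_pulse_ratio(p0$paired, p0$truth$onset_s + c(0, 0.05))
  expect_equal(r0$ppr, 0, tolerance = 0.02)
  expect_error(paired_pulse_ratio(p0$paired, c(0.02, 0.09)), "50 ms")
})

test_that("LTP timecourse bins by minute and normalizes to pre-induction", {
  tt <- seq(-300, 3000, by = 10)
  const <- ltp_timecourse(rep(80, length(tt)), tt, induction_time_s = 0)
  expect_true(all(abs(const$norm_amplitude - 1) < 1e-12))
  step <- ltp_timecourse(ifelse(tt < 0, 80, 160), tt, 0)
  expect_true(all(step$norm_amplitude[step$t_min > 0] == 2))
  # decaying potentiation: x2.4 decaying with tau = 20 min -> < 1.3 at +45 min
  amp <- ifelse(tt < 0, 100, 100 * (1 + 1.4 * exp(-tt / (20 * 60))))
  dec <- ltp_timecourse(amp, tt, 0)
  expect_lt(dec$norm_amplitude[which.min(abs(dec$t_min - 45.5))], 1.3)
  expect_error(ltp_timecourse(rep(1, 5), 1:5, induction_time_s = 0),
               "no pre-induction")
})
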