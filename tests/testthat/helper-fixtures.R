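# Shared fixtures: all synthetic, built in code at test time.

default_channel <- function(gamma_pS = 25.4, sigma_b = 2)
  channel_model(n_channels = 30, i = gamma_pS * -60 / 1000, p_peak = 0.6,
                tau_rise_ms = 0.5, tau_decay_ms = 9, sigma_b = sigma_b)

# analytic variance-mean bins from exact parabola parameters
analytic_bins <- function(i = -1.5, n_channels = 30, sigma_b2 = 4,
                          I = seq(-27, -2, length.out = 15)) {
  data.frame(mean_pA = I,
             var_pA2 = i * I - I^2 / n_channels + sigma_b2,
             n = rep(10L, length(I)))
}

# ideal aligned event matrix from a channel model without running detection:
# fixed true onset, window 2 ms before / 30 ms after the 5 ms onset
ideal_matrix <- function(sweeps) {
  dt <- sweeps$dt
  a <- round(0.003 / dt) + 1L
  b <- round(0.035 / dt) + 1L
  m <- t(vapply(sweeps$sweeps, function(s) -s$samples[a:b], numeric(b - a + 1L)))
  attr(m, "dt") <- dt
  m
}

noiseless_mini_sweep <- function(n_events = 5, amp = 20, dt = 1e-4,
                                 spacing_s = 0.5, tau_rise = 0.5, tau_decay = 9) {
  dur <- spacing_s * (n_events + 1)
  n <- round(dur / dt)
  x <- numeric(n)
  onsets <- spacing_s * seq_len(n_events)
  wav_len <- round(8 * tau_decay / 1000 / dt)
  wav <- biexp_waveform((seq_len(wav_len) - 1) * dt * 1000, tau_rise, tau_decay)
  for (o in onsets) {
    i0 <- round(o / dt) + 1L
    x[i0:(i0 + wav_len - 1L)] <- x[i0:(i0 + wav_len - 1L)] - amp * wav
  }
  out <- sweep_trace(x, dt = dt, signal_kind = "current")
  attr(out, "onsets") <- onsets
  out
}
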