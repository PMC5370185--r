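# Synthetic recording generators.  Every generator is deterministic given
# (model, seed) and exports the ground truth needed to score downstream
# parameter recovery without re-simulation.

#' Peak-normalized biexponential waveform
#'
#' Difference of exponentials \code{exp(-t/tau_decay) - exp(-t/tau_rise)},
#' scaled to unit peak.  The canonical shape of an AMPAR synaptic current.
#'
#' @param t Times (ms or s; any unit, as long as the taus match).
#' @param tau_rise,tau_decay Rise/decay time constants (same unit as t);
#'   \code{tau_rise < tau_decay}.
#' @return Waveform values, zero for \code{t < 0}, unit peak.
#' @export
biexp_waveform <- function(t, tau_rise, tau_decay) {
  if (tau_rise >= tau_decay) stop("tau_rise must be below tau_decay")
  w <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  w / (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
}

#' Stochastic channel-ensemble model
#'
#' Describes a postsynaptic ensemble of \code{n_channels} independently gated
#' channels with single-channel current \code{i}.  At each instant the open
#' count is Binomial(\code{n_channels}, \code{p(t)}) with
#' \code{p(t) = p_peak * w(t)}, \code{w} the unit-peak biexponential.
#'
#' @param n_channels Number of channels (integer >= 1).
#' @param i Single-channel current in pA, signed (negative for inward).
#' @param p_peak Peak open probability in (0, 1].
#' @param tau_rise_ms,tau_decay_ms Gating envelope kinetics (ms).
#' @param sigma_b Baseline (recording) noise SD in pA.
#' @return A list of class \code{"channel_model"}.
#' @export
channel_model <- function(n_channels = 30, i = -1.524, p_peak = 0.6,
                          tau_rise_ms = 0.5, tau_decay_ms = 9, sigma_b = 2) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (p_peak <= 0 || p_peak > 1) stop("p_peak must lie in (0, 1]")
  if (tau_rise_ms >= tau_decay_ms) stop("tau_rise_ms must be below tau_decay_ms")
  if (sigma_b < 0) stop("sigma_b must be >= 0")
  structure(list(n_channels = as.integer(n_channels), i = i, p_peak = p_peak,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 sigma_b = sigma_b),
            class = "channel_model")
}

#' Simulate an ensemble of synaptic-current events from a channel model
#'
#' Each event is an independent sweep \code{I(t) = i * B_t + eps_t} with
#' \code{B_t ~ Binomial(N, p(t))} drawn independently per sample and
#' \code{eps_t ~ Normal(0, sigma_b)}.  Events start \code{onset_s} into the
#' sweep.  Ground truth (i, N, sigma_b, gamma at the stated potentials) is
#' attached so recovery can be scored.
#'
#' @param model A [channel_model()].
#' @param n_events Number of events/sweeps (>= 1).
#' @param dt Sampling interval (s); mEPSC canonical 1e-5 (100 kHz).
#' @param seed Integer RNG seed; identical (model, seed) gives identical output.
#' @param sweep_s Sweep duration (s).
#' @param onset_s Event onset within each sweep (s).
#' @param vm,erev Membrane and reversal potentials (mV) used to state the
#'   ground-truth conductance.
#' @return A \code{sweep_set} with attribute \code{"truth"}: list with
#'   \code{i, n_channels, sigma_b, gamma_pS, p_peak, onset_s}.
#' @export
gen_channel_events <- function(model, n_events, dt = 1e-5, seed = 1L,
                               sweep_s = 0.055, onset_s = 0.005,
                               vm = -60, erev = 0) {
  stopifnot(inherits(model, "channel_model"))
  if (n_events < 1) stop("n_events must be >= 1")
  if (dt <= 0) stop("dt must be positive")
  set.seed(as.integer(seed))
  nsamp <- round(sweep_s / dt)
  t_ms <- (seq_len(nsamp) - 1) * dt * 1000 - onset_s * 1000
  p <- model$p_peak * biexp_waveform(t_ms, model$tau_rise_ms, model$tau_decay_ms)
  p <- pmin(pmax(p, 0), 1)
  total <- nsamp * n_events
  open_counts <- stats::rbinom(total, size = model$n_channels, prob = rep(p, n_events))
  noise <- if (model$sigma_b > 0) stats::rnorm(total, 0, model$sigma_b) else 0
  mat <- matrix(model$i * open_counts + noise, nrow = nsamp, ncol = n_events)
  sweeps <- lapply(seq_len(n_events), function(j)
    sweep_trace(mat[, j], dt = dt, t0 = 0, signal_kind = "current",
                meta = list(event = j)))
  out <- sweep_set(sweeps)
  attr(out, "truth") <- list(i = model$i, n_channels = model$n_channels,
                             sigma_b = model$sigma_b, p_peak = model$p_peak,
                             gamma_pS = 1000 * model$i / (vm - erev),
                             onset_s = onset_s, vm = vm, erev = erev)
  out
}

#' Miniature-EPSC train model
#'
#' Poisson event times at \code{rate}, lognormal peak amplitudes
#' (mean \code{amplitude_mean} pA magnitude, coefficient of variation
#' \code{amplitude_cv}), biexponential kinetics, additive Gaussian noise.
#'
#' @param rate Event rate (Hz).
#' @param amplitude_mean Mean peak amplitude (pA, magnitude > 0).
#' @param amplitude_cv Coefficient of variation of peak amplitude.
#' @param tau_rise_ms,tau_decay_ms Event kinetics (ms).
#' @param duration_s Recording duration (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Baseline noise SD (pA).
#' @return A list of class \code{"mini_train_model"}.
#' @export
mini_train_model <- function(rate = 0.5, amplitude_mean = 17.5, amplitude_cv = 0.3,
                             tau_rise_ms = 0.5, tau_decay_ms = 9,
                             duration_s = 60, dt = 1e-4, noise_sd = 2) {
  if (rate < 0) stop("rate must be >= 0")
  if (amplitude_mean <= 0) stop("amplitude_mean must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (dt <= 0) stop("dt must be positive")
  structure(list(rate = rate, amplitude_mean = amplitude_mean,
                 amplitude_cv = amplitude_cv, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, duration_s = duration_s,
                 dt = dt, noise_sd = noise_sd),
            class = "mini_train_model")
}

#' Simulate a continuous mEPSC recording
#'
#' @param model A [mini_train_model()].
#' @param seed Integer RNG seed.
#' @return A \code{sweep} (inward events, negative deflections) with attribute
#'   \code{"truth"}: data.frame of ground-truth \code{onset_s} and
#'   \code{amplitude_pA} (positive magnitudes), sorted by onset.
#' @export
gen_mini_recording <- function(model, seed = 1L) {
  stopifnot(inherits(model, "mini_train_model"))
  if (model$dt <= 0) stop("dt must be positive")
  set.seed(as.integer(seed))
  n <- round(model$duration_s / model$dt)
  x <- if (model$noise_sd > 0) stats::rnorm(n, 0, model$noise_sd) else numeric(n)
  k <- stats::rpois(1L, model$rate * model$duration_s)
  truth <- data.frame(onset_s = numeric(0), amplitude_pA = numeric(0))
  if (k > 0) {
    onsets <- sort(stats::runif(k, 0, model$duration_s))
    cv2 <- model$amplitude_cv^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(model$amplitude_mean) - sdlog^2 / 2
    amps <- stats::rlnorm(k, meanlog, sdlog)
    wav_len <- round(8 * model$tau_decay_ms / 1000 / model$dt)
    wav <- biexp_waveform((seq_len(wav_len) - 1) * model$dt * 1000,
                          model$tau_rise_ms, model$tau_decay_ms)
    wav <- wav / max(wav)
    for (j in seq_len(k)) {
      i0 <- round(onsets[j] / model$dt) + 1L
      idx <- i0:min(i0 + wav_len - 1L, n)
      if (i0 > n) next
      x[idx] <- x[idx] - amps[j] * wav[seq_along(idx)]
    }
    truth <- data.frame(onset_s = onsets, amplitude_pA = amps)
  }
  out <- sweep_trace(x, dt = model$dt, t0 = 0, signal_kind = "current",
                     meta = list(rate_hz = model$rate,
                                 duration_s = model$duration_s))
  attr(out, "truth") <- truth
  out
}

#' FRAP trace model
#'
#' Single-exponential recovery with an immobile fraction, overlaid with
#' per-frame geometric acquisition photobleaching shared by bleached and
#' reference regions.
#'
#' @param f_pre Pre-bleach fluorescence level (a.u.).
#' @param f_post Fluorescence immediately after photobleaching (a.u.),
#'   \code{0 <= f_post < f_pre}.
#' @param plateau Asymptotic normalized recovery in [0, 1.05]; the immobile
#'   fraction is \code{1 - plateau}.
#' @param tau_rec_s Recovery time constant (s).
#' @param k_acq Per-frame acquisition-bleach factor in (0, 1].
#' @param frame_interval_s Frame interval (s); imaging at 30 s intervals is
#'   typical for receptor FRAP.
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @return A list of class \code{"frap_model"}.
#' @export
frap_model <- function(f_pre = 1, f_post = 0.05, plateau = 0.63,
                       tau_rec_s = 197.3, k_acq = 0.998,
                       frame_interval_s = 30, noise_sd = 0.03) {
  if (f_post < 0 || f_post >= f_pre) stop("need 0 <= f_post < f_pre")
  if (plateau < 0 || plateau > 1.05) stop("plateau must lie in [0, 1.05]")
  if (tau_rec_s <= 0) stop("tau_rec_s must be positive")
  if (k_acq <= 0 || k_acq > 1) stop("k_acq must lie in (0, 1]")
  structure(list(f_pre = f_pre, f_post = f_post, plateau = plateau,
                 tau_rec_s = tau_rec_s, k_acq = k_acq,
                 frame_interval_s = frame_interval_s, noise_sd = noise_sd),
            class = "frap_model")
}

frap_ideal <- function(model, t, t_bleach) {
  ifelse(t < t_bleach, model$f_pre,
         model$f_post + (model$plateau * model$f_pre - model$f_post) *
           (1 - exp(-(t - t_bleach) / model$tau_rec_s)))
}

#' Simulate a FRAP acquisition
#'
#' @param model A [frap_model()].
#' @param n_frames Total frames acquired.
#' @param bleach_frame 1-based index of the frame at which photobleaching
#'   occurs (frames before it are pre-bleach).
#' @param seed Integer RNG seed.
#' @return List with fluorescence sweeps \code{bleached} and \code{reference}
#'   (frame interval as dt) and \code{truth}: list with \code{tau_rec_s,
#'   plateau, f600} (ideal normalized fluorescence 600 s post-bleach).
#' @export
gen_frap_trace <- function(model, n_frames = 26, bleach_frame = 6, seed = 1L) {
  stopifnot(inherits(model, "frap_model"))
  if (bleach_frame < 2 || bleach_frame > n_frames)
    stop("bleach_frame must lie within the trace (with >= 1 pre-bleach frame)")
  set.seed(as.integer(seed))
  t <- (seq_len(n_frames) - 1) * model$frame_interval_s
  t_b <- t[bleach_frame]
  acq <- model$k_acq^(seq_len(n_frames) - 1)
  bleached <- frap_ideal(model, t, t_b) * acq
  reference <- model$f_pre * acq
  if (model$noise_sd > 0) {
    bleached <- bleached + stats::rnorm(n_frames, 0, model$noise_sd)
    reference <- reference + stats::rnorm(n_frames, 0, model$noise_sd)
  }
  truth <- list(tau_rec_s = model$tau_rec_s, plateau = model$plateau,
                f600 = frap_ideal(model, t_b + 600, t_b) / model$f_pre,
                bleach_frame = bleach_frame)
  list(bleached = sweep_trace(bleached, dt = model$frame_interval_s, t0 = 0,
                              signal_kind = "fluorescence",
                              meta = list(role = "bleached")),
       reference = sweep_trace(reference, dt = model$frame_interval_s, t0 = 0,
                               signal_kind = "fluorescence",
                               meta = list(role = "reference")),
       truth = truth)
}

#' Current-voltage model with voltage-dependent block
#'
#' \code{I(V) = g * (V - Erev) * block(V)} where \code{block(V)} is the
#' unblocked fraction, a decreasing logistic in V emulating intracellular
#' polyamine block of GluA2-lacking (Q-form) AMPARs:
#' \code{block(V) = 1 / (1 + exp((V - v_half) / slope))}.
#'
#' @param g Chord conductance (nS, >= 0).
#' @param erev Reversal potential (mV).
#' @param v_half Half-block voltage (mV).
#' @param slope Logistic slope (mV); larger = shallower block.
#' @param block If \code{FALSE}, the ohmic model (block = 1 everywhere).
#' @return A list of class \code{"iv_model"}.
#' @export
iv_model <- function(g = 1, erev = 0, v_half = 10, slope = 20, block = TRUE) {
  if (g < 0) stop("g must be >= 0")
  structure(list(g = g, erev = erev, v_half = v_half, slope = slope,
                 block = isTRUE(block)),
            class = "iv_model")
}

iv_current <- function(model, v) {
  b <- if (model$block) 1 / (1 + exp((v - model$v_half) / model$slope)) else 1
  model$g * (v - model$erev) * b
}

#' Generate an I/V family or voltage-ramp sweep
#'
#' @param model An [iv_model()].
#' @param potentials Holding potentials (mV) for the step variant; defaults
#'   to the canonical -60/0/+40 triplet.
#' @param ramp If \code{TRUE}, also return a 500 ms voltage-ramp sweep,
#'   V swept linearly from -100 to +100 mV.
#' @param dt Ramp sampling interval (s).
#' @return List with \code{currents} (named by potential),
#'   \code{holding} (a [holding_measurements()] when -60/0/+40 are present)
#'   and, if requested, \code{ramp} (a current sweep with
#'   \code{meta$v_start/v_end}).
#' @export
gen_iv_family <- function(model, potentials = c(-60, 0, 40), ramp = FALSE,
                          dt = 1e-4) {
  stopifnot(inherits(model, "iv_model"))
  if (length(potentials) == 0) stop("potentials must be non-empty")
  curr <- stats::setNames(iv_current(model, potentials), as.character(potentials))
  holding <- NULL
  if (all(c(-60, 0, 40) %in% potentials))
    holding <- holding_measurements(curr[["-60"]], curr[["0"]], curr[["40"]],
                                    vm = -60, erev = model$erev)
  out <- list(currents = curr, holding = holding)
  if (ramp) {
    n <- round(0.5 / dt)
    v <- seq(-100, 100, length.out = n)
    out$ramp <- sweep_trace(iv_current(model, v), dt = dt, t0 = 0,
                            signal_kind = "current",
                            meta = list(v_start = -100, v_end = 100,
                                        protocol = "ramp"))
  }
  out
}

#' Generate a matched evoked-response pair and a paired-pulse sweep
#'
#' Builds (i) a -60 mV sweep carrying a fast AMPAR-kinetics EPSC of peak
#' \code{ampar_peak}, (ii) a +40 mV sweep with slow NMDAR-like kinetics whose
#' value 100 ms after onset equals \code{nmdar_peak}, and (iii) a -60 mV
#' paired-pulse sweep with two AMPAR EPSCs 50 ms apart, the second scaled by
#' \code{ppr}.
#'
#' @param ampar_peak AMPAR peak amplitude (pA magnitude).
#' @param nmdar_peak NMDAR current 100 ms after onset (pA magnitude) at +40 mV.
#' @param ppr Paired-pulse ratio (>= 0).
#' @param seed Integer RNG seed (used only when \code{noise_sd > 0}).
#' @param onset_s Stimulus/response onset (s).
#' @param noise_sd Additive noise SD (pA).
#' @param dt Sampling interval (s).
#' @param tau_rise_ms,tau_decay_ms AMPAR kinetics (ms).
#' @param nmdar_tau_rise_ms,nmdar_tau_decay_ms NMDAR kinetics (ms).
#' @return List of sweeps \code{minus60}, \code{plus40}, \code{paired} plus
#'   \code{truth} (the inputs and the onset).
#' @export
gen_evoked_pair <- function(ampar_peak = 100, nmdar_peak = 40, ppr = 2,
                            seed = 1L, onset_s = 0.02, noise_sd = 0,
                            dt = 1e-4, tau_rise_ms = 0.5, tau_decay_ms = 5,
                            nmdar_tau_rise_ms = 5, nmdar_tau_decay_ms = 80) {
  if (ppr < 0) stop("ppr must be >= 0")
  set.seed(as.integer(seed))
  dur <- onset_s + 0.35
  n <- round(dur / dt)
  t_ms <- ((seq_len(n) - 1) * dt - onset_s) * 1000
  fast <- biexp_waveform(t_ms, tau_rise_ms, tau_decay_ms)
  fast <- fast / max(fast)   # exact unit peak on the sampled grid
  slow <- biexp_waveform(t_ms, nmdar_tau_rise_ms, nmdar_tau_decay_ms)
  w100 <- biexp_waveform(100, nmdar_tau_rise_ms, nmdar_tau_decay_ms)
  m60 <- -ampar_peak * fast
  p40 <- (nmdar_peak / w100) * slow            # outward at +40 mV
  fast2 <- biexp_waveform(t_ms - 50, tau_rise_ms, tau_decay_ms)
  fast2 <- fast2 / max(fast2)
  paired <- -ampar_peak * fast - ppr * ampar_peak * fast2
  if (noise_sd > 0) {
    m60 <- m60 + stats::rnorm(n, 0, noise_sd)
    p40 <- p40 + stats::rnorm(n, 0, noise_sd)
    paired <- paired + stats::rnorm(n, 0, noise_sd)
  }
  mk <- function(x, vhold) sweep_trace(x, dt = dt, t0 = 0, "current",
                                       meta = list(v_hold_mV = vhold,
                                                   onset_s = onset_s))
  list(minus60 = mk(m60, -60), plus40 = mk(p40, 40), paired = mk(paired, -60),
       truth = list(ampar_peak = ampar_peak, nmdar_peak = nmdar_peak,
                    ppr = ppr, onset_s = onset_s))
}
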