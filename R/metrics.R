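# Evoked-response metrics: rectification index, ramp I/V, KA/Glu,
# AMPAR/NMDAR, paired-pulse ratio, LTP timecourse normalization.

#' Rectification index
#'
#' \code{RI = -(I(+40) - I(0)) / (I(-60) - I(0))}.  An ohmic conductance
#' with Erev = 0 gives RI = 2/3; polyamine block of the outward limb in
#' GluA2-lacking receptors drives RI far below that.
#'
#' @param h A [holding_measurements()] object.
#' @return Dimensionless rectification index.
#' @export
rectification_index <- function(h) {
  stopifnot(inherits(h, "holding_measurements"))
  den <- h$i_minus60 - h$i_0
  if (den == 0) stop("rectification index undefined: I(-60) equals I(0)")
  -(h$i_plus40 - h$i_0) / den
}

#' Subtracted ramp I/V curve
#'
#' Subtracts a blank (no-agonist) voltage-ramp sweep from the matching
#' glutamate ramp, assigns voltage linearly across the ramp, and reads the
#' currents at -60, 0 and +40 mV (1 ms local average around the nearest
#' sample).
#'
#' @param ramp_glu,ramp_blank Current sweeps of equal length and dt recorded
#'   during a linear voltage ramp; \code{meta$v_start}/\code{meta$v_end}
#'   give the ramp range (defaults -100 to +100 mV).
#' @return List: \code{v} (mV), \code{i} (subtracted current, pA),
#'   \code{holding} (a [holding_measurements()]), \code{ri}.
#' @export
ramp_iv <- function(ramp_glu, ramp_blank) {
  stopifnot(inherits(ramp_glu, "sweep"), inherits(ramp_blank, "sweep"))
  if (length(ramp_glu) != length(ramp_blank) ||
      abs(ramp_glu$dt - ramp_blank$dt) > 1e-12)
    stop("glutamate and blank ramps must share length and dt")
  i_sub <- ramp_glu$samples - ramp_blank$samples
  v0 <- ramp_glu$meta$v_start %||% -100
  v1 <- ramp_glu$meta$v_end %||% 100
  v <- seq(v0, v1, length.out = length(i_sub))
  read_at <- function(vq) {
    j <- which.min(abs(v - vq))
    half <- max(1L, round(0.0005 / ramp_glu$dt))
    mean(i_sub[max(1L, j - half):min(length(i_sub), j + half)])
  }
  h <- holding_measurements(read_at(-60), read_at(0), read_at(40))
  ri <- tryCatch(rectification_index(h), error = function(e) NA_real_)
  list(v = v, i = i_sub, holding = h, ri = ri)
}

#' Kainate/glutamate response ratio
#'
#' Ratio of peak response magnitudes to kainate and glutamate; an index of
#' AMPAR/TARP stoichiometry.
#'
#' @param peak_ka,peak_glu Peak current magnitudes (pA).
#' @return Dimensionless ratio.
#' @export
ka_glu_ratio <- function(peak_ka, peak_glu) {
  if (peak_glu == 0) stop("KA/Glu ratio undefined: zero glutamate response")
  abs(peak_ka) / abs(peak_glu)
}

# first crossing of 3 x baseline SD after the (blanked) stimulus artifact
response_onset_idx <- function(x, dt, stim_idx, blank_ms = 2, bl_ms = 5) {
  bl <- x[max(1L, stim_idx - round(bl_ms / 1000 / dt)):(stim_idx - 1L)]
  thr <- 3 * max(stats::sd(bl), .Machine$double.eps)
  from <- stim_idx + round(blank_ms / 1000 / dt)
  rel <- which(abs(x[from:length(x)] - mean(bl)) > thr)
  if (!length(rel)) return(NA_integer_)
  from + rel[1L] - 1L
}

#' AMPAR/NMDAR ratio
#'
#' AMPAR component: peak current magnitude at -60 mV.  NMDAR component:
#' current at +40 mV measured 100 ms after response initiation (1 ms local
#' average).  Both are measured against a 5 ms pre-stimulus baseline.
#'
#' @param sweep_m60 Current sweep at -60 mV.
#' @param sweep_p40 Current sweep at +40 mV, extending at least 100 ms past
#'   onset.
#' @param onset_s Response onset (s).  If \code{NULL}, taken from
#'   \code{sweep_m60$meta$onset_s} or estimated as the first 3-SD crossing.
#' @return List: \code{ratio}, \code{ampar_pA}, \code{nmdar_pA},
#'   \code{defined} (FALSE with ratio NA when the NMDAR value is <= 0).
#' @export
ampar_nmdar_ratio <- function(sweep_m60, sweep_p40, onset_s = NULL) {
  stopifnot(inherits(sweep_m60, "sweep"), inherits(sweep_p40, "sweep"))
  if (is.null(onset_s)) onset_s <- sweep_m60$meta$onset_s
  if (is.null(onset_s)) {
    j <- response_onset_idx(sweep_m60$samples, sweep_m60$dt,
                            stim_idx = round(0.01 / sweep_m60$dt))
    if (is.na(j)) stop("could not determine response onset")
    onset_s <- sweep_m60$t0 + (j - 1) * sweep_m60$dt
  }
  on60 <- round((onset_s - sweep_m60$t0) / sweep_m60$dt) + 1L
  on40 <- round((onset_s - sweep_p40$t0) / sweep_p40$dt) + 1L
  if (on40 + round(0.1 / sweep_p40$dt) > length(sweep_p40))
    stop("+40 mV sweep must extend at least 100 ms past onset")
  bl_n60 <- round(0.005 / sweep_m60$dt)
  bl60 <- mean(sweep_m60$samples[max(1L, on60 - bl_n60):(on60 - 1L)])
  ampar <- abs(min(sweep_m60$samples[on60:length(sweep_m60)]) - bl60)
  bl_n40 <- round(0.005 / sweep_p40$dt)
  bl40 <- mean(sweep_p40$samples[max(1L, on40 - bl_n40):(on40 - 1L)])
  j100 <- on40 + round(0.1 / sweep_p40$dt)
  half <- max(1L, round(0.0005 / sweep_p40$dt))
  nmdar <- mean(sweep_p40$samples[(j100 - half):(j100 + half)]) - bl40
  if (nmdar <= 0)
    return(list(ratio = NA_real_, ampar_pA = ampar, nmdar_pA = nmdar,
                defined = FALSE))
  list(ratio = ampar / nmdar, ampar_pA = ampar, nmdar_pA = nmdar,
       defined = TRUE)
}

#' Paired-pulse ratio
#'
#' Two EPSCs evoked 50 ms apart.  The first amplitude is measured against
#' the pre-stimulus baseline; the second against the extrapolated
#' monoexponential tail of the first, so residual decay does not contaminate
#' it.
#'
#' @param sweep Current sweep containing both responses (inward, negative).
#' @param stim_times Two stimulus/onset times (s), 50 ms apart.
#' @param isi_tol_s Accepted deviation of the interval from 50 ms.
#' @return List: \code{ppr}, \code{amp1_pA}, \code{amp2_pA},
#'   \code{tail_ok} (FALSE when the tail fit failed and the raw baseline was
#'   used).
#' @export
paired_pulse_ratio <- function(sweep, stim_times, isi_tol_s = 5e-3) {
  stopifnot(inherits(sweep, "sweep"), length(stim_times) == 2L)
  isi <- diff(stim_times)
  if (abs(isi - 0.05) > isi_tol_s)
    stop("paired-pulse interval must be 50 ms")
  x <- -sweep$samples                      # positive-going
  dt <- sweep$dt
  i1 <- round((stim_times[1L] - sweep$t0) / dt) + 1L
  i2 <- round((stim_times[2L] - sweep$t0) / dt) + 1L
  bl_n <- round(0.005 / dt)
  bl <- mean(x[max(1L, i1 - bl_n):max(1L, i1 - 1L)])
  seg1 <- x[i1:(i2 - 1L)]
  p1_rel <- which.max(seg1)
  amp1 <- seg1[p1_rel] - bl
  if (amp1 <= 0) stop("no measurable first response")
  # monoexponential tail of pulse 1 fitted on its decay, extrapolated under
  # pulse 2
  tail_idx <- (i1 + p1_rel - 1L + round(0.002 / dt)):(i2 - 1L)
  tail_ok <- FALSE
  base2 <- function(j) bl
  if (length(tail_idx) >= 5L) {
    tt <- (tail_idx - (i1 + p1_rel - 1L)) * dt * 1000
    yy <- x[tail_idx] - bl
    pos <- yy > 0.02 * amp1
    if (sum(pos) >= 5L) {
      fit <- stats::lm.fit(cbind(1, tt[pos]), log(yy[pos]))
      a <- exp(fit$coefficients[[1L]]); tau <- -1 / fit$coefficients[[2L]]
      if (is.finite(tau) && tau > 0) {
        tail_ok <- TRUE
        base2 <- function(j) bl + a * exp(-((j - (i1 + p1_rel - 1L)) * dt * 1000) / tau)
      }
    }
  }
  seg2 <- x[i2:min(length(x), i2 + round(0.03 / dt))]
  p2_rel <- which.max(seg2)
  j2 <- i2 + p2_rel - 1L
  amp2 <- seg2[p2_rel] - base2(j2)
  if (amp2 < 0) amp2 <- 0
  list(ppr = amp2 / amp1, amp1_pA = amp1, amp2_pA = amp2, tail_ok = tail_ok)
}

#' LTP timecourse: one-minute binning and pre-induction normalization
#'
#' Averages EPSC amplitudes in one-minute bins on a time axis where
#' induction occurs at t = 0, and normalizes every bin to the mean of all
#' pre-induction amplitudes.  Empty bins are reported as NA.
#'
#' @param amplitudes EPSC amplitudes (pA magnitudes).
#' @param times_s Timestamps (s) matching \code{amplitudes}.
#' @param induction_time_s Time of LTP induction (s).
#' @param bin_s Bin width (s), default one minute.
#' @return Data.frame with \code{t_min} (bin centre, minutes relative to
#'   induction), \code{norm_amplitude}, \code{n}.
#' @export
ltp_timecourse <- function(amplitudes, times_s, induction_time_s, bin_s = 60) {
  stopifnot(length(amplitudes) == length(times_s))
  rel <- times_s - induction_time_s
  pre <- amplitudes[rel < 0]
  if (length(pre) == 0L) stop("normalization error: no pre-induction data")
  base <- mean(pre)
  bin <- floor(rel / bin_s)
  allbins <- seq(min(bin), max(bin))
  means <- vapply(allbins, function(b) {
    v <- amplitudes[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  ns <- vapply(allbins, function(b) sum(bin == b), integer(1))
  data.frame(t_min = (allbins + 0.5) * bin_s / 60,
             norm_amplitude = means / base,
             n = ns)
}
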