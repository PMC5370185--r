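# FRAP normalization, acquisition-bleach correction and recovery fitting.

#' Correct a bleached-region trace for acquisition photobleaching
#'
#' Divides the bleached-region trace by the reference-region trace
#' normalized to its own pre-bleach mean:
#' \code{corrected(t) = bleached(t) / (reference(t) / mean(reference[pre]))}.
#' When acquisition bleaching is a shared per-frame geometric factor this
#' removes it exactly (up to a constant that cancels at pre-bleach
#' normalization).
#'
#' @param bleached,reference Fluorescence sweeps on the same frame grid.
#' @param bleach_frame 1-based index of the bleach frame; frames before it
#'   are pre-bleach.
#' @return Corrected fluorescence \code{sweep}.
#' @export
bleach_correct <- function(bleached, reference, bleach_frame) {
  stopifnot(inherits(bleached, "sweep"), inherits(reference, "sweep"))
  if (length(bleached) != length(reference) ||
      abs(bleached$dt - reference$dt) > 1e-12)
    stop("bleached and reference traces must share the frame grid")
  if (any(reference$samples == 0))
    stop("correction error: reference trace contains zero intensity")
  pre <- seq_len(bleach_frame - 1L)
  if (length(pre) < 1L) stop("need at least one pre-bleach frame")
  ref_norm <- reference$samples / mean(reference$samples[pre])
  sweep_trace(bleached$samples / ref_norm, dt = bleached$dt, t0 = bleached$t0,
              signal_kind = "fluorescence", meta = bleached$meta)
}

#' Normalize a FRAP trace to its pre-bleach fluorescence
#'
#' @param corrected Fluorescence \code{sweep} (typically bleach-corrected).
#' @param bleach_frame 1-based bleach frame index; at least 2 pre-bleach
#'   frames are required.
#' @return Normalized \code{sweep}; the pre-bleach mean is exactly 1.
#' @export
normalize_prebleach <- function(corrected, bleach_frame) {
  stopifnot(inherits(corrected, "sweep"))
  pre <- seq_len(bleach_frame - 1L)
  if (length(pre) < 2L) stop("at least 2 pre-bleach frames required")
  sweep_trace(corrected$samples / mean(corrected$samples[pre]),
              dt = corrected$dt, t0 = corrected$t0,
              signal_kind = "fluorescence", meta = corrected$meta)
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of \code{F(t) = F0 + (P - F0) * (1 - exp(-(t - tb)/tau))}
#' to the post-bleach frames of a normalized trace.  The bleach-onset frame
#' itself is excluded (bleaching transient).  Start values: \code{tau0} =
#' time to half recovery / ln 2, \code{F0} = first post-bleach frame,
#' \code{P} = mean of the last 3 frames.
#'
#' @param normalized Normalized fluorescence \code{sweep} (pre-bleach mean 1).
#' @param bleach_frame 1-based bleach frame index; at least 5 post-bleach
#'   frames are required.
#' @param readout_time_s Time after bleach at which late recovery is read
#'   out (600 s conventionally).
#' @return Object of class \code{"frap_fit"} with \code{tau_rec_s},
#'   \code{plateau}, \code{f0}, \code{f600} (fitted curve at the readout
#'   time), \code{f600_empirical} (frame value at the readout time, NA if
#'   not sampled), \code{immobile_fraction = 1 - plateau}, and diagnostics.
#' @export
fit_recovery <- function(normalized, bleach_frame, readout_time_s = 600) {
  stopifnot(inherits(normalized, "sweep"))
  t <- sweep_times(normalized)
  y <- normalized$samples
  n <- length(y)
  post <- (bleach_frame + 1L):n
  if (length(post) < 5L) stop("at least 5 post-bleach frames required")
  tb <- t[bleach_frame]
  tp <- t[post] - tb
  yp <- y[post]
  f0_0 <- yp[1L]
  p_0 <- mean(utils::tail(yp, 3L))
  degenerate <- (p_0 - f0_0) < 0.02
  half <- f0_0 + 0.5 * (p_0 - f0_0)
  i_half <- which(yp >= half)[1L]
  tau0 <- if (!is.na(i_half) && tp[i_half] > 0) tp[i_half] / log(2)
          else diff(range(tp)) / 2
  fit <- NULL
  if (!degenerate) {
    df <- data.frame(t = tp, y = yp)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ f0 + (p - f0) * (1 - exp(-t / tau)),
                        data = df,
                        start = list(f0 = f0_0, p = p_0, tau = tau0),
                        lower = c(f0 = -Inf, p = -Inf, tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    if (!degenerate)
      stop("recovery fit failed to converge (start: f0=", signif(f0_0, 3),
           ", p=", signif(p_0, 3), ", tau=", signif(tau0, 3), ")")
    co <- c(f0 = f0_0, p = p_0, tau = NA_real_)
  } else {
    co <- stats::coef(fit)
  }
  f_at <- function(tt) {
    if (is.na(co[["tau"]])) co[["p"]]
    else co[["f0"]] + (co[["p"]] - co[["f0"]]) * (1 - exp(-tt / co[["tau"]]))
  }
  emp_idx <- which(abs((t - tb) - readout_time_s) < normalized$dt / 2)
  f600_emp <- if (length(emp_idx)) y[emp_idx[1L]] else NA_real_
  structure(list(tau_rec_s = co[["tau"]], plateau = co[["p"]],
                 f0 = co[["f0"]],
                 f600 = f_at(readout_time_s),
                 f600_empirical = f600_emp,
                 f600_extrapolated = length(emp_idx) == 0L,
                 immobile_fraction = 1 - co[["p"]],
                 prebleach_mean = mean(y[seq_len(bleach_frame - 1L)]),
                 degenerate = degenerate,
                 residuals = if (is.null(fit)) yp - co[["p"]] else stats::resid(fit),
                 t_post = tp, y_post = yp,
                 readout_time_s = readout_time_s,
                 call = match.call()),
            class = "frap_fit")
}

#' Full FRAP analysis of a bleached/reference region pair
#'
#' Applies acquisition-bleach correction, pre-bleach normalization and
#' single-exponential recovery fitting in one call.
#'
#' @param bleached,reference Fluorescence sweeps on the same frame grid.
#' @param bleach_frame 1-based bleach frame index.
#' @param readout_time_s Late-recovery readout time (s).
#' @return A \code{"frap_fit"} object (see [fit_recovery()]); the normalized
#'   trace is attached as \code{$normalized}.
#' @examples
#' tr <- gen_frap_trace(frap_model(plateau = 0.63, tau_rec_s = 197.3), seed = 2)
#' fit <- frap(tr$bleached, tr$reference, bleach_frame = 6)
#' coef(fit)
#' @export
frap <- function(bleached, reference, bleach_frame, readout_time_s = 600) {
  corr <- bleach_correct(bleached, reference, bleach_frame)
  norm <- normalize_prebleach(corr, bleach_frame)
  fit <- fit_recovery(norm, bleach_frame, readout_time_s = readout_time_s)
  fit$normalized <- norm
  fit$bleach_frame <- bleach_frame
  fit
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP single-exponential recovery fit\n")
  if (x$degenerate) {
    cat("  no measurable recovery: tau unidentifiable (immobile trace)\n")
  } else {
    cat(sprintf("  tau = %.4g s, plateau = %.4g (immobile fraction %.3g)\n",
                x$tau_rec_s, x$plateau, x$immobile_fraction))
  }
  cat(sprintf("  F(%g s) = %.4g (fitted), %.4g (empirical frame)\n",
              x$readout_time_s, x$f600, x$f600_empirical))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(tau_rec_s = object$tau_rec_s, plateau = object$plateau, f0 = object$f0)
}

#' @export
summary.frap_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.frap_fit")
}

#' @export
print.summary.frap_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  pre-bleach mean %.4g, residual SD %.3g over %d post frames\n",
              x$fit$prebleach_mean, stats::sd(x$fit$residuals),
              length(x$fit$t_post)))
  invisible(x)
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$t_post
  else if (is.data.frame(newdata)) newdata$t else newdata
  if (is.na(object$tau_rec_s)) return(rep(object$plateau, length(tt)))
  object$f0 + (object$plateau - object$f0) * (1 - exp(-tt / object$tau_rec_s))
}

#' @export
residuals.frap_fit <- function(object, ...) object$residuals

#' @export
fitted.frap_fit <- function(object, ...) predict(object)

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$t_post, x$y_post, pch = 19,
                 xlab = "time after bleach (s)",
                 ylab = "normalized fluorescence", ylim = c(0, 1.1), ...)
  tt <- seq(0, max(x$t_post), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
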