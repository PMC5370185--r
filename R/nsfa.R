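# Peak-scaled non-stationary fluctuation analysis.
#
# The mean-variance relation of an ensemble of N independently gated
# channels with single-channel current i and background variance sigma_b^2:
#
#     sigma^2(I) = i * I - I^2 / N + sigma_b^2
#
# The single-channel current is the initial gradient of this parabola; the
# single-channel conductance follows as gamma = i / (Vm - Erev).

#' Per-timepoint mean and variance over the decay phase
#'
#' The decay phase runs from the common (ensemble-mean) peak column to the
#' column where the ensemble mean first returns to 10\% of its peak.  The
#' unbiased (n-1) variance is computed per column.
#'
#' @param mat Peak-scaled aligned event matrix (rows = events,
#'   positive-going), e.g. from [peak_scale()].
#' @param min_events Eligibility minimum (default 20 events).
#' @param decay_end_frac Fraction of the peak at which the decay phase ends.
#' @return Data.frame with columns \code{col, t_ms, mean_pA, var_pA2}.
#' @export
decay_variance <- function(mat, min_events = 20, decay_end_frac = 0.10) {
  if (nrow(mat) < min_events)
    stop(sprintf(paste0("only %d events available; at least %d successful ",
                        "events are required for fluctuation analysis"),
                 nrow(mat), min_events))
  mu <- colMeans(mat)
  pk_col <- which.max(mu)
  pk <- mu[pk_col]
  after <- mu[pk_col:length(mu)]
  below <- which(after <= decay_end_frac * pk)
  end_col <- if (length(below)) pk_col + below[1L] - 1L else length(mu)
  cols <- pk_col:end_col
  v <- apply(mat[, cols, drop = FALSE], 2L, stats::var)
  dt <- attr(mat, "dt") %||% NA_real_
  data.frame(col = cols,
             t_ms = (cols - cols[1L]) * dt * 1000,
             mean_pA = mu[cols],
             var_pA2 = v)
}

#' Bin decay-phase mean/variance points
#'
#' Equal-width bins over the amplitude range of the decay phase (15 by
#' default); per-bin averages of mean amplitude and variance.  Empty bins
#' are dropped.
#'
#' @param points Data.frame from [decay_variance()] (columns \code{mean_pA},
#'   \code{var_pA2}).
#' @param n_bins Number of equal-width bins.
#' @return Data.frame with columns \code{mean_pA, var_pA2, n}.
#' @export
bin_variance <- function(points, n_bins = 15) {
  rng <- range(points$mean_pA)
  if (diff(rng) <= 0)
    stop("degenerate amplitude range: all decay-phase means identical")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  idx <- findInterval(points$mean_pA, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(points)), idx), function(ii)
    data.frame(mean_pA = mean(points$mean_pA[ii]),
               var_pA2 = mean(points$var_pA2[ii]),
               n = length(ii))))
  rownames(out) <- NULL
  out[order(out$mean_pA), , drop = FALSE]
}

#' Fit the variance-mean parabola
#'
#' Least-squares fit of \code{var = i * I - I^2 / N + sigma_b2} over variance
#' bins.  The model is linear in (i, 1/N, sigma_b2), so the unconstrained
#' solution is exact; when it violates the physical constraints N > 0,
#' sigma_b2 >= 0 a bounded refit is used and the result flagged.
#'
#' @param bins Data.frame from [bin_variance()] (\code{mean_pA, var_pA2},
#'   optionally \code{n}).
#' @param weighted If \code{TRUE}, weight bins by their point count
#'   (\code{n}); default is the unweighted fit.
#' @return List: \code{i} (pA, signed as the input amplitudes), \code{n_channels},
#'   \code{sigma_b2} (pA^2), \code{rss}, \code{fitted}, \code{n_bins},
#'   \code{boundary} (TRUE if a constraint was active).
#' @export
fit_parabola <- function(bins, weighted = FALSE) {
  if (nrow(bins) < 3) stop("at least 3 non-degenerate bins required for the 3-parameter fit")
  I <- bins$mean_pA
  V <- bins$var_pA2
  w <- if (weighted && !is.null(bins$n)) bins$n else rep(1, length(I))
  X <- cbind(I = I, negI2 = -I^2, one = 1)
  fit <- stats::lm.wfit(X, V, w)
  beta <- fit$coefficients           # (i, 1/N, sigma_b2)
  boundary <- FALSE
  if (!all(is.finite(beta)) || beta[2L] <= 0 || beta[3L] < 0) {
    obj <- function(p) sum(w * (V - (p[1L] * I - p[2L] * I^2 + p[3L]))^2)
    start <- c(beta[1L], max(beta[2L], 1e-6), max(beta[3L], 0))
    start[!is.finite(start)] <- c(1, 1e-3, 1)[!is.finite(start)]
    opt <- stats::nlminb(start, obj, lower = c(-Inf, 1e-12, 0))
    if (opt$convergence != 0 && opt$objective > sum(w * (V - mean(V))^2))
      stop("parabola fit failed to converge: ", opt$message)
    beta <- opt$par
    boundary <- TRUE
  }
  fitted <- beta[1L] * I - beta[2L] * I^2 + beta[3L]
  list(i = unname(beta[1L]), n_channels = unname(1 / beta[2L]),
       sigma_b2 = unname(beta[3L]),
       rss = sum(w * (V - fitted)^2), fitted = fitted,
       n_bins = nrow(bins), boundary = boundary)
}

#' Single-channel conductance from single-channel current
#'
#' \code{gamma = i / (Vm - Erev)}, converted from pA/mV (nS) to pS.
#'
#' @param i Single-channel current (pA, signed; inward negative).
#' @param vm Membrane potential (mV).
#' @param erev Reversal potential (mV).
#' @return Conductance in pS (positive for physically consistent pairs).
#' @export
conductance <- function(i, vm = -60, erev = 0) {
  if (vm == erev) stop("Vm must differ from Erev")
  1000 * i / (vm - erev)
}

#' Peak-scaled non-stationary fluctuation analysis
#'
#' Runs the full analysis on a set of synaptic-current sweeps: template
#' detection, event measurement, quality control (rise-time cutoff, overlap
#' exclusion, minimum event count), alignment on the point of steepest rise,
#' peak scaling, decay-phase variance, equal-width binning and the parabolic
#' fit, returning single-channel current and conductance.
#'
#' @param x A \code{sweep_set} of current sweeps (one or more events each),
#'   or a pre-aligned positive-going event matrix (rows = events) with a
#'   \code{"dt"} attribute.
#' @param config A [run_config()] carrying template kinetics, detection
#'   threshold, bin count, minimum events and rise cutoff.
#' @param vm,erev Membrane and reversal potentials (mV).
#' @param polarity Sweep sign convention (default inward/negative events).
#' @param weighted Passed to [fit_parabola()].
#' @param ... Unused.
#' @return Object of class \code{"nsfa"}: coefficients (i, N, sigma_b2),
#'   \code{gamma_pS}, variance bins, event bookkeeping and fit diagnostics.
#' @examples
#' mod <- channel_model(n_channels = 30, i = -1.524, p_peak = 0.6, sigma_b = 2)
#' sw <- gen_channel_events(mod, n_events = 60, seed = 7)
#' fit <- nsfa(sw, config = run_config(min_events = 20))
#' coef(fit)
#' @export
nsfa <- function(x, ...) UseMethod("nsfa")

#' @rdname nsfa
#' @export
nsfa.sweep_set <- function(x, config = run_config(), vm = -60, erev = 0,
                           polarity = c("negative", "positive"),
                           weighted = FALSE, ...) {
  polarity <- match.arg(polarity)
  template <- mepsc_template(config$tau_rise_ms, config$tau_decay_ms, dt = x$dt)
  windows <- list()
  peaks <- numeric(0)
  n_detected <- 0L
  n_qc <- 0L
  limit <- NA_real_
  excl <- integer(0)
  for (s in x$sweeps) {
    ev <- detect_events(s, template, threshold = config$threshold,
                        polarity = polarity)
    if (is.na(limit)) limit <- attr(ev, "detection_limit_pA")
    n_detected <- n_detected + nrow(ev)
    if (nrow(ev) == 0L) next
    qc <- qc_filter(ev, rise_cutoff_ms = config$rise_cutoff_ms,
                    min_events = 1L, max_rank_cor = config$max_rank_cor)
    if (nrow(qc$events) == 0L) next
    n_qc <- n_qc + nrow(qc$events)
    mat <- align_events(s, qc$events, polarity = polarity)
    if (nrow(mat) == 0L) next
    # smoothed peak estimate per event for the scale factors
    wpk <- max(3L, round(0.0005 / x$dt))
    pk <- apply(mat, 1L, function(r) max(boxcar(r, wpk)))
    windows[[length(windows) + 1L]] <- mat
    peaks <- c(peaks, pk)
  }
  if (n_qc < config$min_events)
    stop(sprintf(paste0("only %d events passed QC; at least %d successful ",
                        "events are required for fluctuation analysis"),
                 n_qc, config$min_events))
  mat <- do.call(rbind, windows)
  attr(mat, "dt") <- x$dt
  scaled <- peak_scale(mat, peaks = peaks)
  attr(scaled, "dt") <- x$dt
  pts <- decay_variance(scaled, min_events = config$min_events)
  # convert to the signed (physiological) amplitude domain for the fit
  sign_fac <- if (polarity == "negative") -1 else 1
  pts_signed <- data.frame(mean_pA = sign_fac * pts$mean_pA,
                           var_pA2 = pts$var_pA2)
  bins <- bin_variance(pts_signed, n_bins = config$n_bins)
  fit <- fit_parabola(bins, weighted = weighted)
  baseline_var <- NA_real_
  structure(list(coefficients = c(i = fit$i, n_channels = fit$n_channels,
                                  sigma_b2 = fit$sigma_b2),
                 gamma_pS = conductance(fit$i, vm, erev),
                 vm = vm, erev = erev,
                 bins = bins, points = pts_signed,
                 rss = fit$rss, boundary = fit$boundary,
                 n_events_detected = n_detected, n_events_used = nrow(scaled),
                 n_bins_used = fit$n_bins,
                 detection_limit_pA = limit,
                 config = config,
                 call = match.call()),
            class = "nsfa")
}

#' @rdname nsfa
#' @export
nsfa.matrix <- function(x, config = run_config(), vm = -60, erev = 0,
                        weighted = FALSE, ...) {
  scaled <- peak_scale(x)
  attr(scaled, "dt") <- attr(x, "dt")
  pts <- decay_variance(scaled, min_events = config$min_events)
  pts_signed <- data.frame(mean_pA = -pts$mean_pA, var_pA2 = pts$var_pA2)
  bins <- bin_variance(pts_signed, n_bins = config$n_bins)
  fit <- fit_parabola(bins, weighted = weighted)
  structure(list(coefficients = c(i = fit$i, n_channels = fit$n_channels,
                                  sigma_b2 = fit$sigma_b2),
                 gamma_pS = conductance(fit$i, vm, erev),
                 vm = vm, erev = erev, bins = bins, points = pts_signed,
                 rss = fit$rss, boundary = fit$boundary,
                 n_events_detected = nrow(x), n_events_used = nrow(scaled),
                 n_bins_used = fit$n_bins, detection_limit_pA = NA_real_,
                 config = config, call = match.call()),
            class = "nsfa")
}

#' @export
print.nsfa <- function(x, ...) {
  cat("Peak-scaled non-stationary fluctuation analysis\n")
  cat(sprintf("  events used: %d (of %d detected), bins: %d\n",
              x$n_events_used, x$n_events_detected, x$n_bins_used))
  cat(sprintf("  i = %.4g pA, N = %.4g, sigma_b^2 = %.4g pA^2\n",
              x$coefficients[["i"]], x$coefficients[["n_channels"]],
              x$coefficients[["sigma_b2"]]))
  cat(sprintf("  gamma = %.4g pS  (Vm = %g mV, Erev = %g mV)\n",
              x$gamma_pS, x$vm, x$erev))
  invisible(x)
}

#' @export
coef.nsfa <- function(object, ...) object$coefficients

#' @export
summary.nsfa <- function(object, ...) {
  structure(list(fit = object), class = "summary.nsfa")
}

#' @export
print.summary.nsfa <- function(x, ...) {
  print(x$fit)
  b <- x$fit$bins
  cat(sprintf("  variance bins: amplitude %.4g to %.4g pA, RSS = %.4g\n",
              min(b$mean_pA), max(b$mean_pA), x$fit$rss))
  if (x$fit$boundary)
    cat("  note: a physical constraint (N > 0, sigma_b^2 >= 0) was active\n")
  invisible(x)
}

#' @export
predict.nsfa <- function(object, newdata = NULL, ...) {
  I <- if (is.null(newdata)) object$bins$mean_pA
  else if (is.data.frame(newdata)) newdata$mean_pA else newdata
  co <- object$coefficients
  co[["i"]] * I - I^2 / co[["n_channels"]] + co[["sigma_b2"]]
}

#' @export
residuals.nsfa <- function(object, ...) {
  object$bins$var_pA2 - predict(object)
}

#' @export
fitted.nsfa <- function(object, ...) predict(object)

#' @export
plot.nsfa <- function(x, ...) {
  graphics::plot(x$points$mean_pA, x$points$var_pA2, pch = 16,
                 col = "grey70", cex = 0.5,
                 xlab = "mean amplitude (pA)", xlim = rev(range(x$points$mean_pA)),
                 ylab = expression(variance ~ (pA^2)), ...)
  graphics::points(x$bins$mean_pA, x$bins$var_pA2, pch = 19)
  I <- seq(0, max(abs(x$points$mean_pA)), length.out = 200) *
    sign(x$points$mean_pA[1])
  graphics::lines(I, predict(x, I), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.nsfa <- function(object, nsim = 1, seed = NULL, n_events = 100, ...) {
  co <- object$coefficients
  mod <- channel_model(n_channels = max(1, round(co[["n_channels"]])),
                       i = co[["i"]],
                       p_peak = 0.6,
                       tau_rise_ms = object$config$tau_rise_ms,
                       tau_decay_ms = object$config$tau_decay_ms,
                       sigma_b = sqrt(max(co[["sigma_b2"]], 0)))
  lapply(seq_len(nsim), function(k)
    gen_channel_events(mod, n_events = n_events,
                       seed = if (is.null(seed)) k else seed + k - 1,
                       vm = object$vm, erev = object$erev))
}
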