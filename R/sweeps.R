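#' Construct a recording sweep
#'
#' A sweep is a uniformly sampled signal trace: membrane current (pA) or
#' fluorescence intensity (arbitrary units).  Time is stored in seconds,
#' sample-start convention: sample \code{k} (1-based) sits at
#' \code{t0 + (k - 1) * dt}.
#'
#' @param samples Numeric vector of signal values.  Currents follow the
#'   physiological sign convention (inward currents negative, in pA).
#' @param dt Sampling interval in seconds (must be > 0).  Miniature-EPSC
#'   recordings are canonically digitized at 100 kHz (\code{dt = 1e-5}).
#' @param t0 Start time of the first sample in seconds.
#' @param signal_kind Either \code{"current"} or \code{"fluorescence"}.
#' @param meta Named list of free-form annotations (holding potential in mV,
#'   condition label, cell id, region id, ...).
#' @return An object of class \code{"sweep"}.
#' @export
sweep_trace <- function(samples, dt, t0 = 0, signal_kind = c("current", "fluorescence"),
                        meta = list()) {
  signal_kind <- match.arg(signal_kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("sweep must contain at least one sample")
  if (!all(is.finite(samples))) stop("sweep samples must all be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  if (!is.list(meta)) stop("meta must be a named list")
  structure(list(samples = samples, dt = dt, t0 = as.numeric(t0),
                 signal_kind = signal_kind, meta = meta),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s, %d samples, dt = %g s (%.4g s span)\n",
              x$signal_kind, length(x$samples), x$dt,
              length(x$samples) * x$dt))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.sweep <- function(x) length(x$samples)

#' Sample times of a sweep
#' @param x A \code{sweep} object.
#' @return Numeric vector of sample times (s).
#' @export
sweep_times <- function(x) {
  stopifnot(inherits(x, "sweep"))
  x$t0 + (seq_along(x$samples) - 1) * x$dt
}

#' Construct a set of sweeps
#'
#' Sweeps in a set share sampling interval and signal kind; per-sweep group
#' labels (condition, cell) live in each sweep's \code{meta}.
#'
#' @param sweeps List of \code{sweep} objects (or a single sweep).
#' @return An object of class \code{"sweep_set"}.
#' @export
sweep_set <- function(sweeps) {
  if (inherits(sweeps, "sweep")) sweeps <- list(sweeps)
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop("sweep_set needs a non-empty list of sweeps")
  if (!all(vapply(sweeps, inherits, logical(1), "sweep")))
    stop("all elements must be sweep objects")
  dts <- vapply(sweeps, `[[`, numeric(1), "dt")
  kinds <- vapply(sweeps, `[[`, character(1), "signal_kind")
  if (max(dts) - min(dts) > 1e-12 * max(dts))
    stop("sweeps in a set must share the sampling interval")
  if (length(unique(kinds)) != 1L)
    stop("sweeps in a set must share the signal kind")
  if (is.null(names(sweeps)))
    names(sweeps) <- sprintf("sweep%03d", seq_along(sweeps))
  structure(list(sweeps = sweeps, dt = dts[[1L]], signal_kind = kinds[[1L]]),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d %s sweep(s), dt = %g s\n",
              length(x$sweeps), x$signal_kind, x$dt))
  invisible(x)
}

#' @export
length.sweep_set <- function(x) length(x$sweeps)

#' @export
`[[.sweep_set` <- function(x, i) x$sweeps[[i]]

#' @export
`[.sweep_set` <- function(x, i) sweep_set(x$sweeps[i])

#' Analysis run configuration
#'
#' Bundles the tunable parameters of the mEPSC/NSFA pipeline.  Defaults
#' follow common practice for AMPAR miniature-event analysis: 15 variance
#' bins, at least 20 accepted events per cell, 10-90\% rise-time cutoff of
#' 0.9 ms, and a scaled-template detection criterion of 4.
#'
#' @param tau_rise_ms,tau_decay_ms Detection-template kinetics (ms).
#' @param threshold Detection-criterion threshold (dimensionless,
#'   \code{|scale / SE(scale)|}).
#' @param n_bins Number of equal-width variance bins.
#' @param min_events Minimum accepted events for NSFA eligibility.
#' @param rise_cutoff_ms Maximum accepted 10-90\% rise time (ms).
#' @param max_rank_cor Flag cells whose |Spearman correlation| between
#'   amplitude and rise or decay time exceeds this (filtering diagnostic).
#' @param frap_plateau_time_s Time (s) at which late FRAP recovery is read out.
#' @param seed Integer RNG seed recorded with every run.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(tau_rise_ms = 0.5, tau_decay_ms = 9, threshold = 4,
                       n_bins = 15, min_events = 20, rise_cutoff_ms = 0.9,
                       max_rank_cor = 0.7, frap_plateau_time_s = 600,
                       seed = 1L) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (min_events < 1) stop("min_events must be at least 1")
  if (rise_cutoff_ms <= 0) stop("rise_cutoff_ms must be positive")
  if (tau_rise_ms >= tau_decay_ms) stop("tau_rise_ms must be below tau_decay_ms")
  structure(list(tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 threshold = threshold, n_bins = as.integer(n_bins),
                 min_events = as.integer(min_events),
                 rise_cutoff_ms = rise_cutoff_ms, max_rank_cor = max_rank_cor,
                 frap_plateau_time_s = frap_plateau_time_s,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Holding-potential current measurements
#'
#' Currents measured with the cell held at -60, 0 and +40 mV, as used by the
#' rectification-index calculation.
#'
#' @param i_minus60,i_0,i_plus40 Currents (pA) at the three holding potentials.
#' @param vm Membrane potential (mV) used for conductance conversion.
#' @param erev Reversal potential (mV).
#' @return A list of class \code{"holding_measurements"}.
#' @export
holding_measurements <- function(i_minus60, i_0, i_plus40, vm = -60, erev = 0) {
  vals <- c(i_minus60, i_0, i_plus40)
  if (!all(is.finite(vals))) stop("all three currents must be finite")
  structure(list(i_minus60 = i_minus60, i_0 = i_0, i_plus40 = i_plus40,
                 vm = vm, erev = erev),
            class = "holding_measurements")
}

# ---------------------------------------------------------------------------
# Delimited sweep file dialect: '#'-prefixed key=value header lines, then a
# CSV table with one time column followed by one value column per sweep.
# Data values carry 9 significant digits; time carries full double precision
# so that sampling-uniformity checks at 1e-9 s remain meaningful.
# ---------------------------------------------------------------------------

fmt_meta_value <- function(v) {
  if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
}

#' Write a sweep set to a delimited file
#'
#' @param sweeps A \code{sweep_set} (or single \code{sweep}).
#' @param path Destination file path.
#' @param format Only \code{"csv"} (delimited dialect) is supported.
#' @return Invisibly, \code{path}.
#' @seealso [read_sweeps()]
#' @export
write_sweeps <- function(sweeps, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("the HDF5 container is not supported by this build; use format = \"csv\"")
  if (inherits(sweeps, "sweep")) sweeps <- sweep_set(list(sweeps))
  stopifnot(inherits(sweeps, "sweep_set"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path, "' for writing"))
  on.exit(close(con))
  ns <- length(sweeps$sweeps)
  n <- max(vapply(sweeps$sweeps, length, integer(1)))
  if (any(vapply(sweeps$sweeps, length, integer(1)) != n))
    stop("all sweeps in a set must have equal length for the delimited dialect")
  writeLines(sprintf("# dt=%.15g", sweeps$dt), con)
  writeLines(sprintf("# signal_kind=%s", sweeps$signal_kind), con)
  writeLines(sprintf("# t0=%.15g", sweeps$sweeps[[1L]]$t0), con)
  for (j in seq_len(ns)) {
    m <- sweeps$sweeps[[j]]$meta
    for (k in names(m))
      writeLines(sprintf("# meta.%s.%s=%s", names(sweeps$sweeps)[j], k,
                         fmt_meta_value(m[[k]])), con)
  }
  tt <- sweep_times(sweeps$sweeps[[1L]])
  header <- paste(c("time_s", names(sweeps$sweeps)), collapse = ",")
  writeLines(header, con)
  cols <- c(list(sprintf("%.15g", tt)),
            lapply(sweeps$sweeps, function(s) sprintf("%.9g", s$samples)))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

parse_header_meta <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  eq <- regexpr("=", kv, fixed = TRUE)
  keys <- substr(kv, 1L, eq - 1L)
  vals <- substr(kv, eq + 1L, nchar(kv))
  stats::setNames(as.list(vals), keys)
}

#' Read a sweep set from a delimited file
#'
#' Parses the delimited sweep dialect written by [write_sweeps()]: comment
#' header lines \code{# key=value}, then a CSV table whose first column is
#' time (s) and whose remaining columns are sweeps.  The time column must be
#' strictly increasing and uniform within 1e-9 s.
#'
#' @param path File path.
#' @param format Only \code{"csv"} is supported.
#' @return A \code{sweep_set}.
#' @export
read_sweeps <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("the HDF5 container is not supported by this build; use format = \"csv\"")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grepl("^#", lines)
  meta <- parse_header_meta(lines[hdr])
  body <- lines[!hdr]
  if (length(body) < 2L) stop("format error: no data rows in ", path)
  nf <- vapply(strsplit(body, ",", fixed = TRUE), length, integer(1))
  if (any(nf != nf[1L]))
    stop("format error: ragged row at data line ", which(nf != nf[1L])[1L])
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE)
  if (ncol(tab) < 2L) stop("format error: need a time column and >= 1 sweep column")
  tt <- tab[[1L]]
  if (anyNA(tab)) stop("format error: missing value at row ",
                       which(apply(is.na(tab), 1L, any))[1L])
  dts <- diff(tt)
  if (any(dts <= 0)) stop("sampling error: time not strictly increasing")
  jitter <- max(abs(dts - stats::median(dts)))
  if (jitter > 1e-9)
    stop(sprintf("sampling error: non-uniform time base (max jitter %.3g s)", jitter))
  dt <- if (!is.null(meta$dt)) as.numeric(meta$dt) else stats::median(dts)
  kind <- if (!is.null(meta$signal_kind)) meta$signal_kind else "current"
  t0 <- if (!is.null(meta$t0)) as.numeric(meta$t0) else tt[1L]
  sw <- list()
  for (j in 2:ncol(tab)) {
    id <- names(tab)[j]
    mkeys <- grep(paste0("^meta\\.", id, "\\."), names(meta), value = TRUE)
    m <- stats::setNames(meta[mkeys],
                         sub(paste0("^meta\\.", id, "\\."), "", mkeys))
    m <- lapply(m, function(v) {
      nv <- suppressWarnings(as.numeric(v))
      if (!is.na(nv) && grepl("^[-+0-9.eE]+$", v)) nv else v
    })
    sw[[id]] <- sweep_trace(tab[[j]], dt = dt, t0 = t0, signal_kind = kind, meta = m)
  }
  sweep_set(sw)
}

#' Read or write an mEPSC event table
#'
#' Event tables are plain CSV with columns \code{event_id, sweep_id, onset_s,
#' peak_s, amplitude_pA, rise_10_90_ms, decay_tau_ms, qc_pass}.
#'
#' @param path File path.
#' @return For the reader, a data.frame of events (zero rows allowed).
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("event_id", "sweep_id", "onset_s", "peak_s", "amplitude_pA",
            "rise_10_90_ms", "decay_tau_ms", "qc_pass")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("format error: event table lacks column(s) ",
                         paste(miss, collapse = ", "))
  tab$qc_pass <- as.logical(tab$qc_pass)
  tab
}

#' @rdname read_event_table
#' @param events Data.frame of events as returned by [detect_events()].
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a FRAP intensity table
#'
#' FRAP tables are CSV with columns \code{time_s, region_id, role, intensity};
#' \code{role} is \code{"bleached"} or \code{"reference"}.  The reader returns
#' one fluorescence sweep per region.
#'
#' @param path File path.
#' @return For the reader, a named list of \code{sweep} objects (one per
#'   region, \code{meta$role} set).
#' @export
read_frap_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "region_id", "role", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("format error: FRAP table lacks column(s) ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (id in unique(tab$region_id)) {
    sub <- tab[tab$region_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    dts <- diff(sub$time_s)
    if (length(dts) && (any(dts <= 0) || max(abs(dts - stats::median(dts))) > 1e-9))
      stop("sampling error: non-uniform frame times for region ", id)
    out[[as.character(id)]] <-
      sweep_trace(sub$intensity, dt = stats::median(dts), t0 = sub$time_s[1L],
                  signal_kind = "fluorescence",
                  meta = list(role = sub$role[1L], region_id = id))
  }
  out
}

#' @rdname read_frap_table
#' @param regions Named list of fluorescence sweeps with \code{meta$role}.
#' @export
write_frap_table <- function(regions, path) {
  rows <- lapply(names(regions), function(id) {
    s <- regions[[id]]
    data.frame(time_s = sweep_times(s), region_id = id,
               role = s$meta$role %||% "bleached",
               intensity = s$samples)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
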