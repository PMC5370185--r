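# End-to-end scenario orchestration: synthetic generation -> detection ->
# NSFA / FRAP / evoked metrics -> report, with seeded reproducibility and a
# manifest tying outputs to their configuration.

#' Define an analysis scenario
#'
#' A scenario bundles the generator models for the three analysis tracks
#' (channel ensemble -> NSFA, FRAP, evoked I/V), the analysis configuration
#' and the seed.  Any track may be omitted.
#'
#' @param name Scenario name.
#' @param channel A [channel_model()] or NULL.
#' @param n_events Events to simulate for the NSFA track.
#' @param frap A [frap_model()] or NULL.
#' @param n_frames,bleach_frame FRAP acquisition layout.
#' @param iv An [iv_model()] or NULL.
#' @param evoked Named list of [gen_evoked_pair()] arguments or NULL.
#' @param config A [run_config()].
#' @param seed Integer seed governing every track.
#' @return List of class \code{"scenario"}.
#' @export
scenario <- function(name, channel = NULL, n_events = 100, frap = NULL,
                     n_frames = 26, bleach_frame = 6, iv = NULL,
                     evoked = NULL, config = run_config(), seed = 1L) {
  if (!is.null(channel)) stopifnot(inherits(channel, "channel_model"))
  if (!is.null(frap)) stopifnot(inherits(frap, "frap_model"))
  if (!is.null(iv)) stopifnot(inherits(iv, "iv_model"))
  structure(list(name = name, channel = channel, n_events = n_events,
                 frap = frap, n_frames = n_frames, bleach_frame = bleach_frame,
                 iv = iv, evoked = evoked, config = config,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' Read a scenario from a YAML file
#'
#' The file mirrors the [scenario()] arguments: top-level \code{name} and
#' \code{seed}, with optional \code{channel}, \code{frap}, \code{iv},
#' \code{evoked} and \code{config} mappings whose keys are the corresponding
#' constructor arguments.  Unknown keys are rejected.
#'
#' @param path Path to a YAML scenario file.
#' @return A \code{"scenario"}.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$name)) stop("scenario file must define 'name'")
  build <- function(block, ctor) {
    if (is.null(block)) return(NULL)
    unknown <- setdiff(names(block), names(formals(ctor)))
    if (length(unknown))
      stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
    do.call(ctor, block)
  }
  scenario(name = raw$name,
           channel = build(raw$channel, channel_model),
           n_events = raw$n_events %||% 100,
           frap = build(raw$frap, frap_model),
           n_frames = raw$n_frames %||% 26,
           bleach_frame = raw$bleach_frame %||% 6,
           iv = build(raw$iv, iv_model),
           evoked = raw$evoked,
           config = if (is.null(raw$config)) run_config()
                    else build(raw$config, run_config),
           seed = raw$seed %||% 1L)
}

#' Built-in scenarios
#'
#' \code{"glua2q"}, \code{"untransfected"} and \code{"delta-ntd"} carry
#' channel models whose single-channel conductances are 25.4, 11.2 and
#' 22.8 pS at Vm = -60 mV / Erev = 0 mV, together with matching FRAP and
#' rectification models; they exercise every pipeline track at desk scale.
#'
#' @param name Scenario name.
#' @param seed Integer seed.
#' @param n_events Events for the NSFA track.
#' @return A \code{"scenario"}.
#' @export
built_in_scenario <- function(name = c("glua2q", "untransfected", "delta-ntd"),
                              seed = 1L, n_events = 200) {
  name <- match.arg(name)
  gamma <- c("glua2q" = 25.4, "untransfected" = 11.2, "delta-ntd" = 22.8)[[name]]
  ch <- channel_model(n_channels = 30, i = gamma * -60 / 1000, p_peak = 0.6,
                      sigma_b = 2)
  fr <- switch(name,
               "glua2q" = frap_model(plateau = 0.63, tau_rec_s = 197.3),
               "delta-ntd" = frap_model(plateau = 0.93, tau_rec_s = 65.4),
               frap_model(plateau = 0.8, tau_rec_s = 100))
  iv <- if (name == "untransfected") iv_model(g = 1, block = FALSE)
        else iv_model(g = 1, block = TRUE)
  scenario(name = name, channel = ch, n_events = n_events, frap = fr,
           iv = iv, evoked = list(ampar_peak = 100, nmdar_peak = 40, ppr = 2),
           config = run_config(seed = seed), seed = seed)
}

#' Run a scenario end to end
#'
#' Simulates each configured track, runs the corresponding analyses and
#' writes every intermediate and final table into \code{outdir}: simulated
#' sweeps (NSFA track), detected events, NSFA results, FRAP fit, evoked
#' metrics, a text report and \code{manifest.json} with the configuration
#' hash.  Reruns with the same scenario are deterministic.
#'
#' @param scn A \code{"scenario"}.
#' @param outdir Output directory (created).
#' @param keep_sweeps If \code{FALSE}, the (large) simulated sweep file is
#'   skipped and only derived tables are written.
#' @return Invisibly, a list with the analysis results and the manifest.
#' @export
run_scenario <- function(scn, outdir, keep_sweeps = FALSE) {
  stopifnot(inherits(scn, "scenario"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  results <- list()
  log <- c(sprintf("scenario %s, seed %d", scn$name, scn$seed))

  if (!is.null(scn$channel)) {
    sw <- gen_channel_events(scn$channel, n_events = scn$n_events,
                             seed = scn$seed)
    truth <- attr(sw, "truth")
    if (keep_sweeps) write_sweeps(sw, file.path(outdir, "sweeps.csv"))
    fit <- tryCatch(nsfa(sw, config = scn$config),
                    error = function(e)
                      stop("NSFA stage failed for scenario '", scn$name,
                           "': ", conditionMessage(e), call. = FALSE))
    results$nsfa <- fit
    tables$nsfa <- data.frame(cell_id = scn$name,
                              i_pA = coef(fit)[["i"]],
                              N = coef(fit)[["n_channels"]],
                              sigma_b2_pA2 = coef(fit)[["sigma_b2"]],
                              gamma_pS = fit$gamma_pS,
                              gamma_true_pS = truth$gamma_pS,
                              n_events = fit$n_events_used,
                              n_bins = fit$n_bins_used,
                              rss = fit$rss)
    log <- c(log, sprintf("nsfa: %d events detected, %d used, gamma %.3g pS (truth %.3g)",
                          fit$n_events_detected, fit$n_events_used,
                          fit$gamma_pS, truth$gamma_pS))
  }

  if (!is.null(scn$frap)) {
    tr <- gen_frap_trace(scn$frap, n_frames = scn$n_frames,
                         bleach_frame = scn$bleach_frame, seed = scn$seed)
    write_frap_table(list(bleached = tr$bleached, reference = tr$reference),
                     file.path(outdir, "frap.csv"))
    ft <- frap(tr$bleached, tr$reference, bleach_frame = scn$bleach_frame)
    results$frap <- ft
    tables$frap <- data.frame(cell_id = scn$name,
                              tau_rec_s = ft$tau_rec_s,
                              plateau = ft$plateau,
                              f600 = ft$f600,
                              f600_empirical = ft$f600_empirical,
                              tau_true_s = tr$truth$tau_rec_s,
                              plateau_true = tr$truth$plateau)
    log <- c(log, sprintf("frap: tau %.3g s (truth %.3g)", ft$tau_rec_s,
                          tr$truth$tau_rec_s))
  }

  if (!is.null(scn$iv)) {
    fam <- gen_iv_family(scn$iv)
    ri <- rectification_index(fam$holding)
    tables$iv <- data.frame(cell_id = scn$name,
                            i_minus60 = fam$holding$i_minus60,
                            i_0 = fam$holding$i_0,
                            i_plus40 = fam$holding$i_plus40,
                            ri = ri)
    log <- c(log, sprintf("iv: RI %.3g", ri))
  }

  if (!is.null(scn$evoked)) {
    pair <- do.call(gen_evoked_pair, c(scn$evoked, list(seed = scn$seed)))
    an <- ampar_nmdar_ratio(pair$minus60, pair$plus40,
                            onset_s = pair$truth$onset_s)
    pp <- paired_pulse_ratio(pair$paired,
                             pair$truth$onset_s + c(0, 0.05))
    tables$evoked <- data.frame(cell_id = scn$name,
                                ampar_nmdar = an$ratio,
                                ppr = pp$ppr,
                                ppr_true = pair$truth$ppr)
    log <- c(log, sprintf("evoked: AMPAR/NMDAR %.3g, PPR %.3g", an$ratio,
                          pp$ppr))
  }

  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  report <- make_report(tables, config = scn$config)
  write_report(report, file.path(outdir, "report"))
  writeLines(log, file.path(outdir, "run.log"))

  cfg_path <- file.path(outdir, "scenario.json")
  cfg <- scn
  cfg$config <- unclass(cfg$config)
  jsonlite::write_json(lapply(unclass(cfg), function(v)
    if (is.list(v)) unclass(v) else v), cfg_path, auto_unbox = TRUE,
    digits = NA, null = "null")
  manifest <- list(scenario = scn$name, seed = scn$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   outputs = sort(setdiff(list.files(outdir, recursive = TRUE),
                                          "manifest.json")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, tables = tables, manifest = manifest))
}
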