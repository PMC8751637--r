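# Full-session orchestration: phases -> events -> maps/fields -> decoding ->
# replay significance -> precession summaries -> sweeps, plus report output.

#' Analysis configuration
#'
#' All tunable thresholds of the pipeline with their standard defaults.
#'
#' @param theta_band,ripple_band analysis bands (Hz pairs).
#' @param detection_method `"mua"` or `"ripple"` candidate-event detection.
#' @param detect_online_events also run MUA detection over the RUN epoch.
#' @param tbin_validation decoding window on the track (s).
#' @param tbin_event decoding window inside replay events (s).
#' @param n_shuffles cell-identity shuffles per event.
#' @param speeds trajectory-speed search grid (cm/s).
#' @param min_speed running-speed threshold (cm/s).
#' @param max_mean_rate putative-interneuron exclusion threshold (Hz).
#' @param first_per_cycle restrict within-event fits to the first spike per
#'   cycle.
#' @param seed RNG seed controlling the shuffles.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(theta_band = c(6, 12),
                            ripple_band = c(150, 250),
                            detection_method = c("mua", "ripple"),
                            detect_online_events = FALSE,
                            tbin_validation = 0.5,
                            tbin_event = 0.01,
                            n_shuffles = 100,
                            speeds = seq(100, 5000, by = 50),
                            min_speed = 10,
                            max_mean_rate = 10,
                            first_per_cycle = FALSE,
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$detection_method <- match.arg(detection_method)
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full analysis pipeline on a session
#'
#' Sequences the analysis end to end: theta-channel selection and band-limited
#' phase extraction; candidate replay event detection and classification;
#' phase-reference normalization; run segmentation, directional rate maps and
#' place fields; decoding validation; per-event Bayesian decoding, trajectory
#' fitting and shuffle significance; within-event and within-field precession
#' summaries; theta and ripple sweeps. Deterministic given
#' `config$seed`.
#'
#' @param session a `replay_session` (from [generate_session()] or
#'   [read_session()]).
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, report tables are written
#'   as CSV/JSON together with the resolved configuration and a run log.
#' @return list of report tables (invisible when `out_dir` is given).
#' @export
run_pipeline <- function(session, config = analysis_config(), out_dir = NULL) {
  set.seed(config$seed)
  geom <- session$config$geometry
  fs <- session$lfp_fs
  t0 <- session$lfp_t0
  epochs <- session$epochs
  run_epoch <- unlist(epochs[epochs$name == "run", c("start_s", "end_s")])
  rest_epoch <- unlist(epochs[epochs$name == "rest", c("start_s", "end_s")])
  session_dur <- max(epochs$end_s) - min(epochs$start_s)

  ## putative-interneuron exclusion at load time
  rate_tab <- table(factor(session$spikes$cell_id,
                           levels = session$cells$cell_id))
  mean_rate <- as.numeric(rate_tab) / session_dur
  cells <- session$cells
  cells$pyramidal <- cells$pyramidal & mean_rate <= config$max_mean_rate
  pyr_ids <- cells$cell_id[cells$pyramidal]
  spikes <- session$spikes[session$spikes$cell_id %in% pyr_ids, , drop = FALSE]

  ## stage: phases ----------------------------------------------------------
  stage <- "phases"
  res <- tryCatch({
    run_i <- sample_index(run_epoch, t0, fs, nrow(session$lfp))
    channels <- lapply(seq_len(ncol(session$lfp)), function(k)
      session$lfp[run_i[1]:run_i[2], k])
    ch <- select_theta_channel(channels, fs, config$theta_band)
    x <- session$lfp[, ch]
    theta <- instantaneous_phase_amplitude(
      bandpass_filter(x, config$theta_band, fs), fs, t0, config$theta_band)
    ripple <- instantaneous_phase_amplitude(
      bandpass_filter(x, config$ripple_band, fs), fs, t0, config$ripple_band)

    ## stage: events --------------------------------------------------------
    stage <- "events"
    events <- if (config$detection_method == "mua") {
      detect_candidate_events_mua(spikes, cells, session$tracking, rest_epoch)
    } else {
      detect_candidate_events_ripple(x, fs, t0, spikes, cells,
                                     session$tracking, rest_epoch,
                                     band = config$ripple_band)
    }
    events <- classify_events(events, spikes, epochs)
    if (config$detect_online_events) {
      online <- detect_candidate_events_mua(spikes, cells, session$tracking,
                                            run_epoch)
      if (nrow(online) > 0)
        events <- rbind(events, classify_events(online, spikes, epochs))
    }

    ## stage: normalization -------------------------------------------------
    stage <- "normalization"
    ripple_phases_by_cell <- lapply(pyr_ids, function(cid) {
      st <- c()
      for (i in seq_len(nrow(events)))
        st <- c(st, spikes$t_s[spikes$cell_id == cid &
                                 spikes$t_s >= events$start_s[i] &
                                 spikes$t_s <= events$end_s[i]])
      phase_at(ripple, st)
    })
    ripple_norm <- tryCatch(
      reference_phase_normalization(ripple_phases_by_cell, ripple),
      error = function(e) list(offset = 0, series = ripple))
    ripple <- ripple_norm$series
    mv_speed <- track_interp(session$tracking, "speed_cms", spikes$t_s)
    theta_phases_by_cell <- lapply(pyr_ids, function(cid) {
      st <- spikes$t_s[spikes$cell_id == cid & mv_speed >= config$min_speed &
                         spikes$t_s < run_epoch[2]]
      phase_at(theta, st)
    })
    theta_norm <- tryCatch(
      reference_phase_normalization(theta_phases_by_cell, theta),
      error = function(e) list(offset = 0, series = theta))
    theta <- theta_norm$series

    ## stage: rate maps and fields ------------------------------------------
    stage <- "rate_maps"
    runs <- segment_runs(session$tracking, geom)
    map_for <- function(dirn) {
      m <- t(vapply(pyr_ids, function(cid)
        compute_directional_rate_map(
          spikes$t_s[spikes$cell_id == cid], session$tracking, runs, dirn,
          geom, min_speed = config$min_speed)$rate,
        numeric(geom$n_bins)))
      rownames(m) <- pyr_ids
      m
    }
    maps <- list(outbound = map_for(1L), inbound = map_for(-1L))
    fields <- list()
    for (dname in names(maps)) {
      dirn <- if (dname == "outbound") 1L else -1L
      for (cid in pyr_ids) {
        rm <- structure(list(direction = dirn, centres = geom$bin_centres,
                             rate = maps[[dname]][as.character(cid), ],
                             geometry = geom), class = "rate_map")
        f <- detect_place_fields(rm)
        if (nrow(f) > 0) fields[[length(fields) + 1L]] <- cbind(cell_id = cid, f)
      }
    }
    fields <- if (length(fields)) do.call(rbind, fields) else
      data.frame(cell_id = integer(0), start_bin = integer(0),
                 end_bin = integer(0), left_cm = numeric(0),
                 right_cm = numeric(0), peak_cm = numeric(0),
                 peak_hz = numeric(0), width_cm = numeric(0),
                 direction = integer(0))

    ## stage: decoding validation -------------------------------------------
    stage <- "decoding_validation"
    validation <- run_decoding_validation(spikes, pyr_ids, session$tracking,
                                          runs, maps, geom,
                                          tbin = config$tbin_validation,
                                          min_speed = config$min_speed)

    ## stage: replay significance -------------------------------------------
    stage <- "replay_significance"
    trajectories <- vector("list", nrow(events))
    traj_rows <- list()
    for (i in seq_len(nrow(events))) {
      act <- events$active_cells[[i]]
      first_spk <- min(spikes$t_s[spikes$t_s >= events$start_s[i] &
                                    spikes$t_s <= events$end_s[i]])
      counts <- bin_spike_counts(spikes, pyr_ids, first_spk,
                                 events$end_s[i], config$tbin_event)
      if (sum(colSums(counts) > 0) < 2) next
      sig <- trajectory_significance(counts, pyr_ids, act, maps,
                                     config$tbin_event, geom$bin_centres,
                                     n_shuffles = config$n_shuffles,
                                     speeds = config$speeds)
      fit <- sig$fit
      fit$t_start <- first_spk
      trajectories[[i]] <- fit
      traj_rows[[length(traj_rows) + 1L]] <- data.frame(
        event_id = i, origin_cm = fit$origin_cm, speed_cms = fit$speed_cms,
        score = fit$score, p = fit$p, significant = fit$significant,
        map_direction = fit$map_set)
    }
    traj_tab <- if (length(traj_rows)) do.call(rbind, traj_rows) else
      data.frame(event_id = integer(0), origin_cm = numeric(0),
                 speed_cms = numeric(0), score = numeric(0), p = numeric(0),
                 significant = logical(0), map_direction = character(0))

    ## stage: precession -----------------------------------------------------
    stage <- "precession"
    cell_rows <- list()
    for (cid in pyr_ids) {
      st_all <- spikes$t_s[spikes$cell_id == cid]
      fits <- lapply(seq_len(nrow(events)), function(i)
        within_event_fit(st_all, ripple, events$start_s[i], events$end_s[i],
                         restrict_first_per_cycle = config$first_per_cycle))
      summ <- cell_precession_summary(fits, cid)
      if (is.null(summ)) next
      summ$burst_index <- burst_index(st_all)
      cell_rows[[length(cell_rows) + 1L]] <- summ
    }
    cell_tab <- if (length(cell_rows)) do.call(rbind, cell_rows) else NULL

    pooled <- pool_within_field_ripple(events, trajectories, spikes, fields,
                                       ripple, geom$total)
    field_rows <- list()
    if (nrow(pooled) > 0) {
      key <- interaction(pooled$cell_id, pooled$direction, pooled$left_cm)
      for (k in levels(droplevels(key))) {
        pp <- pooled[key == k, , drop = FALSE]
        wf <- within_field_fit(pp$d, pp$phase)
        if (!isTRUE(wf$included)) next
        field_rows[[length(field_rows) + 1L]] <- data.frame(
          cell_id = pp$cell_id[1], direction = pp$direction[1],
          context = "ripple", slope = wf$slope, intercept = wf$intercept,
          n = wf$n, coverage = wf$coverage)
      }
    }
    ## theta variant: actual location, first spike per theta cycle
    for (j in seq_len(nrow(fields))) {
      cid <- fields$cell_id[j]
      dirn <- fields$direction[j]
      use <- runs[runs$successful & runs$direction == dirn, , drop = FALSE]
      st <- spikes$t_s[spikes$cell_id == cid]
      dd <- c(); phs <- c()
      for (r in seq_len(nrow(use))) {
        s <- st[st >= use$t_start[r] & st <= use$t_end[r]]
        s <- first_spike_per_cycle(s, theta)
        if (length(s) == 0) next
        pos <- track_interp(session$tracking, "pos_cm", s)
        spd <- track_interp(session$tracking, "speed_cms", s)
        ok <- spd >= config$min_speed & pos >= fields$left_cm[j] &
          pos <= fields$right_cm[j]
        if (!any(ok)) next
        dd <- c(dd, relative_field_position(pos[ok], fields$left_cm[j],
                                            fields$right_cm[j], dirn))
        phs <- c(phs, phase_at(theta, s[ok]))
      }
      wf <- within_field_fit(dd, phs)
      if (!isTRUE(wf$included)) next
      field_rows[[length(field_rows) + 1L]] <- data.frame(
        cell_id = cid, direction = dirn, context = "theta",
        slope = wf$slope, intercept = wf$intercept, n = wf$n,
        coverage = wf$coverage)
    }
    field_tab <- if (length(field_rows)) do.call(rbind, field_rows) else NULL

    ## stage: sweeps ----------------------------------------------------------
    stage <- "sweeps"
    movement <- detect_movement_events(session$tracking,
                                       min_speed = config$min_speed)
    sweep_rows <- list()
    for (i in seq_len(nrow(movement))) {
      tsel <- session$tracking$t_s >= movement$start_s[i] &
        session$tracking$t_s <= movement$end_s[i]
      dirn <- if (mean(diff(session$tracking$pos_cm[tsel])) >= 0) 1L else -1L
      sw <- theta_sweep(movement$start_s[i], movement$end_s[i], spikes,
                        fields[fields$direction == dirn, , drop = FALSE],
                        theta, session$tracking, dirn)
      if (!sw$included) next
      sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
        event_id = i, context = "theta", slope_cm_per_rad = sw$slope_cm_per_rad,
        range_cm = sw$range_cm, speed_cms = sw$speed_cms,
        direction_consistent = sw$direction_consistent)
    }
    for (i in seq_len(nrow(events))) {
      traj <- trajectories[[i]]
      if (is.null(traj) || !isTRUE(traj$significant)) next
      mv_dir <- sign(traj$speed_cms)
      sw <- ripple_sweep(events$start_s[i], events$end_s[i], traj, spikes,
                         fields[fields$direction == mv_dir, , drop = FALSE],
                         ripple, geom$total)
      if (!sw$included) next
      sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
        event_id = i, context = "ripple",
        slope_cm_per_rad = sw$slope_cm_per_rad, range_cm = sw$range_cm,
        speed_cms = sw$speed_cms,
        direction_consistent = sw$direction_consistent)
    }
    sweep_tab <- if (length(sweep_rows)) do.call(rbind, sweep_rows) else NULL

    list(channel = ch, events = events, trajectories = traj_tab,
         trajectory_fits = trajectories, maps = maps, fields = fields,
         validation = validation, cell_precession = cell_tab,
         field_precession = field_tab, sweeps = sweep_tab,
         ripple_offset = ripple_norm$offset, theta_offset = theta_norm$offset,
         theta = theta, ripple = ripple, runs = runs, config = config)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    write_report(res, out_dir)
    return(invisible(res))
  }
  res
}

# flatten list-columns and write the report bundle
write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) sprintf("%.10g", x)
  ev <- res$events
  ev$active_cells <- vapply(ev$active_cells, paste, character(1),
                            collapse = ";")
  if (!is.null(ev$n_spike_cells))
    ev$n_spike_cells <- vapply(ev$n_spike_cells, paste, character(1),
                               collapse = ";")
  for (cn in c("start_s", "end_s", "peak_s"))
    ev[[cn]] <- num(ev[[cn]])
  utils::write.csv(ev, file.path(out_dir, "events.csv"), row.names = FALSE)
  utils::write.csv(res$trajectories, file.path(out_dir, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(res$fields, file.path(out_dir, "fields.csv"),
                   row.names = FALSE)
  utils::write.csv(res$validation$detail, file.path(out_dir, "decoding.csv"),
                   row.names = FALSE)
  if (!is.null(res$cell_precession)) {
    ct <- res$cell_precession
    ct$shifts_by_pair <- NULL
    ct$all_shifts <- NULL
    utils::write.csv(ct, file.path(out_dir, "cell_precession.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$field_precession))
    utils::write.csv(res$field_precession,
                     file.path(out_dir, "field_precession.csv"),
                     row.names = FALSE)
  if (!is.null(res$sweeps))
    utils::write.csv(res$sweeps, file.path(out_dir, "sweeps.csv"),
                     row.names = FALSE)
  summary <- list(
    n_events = nrow(res$events),
    n_significant = sum(res$trajectories$significant),
    frac_significant = if (nrow(res$trajectories) > 0)
      mean(res$trajectories$significant) else NA,
    median_decode_error_outbound_cm = res$validation$outbound,
    median_decode_error_inbound_cm = res$validation$inbound,
    ripple_offset_rad = res$ripple_offset,
    theta_offset_rad = res$theta_offset,
    theta_channel = res$channel)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cfg <- res$config
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
  hash <- unname(tools::md5sum(file.path(out_dir, "config_resolved.yaml")))
  writeLines(c(sprintf("config_md5: %s", hash),
               sprintf("stages: phases events normalization rate_maps %s",
                       "decoding_validation replay_significance precession sweeps")),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Build a ready-made synthetic fixture
#'
#' @param profile `"small"` (completes the full pipeline in well under two
#'   minutes on one CPU) or `"standard"` (parameters echoing a full recording
#'   session: 34 cells, ~28 min of RUN).
#' @param seed RNG seed.
#' @param path optional directory: when given, the bundle is written there
#'   with [write_session()].
#' @return the `replay_session` (invisibly when `path` is given).
#' @export
make_fixture <- function(profile = c("small", "standard"), seed = 1,
                         path = NULL) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    small = session_config(n_cells = 15, n_runs = 4, run_speed_mean = 60,
                           rest_duration = 200, n_replay_events = 10,
                           replay_speed_range = c(500, 1500),
                           peak_rate = 10),
    standard = session_config(n_cells = 34, n_runs = 60,
                              rest_duration = 1800, n_replay_events = 150))
  session <- generate_session(cfg, seed)
  if (!is.null(path)) {
    write_session(session, path)
    return(invisible(session))
  }
  session
}
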