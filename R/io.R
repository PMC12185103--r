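# Readers, writers, session manifest and the pipeline driver. All CSV is
# comma-separated, '.' decimal, UTF-8, LF; every results directory carries
# the config hash and the seed registry so reruns are bit-identical.

readCsvChecked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  }
  df
}

#' Read a position CSV
#'
#' Schema: `t_s, x_room_cm, y_room_cm, theta_deg`. Validates monotone
#' uniform time, finite coordinates and the arena radius, reporting the
#' offending row on failure.
#'
#' @param path CSV path.
#' @param arenaRadius arena radius, cm.
#' @return A [PositionSeries-class].
#' @export
readPositions <- function(path, arenaRadius = 41) {
  df <- readCsvChecked(path, c("t_s", "x_room_cm", "y_room_cm", "theta_deg"))
  bad <- which(!stats::complete.cases(df) |
                 !is.finite(df$x_room_cm) | !is.finite(df$y_room_cm))
  if (length(bad)) {
    stop(sprintf("%s: non-finite values at row %d", basename(path), bad[1]))
  }
  if (nrow(df) >= 2 && any(diff(df$t_s) <= 0)) {
    stop(sprintf("%s: timestamps not strictly increasing at row %d",
                 basename(path), which(diff(df$t_s) <= 0)[1] + 1L))
  }
  r <- sqrt(df$x_room_cm^2 + df$y_room_cm^2)
  if (any(r > arenaRadius + 5)) {
    stop(sprintf("%s: position outside the arena (radius %.1f cm) at row %d",
                 basename(path), arenaRadius, which(r > arenaRadius + 5)[1]))
  }
  PositionSeries(df$t_s, df$x_room_cm, df$y_room_cm, df$theta_deg,
                 arenaRadius = arenaRadius)
}

#' Write a position CSV
#' @param series a [PositionSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePositions <- function(series, path) {
  df <- data.frame(
    t_s = series@t, x_room_cm = series@x, y_room_cm = series@y,
    theta_deg = series@theta
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a unit metadata CSV
#'
#' Schema: `unit_id, waveform_us, region_tag` (extra columns, e.g. the
#' simulator's ground-truth parameters, are preserved).
#'
#' @param path CSV path.
#' @return data.frame of unit metadata.
#' @export
readUnits <- function(path) {
  df <- readCsvChecked(path, c("unit_id", "waveform_us", "region_tag"))
  df$unit_id <- as.character(df$unit_id)
  df
}

#' Read a spike-time CSV into SpikeTrain objects
#'
#' Schema: `unit_id, t_s`. Spike rows are sorted per unit; exact duplicate
#' (unit, time) rows are removed with a message; a unit appearing in the
#' spike file but not in the metadata is an error.
#'
#' @param path CSV path.
#' @param units optional [readUnits()] data.frame supplying waveform and
#'   region metadata (and the authoritative unit list).
#' @return named list of [SpikeTrain-class].
#' @export
readSpikes <- function(path, units = NULL) {
  df <- readCsvChecked(path, c("unit_id", "t_s"))
  df$unit_id <- as.character(df$unit_id)
  if (nrow(df) == 0) {
    warning(sprintf("%s: empty spike file", basename(path)))
  }
  dup <- duplicated(df[, c("unit_id", "t_s")])
  if (any(dup)) {
    message(sprintf("readSpikes: removed %d duplicate (unit, t) rows",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  if (!is.null(units)) {
    unknown <- setdiff(unique(df$unit_id), units$unit_id)
    if (length(unknown)) {
      stop(sprintf("spike file references unknown unit(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    ids <- units$unit_id
  } else {
    ids <- sort(unique(df$unit_id))
  }
  trains <- lapply(ids, function(id) {
    tt <- sort(df$t_s[df$unit_id == id])
    wf <- NA_real_; rg <- "unknown"
    if (!is.null(units)) {
      row <- units[units$unit_id == id, , drop = FALSE]
      wf <- row$waveform_us[1]
      rg <- row$region_tag[1]
    }
    SpikeTrain(id, tt, waveformUs = wf, regionTag = rg)
  })
  names(trains) <- ids
  trains
}

#' Read a CO optical-density readings CSV
#'
#' Schema: `subject, group, region, hemisphere, reading_index, od`.
#'
#' @param path CSV path.
#' @return data.frame of readings.
#' @export
readCo <- function(path) {
  readCsvChecked(path, c("subject", "group", "region", "od"))
}

#' Analysis configuration defaults
#'
#' One structured list holding every tunable threshold of the analysis:
#' the 133 ms information window, the 5 s overdispersion episode, sector
#' widths, the near/far coverage, debounce and map parameters, and the FDR
#' level.
#'
#' @param ... overrides by name.
#' @return named list of parameters.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    dt = 0.133,              # Ipos window, s
    episodeLen = 5,          # overdispersion episode, s
    zoneWidth = 60,          # shock zone, degrees
    seedWidth = 20,          # least-visited seed sector, degrees
    coverage = 0.5,          # near-half occupancy fraction
    refractory = 1.5,        # entrance debounce, s
    minStep = 0.32,          # distance filter, cm
    binCm = 2.5,             # rate-map bin, cm
    smoothingSigma = 1,      # rate-map smoothing, bins
    minOccupancy = 0.5,      # rate-map mask, s
    nGrid = 16,              # information grid per axis
    minSamples = 10,         # windows per information bin
    minSpikes = 50,          # session spikes to enter the ensemble
    includeZero = FALSE,     # count a cell's silent windows in its dIpos?
    fdrQ = 0.01,             # network FDR level
    frame = "auto"           # overdispersion expectation frame
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  utils::modifyList(cfg, over)
}

#' Hash a configuration (provenance stamp)
#' @param cfg a configuration list.
#' @return md5 hex string.
#' @export
configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Session manifest
#'
#' Describes one session of the training workflow. Phase/zone consistency
#' is enforced: pretraining sessions carry no zone, and a conflict session
#' without an explicit zone derives it 180 degrees from `initialZone`.
#'
#' @param sessionId identifier.
#' @param phase "pretraining", "training", "retention" or "conflict".
#' @param positions,spikes,units file paths (spikes/units may be NA).
#' @param zone [SectorSpec-class] or NULL.
#' @param initialZone the initial-training zone, used to derive the
#'   conflict zone.
#' @return list of class "SessionManifest".
#' @export
sessionManifest <- function(sessionId, phase, positions, spikes = NA,
                            units = NA, zone = NULL, initialZone = NULL) {
  phase <- match.arg(phase,
                     c("pretraining", "training", "retention", "conflict"))
  if (phase == "pretraining" && !is.null(zone)) {
    stop("sessionManifest: pretraining sessions have no shock zone")
  }
  if (phase == "conflict" && is.null(zone)) {
    if (is.null(initialZone)) {
      stop("sessionManifest: conflict phase needs a zone or initialZone")
    }
    zone <- SectorSpec(initialZone@frame,
                       (initialZone@center + 180) %% 360,
                       initialZone@width)
  }
  if (phase %in% c("training", "retention") && is.null(zone)) {
    stop(sprintf("sessionManifest: %s phase needs a zone", phase))
  }
  structure(
    list(sessionId = sessionId, phase = phase, zone = zone,
         positions = positions, spikes = spikes, units = units),
    class = "SessionManifest"
  )
}

writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
}

#' Write a simulated session to disk
#'
#' Produces `positions.csv`, `spikes.csv` (`unit_id,t_s`), `units.csv`
#' (`unit_id,waveform_us,region_tag` plus the ground-truth tuning
#' parameters), `state.csv` and `manifest.json` recording the configuration,
#' its hash and the seed — everything a downstream run needs for an exact
#' replay. All generative processes are synthetic stand-ins and the manifest
#' says so.
#'
#' @param cfg a [SimConfig-class].
#' @param cells list of [CellSpec-class].
#' @param sp a [StateProcess-class].
#' @param gain a [GainProcess-class].
#' @param outDir output directory (created).
#' @return `outDir`, invisibly.
#' @export
simulateSession <- function(cfg, cells, sp = StateProcess("none"),
                            gain = GainProcess(), outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  series <- simulateTrajectory(cfg)
  state <- latentState(series, sp, seed = cfg@seed)
  trains <- simulateEnsemble(series, cells, state, gain, seed = cfg@seed)
  writePositions(series, file.path(outDir, "positions.csv"))
  spk <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(unit_id = tr@unitId, t_s = tr@times)
  }))
  writeTable(spk, file.path(outDir, "spikes.csv"))
  un <- do.call(rbind, lapply(seq_along(cells), function(j) {
    cl <- cells[[j]]
    data.frame(
      unit_id = trains[[j]]@unitId, waveform_us = trains[[j]]@waveformUs,
      region_tag = trains[[j]]@regionTag, frame = cl@frame,
      center_x_cm = cl@center[1], center_y_cm = cl@center[2],
      sigma_cm = cl@sigma, peak_hz = cl@peak, baseline_hz = cl@baseline
    )
  }))
  writeTable(un, file.path(outDir, "units.csv"))
  writeTable(data.frame(t_s = series@t, room_state = state),
             file.path(outDir, "state.csv"))
  man <- list(
    generator = "synthetic stand-in (OU foraging, Gaussian frame-locked tuning, renewal frame switching, per-pass gain)",
    seed = cfg@seed,
    config = list(
      arenaRadius = cfg@arenaRadius, rotationRpm = cfg@rotationRpm,
      fs = cfg@fs, duration = cfg@duration, ouTau = cfg@ouTau,
      ouSigma = cfg@ouSigma, avoidanceGain = cfg@avoidanceGain,
      stateMode = sp@mode, meanDwell = sp@meanDwell,
      pRoomNear = sp@pRoomNear, pRoomFar = sp@pRoomFar,
      gains = gain@gains, gainProbs = gain@probs,
      passLength = gain@passLength
    )
  )
  man$configHash <- configHash(man$config)
  jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Run the full analysis pipeline for a set of sessions
#'
#' For every session: behavioural end points (full session and the first
#' 5 min window when a zone is defined); for sessions with spikes: the
#' unit-metric table, per-pyramidal-cell overdispersion in the configured
#' frame, and the ensemble SFEP with preference map and near/far summary.
#' Writes one results directory carrying the config hash, the seed registry
#' and the retention logs; identical config and seed reproduce identical
#' files.
#'
#' @param manifests list of [sessionManifest()] objects.
#' @param config a [defaultConfig()] list.
#' @param outDir results directory.
#' @return named list of per-session result lists, invisibly; files under
#'   `outDir`.
#' @export
runPipeline <- function(manifests, config = defaultConfig(), outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  results <- list()
  behaviorRows <- list()
  for (man in manifests) {
    stopifnot(inherits(man, "SessionManifest"))
    series <- readPositions(man$positions)
    res <- list(sessionId = man$sessionId, phase = man$phase)
    if (!is.null(man$zone)) {
      res$behavior <- behaviorEndpoints(series, man$zone,
        refractory = config$refractory, minStep = config$minStep)
      res$behaviorFirst5 <- behaviorEndpoints(series, man$zone,
        refractory = config$refractory, minStep = config$minStep,
        window = c(series@t[1], series@t[1] + 300))
      behaviorRows[[man$sessionId]] <- cbind(
        session_id = man$sessionId, phase = man$phase, res$behavior,
        n_entrances_first5 = res$behaviorFirst5$n_entrances
      )
    } else {
      res$behavior <- data.frame(
        distance_m = pathLength(series, minStep = config$minStep),
        time_to_first_entry_s = NA, censored = NA, n_entrances = NA,
        session_length_s = sessionLength(series)
      )
      behaviorRows[[man$sessionId]] <- cbind(
        session_id = man$sessionId, phase = man$phase, res$behavior,
        n_entrances_first5 = NA
      )
    }
    if (!is.na(man$spikes) && !is.na(man$units)) {
      units <- readUnits(man$units)
      trains <- readSpikes(man$spikes, units)
      sl <- sessionLength(series)
      res$unitMetrics <- unitMetrics(trains, sl)
      writeTable(res$unitMetrics,
                 file.path(outDir, paste0(man$sessionId, "_units.csv")))
      pyr <- pyramidalUnits(trains, sl, minSpikes = config$minSpikes)
      if (length(pyr) > 0) {
        od <- lapply(pyr, function(tr) {
          fr <- config$frame
          if (fr == "auto") {
            fr <- preferredFrame(tr, series, binCm = config$binCm,
              smoothingSigma = config$smoothingSigma,
              minOccupancy = config$minOccupancy)
          }
          m <- rateMap(tr, series, fr, binCm = config$binCm,
            smoothingSigma = config$smoothingSigma,
            minOccupancy = config$minOccupancy)
          ez <- episodeZs(tr, series, m, episodeLen = config$episodeLen)
          cbind(unit_id = tr@unitId, frame = fr, ez)
        })
        res$episodes <- do.call(rbind, od)
        writeTable(res$episodes,
                   file.path(outDir, paste0(man$sessionId, "_episodes.csv")))
        odSumm <- do.call(rbind, lapply(od, function(ez) {
          zs <- ez$z[ez$retained]
          data.frame(
            unit_id = ez$unit_id[1], frame = ez$frame[1],
            n_episodes = nrow(ez), n_retained = sum(ez$retained),
            var_z = if (sum(ez$retained) >= 2) stats::var(zs) else NA
          )
        }))
        res$overdispersion <- odSumm
        writeTable(odSumm,
          file.path(outDir, paste0(man$sessionId, "_overdispersion.csv")))
        cellTabs <- lapply(pyr, function(tr) {
          cellDeltaIpos(tr, series, dt = config$dt, nGrid = config$nGrid,
                        minSamples = config$minSamples,
                        includeZero = config$includeZero)
        })
        pref <- deltaIposEnsemble(cellTabs)
        res$sfep <- pref
        writeTable(
          data.frame(t_center = pref@t, ensemble_dI = pref@deltaI),
          file.path(outDir, paste0(man$sessionId, "_sfep_series.csv"))
        )
        summ <- data.frame(
          session_id = man$sessionId, sfep_room = pref@sfepRoom,
          runs_z = pref@runsZ, runs_p = pref@runsP, n_cells = pref@nCells,
          n_windows = length(pref@t), n_ties = pref@nTies
        )
        pm <- preferenceMap(pref, series, nGrid = config$nGrid,
                            minSamples = config$minSamples)
        res$preferenceMap <- pm
        part <- nearFarPartition(series, seedWidth = config$seedWidth,
                                 coverage = config$coverage)
        nf <- tryCatch(nearFarSummary(pm, part), error = function(e) {
          list(pNear = NA_real_, pFar = NA_real_)
        })
        summ$p_near <- nf$pNear
        summ$p_far <- nf$pFar
        res$nearFar <- nf
        writeTable(summ,
                   file.path(outDir, paste0(man$sessionId, "_sfep.csv")))
      }
    }
    results[[man$sessionId]] <- res
  }
  writeTable(do.call(rbind, behaviorRows),
             file.path(outDir, "behavior_endpoints.csv"))
  prov <- list(
    configHash = hash, config = config,
    sessions = vapply(manifests, function(m) m$sessionId, character(1)),
    package = "placeframes",
    version = as.character(utils::packageVersion("placeframes"))
  )
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
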