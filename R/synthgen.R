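# Synthetic recording sessions: multichannel LFP with state-dependent
# spectral structure and a polarity-reversal geometry, a visual-stimulus
# calibration segment, a per-frame movement stream, pose tables with
# proboscis-extension (PE) kinematics and sleeping antennal oscillations, and
# ground-truth labels/events. Everything downstream is testable against the
# configured effect sizes.

#' Build a synthetic-session configuration
#'
#' See [SimConfig-class] for the meaning of every field. Defaults emulate the
#' study conditions: 16-channel probe with the polarity reversal at channel
#' 12, sleep bouts around 10 min separated by ~6 min of activity (night bouts
#' ~1.6x longer), awake 5-40 Hz power twice midsleep power with early/late
#' sleep intermediate, a 5-10 Hz power boost on central channels 1-3 whose
#' strength differs across sleep stages, PE bursts at ~1.5 s intra-burst
#' intervals concentrated beyond 2.5 min into midsleep, and 1 Hz antennal
#' oscillations during sleep.
#'
#' @param ... overrides of any [SimConfig-class] slot.
#' @return validated [SimConfig-class].
#' @export
simConfig <- function(...) {
  defaults <- list(
    n_flies = 16, session_hours = 2,
    fs_lfp = 250, fs_raw = 250, fps_video = 30,
    n_channels = 16, reversal_channel = 12,
    bout_mean_min = 10, bout_sd_min = 2.5,
    interbout_mean_min = 6, interbout_sd_min = 1.5,
    night_bout_factor = 1.6,
    awake_power_gain = 2.0, presleep_gain = 1.7, early_late_gain = 1.45,
    central_theta_boost = c(early = 2.0, mid = 6.0, late = 3.2),
    pe_lfp_boost = 1.5, evoked_amp_uv = 60,
    pe_rate_wake = 0.3, pe_rate_midsleep = 1.5,
    pe_intra_burst_interval_s = 1.5, pe_burst_gap_s = 10,
    pe_single_prob = 0.33,
    antenna_osc_freq = 1, antenna_osc_amp_deg = 10,
    noise_sd = 10, noise_exponent = 1, shared_sd = 5,
    occlusion_per_hour = 0, sleep_prob = 1,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown SimConfig fields: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  do.call(new, c(list(Class = "SimConfig"), defaults))
}

# schedule sleep bouts on a whole-second grid; night (>= 6 h into the
# session) bouts are longer by night_bout_factor
scheduleBouts <- function(config, total_s) {
  bouts <- data.frame(start_s = numeric(), end_s = numeric())
  t0 <- 0
  night_from <- 6 * 3600
  repeat {
    gap <- round(max(stats::rnorm(1, config@interbout_mean_min * 60,
                                  config@interbout_sd_min * 60), 270))
    bstart <- t0 + gap
    bm <- config@bout_mean_min * 60
    if (bstart >= night_from) bm <- bm * config@night_bout_factor
    dur <- round(max(stats::rnorm(1, bm, config@bout_sd_min * 60), 330))
    if (bstart + dur > total_s - 10) break
    if (stats::runif(1) < config@sleep_prob) {
      bouts <- rbind(bouts, data.frame(start_s = bstart, end_s = bstart + dur))
      t0 <- bstart + dur
    } else {
      t0 <- bstart + dur # time passes awake instead
    }
  }
  bouts
}

# gain (power factor relative to midsleep) per label
stageGains <- function(config) {
  c(awake = config@awake_power_gain, pre2 = config@awake_power_gain,
    post2 = config@awake_power_gain, presleep = config@presleep_gain,
    earlysleep = config@early_late_gain, latesleep = config@early_late_gain,
    midsleep = 1)
}

# per-sample stage gain vector from truth labels
gainSeries <- function(labels, config, n, fs) {
  g <- stageGains(config)
  out <- rep(g[["awake"]], n)
  iv <- intervals(labels)
  for (k in seq_len(nrow(iv))) {
    i0 <- floor(iv$start_s[k] * fs) + 1L
    i1 <- min(ceiling(iv$end_s[k] * fs), n)
    if (i1 >= i0) out[i0:i1] <- g[[iv$label[k]]]
  }
  out
}

#' Simulate a PE burst event process
#'
#' Burst onsets are Poisson within each eligible interval; burst length is 1
#' with probability `pe_single_prob`, otherwise 2 + Poisson(1.5); within-burst
#' intervals are Gaussian around `pe_intra_burst_interval_s`. In midsleep,
#' onsets fall at least 2.5 min into the interval with probability 0.9.
#' Bursts closer than `pe_burst_gap_s` to the previous burst are dropped.
#'
#' @param labels truth [StateLabels-class].
#' @param config [SimConfig-class].
#' @return [PEEventTable-class] of ground-truth events.
#' @keywords internal
simulateEvents <- function(labels, config) {
  iv <- intervals(labels)
  onsets <- numeric()
  for (k in seq_len(nrow(iv))) {
    lab <- iv$label[k]
    dur_min <- (iv$end_s[k] - iv$start_s[k]) / 60
    rate <- if (lab %in% c("awake", "presleep", "pre2", "post2"))
      config@pe_rate_wake else if (lab == "midsleep") config@pe_rate_midsleep
    else 0
    nb <- stats::rpois(1, rate * dur_min)
    if (nb == 0L) next
    if (lab == "midsleep") {
      off <- min(150, 0.9 * (iv$end_s[k] - iv$start_s[k]))
      deep <- stats::runif(nb) < 0.9
      u <- ifelse(deep,
                  iv$start_s[k] + off + stats::runif(nb) * (iv$end_s[k] - iv$start_s[k] - off),
                  iv$start_s[k] + stats::runif(nb) * (iv$end_s[k] - iv$start_s[k]))
    } else {
      u <- iv$start_s[k] + stats::runif(nb) * (iv$end_s[k] - iv$start_s[k])
    }
    onsets <- c(onsets, u)
  }
  onsets <- sort(onsets)
  ev <- list()
  burst_id <- 0L
  last_end <- -Inf
  for (on in onsets) {
    if (on - last_end < config@pe_burst_gap_s) next
    L <- if (stats::runif(1) < config@pe_single_prob) 1L
    else 2L + stats::rpois(1, 1.5)
    gaps <- pmax(stats::rnorm(L - 1, config@pe_intra_burst_interval_s, 0.1), 0.8)
    times <- on + c(0, cumsum(gaps))
    # keep the burst inside its state interval
    iv_k <- findInterval(on, intervals(labels)$start_s)
    lim <- intervals(labels)$end_s[iv_k]
    times <- times[times < lim - 0.3]
    if (!length(times)) next
    burst_id <- burst_id + 1L
    ev[[burst_id]] <- data.frame(
      peak_time_s = times, state = intervals(labels)$label[iv_k],
      burst_id = burst_id)
    last_end <- max(times)
  }
  if (!length(ev)) {
    return(new("PEEventTable", events = data.frame(
      peak_frame = integer(), peak_time_s = numeric(), state = character(),
      burst_id = integer(), burst_length = integer(), iei_s = numeric(),
      provenance = character())))
  }
  tab <- do.call(rbind, ev)
  tab <- tab[order(tab$peak_time_s), ]
  tab$peak_frame <- round(tab$peak_time_s * config@fps_video) + 1L
  bl <- table(tab$burst_id)
  tab$burst_length <- as.integer(bl[as.character(tab$burst_id)])
  tab$iei_s <- c(NA, diff(tab$peak_time_s))
  first <- !duplicated(tab$burst_id)
  tab$iei_s[first] <- NA
  tab$provenance <- "truth"
  rownames(tab) <- NULL
  new("PEEventTable", events = tab[, c("peak_frame", "peak_time_s", "state",
                                       "burst_id", "burst_length", "iei_s",
                                       "provenance")])
}

# per-frame movement activity: high only outside sleep bouts; movement is
# forced right at bout edges so detected boundaries match truth closely
simulateMovement <- function(labels, config, total_s) {
  fps <- config@fps_video
  times <- seq(0, total_s - 1 / fps, by = 1 / fps)
  sec <- floor(times)
  iv <- intervals(labels)
  sleeping <- rep(FALSE, length(unique(sec)))
  for (k in which(iv$label %in% c("sleep", "earlysleep", "midsleep", "latesleep"))) {
    s0 <- floor(iv$start_s[k]); s1 <- ceiling(iv$end_s[k]) - 1
    sleeping[(s0:s1) + 1L] <- TRUE
  }
  move_sec <- !sleeping & (stats::runif(length(sleeping)) < 0.75)
  # force movement in the two awake seconds flanking each sleep run
  r <- rle(sleeping)
  ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
  for (k in which(r$values)) {
    for (s in c(starts[k] - 1L, starts[k] - 2L, ends[k] + 1L, ends[k] + 2L)) {
      if (s >= 1L && s <= length(move_sec) && !sleeping[s]) move_sec[s] <- TRUE
    }
  }
  moved <- move_sec[sec + 1L]
  activity <- ifelse(moved, pmax(stats::rnorm(length(moved), 300, 50), 60),
                     abs(stats::rnorm(length(moved), 0, 2)))
  data.frame(time_s = times, activity = activity, truth_moved = moved)
}

#' Threshold a movement-activity series into movement flags
#'
#' @param movement data.frame(time_s, activity) at video rate.
#' @param fps frames per second.
#' @param thresh activity threshold separating moved from still frames.
#' @return [movementFlags()] data.frame.
#' @export
activityToFlags <- function(movement, fps = 30, thresh = 30) {
  movementFlags(movement$activity >= thresh, fps = fps,
                times = movement$time_s, area = movement$activity)
}

# signed ramp channel weights crossing zero at the reversal channel:
# peripheral (high-index) channels positive, central negative
reversalWeights <- function(n_channels, reversal_channel) {
  (seq_len(n_channels) - reversal_channel) / (n_channels - reversal_channel)
}

#' Simulate one complete recording session
#'
#' Generates ground-truth sleep bouts and five-state labels, a movement
#' stream that is active only outside sleep, multichannel LFP with (i)
#' per-channel 1/f background noise, (ii) a shared broadband component whose
#' channel weights form a signed ramp crossing zero at the reversal channel,
#' (iii) state-dependent 5-40 Hz power per the configured gains, (iv) a
#' stage-specific 5-10 Hz boost on channels 1-3 during sleep and a 32-40 Hz
#' boost on channels 1-5 around sleep PEs, plus a calibration segment, a pose
#' table and ground-truth PE events. The LFP is emitted as hourly segments
#' (with small DC offsets) to exercise stitching. Identical config + seed
#' reproduces the session bit-for-bit.
#'
#' @param config [SimConfig-class].
#' @param with_lfp,with_pose set FALSE to skip the expensive streams when only
#'   labels/movement/events are needed.
#' @return [SimSession-class].
#' @export
simulateSession <- function(config, with_lfp = TRUE, with_pose = TRUE) {
  validObject(config)
  set.seed(config@seed %% .Machine$integer.max)
  total_s <- round(config@session_hours * 3600)
  bouts <- scheduleBouts(config, total_s)
  if (config@sleep_prob > 0 && nrow(bouts) == 0L) {
    stop(sprintf(
      paste0("session too short for one >=5-min sleep bout: session_hours=%g",
             " with interbout_mean_min=%g, bout_mean_min=%g"),
      config@session_hours, config@interbout_mean_min, config@bout_mean_min))
  }
  truth_labels <- labelEpochs(boutsToLabels(bouts, total_s))
  movement <- simulateMovement(truth_labels, config, total_s)
  truth_events <- simulateEvents(truth_labels, config)

  lfp_segments <- list()
  if (with_lfp) {
    lfp_segments <- simulateLFP(truth_labels, truth_events, config, total_s)
  }
  calibration <- simulateCalibration(config)
  pose <- if (with_pose) {
    simulatePose(truth_events, config, labels = truth_labels,
                 duration_s = total_s)
  } else {
    new("PoseTrack", data = data.frame(
      eye_x = numeric(), eye_y = numeric(), eye_likelihood = numeric()),
      fps = config@fps_video, parts = "eye")
  }
  new("SimSession", lfp_segments = lfp_segments, calibration = calibration,
      movement = movement, pose = pose, truth_labels = truth_labels,
      truth_events = truth_events, config = config)
}

# core LFP synthesis; returns a list of hourly LFPRecording segments
simulateLFP <- function(labels, events, config, total_s) {
  fs <- config@fs_raw
  n <- total_s * fs
  nch <- config@n_channels
  g <- sqrt(gainSeries(labels, config, n, fs)) # amplitude factor
  w <- reversalWeights(nch, config@reversal_channel)
  shared <- pinkNoise(n, config@noise_exponent) * config@shared_sd
  frac_theta <- bandVarianceFraction(n, fs, c(5, 10), config@noise_exponent)
  frac_high <- bandVarianceFraction(n, fs, c(32, 40), config@noise_exponent)
  gains <- stageGains(config)
  iv <- intervals(labels)

  # stage-specific amplitude series for the central 5-10 Hz boost
  boostAmp <- function(ch) {
    base_var <- (config@noise_sd^2 + (config@shared_sd * w[ch])^2)
    amp <- numeric(n)
    for (k in seq_len(nrow(iv))) {
      stage <- switch(iv$label[k], earlysleep = "early", midsleep = "mid",
                      latesleep = "late", NULL)
      if (is.null(stage)) next
      b <- config@central_theta_boost[[stage]]
      extra <- (b - 1) * gains[[iv$label[k]]] * base_var * frac_theta
      i0 <- floor(iv$start_s[k] * fs) + 1L
      i1 <- min(ceiling(iv$end_s[k] * fs), n)
      amp[i0:i1] <- sqrt(extra)
    }
    amp
  }
  # 32-40 Hz bursts around sleep PEs (channels 1-5); short segments only
  sleep_ev <- events(events)
  sleep_ev <- sleep_ev[sleep_ev$state %in% c("earlysleep", "midsleep", "latesleep"),
                       , drop = FALSE]
  addPEBursts <- function(xc, ch) {
    if (config@pe_lfp_boost <= 1 || nrow(sleep_ev) == 0L) return(xc)
    base_var <- (config@noise_sd^2 + (config@shared_sd * w[ch])^2)
    extra <- (config@pe_lfp_boost - 1) * base_var * frac_high # midsleep gain 1
    for (t0 in sleep_ev$peak_time_s) {
      i0 <- max(floor((t0 - 0.5) * fs) + 1L, 1L)
      i1 <- min(ceiling((t0 + 0.5) * fs), n)
      xc[i0:i1] <- xc[i0:i1] + bandNoise(i1 - i0 + 1L, fs, c(32, 40)) * sqrt(extra)
    }
    xc
  }

  x <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    xc <- (pinkNoise(n, config@noise_exponent) * config@noise_sd +
             shared * w[ch]) * g
    if (ch <= 3) xc <- xc + bandNoise(n, fs, c(5, 10)) * boostAmp(ch)
    if (ch <= 5) xc <- addPEBursts(xc, ch)
    x[ch, ] <- xc
  }
  # emit hourly chunks with small per-segment DC offsets
  seg_starts <- seq(0, total_s - 1, by = 3600)
  lapply(seg_starts, function(s0) {
    i0 <- s0 * fs + 1L
    i1 <- min((s0 + 3600) * fs, n)
    seg <- x[, i0:i1, drop = FALSE] + stats::rnorm(1, 0, 2)
    new("LFPRecording", data = seg, fs = fs,
        channelIds = seq_len(nch), refScheme = "raw", segments = s0)
  })
}

#' Simulate the visual-stimulus calibration segment
#'
#' Emits pink background noise plus square-wave-locked evoked deflections: a
#' 3-s, 1 Hz square-wave stimulus whose leading edges evoke an 80-ms
#' half-sine deflection with signed-ramp channel amplitudes — positive on
#' channels peripheral to the reversal channel, negative central to it, and
#' zero at the reversal channel itself.
#'
#' @param config [SimConfig-class].
#' @param n_stimuli number of stimulus presentations (default 20).
#' @param amplitude_uv evoked amplitude at the outermost channel; 0 produces a
#'   segment with no reversal for degenerate-input tests. Defaults to the
#'   config's `evoked_amp_uv`.
#' @return list(recording = [LFPRecording-class], stimulus_times = onset
#'   seconds, stimulus_duration_s = 3).
#' @export
simulateCalibration <- function(config, n_stimuli = 20,
                                amplitude_uv = config@evoked_amp_uv) {
  set.seed((config@seed + 1) %% .Machine$integer.max)
  fs <- config@fs_lfp
  nch <- config@n_channels
  gap <- 1.5
  dur <- 3
  onsets <- gap + (seq_len(n_stimuli) - 1) * (dur + gap)
  total_s <- ceiling(max(onsets) + dur + gap)
  n <- total_s * fs
  w <- reversalWeights(nch, config@reversal_channel)
  pulse_len <- round(0.08 * fs)
  pulse <- sin(pi * seq_len(pulse_len) / pulse_len)
  evoked <- numeric(n)
  edges <- as.vector(outer(0:(dur - 1), onsets, "+")) # 1 Hz leading edges
  for (t0 in edges) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0:(i0 + pulse_len - 1L)
    keep <- idx <= n
    evoked[idx[keep]] <- evoked[idx[keep]] + pulse[keep]
  }
  x <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    x[ch, ] <- pinkNoise(n, config@noise_exponent) * config@noise_sd +
      evoked * amplitude_uv * w[ch]
  }
  list(recording = new("LFPRecording", data = x, fs = fs,
                       channelIds = seq_len(nch), refScheme = "raw",
                       segments = 0),
       stimulus_times = onsets, stimulus_duration_s = dur)
}

#' Simulate a pose-estimation table for a session
#'
#' Proboscis x/y excursions follow a raised-cosine displacement pulse of
#' 0.5 s at every ground-truth PE event; the proboscis likelihood dips to
#' ~0.75 during extensions (exercising the likelihood-augmentation detector
#' path) and below 0.4 inside occlusion windows. Antennal tips oscillate at
#' the configured frequency during sleep intervals only; eye and abdomen are
#' quasi-static.
#'
#' @param truth_events [PEEventTable-class] events to imprint.
#' @param config [SimConfig-class].
#' @param labels [StateLabels-class] used to gate antennal oscillation;
#'   `NULL` means no sleep anywhere.
#' @param duration_s track length in seconds (default spans the events).
#' @return [PoseTrack-class].
#' @export
simulatePose <- function(truth_events, config, labels = NULL,
                         duration_s = NULL) {
  set.seed((config@seed + 2) %% .Machine$integer.max)
  fps <- config@fps_video
  ev <- events(truth_events)
  if (is.null(duration_s)) {
    duration_s <- if (nrow(ev)) ceiling(max(ev$peak_time_s) + 10) else 60
  }
  stopifnot(nrow(ev) == 0L || max(ev$peak_time_s) <= duration_s)
  nf <- round(duration_s * fps)
  t <- (seq_len(nf) - 1) / fps
  jit <- function(sd) stats::rnorm(nf, 0, sd)
  lik <- function() pmin(stats::runif(nf, 0.93, 1), 1)

  # raised-cosine displacement pulse, 0.5 s, peak at the event time
  disp <- numeric(nf)
  half <- 0.25
  for (tp in ev$peak_time_s) {
    i0 <- max(floor((tp - half) * fps) + 1L, 1L)
    i1 <- min(ceiling((tp + half) * fps), nf)
    idx <- i0:i1
    disp[idx] <- pmax(disp[idx], 0.5 * (1 + cos(pi * (t[idx] - tp) / half)))
  }
  amp <- 20 # px, peak proboscis excursion
  u <- c(1, 1) / sqrt(2)
  prob_lik <- lik()
  prob_lik[disp > 0.15] <- stats::runif(sum(disp > 0.15), 0.72, 0.78)
  # occlusion windows: likelihood below 0.4
  n_occ <- stats::rpois(1, config@occlusion_per_hour * duration_s / 3600)
  if (n_occ > 0) {
    for (s0 in stats::runif(n_occ, 0, duration_s - 5)) {
      idx <- which(t >= s0 & t < s0 + 5)
      prob_lik[idx] <- stats::runif(length(idx), 0.1, 0.35)
    }
  }

  sleep_mask <- rep(FALSE, nf)
  if (!is.null(labels)) {
    iv <- intervals(labels)
    for (k in which(iv$label %in% c("sleep", "earlysleep", "midsleep", "latesleep"))) {
      sleep_mask[t >= iv$start_s[k] & t < iv$end_s[k]] <- TRUE
    }
  }
  osc <- config@antenna_osc_amp_deg * sin(2 * pi * config@antenna_osc_freq * t)
  wander <- filterZeroPhase(stats::rnorm(nf, 0, 4), designFIR(fps, high = 0.2, order = 90))
  ang_L <- ifelse(sleep_mask, osc, wander) # degrees, anterior sweep
  ang_R <- ifelse(sleep_mask, -osc, wander)
  alen <- 15
  bL <- c(80, 90); bR <- c(120, 90) # bases horizontal -> head axis +y
  toTip <- function(base, ang_deg, side_jit) {
    th <- (90 + ang_deg) * pi / 180
    cbind(base[1] + alen * cos(th) + side_jit,
          base[2] + alen * sin(th) + jit(0.2))
  }
  tip_L <- toTip(bL, ang_L, jit(0.2))
  tip_R <- toTip(bR, ang_R, jit(0.2))

  df <- data.frame(
    time_s = t,
    eye_x = 100 + jit(0.3), eye_y = 100 + jit(0.3), eye_likelihood = lik(),
    proboscis_x = 110 + amp * disp * u[1] + jit(1),
    proboscis_y = 120 + amp * disp * u[2] + jit(1),
    proboscis_likelihood = prob_lik,
    leg1_tip_x = 130 + jit(1), leg1_tip_y = 140 + jit(1),
    leg1_tip_likelihood = lik(),
    leg1_joint_x = 125 + jit(1), leg1_joint_y = 130 + jit(1),
    leg1_joint_likelihood = lik(),
    leg3_tip_x = 90 + jit(1), leg3_tip_y = 145 + jit(1),
    leg3_tip_likelihood = lik(),
    leg3_joint_x = 95 + jit(1), leg3_joint_y = 135 + jit(1),
    leg3_joint_likelihood = lik(),
    abdomen_x = 70 + jit(0.3), abdomen_y = 120 + jit(0.3),
    abdomen_likelihood = lik(),
    antenna_L_base_x = bL[1] + jit(0.2), antenna_L_base_y = bL[2] + jit(0.2),
    antenna_L_base_likelihood = lik(),
    antenna_L_tip_x = tip_L[, 1], antenna_L_tip_y = tip_L[, 2],
    antenna_L_tip_likelihood = lik(),
    antenna_R_base_x = bR[1] + jit(0.2), antenna_R_base_y = bR[2] + jit(0.2),
    antenna_R_base_likelihood = lik(),
    antenna_R_tip_x = tip_R[, 1], antenna_R_tip_y = tip_R[, 2],
    antenna_R_tip_likelihood = lik()
  )
  parts <- c("eye", "proboscis", "leg1_tip", "leg1_joint", "leg3_tip",
             "leg3_joint", "abdomen", "antenna_L_base", "antenna_L_tip",
             "antenna_R_base", "antenna_R_tip")
  new("PoseTrack", data = df, fps = fps, parts = parts)
}

#' Simulate a small grayscale frame stack from a movement indicator
#'
#' During "moving" frames a textured blob displaces between consecutive
#' frames; otherwise the scene is static except for sensor noise.
#'
#' @param moving logical vector, one element per frame.
#' @param config [SimConfig-class] (seed and fps).
#' @param h,w frame size in pixels (default 48 x 64).
#' @return array h x w x n of intensities in \[0, 1\].
#' @export
simulateFrames <- function(moving, config, h = 48, w = 64) {
  set.seed((config@seed + 3) %% .Machine$integer.max)
  n <- length(moving)
  blob <- matrix(stats::runif(144, 0.6, 1), 12, 12)
  frames <- array(stats::rnorm(h * w * n, 0.2, 0.015), dim = c(h, w, n))
  pos <- c(18, 26)
  step <- function() sample(c(-3, 3), 2, replace = TRUE)
  for (i in seq_len(n)) {
    if (i > 1 && moving[i]) {
      pos <- pmin(pmax(pos + step(), c(1, 1)), c(h - 12, w - 12))
    }
    frames[pos[1]:(pos[1] + 11), pos[2]:(pos[2] + 11), i] <-
      frames[pos[1]:(pos[1] + 11), pos[2]:(pos[2] + 11), i] + blob
  }
  frames
}

#' Simulate per-fly channel x frequency difference maps
#'
#' Direct generator for the group-level statistics: per-fly condition
#' contrasts as i.i.d. Gaussian cells (zero-mean under the null) with an
#' optional constant effect added inside a channel x frequency box.
#'
#' @param n_flies flies.
#' @param channels integer channel ids (grid rows).
#' @param freqs frequency grid in Hz (grid columns).
#' @param sd_db cell standard deviation across flies (dB).
#' @param effect_db effect size added inside `box` (dB; 0 = null).
#' @param box list(channels =, freq_range =) describing the effect location,
#'   e.g. `list(channels = 1:3, freq_range = c(5, 10))`.
#' @param seed integer seed.
#' @return [DifferenceMap-class].
#' @export
simulateDifferenceMap <- function(n_flies = 16, channels = setdiff(1:16, 12L),
                                  freqs = defaultFreqGrid(), sd_db = 1,
                                  effect_db = 0, box = NULL, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  nc <- length(channels); nf <- length(freqs)
  d <- array(stats::rnorm(n_flies * nc * nf, 0, sd_db),
             dim = c(n_flies, nc, nf))
  if (!is.null(box) && effect_db != 0) {
    ci <- which(channels %in% box$channels)
    fi <- which(freqs >= box$freq_range[1] & freqs <= box$freq_range[2])
    d[, ci, fi] <- d[, ci, fi] + effect_db
  }
  tc <- matrix(Inf, n_flies, 2, dimnames = list(NULL, c("A", "B")))
  new("DifferenceMap", diff = d, conditions = c("A", "B"),
      channels = as.integer(channels), freqs = freqs, trial_counts = tc)
}

#' Default 5-40 Hz Welch frequency grid (145 bins)
#'
#' Bin centers `(20:164) * 250/1024` Hz — the grid produced by the default
#' spectral settings (250 samples/s, 1024-point FFT) restricted to 5-40 Hz.
#'
#' @return numeric vector of 145 frequencies (Hz).
#' @export
defaultFreqGrid <- function() (20:164) * 250 / 1024
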