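# Proboscis-extension (PE) detection from pose tables, burst grouping,
# antennal angle periodicity, and the sleep-depth summaries of PE timing.

#' Construct a PEEventTable
#'
#' Rows are sorted into time order (the class invariant) before validation.
#'
#' @param ev data.frame with at least peak_frame and peak_time_s.
#' @return [PEEventTable-class].
#' @export
peEventTable <- function(ev) {
  for (col in c("state", "provenance")) if (is.null(ev[[col]])) ev[[col]] <- NA_character_
  for (col in c("burst_id", "burst_length")) if (is.null(ev[[col]])) ev[[col]] <- NA_integer_
  if (is.null(ev$iei_s)) ev$iei_s <- NA_real_
  ev <- ev[order(ev$peak_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  new("PEEventTable", events = ev)
}

# zero-phase low-pass with mean restoration (avoids the zero-initial-state
# transient of plain forward-backward filtering; exact identity on constants)
lowpassZeroPhase <- function(v, bf) {
  m <- mean(v)
  as.numeric(signal::filtfilt(bf, v - m)) + m
}

#' Per-frame PE features from a pose track
#'
#' For every body part: raw coordinates, a zero-phase low-pass (Butterworth,
#' 0.1 Hz cutoff, order 2) of each coordinate, and a centered moving average
#' (window 5) of the filtered series. `dist_eyeprob` is the Euclidean
#' proboscis-eye distance multiplied by the proboscis likelihood. NaN
#' coordinates are masked: carried forward for filtering, likelihood forced
#' to 0 and the frame flagged.
#'
#' @param pose [PoseTrack-class] containing at least eye and proboscis.
#' @param parts body parts to featurize (default all tracked).
#' @return data.frame of per-frame features with attribute `fps`.
#' @export
computePEFeatures <- function(pose, parts = bodyParts(pose)) {
  df <- poseData(pose)
  fps <- frameRate(pose)
  need <- c("eye", "proboscis")
  if (!all(need %in% parts)) stop("eye and proboscis must be tracked")
  bf <- signal::butter(2, 0.1 / (fps / 2), type = "low")
  out <- data.frame(row.names = seq_len(nrow(df)))
  if ("time_s" %in% names(df)) out$time_s <- df$time_s
  out$masked <- FALSE
  for (p in parts) {
    for (coord in c("x", "y")) {
      col <- paste0(p, "_", coord)
      v <- df[[col]]
      bad <- !is.finite(v)
      if (any(bad)) {
        out$masked <- out$masked | bad
        v <- fillForward(v)
      }
      filt <- lowpassZeroPhase(v, bf)
      ma <- movingAverage(filt, 5L)
      out[[col]] <- v # masked frames carry the filled value
      out[[paste0(col, "_lp")]] <- filt
      out[[paste0(col, "_ma")]] <- ma
    }
    lik <- df[[paste0(p, "_likelihood")]]
    lik[out$masked] <- 0
    out[[paste0(p, "_likelihood")]] <- lik
  }
  out$dist_eyeprob <- sqrt((out$proboscis_x - out$eye_x)^2 +
                             (out$proboscis_y - out$eye_y)^2) *
    out$proboscis_likelihood
  attr(out, "fps") <- fps
  out
}

fillForward <- function(v) {
  bad <- !is.finite(v)
  if (all(bad)) return(rep(0, length(v)))
  idx <- seq_along(v)
  good <- idx[!bad]
  v[bad] <- v[good[pmax(findInterval(idx[bad], good), 1L)]]
  v
}

movingAverage <- function(v, w = 5L) {
  k <- rep(1 / w, w)
  out <- stats::filter(v, k, sides = 2)
  as.numeric(ifelse(is.na(out), v, out)) # identity at the edges
}

#' Train a frame-level PE classifier
#'
#' Radial-basis-kernel support-vector classifier on the per-frame features,
#' z-score standardized with statistics fit on the training split only
#' (70/30 train/test by default).
#'
#' @param features [computePEFeatures()] table.
#' @param truth_frames integer frame indices that are part of a PE.
#' @param test_fraction held-out fraction (default 0.30).
#' @param seed split/RNG seed.
#' @return list(model, scale_center, scale_sd, metrics, predict_frames)
#'   where `predict_frames(features)` returns a logical per-frame vector.
#' @export
trainPEClassifier <- function(features, truth_frames, test_fraction = 0.30,
                              seed = 1) {
  set.seed(seed)
  y <- factor(seq_len(nrow(features)) %in% truth_frames,
              levels = c(FALSE, TRUE), labels = c("no_pe", "pe"))
  if (length(unique(y)) < 2L) stop("ground truth contains a single class")
  X <- featureColumns(features)
  idx_test <- sort(unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, round(length(i) * test_fraction)))))
  idx_train <- setdiff(seq_along(y), idx_test)
  ctr <- colMeans(X[idx_train, , drop = FALSE])
  sds <- apply(X[idx_train, , drop = FALSE], 2L, stats::sd)
  sds[sds == 0] <- 1
  Z <- scale(X, center = ctr, scale = sds)
  fit <- e1071::svm(Z[idx_train, , drop = FALSE], y[idx_train],
                    kernel = "radial", scale = FALSE)
  pred <- stats::predict(fit, Z[idx_test, , drop = FALSE])
  metrics <- classifierMetrics(pred, y[idx_test])
  list(
    model = fit, scale_center = ctr, scale_sd = sds, metrics = metrics,
    predict_frames = function(feat) {
      Zn <- scale(featureColumns(feat), center = ctr, scale = sds)
      stats::predict(fit, Zn) == "pe"
    }
  )
}

featureColumns <- function(features) {
  drop <- c("time_s", "masked")
  as.matrix(features[, setdiff(names(features), drop), drop = FALSE])
}

#' Detect PE events from classifier output and likelihood crossings
#'
#' Positive frames are merged into candidate segments (gaps up to
#' `merge_gap_s` bridge a segment); additional candidate segments come from
#' frames whose proboscis likelihood falls below `likelihood_thresh`. Within
#' each segment the event peak is the frame of maximum proboscis-eye
#' displacement; segments containing several extensions are split at local
#' minima below half of the neighboring peaks. A review table (one row per
#' event with its peak frame) replaces manual verification.
#'
#' @param features [computePEFeatures()] table.
#' @param positive_frames logical per-frame classifier output (or NULL for
#'   the threshold-only mode).
#' @param likelihood_thresh augmentation threshold (default 0.9).
#' @param labels optional [StateLabels-class] to attach state labels.
#' @param merge_gap_s candidate frames closer than this are one segment.
#' @return [PEEventTable-class] (provenance "classifier" or "threshold").
#' @export
detectPEEvents <- function(features, positive_frames = NULL,
                           likelihood_thresh = 0.9, labels = NULL,
                           merge_gap_s = 0.2) {
  fps <- attr(features, "fps")
  n <- nrow(features)
  cls <- if (is.null(positive_frames)) rep(FALSE, n) else positive_frames
  aug <- features$proboscis_likelihood < likelihood_thresh &
    features$proboscis_likelihood > 0
  cand <- cls | aug
  if (!any(cand)) return(emptyEventTable())
  # merge candidate frames into segments
  idx <- which(cand)
  gap <- c(Inf, diff(idx)) / fps
  seg_id <- cumsum(gap > merge_gap_s)
  dist <- sqrt((features$proboscis_x - features$eye_x)^2 +
                 (features$proboscis_y - features$eye_y)^2)
  ev <- list()
  for (s in unique(seg_id)) {
    fr <- idx[seg_id == s]
    fr <- seq(min(fr), max(fr))
    peaks <- splitSegmentPeaks(dist[fr])
    src <- if (any(cls[fr])) "classifier" else "threshold"
    for (pk in peaks) {
      ev[[length(ev) + 1L]] <- data.frame(
        peak_frame = fr[pk], provenance = src)
    }
  }
  tab <- do.call(rbind, ev)
  tab$peak_time_s <- if ("time_s" %in% names(features))
    features$time_s[tab$peak_frame] else (tab$peak_frame - 1) / fps
  tab <- tab[order(tab$peak_time_s), , drop = FALSE]
  tab$state <- if (!is.null(labels)) labelAt(labels, tab$peak_time_s)
  else NA_character_
  tab$burst_id <- NA_integer_
  tab$burst_length <- NA_integer_
  tab$iei_s <- NA_real_
  rownames(tab) <- NULL
  new("PEEventTable", events = tab[, c("peak_frame", "peak_time_s", "state",
                                       "burst_id", "burst_length", "iei_s",
                                       "provenance")])
}

emptyEventTable <- function() {
  new("PEEventTable", events = data.frame(
    peak_frame = integer(), peak_time_s = numeric(), state = character(),
    burst_id = integer(), burst_length = integer(), iei_s = numeric(),
    provenance = character()))
}

# indices of sub-event peaks within one segment's distance trace: local
# maxima, split where an interior minimum drops below 50% of both peaks
splitSegmentPeaks <- function(d) {
  if (length(d) < 3L) return(list(which.max(d)))
  pk <- which(diff(sign(diff(d))) < 0) + 1L
  if (length(pk) < 2L) return(list(which.max(d)))
  keep <- pk[1]
  for (p in pk[-1]) {
    valley <- min(d[keep[length(keep)]:p])
    if (valley < 0.5 * min(d[keep[length(keep)]], d[p])) {
      keep <- c(keep, p)
    } else if (d[p] > d[keep[length(keep)]]) {
      keep[length(keep)] <- p
    }
  }
  as.list(keep)
}

# state label at given times from a StateLabels interval table
labelAt <- function(labels, times) {
  iv <- intervals(labels)
  k <- findInterval(times, iv$start_s)
  k[k < 1L] <- 1L
  iv$label[k]
}

#' Peak-picking PE detector on a resting-distance series
#'
#' The resting position is the per-recording median; events are local maxima
#' of the distance to it, with three exclusions applied in order: peaks
#' exceeding a biologically plausible amplitude (`max_dist_px`), single-frame
#' spikes, and peaks with an implausibly fast rise (baseline-to-peak time
#' below `min_rise_s`).
#'
#' @param dist distance series to the resting position (px), or a raw
#'   x/y data.frame from which the distance to the median position is taken.
#' @param fps frames per second.
#' @param min_rise_s minimum plausible rise time (s).
#' @param max_dist_px amplitude cap (px).
#' @param min_height_px detection floor; default 5 * mad above the median.
#' @param labels optional [StateLabels-class] for state tags.
#' @return [PEEventTable-class] (provenance "peak-picker") with per-event
#'   duration columns.
#' @export
detectPEPeaks <- function(dist, fps, min_rise_s = 0.1, max_dist_px = 50,
                          min_height_px = NULL, labels = NULL) {
  if (is.data.frame(dist)) {
    dist <- sqrt((dist$x - median(dist$x))^2 + (dist$y - median(dist$y))^2)
  }
  if (is.null(min_height_px)) {
    min_height_px <- 5 * stats::mad(dist) + stats::median(dist)
  }
  pk <- pracma::findpeaks(dist, minpeakheight = min_height_px)
  if (is.null(pk)) return(emptyEventTable())
  # columns: height, position, left trough, right trough
  keep <- rep(TRUE, nrow(pk))
  keep[pk[, 1] > max_dist_px] <- FALSE                     # amplitude cap
  keep[(pk[, 4] - pk[, 3]) <= 2] <- FALSE                  # single-frame spike
  keep[(pk[, 2] - pk[, 3]) / fps < min_rise_s] <- FALSE    # implausible rise
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(emptyEventTable())
  tab <- data.frame(
    peak_frame = pk[, 2],
    peak_time_s = (pk[, 2] - 1) / fps,
    state = NA_character_, burst_id = NA_integer_,
    burst_length = NA_integer_, iei_s = NA_real_,
    provenance = "peak-picker",
    duration_s = (pk[, 4] - pk[, 3]) / fps,
    amplitude_px = pk[, 1]
  )
  tab <- tab[order(tab$peak_time_s), , drop = FALSE]
  if (!is.null(labels)) tab$state <- labelAt(labels, tab$peak_time_s)
  rownames(tab) <- NULL
  new("PEEventTable", events = tab)
}

#' Group PE events into bursts
#'
#' Single-linkage chaining: consecutive events at most `gap_s` apart share a
#' burst. Fills `burst_id`, `burst_length` and the intra-burst inter-event
#' interval; events in bursts of length 1 are "single", the rest "multi".
#' Idempotent, order-independent, and conserves the event count.
#'
#' @param pe [PEEventTable-class].
#' @param gap_s burst-joining gap (default 10 s).
#' @return [PEEventTable-class] with burst columns filled.
#' @export
groupBursts <- function(pe, gap_s = 10) {
  ev <- events(pe)
  if (nrow(ev) == 0L) return(pe)
  ev <- ev[order(ev$peak_time_s), , drop = FALSE]
  gaps <- c(Inf, diff(ev$peak_time_s))
  ev$burst_id <- cumsum(gaps > gap_s)
  bl <- table(ev$burst_id)
  ev$burst_length <- as.integer(bl[as.character(ev$burst_id)])
  ev$iei_s <- ifelse(gaps > gap_s, NA_real_, gaps)
  ev$burst_class <- ifelse(ev$burst_length > 1L, "multi", "single")
  rownames(ev) <- NULL
  new("PEEventTable", events = ev)
}

#' Antennal angles corrected for head orientation
#'
#' Per antenna: the tip-base direction expressed relative to the head axis
#' (the perpendicular of the line joining the two antenna bases, pointing
#' anterior), in degrees, unwrapped over time. Frames where base and tip
#' coincide are masked (NA). A rigid rotation of the whole head leaves the
#' angles unchanged.
#'
#' @param pose [PoseTrack-class] with antenna_L/R base and tip parts.
#' @return data.frame(time_s, angle_L_deg, angle_R_deg) with attribute `fps`.
#' @export
antennaAngles <- function(pose) {
  df <- poseData(pose)
  fps <- frameRate(pose)
  head_ang <- atan2(df$antenna_R_base_y - df$antenna_L_base_y,
                    df$antenna_R_base_x - df$antenna_L_base_x) + pi / 2
  one <- function(side) {
    dx <- df[[paste0("antenna_", side, "_tip_x")]] -
      df[[paste0("antenna_", side, "_base_x")]]
    dy <- df[[paste0("antenna_", side, "_tip_y")]] -
      df[[paste0("antenna_", side, "_base_y")]]
    ang <- atan2(dy, dx) - head_ang
    ang[dx == 0 & dy == 0] <- NA # degenerate base/tip coincidence
    unwrapAngles(ang) * 180 / pi
  }
  out <- data.frame(
    time_s = if ("time_s" %in% names(df)) df$time_s
    else (seq_len(nrow(df)) - 1) / fps,
    angle_L_deg = one("L"), angle_R_deg = one("R"))
  attr(out, "fps") <- fps
  out
}

unwrapAngles <- function(a) {
  ok <- is.finite(a)
  a[ok] <- ((a[ok] + pi) %% (2 * pi)) - pi
  if (sum(ok) > 1L) {
    idx <- which(ok)
    d <- diff(a[idx])
    d <- d - 2 * pi * round(d / (2 * pi))
    a[idx] <- a[idx][1L] + c(0, cumsum(d))
  }
  a
}

#' Detect periodic micro-behavior segments
#'
#' Antennae: over sliding windows of the angle series, the FFT magnitude
#' spectrum is computed and a window is flagged periodic when the in-band
#' spectral peak exceeds `peak_criterion` times the median in-band level;
#' the dominant frequency is reported. Proboscis: an event is periodic iff
#' its predecessor occurred less than `period_rule_s` earlier.
#'
#' @param x numeric angle series (antenna mode) or [PEEventTable-class]
#'   (proboscis mode).
#' @param fps sampling rate of the angle series (frames/s).
#' @param window_s sliding window length (default 30 s, 50% overlap).
#' @param band in-band frequency range (default 0.1-5 Hz).
#' @param peak_criterion peak / median-level ratio (default 6).
#' @param organ label written into the output table.
#' @param period_rule_s proboscis periodicity rule (default 6 s).
#' @return data.frame of segments (start_s, end_s, organ, periodic,
#'   dominant_freq_hz) in antenna mode; in proboscis mode the event table
#'   with a `periodic` column.
#' @export
detectPeriodicity <- function(x, fps = 30, window_s = 30, band = c(0.1, 5),
                              peak_criterion = 6, organ = "antenna_L",
                              period_rule_s = 6) {
  if (is(x, "PEEventTable")) {
    ev <- events(x)
    ev$periodic <- c(FALSE, diff(ev$peak_time_s) < period_rule_s)
    return(new("PEEventTable", events = ev))
  }
  n <- length(x)
  wlen <- round(window_s * fps)
  if (wlen > n) stop("window longer than series")
  step <- wlen %/% 2L
  starts <- seq(1L, n - wlen + 1L, by = step)
  out <- lapply(starts, function(s0) {
    seg <- x[s0:(s0 + wlen - 1L)]
    seg <- seg - mean(seg)
    sp <- abs(stats::fft(seg))[seq_len(wlen %/% 2L) + 1L]
    fr <- seq_len(wlen %/% 2L) * fps / wlen
    inb <- fr >= band[1] & fr <= band[2]
    ref <- stats::median(sp[inb])
    pk <- which.max(sp * inb)
    periodic <- ref > 0 && sp[pk] > peak_criterion * ref
    data.frame(start_s = (s0 - 1) / fps, end_s = (s0 - 1 + wlen) / fps,
               organ = organ, periodic = periodic,
               dominant_freq_hz = if (periodic) fr[pk] else NA_real_)
  })
  do.call(rbind, out)
}

#' Fraction of time periodic by behavioral state
#'
#' @param segments antenna output of [detectPeriodicity()].
#' @param labels [StateLabels-class].
#' @return data.frame(state, periodic_fraction) where state is sleep/awake.
#' @export
periodicFractionByState <- function(segments, labels) {
  mid <- (segments$start_s + segments$end_s) / 2
  lab <- labelAt(labels, mid)
  asleep <- lab %in% c("sleep", "earlysleep", "midsleep", "latesleep")
  data.frame(
    state = c("sleep", "awake"),
    periodic_fraction = c(mean(segments$periodic[asleep]),
                          mean(segments$periodic[!asleep])))
}

#' PE counts by sleep depth
#'
#' Per-fly counts of events before vs after the 5th minute of sleep bouts
#' (with the same split over awake inter-bout periods as a control),
#' normalized event rates per epoch-relative bin, and the distribution of
#' event times into midsleep with its 95th-percentile onset.
#'
#' @param pe [PEEventTable-class] with state labels attached.
#' @param labels full-scheme [StateLabels-class].
#' @return list(before_after, bin_rates, midsleep_onset_s,
#'   midsleep_onset_q95_s).
#' @export
peDepthSummary <- function(pe, labels) {
  ev <- events(pe)
  iv <- intervals(labels)
  asleep <- c("earlysleep", "midsleep", "latesleep")
  bout_start <- tapply(iv$start_s[iv$label %in% asleep],
                       iv$bout_id[iv$label %in% asleep], min)
  bout_end <- tapply(iv$end_s[iv$label %in% asleep],
                     iv$bout_id[iv$label %in% asleep], max)
  # before/after the 5th minute of sleep bouts
  inBout <- function(t) {
    k <- which(bout_start <= t & bout_end > t)
    if (length(k)) t - bout_start[k[1]] else NA_real_
  }
  off <- vapply(ev$peak_time_s, inBout, 0)
  before5 <- sum(!is.na(off) & off < 300)
  after5 <- sum(!is.na(off) & off >= 300)
  # awake control: offset into the enclosing awake period
  awk <- iv[iv$label == "awake", , drop = FALSE]
  offA <- vapply(ev$peak_time_s, function(t) {
    k <- which(awk$start_s <= t & awk$end_s > t)
    if (length(k)) t - awk$start_s[k[1]] else NA_real_
  }, 0)
  before_after <- data.frame(
    context = c("sleep", "awake"),
    before_5min = c(before5, sum(!is.na(offA) & offA < 300)),
    after_5min = c(after5, sum(!is.na(offA) & offA >= 300)))
  # normalized rate per epoch-relative bin
  binOf <- function(t) {
    k <- findInterval(t, iv$start_s)
    lab <- iv$label[k]
    bid <- iv$bout_id[k]
    bs <- if (!is.na(bid)) bout_start[[as.character(bid)]] else NA_real_
    be <- if (!is.na(bid)) bout_end[[as.character(bid)]] else NA_real_
    switch(lab,
           presleep = if (t >= bs - 60) "-1:0" else "-2:-1",
           earlysleep = if (t < bs + 60) "+0:+1" else "+1:+2",
           midsleep = "mid",
           latesleep = if (t < be - 60) "x:-2" else "x:-1",
           NA_character_)
  }
  bins <- c("-2:-1", "-1:0", "+0:+1", "+1:+2", "mid", "x:-2", "x:-1")
  evbin <- vapply(ev$peak_time_s, binOf, "")
  dur <- c(rep(60, 4), sum(iv$end_s[iv$label == "midsleep"] -
                             iv$start_s[iv$label == "midsleep"]), 60, 60)
  nb <- length(unique(iv$bout_id[!is.na(iv$bout_id)]))
  dur[c(1:4, 6:7)] <- dur[c(1:4, 6:7)] * max(nb, 1L)
  rate <- vapply(bins, function(b) sum(evbin == b, na.rm = TRUE), 0) / dur
  norm <- if (sum(rate) > 0) rate / sum(rate) else rate
  # time into midsleep
  msv <- iv[iv$label == "midsleep", , drop = FALSE]
  intoMid <- vapply(ev$peak_time_s, function(t) {
    k <- which(msv$start_s <= t & msv$end_s > t)
    if (length(k)) t - msv$start_s[k[1]] else NA_real_
  }, 0)
  intoMid <- intoMid[!is.na(intoMid)]
  list(before_after = before_after,
       bin_rates = data.frame(bin = bins, rate_per_s = rate,
                              normalized = norm),
       midsleep_onset_s = intoMid,
       midsleep_onset_q95_s = if (length(intoMid))
         as.numeric(stats::quantile(intoMid, 0.05)) else NA_real_)
}
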