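# LFP preprocessing, polarity-reversal detection and re-referencing, epoching
# by behavioral labels, and the Welch channel x frequency spectral features.

#' Construct an LFPRecording
#'
#' @param data channels x samples numeric matrix (uV).
#' @param fs sampling rate, samples/s.
#' @param channelIds original electrode indices (default 1:nrow).
#' @param refScheme reference scheme tag (default "raw").
#' @param segments start times (s) of acquisition segments (default 0).
#' @return [LFPRecording-class].
#' @export
lfpRecording <- function(data, fs, channelIds = seq_len(nrow(data)),
                         refScheme = "raw", segments = 0) {
  new("LFPRecording", data = data, fs = fs,
      channelIds = as.integer(channelIds), refScheme = refScheme,
      segments = segments)
}

#' Preprocess a raw recording
#'
#' Anti-aliased polyphase resampling to `fs_out`, a zero-phase Hamming
#' windowed-sinc FIR band-pass, and a zero-phase FIR notch at the line
#' frequency. Filters are linear-phase with exact group-delay compensation,
#' so the net phase shift is zero.
#'
#' @param rec raw [LFPRecording-class].
#' @param fs_out target rate (default 250 samples/s).
#' @param band band-pass edges in Hz (default 0.5-40).
#' @param notch line frequency to remove (Hz, default 50; `NULL` disables).
#' @param notch_width half-width of the notch stop band (Hz).
#' @return filtered [LFPRecording-class] at `fs_out`.
#' @export
preprocessLFP <- function(rec, fs_out = 250, band = c(0.5, 40), notch = 50,
                          notch_width = 2) {
  fs <- samplingRate(rec)
  if (fs < 2 * band[2]) {
    stop(sprintf("sampling rate %g below Nyquist requirement for %g Hz", fs, band[2]))
  }
  x <- lfpData(rec)
  if (fs != fs_out) {
    x <- resampleRows(x, fs, fs_out)
    fs <- fs_out
  }
  h <- designFIR(fs, band[1], band[2])
  if (!is.null(notch) && notch < fs / 2) {
    hn <- designFIR(fs, notch - notch_width, notch + notch_width,
                    order = 500, type = "stop")
    h <- signal::conv(h, hn) # one combined zero-phase kernel
  }
  x <- filterZeroPhase(x, h)
  lfpRecording(x, fs, channelIds = channelIds(rec),
               refScheme = refScheme(rec), segments = rec@segments)
}

# anti-aliased resampling: zero-phase FIR low-pass at 0.45 * the lower of
# the two rates, then interpolation onto the target time grid
resampleRows <- function(x, fs_in, fs_out) {
  cutoff <- 0.45 * min(fs_in, fs_out)
  h <- designFIR(fs_in, high = cutoff, order = 2 * ceiling(3.3 * fs_in / (0.1 * cutoff) / 2))
  x <- filterZeroPhase(x, h)
  n_out <- floor(ncol(x) * fs_out / fs_in)
  t_in <- (seq_len(ncol(x)) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  t(apply(x, 1L, function(ch) stats::approx(t_in, ch, xout = t_out)$y))
}

#' Stitch hourly segments into one continuous recording
#'
#' Concatenates ordered segments and removes boundary discontinuities by
#' subtracting, from the start of each appended segment, a linear ramp that
#' starts at the boundary step and decays to zero over `bridge_s` seconds.
#' Total duration is exactly the sum of the segment durations.
#'
#' @param segments list of [LFPRecording-class] with equal channel counts and
#'   rates, in time order.
#' @param bridge_s bridge length in seconds (default 1).
#' @return single [LFPRecording-class].
#' @export
stitchHours <- function(segments, bridge_s = 1) {
  stopifnot(length(segments) >= 1L)
  if (length(segments) == 1L) return(segments[[1L]])
  fs <- samplingRate(segments[[1L]])
  nch <- nrow(lfpData(segments[[1L]]))
  for (s in segments) {
    if (nrow(lfpData(s)) != nch) stop("mismatched channel counts across segments")
    if (samplingRate(s) != fs) stop("mismatched sampling rates across segments")
  }
  out <- lfpData(segments[[1L]])
  k <- round(bridge_s * fs)
  for (i in 2:length(segments)) {
    b <- lfpData(segments[[i]])
    offset <- b[, 1L] - out[, ncol(out)]
    m <- min(k, ncol(b))
    ramp <- 1 - (seq_len(m) - 1) / m
    b[, seq_len(m)] <- b[, seq_len(m)] - outer(offset, ramp)
    out <- cbind(out, b)
  }
  lfpRecording(out, fs, channelIds = channelIds(segments[[1L]]),
               refScheme = refScheme(segments[[1L]]),
               segments = vapply(segments, function(s) s@segments[1L], 0))
}

#' Detect the polarity-reversal channel from calibration data
#'
#' Per channel, stimulus-locked deflection amplitude = mean over a post-onset
#' window minus a pre-onset baseline, averaged over all square-wave leading
#' edges. Going from central to peripheral electrodes the signed amplitude
#' profile must change sign exactly once (negative centrally, positive
#' peripherally); the reversal channel is the channel with the smallest
#' deflection inside the sign change. Channels with |amplitude| below
#' `snr_thresh` standard errors are ignored when counting sign changes.
#'
#' @param calibration raw [LFPRecording-class] of the calibration segment.
#' @param stimulus_times square-wave stimulus onset times (s).
#' @param stimulus_duration_s square-wave duration (default 3 s at 1 Hz, i.e.
#'   3 leading edges per stimulus).
#' @param post_window post-edge averaging window (s, default 10-100 ms).
#' @param baseline_s pre-edge baseline length (s, default 50 ms).
#' @param snr_thresh amplitude/SE threshold for a channel to count as evoked.
#' @return list(reversal_channel, amplitudes, se, quality) where quality is
#'   "good" or "low" (multiple sign changes).
#' @export
detectPolarityReversal <- function(calibration, stimulus_times,
                                   stimulus_duration_s = 3,
                                   post_window = c(0.01, 0.1),
                                   baseline_s = 0.05, snr_thresh = 3) {
  if (length(stimulus_times) < 5L) stop("need at least 5 stimulus repetitions")
  fs <- samplingRate(calibration)
  x <- lfpData(calibration)
  edges <- as.vector(outer(0:(stimulus_duration_s - 1), stimulus_times, "+"))
  edges <- edges[edges * fs + post_window[2] * fs < ncol(x) &
                   edges - baseline_s > 0]
  defl <- sapply(edges, function(t0) {
    i0 <- round(t0 * fs)
    post <- x[, (i0 + round(post_window[1] * fs)):(i0 + round(post_window[2] * fs)),
              drop = FALSE]
    base <- x[, (i0 - round(baseline_s * fs)):i0, drop = FALSE]
    rowMeans(post) - rowMeans(base)
  })
  amp <- rowMeans(defl)
  se <- apply(defl, 1L, stats::sd) / sqrt(ncol(defl))
  sig <- which(abs(amp) > snr_thresh * se)
  signs <- sign(amp[sig])
  if (length(sig) == 0L || length(unique(signs)) == 1L) {
    stop("no reversal found: stimulus-locked deflections do not change sign")
  }
  flips <- which(diff(signs) != 0)
  quality <- if (length(flips) == 1L) "good" else "low"
  # channel with the smallest deflection inside the (first) sign change
  lo <- sig[flips[1L]]; hi <- sig[flips[1L] + 1L]
  inside <- lo:hi
  rev_ch <- inside[which.min(abs(amp[inside]))]
  list(reversal_channel = channelIds(calibration)[rev_ch],
       amplitudes = stats::setNames(amp, channelIds(calibration)),
       se = se, quality = quality)
}

#' Re-reference against the polarity-reversal channel
#'
#' Output channel i = reference minus channel i (the stated convention:
#' every channel is subtracted *from* the reversal channel); the reversal
#' channel itself is dropped, so 16 input channels give 15 outputs. Any
#' component identical on all input channels cancels exactly.
#'
#' @param rec [LFPRecording-class].
#' @param reversal_channel original electrode index of the reference.
#' @return [LFPRecording-class] with one fewer channel, tagged
#'   "reversal-subtracted".
#' @export
rereferenceReversal <- function(rec, reversal_channel) {
  ids <- channelIds(rec)
  ri <- match(reversal_channel, ids)
  if (is.na(ri)) stop("invalid reversal channel index: ", reversal_channel)
  x <- lfpData(rec)
  ref <- x[ri, ]
  out <- sweep(-x[-ri, , drop = FALSE], 2L, ref, "+") # ref - channel
  lfpRecording(out, samplingRate(rec), channelIds = ids[-ri],
               refScheme = "reversal-subtracted", segments = rec@segments)
}

#' Bipolar (differential) re-referencing
#'
#' Output i = channel i+1 minus channel i; n input channels give n-1 outputs,
#' labeled by the lower electrode of each pair.
#'
#' @param rec [LFPRecording-class] with at least 2 channels.
#' @return [LFPRecording-class] tagged "bipolar".
#' @export
rereferenceBipolar <- function(rec) {
  x <- lfpData(rec)
  if (nrow(x) < 2L) stop("bipolar referencing needs at least 2 channels")
  n <- nrow(x)
  out <- x[-1L, , drop = FALSE] - x[-n, , drop = FALSE]
  lfpRecording(out, samplingRate(rec), channelIds = channelIds(rec)[-n],
               refScheme = "bipolar", segments = rec@segments)
}

# ---- epoching ----

#' LFPEpochs: labeled fixed-length epochs of a recording
#'
#' Lazy epoch container: keeps the recording plus one metadata row per epoch
#' (sample offset, state label, relative-time bin, bout id).
#'
#' @slot recording [LFPRecording-class].
#' @slot meta data.frame(epoch, start_s, i0, label, state, rel_bin, bout_id,
#'   never_train).
#' @slot epoch_len_s epoch length in seconds.
#' @export
setClass("LFPEpochs", representation(
  recording = "LFPRecording", meta = "data.frame", epoch_len_s = "numeric"
))

setMethod("show", "LFPEpochs", function(object) {
  cat(sprintf("LFPEpochs: %d epochs of %g s\n", nrow(object@meta),
              object@epoch_len_s))
  if (nrow(object@meta)) print(table(object@meta$state))
})

#' @describeIn LFPEpochs-class per-epoch metadata
#' @param x object
#' @export
setMethod("epochMeta", "LFPEpochs", function(x) x@meta)

# map a bout-relative epoch midpoint to its relative-time bin tag
relBin <- function(label, mid_s, bout_start, bout_end) {
  if (label == "awake" || is.na(bout_start)) return("awake")
  if (label %in% c("presleep", "pre2")) {
    off <- floor((mid_s - bout_start) / 60)
    return(c("-4:-3", "-3:-2", "-2:-1", "-1:0")[off + 5L])
  }
  if (label == "earlysleep") {
    off <- floor((mid_s - bout_start) / 60)
    return(c("0:+1", "+1:+2")[off + 1L])
  }
  if (label == "midsleep") return("mid")
  if (label == "latesleep") {
    off <- floor((mid_s - bout_end) / 60)
    return(c("x-2:x-1", "x-1:x")[off + 3L])
  }
  if (label == "post2") {
    off <- floor((mid_s - bout_end) / 60)
    return(c("x:x+1", "x+1:x+2")[off + 1L])
  }
  "awake"
}

#' Cut a recording into fixed-length epochs inside labeled intervals
#'
#' Non-overlapping epochs are placed from the start of every labeled
#' interval; partial trailing windows are discarded (an interval shorter
#' than one epoch yields none). Each epoch carries its state label, bout id
#' and relative-time bin (the bin containing the epoch midpoint); the
#' evaluation-only bins pre2/post2 are flagged `never_train`.
#'
#' @param rec re-referenced [LFPRecording-class].
#' @param labels [StateLabels-class] (full scheme or sleep/awake).
#' @param epoch_len_s epoch length in seconds (60 for the sleep analysis,
#'   1 for the PE analysis).
#' @return [LFPEpochs-class].
#' @export
epochByLabels <- function(rec, labels, epoch_len_s = 60) {
  fs <- samplingRate(rec)
  iv <- intervals(labels)
  span_s <- ncol(lfpData(rec)) / fs
  if (max(iv$end_s) > span_s + 1e-6) {
    stop("labels extend beyond the recording span")
  }
  # bout geometry for relative-time tags
  asleep <- c("earlysleep", "midsleep", "latesleep", "sleep")
  bout_start <- tapply(iv$start_s[iv$label %in% asleep],
                       iv$bout_id[iv$label %in% asleep], min)
  bout_end <- tapply(iv$end_s[iv$label %in% asleep],
                     iv$bout_id[iv$label %in% asleep], max)
  rows <- list()
  for (k in seq_len(nrow(iv))) {
    ne <- floor((iv$end_s[k] - iv$start_s[k]) / epoch_len_s)
    if (ne < 1L) next
    st <- iv$start_s[k] + (seq_len(ne) - 1L) * epoch_len_s
    bid <- iv$bout_id[k]
    bs <- if (!is.na(bid)) bout_start[[as.character(bid)]] else NA_real_
    be <- if (!is.na(bid)) bout_end[[as.character(bid)]] else NA_real_
    bins <- vapply(st + epoch_len_s / 2, function(m)
      relBin(iv$label[k], m, bs, be), "")
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = st, i0 = round(st * fs) + 1L, label = iv$label[k],
      state = stateOf(iv$label[k]), rel_bin = bins, bout_id = bid,
      never_train = iv$label[k] %in% c("pre2", "post2"))
  }
  meta <- if (length(rows)) do.call(rbind, rows) else data.frame(
    start_s = numeric(), i0 = integer(), label = character(),
    state = character(), rel_bin = character(), bout_id = integer(),
    never_train = logical())
  meta <- meta[order(meta$start_s), , drop = FALSE]
  meta$epoch <- seq_len(nrow(meta))
  rownames(meta) <- NULL
  new("LFPEpochs", recording = rec, meta = meta, epoch_len_s = epoch_len_s)
}

# training-class state of a label: evaluation bins are awake time
stateOf <- function(label) {
  if (label %in% c("pre2", "post2", "sleep")) {
    if (label == "sleep") "sleep" else "awake"
  } else label
}

#' Welch power spectra per epoch per channel
#'
#' Each epoch is zero-phase band-pass filtered, then Welch-averaged
#' (Hamming windows of `nfft` samples, 50% overlap). Power is reported in
#' dB (10 log10 uV^2/Hz) on the FFT grid restricted to
#' `floor(band[1]/df) .. ceiling(band[2]/df)` bins; at 250 samples/s with
#' nfft = 1024 and band 5-40 Hz this is bins 20-164, i.e. 145 bins
#' (4.88-40.04 Hz) per channel.
#'
#' @param epochs [LFPEpochs-class] (re-referenced, preprocessed).
#' @param band band-pass edges in Hz (default 5-40).
#' @param nfft Welch FFT/window length (default 1024).
#' @param fly fly identifier stored with every epoch.
#' @return [SpectraTable-class] with one assay `"power_db"` (features x
#'   epochs, channel-major).
#' @export
powerSpectrum <- function(epochs, band = c(5, 40), nfft = 1024L, fly = "fly1") {
  rec <- epochs@recording
  fs <- samplingRate(rec)
  x <- lfpData(rec)
  meta <- epochs@meta
  len <- round(epochs@epoch_len_s * fs)
  if (len < nfft) {
    stop(sprintf("epoch length %d samples is shorter than one FFT window (%d)",
                 len, nfft))
  }
  df <- fs / nfft
  k0 <- floor(band[1] / df); k1 <- ceiling(band[2] / df)
  bins <- (k0:k1) + 1L # 1-based FFT grid indices
  freqs <- (k0:k1) * df
  h <- designFIR(fs, band[1], band[2])
  nch <- nrow(x)
  nfr <- length(bins)
  pw <- matrix(NA_real_, nch * nfr, nrow(meta))
  for (e in seq_len(nrow(meta))) {
    seg <- x[, meta$i0[e]:(meta$i0[e] + len - 1L), drop = FALSE]
    seg <- filterZeroPhase(seg, h)
    for (ch in seq_len(nch)) {
      psd <- welchPSD(seg[ch, ], fs, nfft = nfft)$psd[bins]
      pw[((ch - 1L) * nfr + 1L):(ch * nfr), e] <- 10 * log10(psd)
    }
  }
  rd <- S4Vectors::DataFrame(
    channel = rep(channelIds(rec), each = nfr),
    freq_hz = rep(freqs, nch))
  cd <- S4Vectors::DataFrame(
    fly = fly, state = meta$state, label = meta$label, rel_bin = meta$rel_bin,
    bout_id = meta$bout_id, epoch_start_s = meta$start_s,
    never_train = meta$never_train)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(power_db = pw), rowData = rd, colData = cd)
  new("SpectraTable", se)
}

#' Combine SpectraTables from multiple flies or sessions
#'
#' @param ... [SpectraTable-class] objects on identical feature grids.
#' @return combined [SpectraTable-class].
#' @export
combineSpectra <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]])) tabs <- tabs[[1L]]
  rd0 <- SummarizedExperiment::rowData(tabs[[1L]])
  for (t in tabs[-1L]) {
    if (!identical(as.data.frame(SummarizedExperiment::rowData(t)),
                   as.data.frame(rd0))) {
      stop("feature grids differ across SpectraTables")
    }
  }
  pw <- do.call(cbind, lapply(tabs, SummarizedExperiment::assay, "power_db"))
  cd <- do.call(rbind, lapply(tabs, function(t)
    as.data.frame(SummarizedExperiment::colData(t))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(power_db = pw), rowData = rd0,
    colData = S4Vectors::DataFrame(cd))
  new("SpectraTable", se)
}

#' Mean spectra per channel group
#'
#' Averages spectra over the central (electrodes 1-5), middle (6-10) and
#' peripheral (12-16) channel groups — the reversal channel is absent after
#' re-referencing and does not contribute — per state per fly.
#'
#' @param spectra [SpectraTable-class].
#' @param groups named list of original channel indices.
#' @return data.frame(fly, state, group, freq_hz, power_db).
#' @export
groupChannels <- function(spectra, groups = list(central = 1:5, middle = 6:10,
                                                 peripheral = 12:16)) {
  rd <- SummarizedExperiment::rowData(spectra)
  cd <- SummarizedExperiment::colData(spectra)
  pw <- SummarizedExperiment::assay(spectra, "power_db")
  out <- list()
  for (gname in names(groups)) {
    rsel <- rd$channel %in% groups[[gname]]
    if (!any(rsel)) next
    for (fly in unique(cd$fly)) {
      for (st in unique(cd$state)) {
        csel <- cd$fly == fly & cd$state == st
        if (!any(csel)) next
        sub <- pw[rsel, csel, drop = FALSE]
        fr <- rd$freq_hz[rsel]
        m <- tapply(rowMeans(sub), fr, mean)
        out[[length(out) + 1L]] <- data.frame(
          fly = fly, state = st, group = gname,
          freq_hz = as.numeric(names(m)), power_db = as.numeric(m))
      }
    }
  }
  do.call(rbind, out)
}

#' Electrode positions from dye points
#'
#' First principal axis of the centered dye point cloud; the innermost
#' electrode is the projection of the innermost point onto that axis and the
#' remaining electrodes sit at exact multiples of `spacing_um` along the
#' axis toward the periphery (the side holding the bulk of the dye).
#'
#' @param dye_points n x 3 matrix of dye coordinates (um).
#' @param innermost_point length-3 coordinates of the innermost dye point.
#' @param spacing_um inter-electrode spacing (default 25 um).
#' @param n number of electrodes (default 16).
#' @return list(axis = unit vector, innermost = projected point,
#'   positions = n x 3 matrix, residual_rms = rms distance to the axis).
#' @export
localizeElectrodes <- function(dye_points, innermost_point, spacing_um = 25,
                               n = 16) {
  dye_points <- as.matrix(dye_points)
  if (nrow(unique(dye_points)) < 2L) stop("need at least 2 non-coincident points")
  ctr <- colMeans(dye_points)
  pc <- stats::prcomp(dye_points, center = TRUE, scale. = FALSE)
  u <- pc$rotation[, 1L]
  t_all <- as.vector((dye_points - matrix(ctr, nrow(dye_points), 3, byrow = TRUE)) %*% u)
  t_in <- sum((innermost_point - ctr) * u)
  if (stats::median(t_all) < t_in) u <- -u # orient toward the dye bulk
  t_in <- sum((innermost_point - ctr) * u)
  inner <- ctr + t_in * u
  positions <- t(sapply(seq_len(n) - 1L, function(k) inner + k * spacing_um * u))
  resid <- dye_points - (matrix(ctr, nrow(dye_points), 3, byrow = TRUE) +
                           outer(t_all, u))
  list(axis = u, innermost = inner, positions = positions,
       residual_rms = sqrt(mean(rowSums(resid^2))))
}
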