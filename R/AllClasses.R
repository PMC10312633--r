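# Central S4 containers. SpectraTable extends SummarizedExperiment so that the
# epochs-by-(channel,frequency) power grid carries its epoch metadata the way
# expression matrices carry sample metadata.

#' @import methods
NULL

#' SimConfig: parameters of a synthetic recording session
#'
#' Holds every tunable of the synthetic-session generator: recording geometry,
#' sleep-bout statistics, state-dependent spectral gains, proboscis-extension
#' (PE) burst process and pose/antenna kinematics. Defaults emulate the study
#' conditions of the tethered-fly recordings the pipeline targets; see the
#' methods vignette for the rationale behind each value.
#'
#' Power gains are multiplicative 5-40 Hz band-power factors relative to
#' midsleep (= 1): `awake_power_gain` > `presleep_gain` > `early_late_gain` > 1
#' orders the stages by construction and makes them separable.
#'
#' @slot n_flies number of flies (sessions) a multi-fly harness should draw.
#' @slot session_hours session duration in hours.
#' @slot fs_lfp native LFP sampling rate, samples/s.
#' @slot fs_raw raw emitted rate (>= fs_lfp) to exercise resampling.
#' @slot fps_video video frame rate, frames/s.
#' @slot n_channels electrode count (1 = most central, n = most peripheral).
#' @slot reversal_channel 1-based polarity-reversal channel (11-13 in practice).
#' @slot bout_mean_min,bout_sd_min sleep-bout duration distribution (minutes).
#' @slot interbout_mean_min,interbout_sd_min awake inter-bout gap distribution.
#' @slot night_bout_factor multiplicative factor on bout means in the night
#'   half of the session (night bouts longer).
#' @slot awake_power_gain,presleep_gain,early_late_gain state power gains.
#' @slot central_theta_boost named numeric (early, mid, late): extra 5-10 Hz
#'   power factor on channels 1-3 during the corresponding sleep stage.
#' @slot pe_lfp_boost 32-40 Hz power factor on channels 1-5 around sleep PEs.
#' @slot evoked_amp_uv calibration evoked-deflection amplitude at the outermost
#'   channel (uV).
#' @slot pe_rate_wake,pe_rate_midsleep PE burst-initiation rates (bursts/min).
#' @slot pe_intra_burst_interval_s mean within-burst inter-event interval (s).
#' @slot pe_burst_gap_s minimum separation between bursts (s, >= 10).
#' @slot pe_single_prob probability that a burst contains a single event.
#' @slot antenna_osc_freq antennal oscillation frequency during sleep (Hz).
#' @slot antenna_osc_amp_deg antennal oscillation amplitude (degrees).
#' @slot noise_sd background LFP noise standard deviation (uV).
#' @slot noise_exponent spectral exponent of the 1/f^a background.
#' @slot shared_sd amplitude of the shared polarity-flipping component (uV).
#' @slot occlusion_per_hour pose-occlusion windows per hour (likelihood < 0.4).
#' @slot sleep_prob probability that a scheduled bout is actually emitted
#'   (0 disables sleep entirely).
#' @slot seed integer seed; identical config + seed reproduces a session
#'   bit-for-bit.
#' @export
setClass("SimConfig", representation(
  n_flies = "numeric", session_hours = "numeric",
  fs_lfp = "numeric", fs_raw = "numeric", fps_video = "numeric",
  n_channels = "numeric", reversal_channel = "numeric",
  bout_mean_min = "numeric", bout_sd_min = "numeric",
  interbout_mean_min = "numeric", interbout_sd_min = "numeric",
  night_bout_factor = "numeric",
  awake_power_gain = "numeric", presleep_gain = "numeric",
  early_late_gain = "numeric",
  central_theta_boost = "numeric", pe_lfp_boost = "numeric",
  evoked_amp_uv = "numeric",
  pe_rate_wake = "numeric", pe_rate_midsleep = "numeric",
  pe_intra_burst_interval_s = "numeric", pe_burst_gap_s = "numeric",
  pe_single_prob = "numeric",
  antenna_osc_freq = "numeric", antenna_osc_amp_deg = "numeric",
  noise_sd = "numeric", noise_exponent = "numeric", shared_sd = "numeric",
  occlusion_per_hour = "numeric", sleep_prob = "numeric",
  seed = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(
    session_hours = object@session_hours, fs_lfp = object@fs_lfp,
    fps_video = object@fps_video, bout_mean_min = object@bout_mean_min,
    interbout_mean_min = object@interbout_mean_min,
    awake_power_gain = object@awake_power_gain,
    early_late_gain = object@early_late_gain,
    pe_intra_burst_interval_s = object@pe_intra_burst_interval_s,
    pe_burst_gap_s = object@pe_burst_gap_s, noise_sd = object@noise_sd
  )
  if (any(pos <= 0)) {
    msg <- c(msg, paste("must be strictly positive:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (object@reversal_channel < 1 || object@reversal_channel > object@n_channels)
    msg <- c(msg, "reversal_channel outside channel range")
  if (!(object@awake_power_gain > object@early_late_gain &&
        object@early_late_gain > 1))
    msg <- c(msg, "need awake_power_gain > early_late_gain > 1 (stage separability)")
  if (!all(c("early", "mid", "late") %in% names(object@central_theta_boost)))
    msg <- c(msg, "central_theta_boost needs named entries early, mid, late")
  if (length(msg)) msg else TRUE
})

#' LFPRecording: a multichannel voltage series
#'
#' Channels are rows (1 = most central electrode), samples are columns.
#' `channelIds` keeps the original electrode numbering across re-referencing,
#' where one channel is consumed. `segments` records the start times (s) of the
#' hourly acquisition chunks the recording was stitched from.
#'
#' @slot data channels x samples numeric matrix (uV).
#' @slot fs sampling rate, samples/s.
#' @slot channelIds integer original electrode indices, one per row.
#' @slot refScheme one of "raw", "reversal-subtracted", "bipolar".
#' @slot segments numeric, start time (s) of each acquisition segment.
#' @export
setClass("LFPRecording", representation(
  data = "matrix", fs = "numeric", channelIds = "integer",
  refScheme = "character", segments = "numeric"
))

setValidity("LFPRecording", function(object) {
  msg <- character()
  if (!all(is.finite(object@data))) msg <- c(msg, "non-finite voltage values")
  if (nrow(object@data) != length(object@channelIds))
    msg <- c(msg, "channelIds length != channel count")
  if (!object@refScheme %in% c("raw", "reversal-subtracted", "bipolar"))
    msg <- c(msg, "unknown refScheme")
  if (length(msg)) msg else TRUE
})

#' StateLabels: behavioral-state interval table
#'
#' Non-overlapping, half-open `[start_s, end_s)` intervals tiling a session.
#' Labels are awake / presleep / earlysleep / midsleep / latesleep plus the
#' evaluation-only flanking bins pre2 (-4 to -2 min before a bout) and post2
#' (first 2 min after a bout); `bout_id` links sleep-derived intervals to
#' their bout.
#'
#' @slot intervals data.frame(start_s, end_s, label, bout_id).
#' @slot session_end_s session duration in seconds.
#' @export
setClass("StateLabels", representation(
  intervals = "data.frame", session_end_s = "numeric"
))

setValidity("StateLabels", function(object) {
  iv <- object@intervals
  need <- c("start_s", "end_s", "label", "bout_id")
  if (!all(need %in% names(iv))) return("missing interval columns")
  if (nrow(iv) == 0L) return(TRUE)
  iv <- iv[order(iv$start_s), ]
  if (any(iv$end_s <= iv$start_s)) return("empty or inverted interval")
  if (any(abs(head(iv$end_s, -1) - tail(iv$start_s, -1)) > 1e-9))
    return("intervals do not tile the session (gap or overlap)")
  TRUE
})

#' PoseTrack: per-frame body-part positions
#'
#' One row per video frame; for every tracked body part three columns
#' `<part>_x`, `<part>_y`, `<part>_likelihood` in the pose-estimation
#' convention, plus `time_s`.
#'
#' @slot data data.frame of frames.
#' @slot fps frames per second.
#' @slot parts character vector of tracked body parts.
#' @export
setClass("PoseTrack", representation(
  data = "data.frame", fps = "numeric", parts = "character"
))

setValidity("PoseTrack", function(object) {
  lk <- paste0(object@parts, "_likelihood")
  cols <- c(paste0(object@parts, "_x"), paste0(object@parts, "_y"), lk)
  if (!all(cols %in% names(object@data))) return("incomplete body-part columns")
  for (c0 in lk) {
    v <- object@data[[c0]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      return("likelihood outside [0, 1]")
  }
  TRUE
})

#' PEEventTable: detected proboscis-extension events
#'
#' Time-ordered events with burst membership. `iei_s` is the interval to the
#' previous event inside the same burst (NA for burst-initial events);
#' `provenance` records which detector emitted the event.
#'
#' @slot events data.frame(peak_frame, peak_time_s, state, burst_id,
#'   burst_length, iei_s, provenance, ...).
#' @export
setClass("PEEventTable", representation(events = "data.frame"))

setValidity("PEEventTable", function(object) {
  ev <- object@events
  if (nrow(ev) == 0L) return(TRUE)
  if (is.unsorted(ev$peak_time_s)) return("events not time-ordered")
  if ("burst_length" %in% names(ev) &&
      any(ev$burst_length < 1, na.rm = TRUE)) return("burst_length < 1")
  TRUE
})

#' SpectraTable: epochs x (channel, frequency) power grid
#'
#' A SummarizedExperiment whose rows are (channel, frequency-bin) features in
#' channel-major order and whose columns are epochs. The single assay
#' `"power_db"` holds Welch power in dB (10 log10 uV^2/Hz). `rowData` carries
#' `channel` (original electrode index) and `freq_hz`; `colData` carries
#' `fly`, `state`, `rel_bin` (relative-time tag), `bout_id`, `epoch_start_s`
#' and `never_train`.
#'
#' @export
setClass("SpectraTable", contains = "SummarizedExperiment")

#' FeatureMatrix: classifier-ready epoch features
#'
#' Epochs x features matrix (channel-major flattening of the spectral grid)
#' with per-epoch metadata and the never-train audit flag for evaluation-only
#' relative-time bins.
#'
#' @slot x epochs x features numeric matrix.
#' @slot meta data.frame(fly, state, rel_bin, bout_id, epoch_start_s,
#'   never_train, row_id).
#' @slot channels integer original channel index per feature column.
#' @slot freqs numeric frequency (Hz) per feature column.
#' @export
setClass("FeatureMatrix", representation(
  x = "matrix", meta = "data.frame", channels = "integer", freqs = "numeric"
))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@x) != nrow(object@meta)) return("meta/feature row mismatch")
  if (ncol(object@x) != length(object@channels)) return("channel map mismatch")
  if (anyNA(object@x)) return("missing feature values")
  TRUE
})

#' DifferenceMap: per-fly condition contrasts on the channel x frequency grid
#'
#' @slot diff flies x channels x frequency-bins array of per-fly mean spectral
#'   differences (condition A minus condition B, dB).
#' @slot conditions character(2): names of conditions A and B.
#' @slot channels original channel indices (dimension 2).
#' @slot freqs frequency grid in Hz (dimension 3).
#' @slot trial_counts flies x 2 matrix of trials per condition.
#' @export
setClass("DifferenceMap", representation(
  diff = "array", conditions = "character", channels = "integer",
  freqs = "numeric", trial_counts = "matrix"
))

setValidity("DifferenceMap", function(object) {
  d <- dim(object@diff)
  if (length(d) != 3L) return("diff must be flies x channels x freqs")
  if (d[2] != length(object@channels) || d[3] != length(object@freqs))
    return("grid metadata does not match array dimensions")
  if (anyNA(object@diff)) return("missing cells in difference map")
  TRUE
})

#' ClusterResult: cluster-based permutation test output
#'
#' @slot tmap channels x freqs matrix of one-sample t statistics.
#' @slot clusters list of cluster masks (logical channels x freqs matrices).
#' @slot mass numeric per-cluster mass (sum of t inside the cluster).
#' @slot p numeric per-cluster permutation p-value in (0, 1].
#' @slot n_perm permutations used (2^n when exhaustive).
#' @slot exhaustive logical, whether all sign flips were enumerated.
#' @slot threshold cluster-forming |t| threshold used.
#' @slot channels,freqs grid metadata.
#' @export
setClass("ClusterResult", representation(
  tmap = "matrix", clusters = "list", mass = "numeric", p = "numeric",
  n_perm = "numeric", exhaustive = "logical", threshold = "numeric",
  channels = "integer", freqs = "numeric"
))

setValidity("ClusterResult", function(object) {
  if (length(object@clusters) != length(object@p)) return("cluster/p mismatch")
  if (length(object@p) && any(object@p <= 0 | object@p > 1))
    return("p-values outside (0, 1]")
  TRUE
})

#' SimSession: one complete synthetic recording session
#'
#' @slot lfp_segments list of raw hourly [LFPRecording] chunks.
#' @slot calibration list(recording = LFPRecording, stimulus_times = numeric).
#' @slot movement data.frame(time_s, activity) at video rate.
#' @slot pose [PoseTrack].
#' @slot truth_labels [StateLabels] ground-truth five-state labels.
#' @slot truth_events [PEEventTable] ground-truth PE events.
#' @slot config [SimConfig] provenance record.
#' @export
setClass("SimSession", representation(
  lfp_segments = "list", calibration = "list", movement = "data.frame",
  pose = "PoseTrack", truth_labels = "StateLabels",
  truth_events = "PEEventTable", config = "SimConfig"
))
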