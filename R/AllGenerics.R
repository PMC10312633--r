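# Accessors and show methods. Slot access from user code should go through
# these, never through @.

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @export
setGeneric("lfpData", function(x) standardGeneric("lfpData"))
#' @export
setGeneric("refScheme", function(x) standardGeneric("refScheme"))
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @export
setGeneric("poseData", function(x) standardGeneric("poseData"))
#' @export
setGeneric("bodyParts", function(x) standardGeneric("bodyParts"))
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))
#' @export
setGeneric("epochMeta", function(x) standardGeneric("epochMeta"))
#' @export
setGeneric("featureChannels", function(x) standardGeneric("featureChannels"))
#' @export
setGeneric("featureFreqs", function(x) standardGeneric("featureFreqs"))
#' @export
setGeneric("differenceArray", function(x) standardGeneric("differenceArray"))
#' @export
setGeneric("clusterMasks", function(x) standardGeneric("clusterMasks"))
#' @export
setGeneric("clusterP", function(x) standardGeneric("clusterP"))
#' @export
setGeneric("clusterMass", function(x) standardGeneric("clusterMass"))
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))

#' @describeIn LFPRecording-class sampling rate in samples/s
#' @param x object
#' @export
setMethod("samplingRate", "LFPRecording", function(x) x@fs)
#' @describeIn LFPRecording-class original electrode indices per row
#' @export
setMethod("channelIds", "LFPRecording", function(x) x@channelIds)
#' @describeIn LFPRecording-class channels x samples voltage matrix (uV)
#' @export
setMethod("lfpData", "LFPRecording", function(x) x@data)
#' @describeIn LFPRecording-class reference scheme tag
#' @export
setMethod("refScheme", "LFPRecording", function(x) x@refScheme)

#' @describeIn StateLabels-class interval table (start_s, end_s, label, bout_id)
#' @param x object
#' @export
setMethod("intervals", "StateLabels", function(x) x@intervals)

#' @describeIn PoseTrack-class per-frame coordinate table
#' @param x object
#' @export
setMethod("poseData", "PoseTrack", function(x) x@data)
#' @describeIn PoseTrack-class tracked body parts
#' @export
setMethod("bodyParts", "PoseTrack", function(x) x@parts)
#' @describeIn PoseTrack-class frames per second
#' @export
setMethod("frameRate", "PoseTrack", function(x) x@fps)

#' @describeIn PEEventTable-class event table
#' @param x object
#' @export
setMethod("events", "PEEventTable", function(x) x@events)

#' @describeIn FeatureMatrix-class epochs x features matrix
#' @param x object
#' @export
setMethod("featureData", "FeatureMatrix", function(x) x@x)
#' @describeIn FeatureMatrix-class per-epoch metadata
#' @export
setMethod("epochMeta", "FeatureMatrix", function(x) x@meta)
#' @describeIn FeatureMatrix-class original channel per feature column
#' @export
setMethod("featureChannels", "FeatureMatrix", function(x) x@channels)
#' @describeIn FeatureMatrix-class frequency (Hz) per feature column
#' @export
setMethod("featureFreqs", "FeatureMatrix", function(x) x@freqs)

#' @describeIn DifferenceMap-class flies x channels x freqs array
#' @param x object
#' @export
setMethod("differenceArray", "DifferenceMap", function(x) x@diff)
#' @describeIn DifferenceMap-class channel indices of the grid
#' @export
setMethod("featureChannels", "DifferenceMap", function(x) x@channels)
#' @describeIn DifferenceMap-class frequency grid (Hz)
#' @export
setMethod("featureFreqs", "DifferenceMap", function(x) x@freqs)

#' @describeIn ClusterResult-class list of logical cluster masks
#' @param x object
#' @export
setMethod("clusterMasks", "ClusterResult", function(x) x@clusters)
#' @describeIn ClusterResult-class per-cluster permutation p-values
#' @export
setMethod("clusterP", "ClusterResult", function(x) x@p)
#' @describeIn ClusterResult-class per-cluster mass (sum of t)
#' @export
setMethod("clusterMass", "ClusterResult", function(x) x@mass)
#' @describeIn ClusterResult-class cell-wise one-sample t map
#' @export
setMethod("tMap", "ClusterResult", function(x) x@tmap)

setMethod("show", "LFPRecording", function(object) {
  cat(sprintf(
    "LFPRecording: %d channels x %d samples @ %g Hz (%s), %.2f min\n",
    nrow(object@data), ncol(object@data), object@fs, object@refScheme,
    ncol(object@data) / object@fs / 60
  ))
})

setMethod("show", "StateLabels", function(object) {
  iv <- object@intervals
  cat(sprintf("StateLabels: %d intervals over %.1f min\n",
              nrow(iv), object@session_end_s / 60))
  if (nrow(iv)) print(table(iv$label))
})

setMethod("show", "PoseTrack", function(object) {
  cat(sprintf("PoseTrack: %d frames @ %g fps, parts: %s\n",
              nrow(object@data), object@fps,
              paste(object@parts, collapse = ", ")))
})

setMethod("show", "PEEventTable", function(object) {
  ev <- object@events
  nb <- if (nrow(ev) && "burst_id" %in% names(ev))
    length(unique(ev$burst_id)) else 0L
  cat(sprintf("PEEventTable: %d events in %d bursts\n", nrow(ev), nb))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d cluster(s), %s permutations (threshold |t| > %.2f)\n",
    length(object@clusters),
    format(object@n_perm, big.mark = ","), object@threshold
  ))
  if (length(object@p)) {
    for (i in seq_along(object@p)) {
      cat(sprintf("  cluster %d: mass %.1f, p = %.4g, %d cells\n",
                  i, object@mass[i], object@p[i], sum(object@clusters[[i]])))
    }
  }
})

setMethod("show", "SimSession", function(object) {
  cat(sprintf(
    "SimSession: %.1f h, %d LFP segment(s), %d truth events, %d bouts\n",
    object@config@session_hours, length(object@lfp_segments),
    nrow(object@truth_events@events),
    length(unique(stats::na.omit(object@truth_labels@intervals$bout_id)))
  ))
})
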