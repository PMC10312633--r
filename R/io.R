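# Plain-text persistence: CSV interval/event tables, pose tables in the
# standard pose-estimation layout (three header rows: scorer, bodyparts,
# coords), long-format spectra export, cluster summaries as JSON, and a
# session directory with a JSON config sidecar.

#' Write/read a StateLabels interval table as CSV
#'
#' Columns: start_s, end_s, label, bout_id.
#'
#' @param labels [StateLabels-class].
#' @param path CSV file path.
#' @return `readStateLabels` returns a [StateLabels-class].
#' @export
writeStateLabels <- function(labels, path) {
  utils::write.csv(intervals(labels), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStateLabels
#' @export
readStateLabels <- function(path) {
  iv <- utils::read.csv(path)
  iv$bout_id <- as.integer(iv$bout_id)
  new("StateLabels", intervals = iv, session_end_s = max(iv$end_s))
}

#' Write/read a PE event table as CSV
#'
#' @param pe [PEEventTable-class].
#' @param path CSV file path.
#' @return `readPEEvents` returns a [PEEventTable-class].
#' @export
writePEEvents <- function(pe, path) {
  utils::write.csv(events(pe), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePEEvents
#' @export
readPEEvents <- function(path) {
  ev <- utils::read.csv(path)
  ev$burst_id <- as.integer(ev$burst_id)
  ev$burst_length <- as.integer(ev$burst_length)
  new("PEEventTable", events = ev)
}

#' Write/read a pose table in the pose-estimation CSV layout
#'
#' Three header rows (scorer, bodyparts, coords) above the numeric block,
#' with x, y, likelihood columns per body part and the frame index as the
#' first column.
#'
#' @param pose [PoseTrack-class].
#' @param path CSV file path.
#' @param scorer scorer tag written in the first header row.
#' @param fps frame rate used when reading (`readPoseCSV`).
#' @return `readPoseCSV` returns a [PoseTrack-class].
#' @export
writePoseCSV <- function(pose, path, scorer = "synthetic") {
  df <- poseData(pose)
  parts <- bodyParts(pose)
  cols <- as.vector(t(outer(parts, c("x", "y", "likelihood"), paste, sep = "_")))
  block <- df[, cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, length(cols))), collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(parts, each = 3)), collapse = ","), con)
  writeLines(paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
                   collapse = ","), con)
  utils::write.table(cbind(seq_len(nrow(block)) - 1L, block), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePoseCSV
#' @export
readPoseCSV <- function(path, fps = 30) {
  hdr <- readLines(path, n = 3L)
  parts_row <- strsplit(hdr[2L], ",")[[1L]][-1L]
  coords_row <- strsplit(hdr[3L], ",")[[1L]][-1L]
  dat <- utils::read.csv(path, skip = 3L, header = FALSE)
  dat <- dat[, -1L, drop = FALSE]
  names(dat) <- paste(parts_row, coords_row, sep = "_")
  parts <- unique(parts_row)
  dat$time_s <- (seq_len(nrow(dat)) - 1L) / fps
  new("PoseTrack", data = dat, fps = fps, parts = parts)
}

#' Export a SpectraTable as long-format CSV
#'
#' Columns: fly, epoch, state, rel_bin, channel, freq_hz, power_db.
#'
#' @param spectra [SpectraTable-class].
#' @param path CSV file path.
#' @export
writeSpectraCSV <- function(spectra, path) {
  rd <- SummarizedExperiment::rowData(spectra)
  cd <- SummarizedExperiment::colData(spectra)
  pw <- SummarizedExperiment::assay(spectra, "power_db")
  long <- data.frame(
    fly = rep(cd$fly, each = nrow(pw)),
    epoch = rep(seq_len(ncol(pw)), each = nrow(pw)),
    state = rep(cd$state, each = nrow(pw)),
    rel_bin = rep(cd$rel_bin, each = nrow(pw)),
    channel = rep(rd$channel, ncol(pw)),
    freq_hz = rep(rd$freq_hz, ncol(pw)),
    power_db = as.vector(pw))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Export a ClusterResult as a JSON summary plus long CSV
#'
#' The JSON holds cluster ids, masses, p-values, permutation count and the
#' forming threshold; the CSV lists every supra-threshold cell with its
#' cluster id.
#'
#' @param res [ClusterResult-class].
#' @param json_path,csv_path output paths (`NULL` skips one of them).
#' @export
writeClusterResult <- function(res, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    summ <- list(
      n_clusters = length(clusterMasks(res)),
      mass = clusterMass(res), p = clusterP(res),
      n_permutations = res@n_perm, exhaustive = res@exhaustive,
      threshold = res@threshold)
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    rows <- list()
    for (k in seq_along(clusterMasks(res))) {
      idx <- which(clusterMasks(res)[[k]], arr.ind = TRUE)
      if (nrow(idx)) {
        rows[[k]] <- data.frame(
          cluster = k, channel = res@channels[idx[, 1L]],
          freq_hz = res@freqs[idx[, 2L]],
          t = res@tmap[idx])
      }
    }
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  invisible(res)
}

#' Read a multichannel LFP recording from CSV
#'
#' Expects one column per channel (header `ch<k>` or plain names in central
#' to peripheral order) and one row per sample.
#'
#' @param path CSV file path.
#' @param fs sampling rate of the stored series (samples/s).
#' @return [LFPRecording-class] tagged "raw".
#' @export
readLFPCSV <- function(path, fs) {
  m <- as.matrix(utils::read.csv(path))
  ids <- sub("^ch", "", colnames(m))
  ids <- suppressWarnings(as.integer(ids))
  if (anyNA(ids)) ids <- seq_len(ncol(m))
  lfpRecording(t(m), fs, channelIds = ids)
}

#' Export an importance map as long-format CSV
#'
#' @param imp result of [permutationImportance()].
#' @param path CSV file path.
#' @export
writeImportanceCSV <- function(imp, path) {
  utils::write.csv(data.frame(channel = imp$channels, freq_hz = imp$freqs,
                              importance = imp$per_feature),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export classifier reports as JSON
#'
#' Writes the per-iteration [classifierMetrics()] reports of a probe or
#' staging fit.
#'
#' @param fit `peProbe` or `stageRF` object.
#' @param path JSON file path.
#' @export
writeClassifierReport <- function(fit, path) {
  reports <- lapply(seq_along(fit$iterations), function(i) {
    m <- fit$iterations[[i]]$metrics
    list(iteration = i, accuracy = m$accuracy, roc_auc = m$roc_auc,
         per_class = m$per_class,
         confusion = as.data.frame.matrix(m$confusion))
  })
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write/read a FeatureMatrix as CSV
#'
#' One row per epoch: metadata columns (fly, state, rel_bin, bout_id,
#' epoch_start_s, never_train, row_id) followed by the feature columns in
#' channel-major order. Feature values are written with 17 significant
#' digits, so a write/read round trip is bit-identical.
#'
#' @param ft [FeatureMatrix-class].
#' @param path CSV file path.
#' @return `readFeatureMatrix` returns a [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(ft, path) {
  x <- featureData(ft)
  meta <- epochMeta(ft)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(names(meta), colnames(x))
  writeLines(paste(hdr, collapse = ","), con)
  chan_line <- paste(c(rep("", ncol(meta)), featureChannels(ft)), collapse = ",")
  freq_line <- paste(c(rep("", ncol(meta)), sprintf("%.17g", featureFreqs(ft))),
                     collapse = ",")
  writeLines(c(chan_line, freq_line), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(vapply(meta[i, ], as.character, ""),
                       sprintf("%.17g", x[i, ])), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], ",")[[1L]]
  meta_cols <- c("fly", "state", "rel_bin", "bout_id", "epoch_start_s",
                 "never_train", "row_id")
  nm <- length(meta_cols)
  chans <- as.integer(strsplit(lines[2L], ",")[[1L]][-seq_len(nm)])
  freqs <- as.numeric(strsplit(lines[3L], ",")[[1L]][-seq_len(nm)])
  body <- strsplit(lines[-(1:3)], ",")
  meta <- do.call(rbind, lapply(body, function(r)
    as.data.frame(as.list(stats::setNames(r[seq_len(nm)], meta_cols)))))
  meta$bout_id <- suppressWarnings(as.integer(meta$bout_id))
  meta$epoch_start_s <- suppressWarnings(as.numeric(meta$epoch_start_s))
  meta$never_train <- as.logical(meta$never_train)
  meta$row_id <- suppressWarnings(as.integer(meta$row_id))
  x <- do.call(rbind, lapply(body, function(r) as.numeric(r[-seq_len(nm)])))
  colnames(x) <- hdr[-seq_len(nm)]
  new("FeatureMatrix", x = x, meta = meta, channels = chans, freqs = freqs)
}

#' Write/read a synthetic session as a plain-text directory
#'
#' Persists labels, events, movement and pose as CSV plus a JSON sidecar
#' recording the full configuration and seed. The voltage series is not
#' written by default (it is exactly reproducible from the sidecar);
#' `lfp = TRUE` adds one CSV per hourly segment.
#'
#' @param session [SimSession-class].
#' @param dir output directory (created).
#' @param lfp also write the voltage series (large).
#' @return `readSession` returns a list with labels, events, movement, pose
#'   and config (as a plain list).
#' @export
writeSession <- function(session, dir, lfp = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStateLabels(session@truth_labels, file.path(dir, "labels.csv"))
  writePEEvents(session@truth_events, file.path(dir, "events.csv"))
  utils::write.csv(session@movement, file.path(dir, "movement.csv"),
                   row.names = FALSE)
  if (length(bodyParts(session@pose)) > 1L) {
    writePoseCSV(session@pose, file.path(dir, "pose.csv"))
  }
  cfg <- attributes(session@config)
  cfg <- cfg[setdiff(names(cfg), "class")]
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  if (lfp) {
    for (i in seq_along(session@lfp_segments)) {
      utils::write.csv(t(lfpData(session@lfp_segments[[i]])),
                       file.path(dir, sprintf("lfp_segment_%02d.csv", i)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  pose_path <- file.path(dir, "pose.csv")
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  list(
    labels = readStateLabels(file.path(dir, "labels.csv")),
    events = readPEEvents(file.path(dir, "events.csv")),
    movement = utils::read.csv(file.path(dir, "movement.csv")),
    pose = if (file.exists(pose_path)) readPoseCSV(pose_path, fps = cfg$fps_video)
    else NULL,
    config = cfg)
}
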