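# Movement quantification and sleep-bout labeling. The immobility criterion is
# the standard Drosophila one: complete stillness for (strictly) more than
# 5 minutes. All duration logic runs on frame timestamps, not indices, so
# dropped frames cannot shift bout durations.

#' Construct per-frame movement flags
#'
#' @param moved logical (or 0/1) vector, one element per frame.
#' @param fps frames per second.
#' @param times frame timestamps in seconds (default a uniform grid at `fps`).
#' @param area optional per-frame largest-contour area (pixels).
#' @return data.frame(time_s, moved, area) with attribute `fps`.
#' @export
movementFlags <- function(moved, fps, times = NULL, area = NULL) {
  n <- length(moved)
  if (is.null(times)) times <- (seq_len(n) - 1L) / fps
  if (is.unsorted(times, strictly = TRUE)) stop("timestamps must be strictly increasing")
  out <- data.frame(time_s = times, moved = as.logical(moved),
                    area = if (is.null(area)) NA_real_ else area)
  attr(out, "fps") <- fps
  out
}

#' Quantify movement from a grayscale frame stack
#'
#' Implements the frame-differencing chain: crop, grayscale, absolute frame
#' difference, binarize, dilate (3x3 box, 2 iterations), connected-contour
#' extraction; a frame is "moved" iff any contour area reaches `area_thresh`
#' pixels. The first frame is "still" by convention (no predecessor).
#'
#' @param frames array h x w x n (grayscale) or h x w x 3 x n (color, averaged
#'   to grayscale), intensities in any consistent scale.
#' @param pixel_thresh intensity threshold on the absolute frame difference.
#' @param area_thresh minimum contour area (pixels) for a movement event.
#' @param crop optional integer c(row0, row1, col0, col1) region kept.
#' @param fps frames per second (for the timestamps of the output).
#' @return [movementFlags()] data.frame.
#' @export
quantifyMovement <- function(frames, pixel_thresh, area_thresh, crop = NULL,
                             fps = 30) {
  stopifnot(pixel_thresh > 0, area_thresh > 0)
  if (length(dim(frames)) == 4L) {
    frames <- apply(frames, c(1, 2, 4), mean) # color -> grayscale
  }
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be h x w x n")
  if (d[3] < 2L) stop("need at least 2 frames")
  if (!is.null(crop)) {
    frames <- frames[crop[1]:crop[2], crop[3]:crop[4], , drop = FALSE]
  }
  n <- dim(frames)[3]
  brush <- EBImage::makeBrush(3, shape = "box")
  moved <- logical(n)
  area <- numeric(n)
  for (i in 2:n) {
    delta <- abs(frames[, , i] - frames[, , i - 1L])
    bin <- EBImage::Image(delta >= pixel_thresh)
    bin <- EBImage::dilate(EBImage::dilate(bin, brush), brush)
    lab <- EBImage::bwlabel(bin)
    if (max(lab) > 0) {
      sizes <- tabulate(as.integer(lab[lab > 0]))
      area[i] <- max(sizes)
      moved[i] <- any(sizes >= area_thresh)
    }
  }
  movementFlags(moved, fps = fps, area = area)
}

#' Prune brief movement and stillness runs
#'
#' Movement runs shorter than `min_move_s` become still, then still runs
#' shorter than `min_still_s` become moved. Idempotent on its own output.
#'
#' @param flags [movementFlags()] data.frame.
#' @param min_move_s,min_still_s minimum run durations (s); 0 disables a pass.
#' @return pruned flags, same shape.
#' @export
pruneMovement <- function(flags, min_move_s = 1, min_still_s = 1) {
  stopifnot(min_move_s >= 0, min_still_s >= 0)
  fps <- attr(flags, "fps")
  rewrite <- function(v, target, min_s) {
    if (min_s <= 0) return(v)
    r <- runsFromFlags(v, flags$time_s, fps)
    for (k in seq_len(nrow(r))) {
      if (r$value[k] == target && (r$end_s[k] - r$start_s[k]) < min_s) {
        v[r$start_idx[k]:r$end_idx[k]] <- !target
      }
    }
    v
  }
  v <- rewrite(flags$moved, TRUE, min_move_s)
  v <- rewrite(v, FALSE, min_still_s)
  out <- flags
  out$moved <- v
  out
}

#' Detect sleep bouts by the 5-minute immobility criterion
#'
#' Maximal still runs strictly longer than `min_sleep_min` minutes become
#' sleep bouts (a run of exactly the threshold duration stays awake); all
#' other time is awake. Bout ids are assigned in time order.
#'
#' @param flags pruned [movementFlags()].
#' @param min_sleep_min immobility threshold in minutes (default 5).
#' @return [StateLabels-class] with labels "sleep"/"awake".
#' @export
detectSleepBouts <- function(flags, min_sleep_min = 5) {
  fps <- attr(flags, "fps")
  r <- runsFromFlags(flags$moved, flags$time_s, fps)
  end_s <- max(r$end_s)
  sleep <- r[!r$value & (r$end_s - r$start_s) > min_sleep_min * 60, , drop = FALSE]
  boutsToLabels(sleep[, c("start_s", "end_s")], end_s)
}

# sleep/awake StateLabels from a table of bout intervals
boutsToLabels <- function(bouts, session_end_s, session_start_s = 0) {
  bouts <- bouts[order(bouts$start_s), , drop = FALSE]
  iv <- data.frame(start_s = numeric(), end_s = numeric(),
                   label = character(), bout_id = integer())
  t0 <- session_start_s
  for (k in seq_len(nrow(bouts))) {
    if (bouts$start_s[k] > t0) {
      iv <- rbind(iv, data.frame(start_s = t0, end_s = bouts$start_s[k],
                                 label = "awake", bout_id = NA_integer_))
    }
    iv <- rbind(iv, data.frame(start_s = bouts$start_s[k], end_s = bouts$end_s[k],
                               label = "sleep", bout_id = k))
    t0 <- bouts$end_s[k]
  }
  if (t0 < session_end_s) {
    iv <- rbind(iv, data.frame(start_s = t0, end_s = session_end_s,
                               label = "awake", bout_id = NA_integer_))
  }
  new("StateLabels", intervals = iv, session_end_s = session_end_s)
}

#' Expand sleep/awake bouts into the five-state epoch scheme
#'
#' Per sleep bout: presleep = the 2 min of awake time before bout start,
#' earlysleep = first 2 min of the bout, latesleep = last 2 min, midsleep =
#' the remainder; evaluation-only flanking bins pre2 = [-4, -2) min before
#' the bout and post2 = the 2 min after it are tagged with their own labels
#' and must never enter a training set. When the awake gap between two bouts
#' is too short for all flanking bins, bins are clipped at the gap midpoint
#' with sleep-adjacent bins (presleep) taking priority over the evaluation
#' bins; all bins stay disjoint.
#'
#' @param bouts [StateLabels-class] with "sleep"/"awake" labels.
#' @return [StateLabels-class] with the full label scheme.
#' @export
labelEpochs <- function(bouts) {
  iv <- intervals(bouts)
  end_s <- bouts@session_end_s
  sl <- iv[iv$label == "sleep", , drop = FALSE]
  sl <- sl[order(sl$start_s), , drop = FALSE]
  two <- 120
  pieces <- list()
  add <- function(s, e, lab, id) {
    if (e - s > 1e-9) {
      pieces[[length(pieces) + 1L]] <<- data.frame(
        start_s = s, end_s = e, label = lab, bout_id = id)
    }
  }
  n <- nrow(sl)
  for (k in seq_len(n)) {
    s <- sl$start_s[k]; e <- sl$end_s[k]; id <- sl$bout_id[k]
    prev_end <- if (k > 1L) sl$end_s[k - 1L] else 0
    next_start <- if (k < n) sl$start_s[k + 1L] else end_s
    # awake-side bins before the bout; midpoint clipping against the
    # previous bout's post2 bin, presleep wins over evaluation bins
    mid_prev <- (prev_end + s) / 2
    ps0 <- max(s - two, prev_end)
    if (k > 1L && ps0 < prev_end + two) ps0 <- max(ps0, min(mid_prev, s))
    add(ps0, s, "presleep", id)
    p2a <- max(s - 2 * two, prev_end)
    if (k > 1L) p2a <- max(p2a, prev_end + min(two, mid_prev - prev_end))
    add(p2a, ps0, "pre2", id)
    # the bout itself
    add(s, min(s + two, e), "earlysleep", id)
    add(min(s + two, e), max(e - two, s + two), "midsleep", id)
    add(max(e - two, s + two), e, "latesleep", id)
    # post-bout evaluation bin, clipped at the midpoint to the next bout
    mid_next <- (e + next_start) / 2
    po1 <- min(e + two, next_start)
    if (k < n && next_start - e < 2 * two) po1 <- min(po1, mid_next)
    add(e, po1, "post2", id)
  }
  if (!length(pieces)) { # no sleep anywhere: one awake block
    return(new("StateLabels", intervals = data.frame(
      start_s = 0, end_s = end_s, label = "awake", bout_id = NA_integer_),
      session_end_s = end_s))
  }
  lab <- do.call(rbind, pieces)
  lab <- lab[order(lab$start_s), , drop = FALSE]
  # fill remaining time with awake
  out <- list()
  cursor <- 0
  for (k in seq_len(nrow(lab))) {
    if (lab$start_s[k] > cursor + 1e-9) {
      out[[length(out) + 1L]] <- data.frame(
        start_s = cursor, end_s = lab$start_s[k],
        label = "awake", bout_id = NA_integer_)
    }
    out[[length(out) + 1L]] <- lab[k, ]
    cursor <- lab$end_s[k]
  }
  if (cursor < end_s - 1e-9) {
    out[[length(out) + 1L]] <- data.frame(
      start_s = cursor, end_s = end_s, label = "awake", bout_id = NA_integer_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  new("StateLabels", intervals = res, session_end_s = end_s)
}

#' Day/night sleep-bout summary
#'
#' Partitions sleep bouts by onset clock time into day (lights on) and night,
#' and returns per-partition bout-duration medians and counts. Sessions are
#' assumed to start at `session_start_h` on the 24-h clock.
#'
#' @param bouts [StateLabels-class] containing sleep bouts (any scheme).
#' @param lights_on,lights_off clock hours of the light phase (default 8, 20).
#' @param session_start_h clock hour at session time 0 (default 14).
#' @return data.frame with one row per partition: n bouts, median and mean
#'   duration (min); medians are NA (flagged) when a partition is empty.
#' @export
boutSummary <- function(bouts, lights_on = 8, lights_off = 20,
                        session_start_h = 14) {
  iv <- intervals(bouts)
  asleep <- c("sleep", "earlysleep", "midsleep", "latesleep")
  sl <- iv[!is.na(iv$bout_id) & iv$label %in% asleep, , drop = FALSE]
  if (nrow(sl)) {
    spl <- split(sl, sl$bout_id)
    agg <- data.frame(
      start_s = vapply(spl, function(d) min(d$start_s), 0),
      dur = vapply(spl, function(d) sum(d$end_s - d$start_s), 0)
    )
    onset_h <- (session_start_h + agg$start_s / 3600) %% 24
    is_day <- onset_h >= lights_on & onset_h < lights_off
  } else {
    agg <- data.frame(dur = numeric()); is_day <- logical()
  }
  part <- function(sel, name) {
    d <- agg$dur[sel] / 60
    data.frame(phase = name, n = length(d),
               median_min = if (length(d)) median(d) else NA_real_,
               mean_min = if (length(d)) mean(d) else NA_real_)
  }
  out <- rbind(part(is_day, "day"), part(!is_day, "night"))
  out$flagged <- out$n == 0L
  out
}
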