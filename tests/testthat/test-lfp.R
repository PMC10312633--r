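# Preprocessing, polarity reversal, re-referencing, epoching and spectra.

test_that("preprocessing passes 10 Hz, kills 50 Hz and removes DC", {
  fs <- 250
  t <- seq_len(fs * 30) / fs
  x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 50 * t), rep(1, length(t)))
  rec <- lfpRecording(x, fs)
  out <- lfpData(preprocessLFP(rec))
  core <- seq(fs * 5, fs * 25)
  expect_lt(abs(sd(out[1, core]) / sd(x[1, core]) - 1), 0.01)
  atten_db <- 20 * log10(sd(x[2, core]) / sd(out[2, core]))
  expect_gt(atten_db, 20)
  expect_lt(max(abs(out[3, core])), 0.05) # DC removed by the 0.5 Hz edge
})

test_that("preprocessing resamples a higher-rate recording", {
  fs <- 1000
  t <- seq_len(fs * 20) / fs
  rec <- lfpRecording(rbind(sin(2 * pi * 10 * t)), fs)
  out <- preprocessLFP(rec)
  expect_equal(samplingRate(out), 250)
  expect_equal(ncol(lfpData(out)), 250 * 20)
  core <- seq(250 * 5, 250 * 15)
  expect_lt(abs(sd(lfpData(out)[1, core]) - sd(sin(2 * pi * 10 * t)[seq(5000, 15000)])), 0.01)
  expect_error(preprocessLFP(lfpRecording(rbind(rnorm(100)), 60)), "Nyquist")
})

test_that("stitching conserves duration and bounds boundary jumps", {
  fs <- 250
  mk <- function(offset) lfpRecording(matrix(offset, 2, fs * 10), fs)
  one <- stitchHours(list(mk(0)))
  expect_equal(ncol(lfpData(one)), fs * 10)
  # step offset between segments: no jump larger than the bridge slope bound
  st <- stitchHours(list(mk(0), mk(5)), bridge_s = 1)
  expect_equal(ncol(lfpData(st)), fs * 20)
  d <- abs(diff(lfpData(st)[1, ]))
  expect_lt(max(d), 5 / fs + 1e-9)
  three <- stitchHours(list(mk(0), mk(1), mk(2)))
  expect_equal(ncol(lfpData(three)), fs * 30)
  expect_error(stitchHours(list(mk(0), lfpRecording(matrix(0, 3, 100), fs))),
               "channel")
})

test_that("polarity reversal is recovered exactly for channels 11-13", {
  for (rev_ch in 11:13) {
    for (seed in 1:6) {
      cfg <- simConfig(reversal_channel = rev_ch, seed = 200 * rev_ch + seed)
      cal <- simulateCalibration(cfg)
      res <- detectPolarityReversal(cal$recording, cal$stimulus_times)
      expect_equal(res$reversal_channel, rev_ch)
      expect_equal(res$quality, "good")
      # deflection signs by construction: + peripheral, - central
      amp <- res$amplitudes
      expect_true(all(amp[seq_len(rev_ch - 1)] < 0))
      expect_true(all(amp[seq(rev_ch + 1, 16)] > 0))
    }
  }
})

test_that("degenerate calibration inputs are rejected", {
  cfg <- simConfig(seed = 3)
  cal <- simulateCalibration(cfg, amplitude_uv = 0)
  expect_error(detectPolarityReversal(cal$recording, cal$stimulus_times),
               "no reversal found")
  # all-positive deflections
  cal2 <- simulateCalibration(simConfig(seed = 4, reversal_channel = 11))
  rec <- cal2$recording
  shifted <- lfpRecording(abs(lfpData(rec)) + 1, samplingRate(rec))
  expect_error(detectPolarityReversal(shifted, cal2$stimulus_times),
               "no reversal found")
  expect_error(detectPolarityReversal(cal$recording, cal$stimulus_times[1:3]),
               "at least 5")
})

test_that("reversal re-referencing drops the reference and cancels common mode", {
  set.seed(9)
  x <- matrix(rnorm(16 * 1000), 16, 1000)
  rec <- lfpRecording(x, 250)
  rr <- rereferenceReversal(rec, 12)
  expect_equal(nrow(lfpData(rr)), 15L)
  expect_equal(channelIds(rr), setdiff(1:16, 12L))
  expect_equal(refScheme(rr), "reversal-subtracted")
  expect_equal(lfpData(rr)[1, ], x[12, ] - x[1, ]) # reference minus channel
  # common-mode cancellation
  common <- matrix(rep(rnorm(1000), each = 16), 16, 1000)
  expect_equal(max(abs(lfpData(rereferenceReversal(lfpRecording(common, 250), 12)))), 0)
  # signal only on the reversal channel appears on all outputs
  solo <- matrix(0, 16, 1000); solo[12, ] <- rnorm(1000)
  out <- lfpData(rereferenceReversal(lfpRecording(solo, 250), 12))
  for (i in 1:15) expect_equal(out[i, ], solo[12, ])
  expect_error(rereferenceReversal(rec, 17), "invalid")
})

test_that("bipolar re-referencing is the nearest-neighbor difference", {
  x <- matrix(0, 16, 100)
  for (i in 1:16) x[i, ] <- i # linear spatial ramp
  out <- lfpData(rereferenceBipolar(lfpRecording(x, 250)))
  expect_equal(dim(out), c(15L, 100L))
  expect_true(all(out == 1)) # constant nonzero differences
  common <- matrix(rep(rnorm(100), each = 16), 16, 100)
  expect_equal(max(abs(lfpData(rereferenceBipolar(lfpRecording(common, 250))))), 0)
  expect_error(rereferenceBipolar(lfpRecording(matrix(0, 1, 10), 250)), "2 channels")
})

test_that("re-referencing operators are linear", {
  set.seed(10)
  a <- matrix(rnorm(16 * 500), 16, 500)
  b <- matrix(rnorm(16 * 500), 16, 500)
  for (op in list(function(m) lfpData(rereferenceReversal(lfpRecording(m, 250), 12)),
                  function(m) lfpData(rereferenceBipolar(lfpRecording(m, 250))))) {
    expect_equal(op(a + b), op(a) + op(b))
    expect_equal(op(2.5 * a), 2.5 * op(a))
  }
})

test_that("epoching floors interval durations and accounts for all time", {
  fs <- 250
  rec <- lfpRecording(matrix(rnorm(2 * fs * 400), 2), fs)
  iv <- data.frame(start_s = c(0, 150, 300.5), end_s = c(150, 300.5, 400),
                   label = c("awake", "sleep", "awake"),
                   bout_id = c(NA, 1L, NA))
  labels <- new("StateLabels", intervals = iv, session_end_s = 400)
  ep <- epochByLabels(rec, labels, 60)
  m <- epochMeta(ep)
  expect_equal(sum(m$label == "sleep"), 2L) # floor(150.5/60)
  expect_equal(nrow(m), 2L + 2L + 1L)
  # accounting identity: epoch time <= labeled time, deficit < 1 epoch/interval
  expect_lte(nrow(m) * 60, 400)
  expect_gt(nrow(m) * 60, 400 - 3 * 60)
  # sub-epoch interval yields nothing
  iv2 <- data.frame(start_s = c(0, 10), end_s = c(10, 10.9),
                    label = c("awake", "sleep"), bout_id = c(NA, 1L))
  lab2 <- new("StateLabels", intervals = iv2, session_end_s = 10.9)
  rec2 <- lfpRecording(matrix(rnorm(2 * fs * 11), 2), fs)
  ep2 <- epochByLabels(rec2, lab2, 1)
  expect_equal(sum(epochMeta(ep2)$label == "sleep"), 0L)
})

test_that("power spectra have the printed grid and calibrated level", {
  fs <- 250
  set.seed(11)
  # 16-channel white-noise recording, re-referenced then epoched
  rec <- lfpRecording(matrix(rnorm(16 * fs * 120, sd = 10), 16), fs)
  rr <- rereferenceReversal(rec, 12)
  labels <- new("StateLabels", intervals = data.frame(
    start_s = 0, end_s = 120, label = "awake", bout_id = NA_integer_),
    session_end_s = 120)
  sp <- powerSpectrum(epochByLabels(rr, labels, 60))
  expect_equal(dim(sp), c(15L * 145L, 2L))
  rd <- SummarizedExperiment::rowData(sp)
  expect_equal(length(unique(rd$freq_hz)), 145L)
  expect_equal(range(rd$freq_hz), c(20, 164) * 250 / 1024)
  expect_equal(length(unique(rd$channel)), 15L)
  # difference of two independent sd-10 channels has variance 200; inside
  # the 5-40 Hz passband the density is flat at 2*200/fs
  pw <- SummarizedExperiment::assay(sp, "power_db")
  inband <- rd$freq_hz > 8 & rd$freq_hz < 35
  expect_lt(abs(mean(pw[inband, ]) - 10 * log10(2 * 200 / fs)), 0.5)
})

test_that("a 10 Hz tone lands in the nearest frequency bin", {
  fs <- 250
  t <- seq_len(fs * 60) / fs
  x <- rbind(sin(2 * pi * 10 * t), 0)
  rec <- lfpRecording(x + matrix(rnorm(length(x), sd = 0.01), 2), fs)
  labels <- new("StateLabels", intervals = data.frame(
    start_s = 0, end_s = 60, label = "awake", bout_id = NA_integer_),
    session_end_s = 60)
  sp <- powerSpectrum(epochByLabels(rereferenceBipolar(rec), labels, 60))
  rd <- SummarizedExperiment::rowData(sp)
  pw <- SummarizedExperiment::assay(sp, "power_db")[, 1]
  expect_equal(rd$freq_hz[which.max(pw)], 41 * 250 / 1024) # nearest to 10 Hz
})

test_that("band power from the spectrum matches time-domain variance", {
  fs <- 250
  set.seed(12)
  x <- bandNoise(fs * 60, fs, c(8, 30)) * 4
  w <- welchPSD(x, fs)
  df <- fs / 1024
  expect_lt(abs(sum(w$psd) * df / var(x) - 1), 0.05)
})

test_that("channel-group means shift only with their channels", {
  set.seed(13)
  pw <- matrix(rnorm(15 * 145 * 4, 0, 0.01), 15 * 145, 4)
  boosted <- rep(c(1, 2, 3), each = 145)
  pw[seq_len(3 * 145), ] <- pw[seq_len(3 * 145), ] + 5 # channels 1-3 boost
  rd <- S4Vectors::DataFrame(channel = rep(setdiff(1:16, 12L), each = 145),
                             freq_hz = rep(defaultFreqGrid(), 15))
  cd <- S4Vectors::DataFrame(fly = "f1", state = "awake",
                             label = "awake", rel_bin = "awake",
                             bout_id = NA_integer_, epoch_start_s = 0,
                             never_train = FALSE)[rep(1, 4), ]
  sp <- new("SpectraTable", SummarizedExperiment::SummarizedExperiment(
    assays = list(power_db = pw), rowData = rd, colData = cd))
  g <- groupChannels(sp)
  m <- tapply(g$power_db, g$group, mean)
  expect_gt(m[["central"]], m[["middle"]] + 2)
  expect_lt(abs(m[["middle"]] - m[["peripheral"]]), 0.1)
})

test_that("electrode localization follows the dye axis at 25 um spacing", {
  u <- c(1, 2, 2) / 3
  ts <- seq(0, 300, by = 20)
  pts <- t(sapply(ts, function(s) s * u))
  geo <- localizeElectrodes(pts, innermost_point = pts[1, ])
  expect_equal(abs(sum(geo$axis * u)), 1, tolerance = 1e-8)
  expect_equal(geo$residual_rms, 0, tolerance = 1e-8)
  d <- sqrt(rowSums(diff(geo$positions)^2))
  expect_equal(d, rep(25, 15))
  # noisy points: axis within 2 degrees of truth (Monte Carlo)
  angs <- sapply(1:100, function(i) {
    noisy <- pts + matrix(rnorm(length(pts), 0, 1), nrow(pts))
    g <- localizeElectrodes(noisy, noisy[1, ])
    acos(min(abs(sum(g$axis * u)), 1)) * 180 / pi
  })
  expect_lt(max(angs), 2)
  expect_error(localizeElectrodes(rbind(u, u), u), "non-coincident")
})
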