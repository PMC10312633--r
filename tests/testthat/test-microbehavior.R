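# PE feature extraction, the two detectors, burst grouping, antennal angles
# and periodicity.

makePose <- function(n = 300, fps = 30, prob_xy = NULL, lik = NULL) {
  df <- data.frame(
    time_s = (seq_len(n) - 1) / fps,
    eye_x = rep(100, n), eye_y = rep(100, n), eye_likelihood = rep(1, n),
    proboscis_x = if (is.null(prob_xy)) rep(110, n) else prob_xy[, 1],
    proboscis_y = if (is.null(prob_xy)) rep(120, n) else prob_xy[, 2],
    proboscis_likelihood = if (is.null(lik)) rep(1, n) else lik)
  new("PoseTrack", data = df, fps = fps, parts = c("eye", "proboscis"))
}

test_that("dist_eyeprob follows its definition", {
  # proboscis at (3,4) from the eye with likelihood 0.5 -> 2.5
  p <- makePose(n = 50, prob_xy = cbind(rep(103, 50), rep(104, 50)),
                lik = rep(0.5, 50))
  f <- computePEFeatures(p)
  expect_equal(unique(f$dist_eyeprob), 2.5)
  # coincident with the eye -> 0 regardless of likelihood
  p0 <- makePose(n = 50, prob_xy = cbind(rep(100, 50), rep(100, 50)),
                 lik = runif(50))
  expect_equal(unique(computePEFeatures(p0)$dist_eyeprob), 0)
})

test_that("filter and moving average are the identity on constants", {
  p <- makePose(n = 200)
  f <- computePEFeatures(p)
  expect_equal(f$proboscis_x_lp, rep(110, 200), tolerance = 1e-6)
  expect_equal(f$proboscis_x_ma, rep(110, 200), tolerance = 1e-6)
})

test_that("NaN coordinates are masked with likelihood zero", {
  xy <- cbind(rep(110, 100), rep(120, 100))
  xy[40:42, 1] <- NaN
  p <- makePose(n = 100, prob_xy = xy)
  f <- quietly(computePEFeatures(p))
  expect_true(all(f$masked[40:42]))
  expect_equal(f$proboscis_likelihood[40:42], c(0, 0, 0))
  expect_equal(f$dist_eyeprob[40:42], c(0, 0, 0))
})

test_that("the frame classifier is perfect on separable features and at
           chance on shuffled labels", {
  set.seed(1)
  n <- 600
  truth <- sort(sample(n, 150))
  xy <- cbind(110 + rnorm(n, 0, 0.5), 120 + rnorm(n, 0, 0.5))
  xy[truth, ] <- xy[truth, ] + 15 # clear displacement
  p <- makePose(n = n, prob_xy = xy)
  f <- computePEFeatures(p)
  clf <- trainPEClassifier(f, truth, seed = 2)
  expect_equal(clf$metrics$accuracy, 1.0)
  # permutation baseline: shuffled ground truth -> accuracy near prior
  accs <- sapply(1:10, function(i) {
    tr <- sample(n, 150)
    quietly(trainPEClassifier(f, tr, seed = i))$metrics$accuracy
  })
  prior <- 1 - 150 / n
  expect_lt(abs(mean(accs) - prior), 0.1)
  expect_error(trainPEClassifier(f, integer(0)), "single class")
})

test_that("event detection finds pulse apices and honors empty input", {
  fps <- 30
  n <- 900
  t <- (seq_len(n) - 1) / fps
  disp <- exp(-((t - 10) / 0.12)^2) # one smooth pulse at 10 s
  xy <- cbind(110 + 15 * disp, 120 + 15 * disp)
  p <- makePose(n = n, prob_xy = xy)
  f <- computePEFeatures(p)
  pos <- disp > 0.3
  ev <- events(detectPEEvents(f, pos))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$peak_time_s - 10), 0.1)
  # nothing positive, likelihood high everywhere -> empty table
  empty <- detectPEEvents(f, rep(FALSE, n), likelihood_thresh = 0.9)
  expect_equal(nrow(events(empty)), 0L)
})

test_that("time-reversal symmetry of event detection", {
  s <- simulateSession(simConfig(session_hours = 0.4, seed = 31),
                       with_lfp = FALSE)
  f <- computePEFeatures(s@pose, parts = c("eye", "proboscis"))
  fwd <- events(detectPEEvents(f))$peak_time_s
  frev <- f[rev(seq_len(nrow(f))), ]
  frev$time_s <- f$time_s
  attr(frev, "fps") <- attr(f, "fps")
  bwd <- events(detectPEEvents(frev))$peak_time_s
  total <- max(f$time_s)
  expect_equal(sort(round(total - bwd, 1)), sort(round(fwd, 1)), tolerance = 0.11)
})

test_that("peak-picking applies the three exclusions in order", {
  fps <- 30
  n <- 600
  t <- (seq_len(n) - 1) / fps
  base <- rnorm(n, 0, 0.2)
  pulse <- function(t0, amp, width) amp * exp(-((t - t0) / width)^2)
  d <- base + pulse(5, 10, 0.15)            # clean event
  d[300] <- 12                              # one-frame spike
  d <- d + pulse(15, 80, 0.15)              # exceeds the amplitude cap
  ev <- events(detectPEPeaks(d, fps, min_rise_s = 0.1, max_dist_px = 50,
                             min_height_px = 5))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$peak_time_s - 5), 0.2)
})

test_that("burst grouping implements single-linkage chaining", {
  mk <- function(times) {
    new("PEEventTable", events = data.frame(
      peak_frame = round(times * 30) + 1L, peak_time_s = times,
      state = "awake", burst_id = NA_integer_, burst_length = NA_integer_,
      iei_s = NA_real_, provenance = "truth"))
  }
  g <- events(groupBursts(mk(c(0, 5, 30))))
  expect_equal(g$burst_id, c(1L, 1L, 2L))
  expect_equal(g$burst_length, c(2L, 2L, 1L))
  expect_equal(g$burst_class, c("multi", "multi", "single"))
  expect_equal(g$iei_s, c(NA, 5, NA))
  # all gaps > 10 s: every event single
  g2 <- events(groupBursts(mk(c(0, 11, 40))))
  expect_true(all(g2$burst_class == "single"))
  # idempotence and order independence
  ev <- mk(c(2, 3.5, 30, 31.5, 60))
  once <- groupBursts(ev)
  twice <- groupBursts(once)
  expect_equal(events(twice), events(once))
  perm <- peEventTable(events(ev)[c(3, 1, 5, 2, 4), ])
  expect_equal(events(groupBursts(perm)), events(once))
  # conservation of event count
  expect_equal(nrow(events(once)), 5L)
})

test_that("antennal angles are zero ahead and invariant to head rotation", {
  n <- 100
  mkAnt <- function(rot_deg = 0, sweep_deg = 0) {
    rot <- rot_deg * pi / 180
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    bL <- c(80, 90); bR <- c(120, 90)
    th <- (90 + sweep_deg) * pi / 180
    tL <- bL + 15 * c(cos(th), sin(th))
    tR <- bR + 15 * c(cos(th), sin(th))
    pts <- lapply(list(bL, tL, bR, tR), function(p) as.vector(R %*% p))
    df <- data.frame(
      time_s = (seq_len(n) - 1) / 30,
      antenna_L_base_x = pts[[1]][1], antenna_L_base_y = pts[[1]][2],
      antenna_L_base_likelihood = 1,
      antenna_L_tip_x = pts[[2]][1], antenna_L_tip_y = pts[[2]][2],
      antenna_L_tip_likelihood = 1,
      antenna_R_base_x = pts[[3]][1], antenna_R_base_y = pts[[3]][2],
      antenna_R_base_likelihood = 1,
      antenna_R_tip_x = pts[[4]][1], antenna_R_tip_y = pts[[4]][2],
      antenna_R_tip_likelihood = 1)
    new("PoseTrack", data = df, fps = 30,
        parts = c("antenna_L_base", "antenna_L_tip",
                  "antenna_R_base", "antenna_R_tip"))
  }
  a0 <- antennaAngles(mkAnt())
  expect_equal(unique(a0$angle_L_deg), 0, tolerance = 1e-8)
  # rigid rotation of the whole head leaves the angle unchanged
  a30 <- antennaAngles(mkAnt(rot_deg = 30, sweep_deg = 12))
  aRef <- antennaAngles(mkAnt(rot_deg = 0, sweep_deg = 12))
  expect_equal(a30$angle_L_deg, aRef$angle_L_deg, tolerance = 1e-8)
  expect_equal(unique(aRef$angle_L_deg), 12, tolerance = 1e-8)
})

test_that("synthetic antennal oscillation amplitude is recovered within 1 degree", {
  cfg <- simConfig(seed = 12, antenna_osc_amp_deg = 10, antenna_osc_freq = 0.5)
  lab <- boutsToLabels(data.frame(start_s = 0, end_s = 600), 600) # all sleep
  pose <- simulatePose(emptyEvents(), cfg, labels = lab, duration_s = 600)
  ang <- antennaAngles(pose)
  t <- ang$time_s
  fit <- lm(angle_L_deg ~ sin(2 * pi * 0.5 * t) + cos(2 * pi * 0.5 * t),
            data = ang)
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 10), 1)
})

test_that("periodicity detection flags sines, not noise, and applies the 6-s rule", {
  fps <- 30
  t <- (seq_len(fps * 120) - 1) / fps
  seg <- detectPeriodicity(10 * sin(2 * pi * 0.5 * t), fps = fps)
  expect_true(all(seg$periodic))
  expect_equal(unique(seg$dominant_freq_hz), 0.5, tolerance = 0.02)
  # white noise false-positive rate at the default criterion
  set.seed(4)
  flags <- replicate(20, {
    s <- detectPeriodicity(rnorm(fps * 120), fps = fps)
    mean(s$periodic)
  })
  expect_lte(mean(flags), 0.1)
  # proboscis rule: events at 0, 3, 20 -> exactly one periodic event
  ev <- new("PEEventTable", events = data.frame(
    peak_frame = c(1L, 91L, 601L), peak_time_s = c(0, 3, 20),
    state = "midsleep", burst_id = NA_integer_, burst_length = NA_integer_,
    iei_s = NA_real_, provenance = "truth"))
  out <- events(detectPeriodicity(ev))
  expect_equal(sum(out$periodic), 1L)
  expect_true(out$periodic[2])
  expect_error(detectPeriodicity(rnorm(100), fps = 30, window_s = 30),
               "window longer")
})

test_that("PE depth summary counts events around the 5th minute correctly", {
  lab <- labelEpochs(boutsToLabels(
    data.frame(start_s = 600, end_s = 1200), 1800)) # 10-min bout at t=10min
  mk <- function(times, states) new("PEEventTable", events = data.frame(
    peak_frame = round(times * 30) + 1L, peak_time_s = times, state = states,
    burst_id = NA_integer_, burst_length = NA_integer_, iei_s = NA_real_,
    provenance = "truth"))
  # all events in the first minute of sleep
  s1 <- peDepthSummary(mk(c(610, 630, 650), rep("earlysleep", 3)), lab)
  ba <- s1$before_after
  expect_equal(ba$after_5min[ba$context == "sleep"], 0)
  expect_equal(ba$before_5min[ba$context == "sleep"], 3)
  # uniform events over the 10-min bout: before/after within 1 of equal
  times <- seq(601, 1199, length.out = 20)
  s2 <- peDepthSummary(mk(times, rep("midsleep", 20)), lab)
  ba2 <- s2$before_after
  expect_lte(abs(ba2$before_5min[ba2$context == "sleep"] -
                   ba2$after_5min[ba2$context == "sleep"]), 1)
  # events concentrated in midsleep dominate the normalized bins
  s3 <- peDepthSummary(mk(c(850, 900, 950, 1000), rep("midsleep", 4)), lab)
  br <- s3$bin_rates
  expect_equal(br$bin[which.max(br$normalized)], "mid")
})

test_that("periodic fraction splits by behavioral state", {
  lab <- boutsToLabels(data.frame(start_s = 60, end_s = 460), 600)
  seg <- data.frame(start_s = c(0, 100, 200, 500), end_s = c(30, 130, 230, 530),
                    organ = "antenna_L", periodic = c(FALSE, TRUE, TRUE, FALSE),
                    dominant_freq_hz = c(NA, 1, 1, NA))
  pf <- periodicFractionByState(seg, lab)
  expect_equal(pf$periodic_fraction[pf$state == "sleep"], 1)
  expect_equal(pf$periodic_fraction[pf$state == "awake"], 0)
})
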