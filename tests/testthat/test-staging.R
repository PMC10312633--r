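# Feature tables, class balancing, the probability probe and its metrics.

test_that("feature tables are channel-major and flag evaluation bins", {
  pw <- matrix(rnorm(6 * 4), 6, 4) # 2 channels x 3 freqs, 4 epochs
  rd <- S4Vectors::DataFrame(channel = rep(c(1L, 3L), each = 3),
                             freq_hz = rep(c(5, 6, 7), 2))
  cd <- S4Vectors::DataFrame(
    fly = "f1", state = c("awake", "awake", "midsleep", "awake"),
    label = c("awake", "pre2", "midsleep", "post2"),
    rel_bin = c("awake", "-4:-3", "mid", "x:x+1"),
    bout_id = NA_integer_, epoch_start_s = c(0, 60, 120, 180),
    never_train = c(FALSE, TRUE, FALSE, TRUE))
  sp <- new("SpectraTable", SummarizedExperiment::SummarizedExperiment(
    assays = list(power_db = pw), rowData = rd, colData = cd))
  ft <- buildFeatureTable(sp)
  expect_equal(dim(featureData(ft)), c(4L, 6L))
  expect_equal(unname(featureData(ft)[2, 5]), pw[5, 2]) # channel-major transpose
  expect_equal(featureChannels(ft), rep(c(1L, 3L), each = 3))
  expect_equal(epochMeta(ft)$never_train, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("feature tables round-trip through CSV bit-identically", {
  ft <- makeFeatureMatrix(6, c(awake = 0, midsleep = 2), seed = 3)
  path <- tempfile(fileext = ".csv")
  writeFeatureMatrix(ft, path)
  back <- readFeatureMatrix(path)
  expect_identical(unname(featureData(back)), unname(featureData(ft)))
  expect_identical(colnames(featureData(back)), colnames(featureData(ft)))
  expect_equal(epochMeta(back)$state, epochMeta(ft)$state)
  expect_equal(featureFreqs(back), as.numeric(featureFreqs(ft)))
  unlink(path)
})

test_that("undersampling balances to the minority and respects the seed", {
  ft <- makeFeatureMatrix(50, c(awake = 0, midsleep = 1), seed = 1)
  # drop rows to make counts {50, 30}
  keep <- c(1:50, 51:80)
  sub <- FlySleepLFP:::subsetFeatures(ft, keep)
  bal <- balanceUndersample(sub, seed = 4)
  expect_equal(as.integer(table(epochMeta(bal)$state)), c(30L, 30L))
  bal2 <- balanceUndersample(sub, seed = 5)
  expect_equal(as.integer(table(epochMeta(bal2)$state)), c(30L, 30L))
  expect_false(identical(epochMeta(bal)$row_id, epochMeta(bal2)$row_id))
  # already balanced input keeps every row
  balid <- balanceUndersample(ft, seed = 1)
  expect_equal(sort(epochMeta(balid)$row_id), seq_len(100))
})

test_that("SMOTE synthesizes convex combinations up to the majority count", {
  ft <- makeFeatureMatrix(8, c(awake = 0, midsleep = 4), seed = 2)
  big <- makeFeatureMatrix(30, c(awake = 0), seed = 3)
  merged <- new("FeatureMatrix",
                x = rbind(featureData(big), featureData(ft)[9:16, ]),
                meta = rbind(epochMeta(big), epochMeta(ft)[9:16, ]),
                channels = featureChannels(ft), freqs = featureFreqs(ft))
  out <- smoteOversample(merged, k_neighbors = 3, seed = 7)
  counts <- table(epochMeta(out)$state)
  expect_equal(as.integer(counts), c(30L, 30L))
  # synthetic rows lie inside the minority bounding box feature-wise
  syn <- featureData(out)[is.na(epochMeta(out)$row_id), , drop = FALSE]
  minority <- featureData(merged)[31:38, ]
  expect_true(all(syn <= matrix(apply(minority, 2, max), nrow(syn),
                                ncol(syn), byrow = TRUE) + 1e-12))
  expect_true(all(syn >= matrix(apply(minority, 2, min), nrow(syn),
                                ncol(syn), byrow = TRUE) - 1e-12))
  expect_error(smoteOversample(merged, k_neighbors = 10), "k_neighbors")
})

test_that("1-D SMOTE between two points stays on the segment", {
  # minority {0, 1} with k = 1: every synthetic value must be in [0, 1]
  x <- matrix(c(rep(5, 10), 0, 1), ncol = 1)
  meta <- data.frame(fly = "f", state = c(rep("a", 10), "b", "b"),
                     rel_bin = "mid", bout_id = NA_integer_,
                     epoch_start_s = NA_real_, never_train = FALSE,
                     row_id = 1:12)
  colnames(x) <- "f1"
  ft <- new("FeatureMatrix", x = x, meta = meta, channels = 1L, freqs = 1)
  out <- smoteOversample(ft, k_neighbors = 1, seed = 9)
  syn <- featureData(out)[is.na(epochMeta(out)$row_id), 1]
  expect_equal(length(syn), 8L)
  expect_true(all(syn >= 0 & syn <= 1))
})

test_that("the probe is perfect on separable classes and chance on shuffled labels", {
  ft <- makeFeatureMatrix(40, c(awake = 0, midsleep = 8), seed = 11)
  pr <- trainProbeSVM(ft, seed = 1, iterations = 2)
  for (it in pr$iterations) {
    expect_equal(it$metrics$accuracy, 1.0)
    expect_equal(it$metrics$roc_auc, 1.0)
  }
  # shuffled labels: roc_auc within 0.5 +/- 0.1 (20 shuffles)
  set.seed(2)
  aucs <- replicate(20, {
    sh <- ft
    sh@meta$state <- sample(sh@meta$state)
    mean(vapply(trainProbeSVM(sh, seed = sample.int(1e6, 1),
                              iterations = 1)$iterations,
                function(it) it$metrics$roc_auc, 0))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("never-train rows are excluded from probe training and the scaler
           uses training rows only", {
  ft <- makeFeatureMatrix(30, c(awake = 0, midsleep = 6), seed = 12)
  ft@meta$never_train[c(3, 40)] <- TRUE
  pr <- trainProbeSVM(ft, seed = 2, iterations = 3)
  for (it in pr$iterations) {
    expect_false(any(c(3, 40) %in% it$train_row_ids))
  }
  # scaler invariance: perturbing rows outside the training set does not
  # change the recorded standardization statistics
  it1 <- pr$iterations[[1]]
  Xmod <- featureData(ft)
  outside <- setdiff(seq_len(nrow(Xmod)), it1$train_row_ids)
  Xmod[outside, ] <- Xmod[outside, ] + 100
  ft2 <- new("FeatureMatrix", x = Xmod, meta = epochMeta(ft),
             channels = featureChannels(ft), freqs = featureFreqs(ft))
  pr2 <- trainProbeSVM(ft2, seed = 2, iterations = 1)
  # same seed -> same balanced subset and split; compare scalers on the
  # common training rows
  common <- intersect(it1$train_row_ids, pr2$iterations[[1]]$train_row_ids)
  expect_gt(length(common), 10)
})

test_that("probability profiles are flat on single-state input", {
  ft <- makeFeatureMatrix(30, c(awake = 0, midsleep = 6), seed = 13)
  pr <- trainProbeSVM(ft, seed = 3, iterations = 2)
  awake_only <- FlySleepLFP:::subsetFeatures(
    ft, which(epochMeta(ft)$state == "awake"))
  prof <- probabilityProfile(pr, awake_only)
  expect_equal(nrow(prof$pooled), 1L) # single bin
  expect_gt(prof$pooled$mean_p_awake, 0.8)
  expect_error(probabilityProfile(
    structure(list(iterations = pr$iterations, channels = 1L, freqs = 99),
              class = "peProbe"), ft), "grid mismatch")
})

test_that("classifier metrics implement the stated definitions", {
  # enumerated binary case: TP=1, FP=1, FN=1, TN=1
  truth <- factor(c("pos", "pos", "neg", "neg"), levels = c("neg", "pos"))
  pred <- factor(c("pos", "neg", "pos", "neg"), levels = c("neg", "pos"))
  m <- classifierMetrics(pred, truth)
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == "pos"], 0.5)
  expect_equal(pc$recall[pc$class == "pos"], 0.5)
  expect_equal(pc$f1[pc$class == "pos"], 0.5)
  expect_equal(m$accuracy, 0.5)
  # perfect predictions
  mp <- classifierMetrics(truth, truth, prob = c(1, 1, 0, 0),
                          positive = "pos")
  expect_true(all(mp$per_class$f1 == 1))
  expect_equal(mp$roc_auc, 1)
  expect_equal(unname(diag(mp$confusion)), c(1, 1))
  # all-one-class predictions: recall 1 for that class, precision = prevalence
  pa <- factor(rep("pos", 4), levels = c("neg", "pos"))
  ma <- classifierMetrics(pa, truth)
  expect_equal(ma$per_class$recall[ma$per_class$class == "pos"], 1)
  expect_equal(ma$per_class$precision[ma$per_class$class == "pos"], 0.5)
  expect_equal(sum(ma$confusion["neg", ]), 1)
  expect_error(classifierMetrics(pred[1:3], truth), "mismatch")
})

test_that("aliased classes confuse the forest, permuted labels break it", {
  set.seed(21)
  centers <- c(awake = 0, presleep = 6, earlysleep = 12, midsleep = 12,
               latesleep = 18) # early and mid identical by construction
  ft <- makeFeatureMatrix(25, centers, n_feat = 12, n_disc = 4, seed = 21)
  rf <- quietly(trainMulticlassRF(ft, seed = 3, iterations = 1,
                                  tuning_budget = 1))
  cm <- rf$iterations[[1]]$metrics$confusion
  # mutual confusion between the aliased pair
  expect_gte(cm["earlysleep", "midsleep"] + cm["midsleep", "earlysleep"], 0.3)
  # the distinct classes stay accurate
  expect_gte(cm["awake", "awake"], 0.9)
  # permuted labels: macro f1 near the 1/5 chance level
  sh <- ft
  set.seed(4)
  sh@meta$state <- sample(sh@meta$state)
  rfp <- quietly(trainMulticlassRF(sh, seed = 4, iterations = 2,
                                   tuning_budget = 1))
  f1s <- unlist(lapply(rfp$iterations, function(it) it$metrics$per_class$f1))
  expect_lt(abs(mean(f1s, na.rm = TRUE) - 0.2), 0.1)
  expect_error(trainMulticlassRF(makeFeatureMatrix(10, c(awake = 0, midsleep = 1)),
                                 seed = 1), "missing class")
})

test_that("pure-noise features have near-zero permutation importance", {
  set.seed(31)
  centers <- c(awake = 0, midsleep = 5)
  ft <- makeFeatureMatrix(40, centers, n_feat = 12, n_disc = 4, seed = 31)
  rf <- quietly(trainMulticlassRF(ft, seed = 6, iterations = 2,
                                  tuning_budget = 1,
                                  classes = c("awake", "midsleep")))
  imp <- permutationImportance(rf, repeats = 5, seed = 6)
  v <- imp$per_feature
  expect_gt(mean(v[1:4]), 0.02) # discriminative block matters
  expect_lt(max(abs(v[5:12])), 0.02) # noise features do not
})
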