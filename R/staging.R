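# Classifier-based sleep staging: the awake-vs-midsleep probability probe,
# the five-class random forest with SMOTE balancing and permutation feature
# importance, and class balancing utilities. Evaluation-only relative-time
# bins (pre2/post2) carry a never-train flag that is audited on every fit.

#' Flatten a SpectraTable into a classifier feature matrix
#'
#' One row per epoch; features are the (channel, frequency) powers in
#' channel-major order (15 x 145 = 2175 under default spectral settings).
#' Epochs from evaluation-only bins keep their rows but are flagged
#' never-train.
#'
#' @param spectra [SpectraTable-class] with state labels and relative-time
#'   tags in its colData.
#' @return [FeatureMatrix-class].
#' @export
buildFeatureTable <- function(spectra) {
  cd <- SummarizedExperiment::colData(spectra)
  rd <- SummarizedExperiment::rowData(spectra)
  x <- t(SummarizedExperiment::assay(spectra, "power_db"))
  colnames(x) <- paste0("ch", rd$channel, "_", signif(rd$freq_hz, 5), "hz")
  meta <- data.frame(
    fly = cd$fly, state = cd$state, rel_bin = cd$rel_bin,
    bout_id = cd$bout_id, epoch_start_s = cd$epoch_start_s,
    never_train = cd$never_train, row_id = seq_len(nrow(x)))
  new("FeatureMatrix", x = x, meta = meta,
      channels = as.integer(rd$channel), freqs = rd$freq_hz)
}

subsetFeatures <- function(ft, sel) {
  meta <- epochMeta(ft)[sel, , drop = FALSE]
  rownames(meta) <- NULL
  new("FeatureMatrix", x = featureData(ft)[sel, , drop = FALSE], meta = meta,
      channels = featureChannels(ft), freqs = featureFreqs(ft))
}

#' Random undersampling to the minority class
#'
#' @param ft [FeatureMatrix-class].
#' @param classes states to balance (default all present).
#' @param seed RNG seed.
#' @return balanced [FeatureMatrix-class] (rows in time order).
#' @export
balanceUndersample <- function(ft, classes = NULL, seed = 1) {
  set.seed(seed)
  meta <- epochMeta(ft)
  if (is.null(classes)) classes <- unique(meta$state)
  if (length(classes) < 2L) stop("need at least 2 classes")
  idx <- split(which(meta$state %in% classes), meta$state[meta$state %in% classes])
  if (any(lengths(idx) == 0L)) stop("empty class among: ", paste(classes, collapse = ", "))
  m <- min(lengths(idx))
  keep <- sort(unlist(lapply(idx, function(i) sample(i, m))))
  subsetFeatures(ft, keep)
}

#' SMOTE oversampling to the majority class
#'
#' Minority classes are augmented with synthetic rows placed uniformly at
#' random on the segment between a minority row and one of its `k_neighbors`
#' nearest minority neighbors (Euclidean distance in feature space), until
#' every class matches the majority count.
#'
#' @param ft [FeatureMatrix-class].
#' @param k_neighbors neighbors considered per minority point (default 5).
#' @param seed RNG seed.
#' @return [FeatureMatrix-class] with synthetic rows appended (row_id NA).
#' @export
smoteOversample <- function(ft, k_neighbors = 5, seed = 1) {
  set.seed(seed)
  meta <- epochMeta(ft)
  x <- featureData(ft)
  counts <- table(meta$state)
  M <- max(counts)
  add_x <- list(); add_meta <- list()
  for (cl in names(counts)) {
    need <- M - counts[[cl]]
    if (need == 0L) next
    rows <- which(meta$state == cl)
    if (length(rows) <= k_neighbors) {
      stop(sprintf("class '%s' has %d members; SMOTE needs more than k_neighbors = %d",
                   cl, length(rows), k_neighbors))
    }
    xc <- x[rows, , drop = FALSE]
    dd <- as.matrix(stats::dist(xc))
    diag(dd) <- Inf
    nn <- matrix(apply(dd, 1L, function(r) order(r)[seq_len(k_neighbors)]),
                 nrow = k_neighbors)
    pick_i <- sample(length(rows), need, replace = TRUE)
    pick_j <- vapply(pick_i, function(i) nn[sample(k_neighbors, 1L), i], 0L)
    lam <- stats::runif(need)
    syn <- xc[pick_i, , drop = FALSE] +
      lam * (xc[pick_j, , drop = FALSE] - xc[pick_i, , drop = FALSE])
    add_x[[cl]] <- syn
    add_meta[[cl]] <- data.frame(
      fly = meta$fly[rows][pick_i], state = cl, rel_bin = "synthetic",
      bout_id = NA_integer_, epoch_start_s = NA_real_, never_train = FALSE,
      row_id = NA_integer_)
  }
  if (!length(add_x)) return(ft)
  new("FeatureMatrix",
      x = rbind(x, do.call(rbind, add_x)),
      meta = rbind(meta, do.call(rbind, add_meta)),
      channels = featureChannels(ft), freqs = featureFreqs(ft))
}

# stratified train/test split of indices; returns list(train, test)
stratifiedSplit <- function(states, test_fraction) {
  test <- sort(unlist(lapply(split(seq_along(states), states), function(i)
    sample(i, max(1L, round(length(i) * test_fraction))))))
  list(train = setdiff(seq_along(states), test), test = test)
}

# z-score scaler fit on training rows only
fitScaler <- function(X) {
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1
  list(center = ctr, sd = sds)
}
applyScaler <- function(X, sc) scale(X, center = sc$center, scale = sc$sd)

# audit: no never-train row id may appear in a training index set
assertNoEvalRows <- function(meta, train_idx) {
  if (any(meta$never_train[train_idx])) {
    stop("internal audit failure: evaluation-only rows in a training split")
  }
}

#' Train the awake-vs-midsleep probability probe
#'
#' Per iteration: undersample to balance awake and midsleep, stratified
#' 80/20 split, z-score scaling fit on the training rows only, linear-kernel
#' support-vector classifier with calibrated (sigmoid-fit) class
#' probabilities, and held-out metrics. Repeated for `iterations`
#' independent splits. Epochs flagged never-train are excluded from every
#' training set (audited).
#'
#' @param ft [FeatureMatrix-class].
#' @param seed RNG seed.
#' @param iterations split repetitions (default 5).
#' @param test_fraction held-out fraction (default 0.2).
#' @return object of class `peProbe`: per-iteration models, scalers and
#'   [classifierMetrics()] reports.
#' @export
trainProbeSVM <- function(ft, seed = 1, iterations = 5, test_fraction = 0.2) {
  meta <- epochMeta(ft)
  usable <- which(meta$state %in% c("awake", "midsleep") & !meta$never_train)
  if (!all(c("awake", "midsleep") %in% meta$state[usable])) {
    stop("need both awake and midsleep epochs")
  }
  base <- subsetFeatures(ft, usable)
  iters <- lapply(seq_len(iterations), function(i) {
    bal <- balanceUndersample(base, c("awake", "midsleep"), seed = seed + i)
    m <- epochMeta(bal)
    X <- featureData(bal)
    set.seed(seed * 1000L + i)
    sp <- stratifiedSplit(m$state, test_fraction)
    assertNoEvalRows(m, sp$train)
    sc <- fitScaler(X[sp$train, , drop = FALSE])
    y <- factor(m$state, levels = c("awake", "midsleep"))
    fit <- e1071::svm(applyScaler(X[sp$train, , drop = FALSE], sc),
                      y[sp$train], kernel = "linear", probability = TRUE, scale = FALSE)
    pp <- stats::predict(fit, applyScaler(X[sp$test, , drop = FALSE], sc),
                         probability = TRUE)
    pr_awake <- attr(pp, "probabilities")[, "awake"]
    rep <- classifierMetrics(pp, y[sp$test], prob = pr_awake,
                             positive = "awake")
    list(model = fit, scaler = sc, metrics = rep,
         train_row_ids = m$row_id[sp$train])
  })
  structure(list(iterations = iters,
                 channels = featureChannels(ft), freqs = featureFreqs(ft)),
            class = "peProbe")
}

#' Awake-probability profile across relative-time bins
#'
#' Applies the probe to every epoch (including the never-trained bins) and
#' summarizes the awake-class probability per relative-time bin, per
#' iteration and pooled.
#'
#' @param probe `peProbe` from [trainProbeSVM()].
#' @param ft [FeatureMatrix-class] to profile.
#' @return list(per_epoch, per_iteration, pooled); `pooled` has the mean,
#'   sd and n of the awake probability per bin.
#' @export
probabilityProfile <- function(probe, ft) {
  if (!identical(probe$freqs, featureFreqs(ft))) {
    stop("feature grid mismatch between probe and feature table")
  }
  X <- featureData(ft)
  meta <- epochMeta(ft)
  probs <- vapply(probe$iterations, function(it) {
    pp <- stats::predict(it$model, applyScaler(X, it$scaler),
                         probability = TRUE)
    attr(pp, "probabilities")[, "awake"]
  }, numeric(nrow(X)))
  per_epoch <- data.frame(meta, p_awake = rowMeans(probs))
  per_iter <- do.call(rbind, lapply(seq_len(ncol(probs)), function(i) {
    agg <- tapply(probs[, i], meta$rel_bin, mean)
    data.frame(iteration = i, rel_bin = names(agg),
               mean_p_awake = as.numeric(agg), row.names = NULL)
  }))
  pooled <- do.call(rbind, lapply(split(seq_len(nrow(meta)), meta$rel_bin),
                                  function(idx) {
    v <- as.vector(probs[idx, , drop = FALSE])
    data.frame(rel_bin = meta$rel_bin[idx[1]], mean_p_awake = mean(v),
               sd_p_awake = stats::sd(v), n_epochs = length(idx))
  }))
  rownames(pooled) <- NULL
  list(per_epoch = per_epoch, per_iteration = per_iter, pooled = pooled)
}

#' Train the five-class staging random forest
#'
#' Per iteration: SMOTE balancing, stratified 80/20 split, z-score scaling
#' fit on training rows, and a random forest tuned by a seeded two-stage
#' hyperparameter search (randomized screen by out-of-bag error, then a
#' local grid around the best configuration) within `tuning_budget` total
#' fits. Reports per-class precision/recall/f1 and the row-normalized
#' confusion matrix on the held-out split.
#'
#' @param ft [FeatureMatrix-class] with all five states present.
#' @param seed RNG seed.
#' @param iterations split repetitions (default 5).
#' @param tuning_budget maximum model fits during the search (default 6).
#' @param classes states to include (default the five-stage scheme).
#' @return object of class `stageRF`: per-iteration models, scalers,
#'   held-out rows and reports.
#' @export
trainMulticlassRF <- function(ft, seed = 1, iterations = 5, tuning_budget = 6,
                              classes = c("awake", "presleep", "earlysleep",
                                          "midsleep", "latesleep")) {
  meta <- epochMeta(ft)
  usable <- which(meta$state %in% classes & !meta$never_train)
  missing <- setdiff(classes, meta$state[usable])
  if (length(missing)) stop("missing class(es): ", paste(missing, collapse = ", "))
  base <- subsetFeatures(ft, usable)
  space <- list(ntree = seq(200L, 800L, by = 100L), nodesize = 1:4)
  iters <- lapply(seq_len(iterations), function(i) {
    set.seed(seed * 100L + i)
    bal <- smoteOversample(base, seed = seed * 100L + i)
    m <- epochMeta(bal)
    X <- featureData(bal)
    sp <- stratifiedSplit(m$state, 0.2)
    assertNoEvalRows(m, sp$train)
    sc <- fitScaler(X[sp$train, , drop = FALSE])
    Ztr <- applyScaler(X[sp$train, , drop = FALSE], sc)
    Zte <- applyScaler(X[sp$test, , drop = FALSE], sc)
    y <- factor(m$state, levels = classes)
    oob <- function(cfg) {
      f <- randomForest::randomForest(Ztr, y[sp$train], ntree = cfg$ntree,
                                      nodesize = cfg$nodesize)
      list(fit = f, err = f$err.rate[cfg$ntree, "OOB"])
    }
    n_screen <- max(1L, tuning_budget - 2L)
    cfgs <- unique(data.frame(
      ntree = sample(space$ntree, n_screen, replace = TRUE),
      nodesize = sample(space$nodesize, n_screen, replace = TRUE)))
    screened <- lapply(seq_len(nrow(cfgs)), function(k) oob(cfgs[k, ]))
    best_k <- which.min(vapply(screened, `[[`, 0, "err"))
    best_cfg <- cfgs[best_k, ]; best <- screened[[best_k]]
    # local grid around the screen winner, within the remaining budget
    local <- data.frame(
      ntree = pmin(pmax(best_cfg$ntree + c(-100L, 100L), 200L), 800L),
      nodesize = pmin(pmax(best_cfg$nodesize + c(1L, -1L), 1L), 4L))
    local <- unique(local[!duplicated(rbind(best_cfg, local))[-1L], , drop = FALSE])
    n_local <- min(nrow(local), max(0L, tuning_budget - nrow(cfgs)))
    for (k in seq_len(n_local)) {
      cand <- oob(local[k, ])
      if (cand$err < best$err) { best <- cand; best_cfg <- local[k, ] }
    }
    pred <- stats::predict(best$fit, Zte)
    rep <- classifierMetrics(pred, y[sp$test])
    list(model = best$fit, scaler = sc, config = best_cfg, metrics = rep,
         test_x = Zte, test_y = y[sp$test],
         train_row_ids = m$row_id[sp$train])
  })
  structure(list(iterations = iters, classes = classes,
                 channels = featureChannels(ft), freqs = featureFreqs(ft)),
            class = "stageRF")
}

#' Permutation feature importance on the channel x frequency grid
#'
#' Per feature: the mean drop in the model score on the held-out rows over
#' `repeats` independent within-column shuffles, computed per split
#' iteration and averaged across iterations; reshaped to the channels x
#' frequencies grid. The default score is the mean probability the model
#' assigns to the true class — a continuous criterion that ranks features
#' reliably on held-out sets far smaller than an accuracy-based score can
#' resolve; `score = "accuracy"` uses the raw accuracy drop instead.
#'
#' @param fit `stageRF` (or any object with iterations carrying model,
#'   test_x, test_y).
#' @param repeats shuffles per feature (default 5).
#' @param seed RNG seed.
#' @param score "true_class_prob" (default) or "accuracy".
#' @param iterations which split iterations to use (default all).
#' @return list(importance = channels x freqs matrix, per_feature, channels,
#'   freqs).
#' @export
permutationImportance <- function(fit, repeats = 5, seed = 1,
                                  score = c("true_class_prob", "accuracy"),
                                  iterations = seq_along(fit$iterations)) {
  score <- match.arg(score)
  set.seed(seed)
  nf <- length(unique(fit$freqs))
  scoreOf <- function(model, X, y) {
    if (score == "accuracy") {
      mean(stats::predict(model, X) == y)
    } else {
      pr <- stats::predict(model, X, type = "prob")
      mean(pr[cbind(seq_along(y), match(as.character(y), colnames(pr)))])
    }
  }
  per_iter <- lapply(fit$iterations[iterations], function(it) {
    X <- it$test_x; y <- it$test_y
    n <- nrow(X)
    if (n < 2L) stop("held-out set too small for importance")
    base <- scoreOf(it$model, X, y)
    drops <- numeric(ncol(X))
    # batch the shuffled copies of each feature into one prediction call
    Xrep <- X[rep(seq_len(n), repeats), , drop = FALSE]
    yrep <- y[rep(seq_len(n), repeats)]
    blk <- rep(seq_len(repeats), each = n)
    for (j in seq_len(ncol(X))) {
      shuf <- as.vector(vapply(seq_len(repeats),
                               function(r) X[sample(n), j], numeric(n)))
      orig <- Xrep[, j]
      Xrep[, j] <- shuf
      if (score == "accuracy") {
        ok <- stats::predict(it$model, Xrep) == yrep
        drops[j] <- base - mean(tapply(ok, blk, mean))
      } else {
        pr <- stats::predict(it$model, Xrep, type = "prob")
        v <- pr[cbind(seq_along(yrep), match(as.character(yrep), colnames(pr)))]
        drops[j] <- base - mean(tapply(v, blk, mean))
      }
      Xrep[, j] <- orig
    }
    drops
  })
  per_feature <- Reduce(`+`, per_iter) / length(per_iter)
  chs <- unique(fit$channels)
  imp <- matrix(per_feature, nrow = length(chs), ncol = nf, byrow = TRUE,
                dimnames = list(channel = chs, freq_hz = signif(unique(fit$freqs), 5)))
  list(importance = imp, per_feature = per_feature,
       channels = fit$channels, freqs = fit$freqs)
}
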