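# Shared fixtures, all generated in code.

# internal helpers exercised directly by tests
boutsToLabels <- FlySleepLFP:::boutsToLabels
welchPSD <- FlySleepLFP::welchPSD

# small separable feature table for classifier unit tests: `centers` gives a
# per-class mean offset applied to the first `n_disc` features
makeFeatureMatrix <- function(n_per_class, centers, n_feat = 30L, n_disc = 5L,
                              sd = 1, seed = 1, rel_bin = "mid") {
  set.seed(seed)
  classes <- names(centers)
  x <- NULL; meta <- NULL
  for (cl in classes) {
    m <- matrix(rnorm(n_per_class * n_feat, 0, sd), n_per_class, n_feat)
    m[, seq_len(n_disc)] <- m[, seq_len(n_disc)] + centers[[cl]]
    x <- rbind(x, m)
    meta <- rbind(meta, data.frame(
      fly = "f1", state = rep(cl, n_per_class), rel_bin = rel_bin,
      bout_id = NA_integer_, epoch_start_s = NA_real_, never_train = FALSE,
      row_id = NA_integer_))
  }
  meta$row_id <- seq_len(nrow(meta))
  colnames(x) <- paste0("f", seq_len(n_feat))
  new("FeatureMatrix", x = x, meta = meta,
      channels = rep(1:3, each = n_feat / 3),
      freqs = rep(seq_len(n_feat / 3), 3))
}

# movement flags from run-length (seconds, value) pairs at a given fps
flagsFromRuns <- function(runs, fps = 30) {
  moved <- unlist(lapply(seq_len(nrow(runs)), function(i)
    rep(runs$moved[i], round(runs$dur_s[i] * fps))))
  movementFlags(moved, fps = fps)
}

# difference map with an optional effect box (thin wrapper with fixed grid)
nullDiffMap <- function(n_flies = 16, seed = 1, nch = 15, nfreq = 40) {
  simulateDifferenceMap(n_flies = n_flies, channels = seq_len(nch),
                        freqs = as.numeric(seq_len(nfreq)), seed = seed)
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

emptyEvents <- FlySleepLFP:::emptyEventTable
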