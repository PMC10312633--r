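# Group-level inference on channel x frequency difference maps: one-sample
# cluster-based permutation test with exhaustive sign flips, Cohen's d effect
# maps, and within-cluster post-hoc direction summaries.

#' Per-fly condition difference maps from a SpectraTable
#'
#' Per fly: mean spectrum per condition, then condition A minus condition B.
#' Flies with fewer than `min_trials` epochs in either condition are excluded
#' (and reported via the `excluded` attribute).
#'
#' @param spectra [SpectraTable-class] holding epochs from several flies.
#' @param cond_a,cond_b state labels to contrast (e.g. "awake", "midsleep").
#' @param min_trials per-condition trial gate (10 for the 60-s sleep/wake
#'   analysis, 50 for the 1-s PE analysis).
#' @return [DifferenceMap-class].
#' @export
buildDifferenceMap <- function(spectra, cond_a, cond_b, min_trials = 10) {
  cd <- SummarizedExperiment::colData(spectra)
  rd <- SummarizedExperiment::rowData(spectra)
  pw <- SummarizedExperiment::assay(spectra, "power_db")
  flies <- unique(cd$fly)
  keep <- list()
  excluded <- character()
  counts <- list()
  for (fl in flies) {
    na <- sum(cd$fly == fl & cd$state == cond_a)
    nb <- sum(cd$fly == fl & cd$state == cond_b)
    if (na < min_trials || nb < min_trials) {
      excluded <- c(excluded, fl)
      message(sprintf("fly %s excluded: %d/%d trials vs gate %d",
                      fl, na, nb, min_trials))
      next
    }
    ma <- rowMeans(pw[, cd$fly == fl & cd$state == cond_a, drop = FALSE])
    mb <- rowMeans(pw[, cd$fly == fl & cd$state == cond_b, drop = FALSE])
    keep[[fl]] <- ma - mb
    counts[[fl]] <- c(na, nb)
  }
  if (length(keep) < 2L) stop("fewer than 2 flies survive the trial gate")
  channels <- unique(rd$channel)
  freqs <- unique(rd$freq_hz)
  d <- array(NA_real_, dim = c(length(keep), length(channels), length(freqs)))
  for (i in seq_along(keep)) {
    d[i, , ] <- matrix(keep[[i]], length(channels), length(freqs), byrow = TRUE)
  }
  tc <- do.call(rbind, counts)
  colnames(tc) <- c(cond_a, cond_b)
  out <- new("DifferenceMap", diff = d, conditions = c(cond_a, cond_b),
             channels = as.integer(channels), freqs = freqs,
             trial_counts = tc)
  attr(out, "excluded") <- excluded
  out
}

# channel-pair adjacency: channels adjacent iff their original electrode
# indices are consecutive (a dropped reversal channel does not bridge)
channelAdjacency <- function(channels) {
  diff(channels) == 1L
}

#' One-sample cluster-based permutation test
#'
#' Cell-wise one-sample t statistics across flies are thresholded at the
#' two-tailed t quantile (`cluster_forming_alpha`, df = n-1); supra-threshold
#' cells of equal sign are grouped into connected clusters (4-connectivity:
#' consecutive frequency bins, and channels with consecutive original
#' electrode indices). Cluster mass is the sum of t inside the cluster. The
#' null distribution of the maximum |cluster mass| is built from all 2^n
#' sign-flip permutations when n <= `exhaustive_max` flies, otherwise from
#' `n_perm` seeded random sign patterns; cluster p = proportion of
#' permutations whose max mass reaches the observed mass. Positive and
#' negative clusters are reported with their signs.
#'
#' @param diff [DifferenceMap-class].
#' @param cluster_forming_alpha two-tailed alpha of the cell threshold.
#' @param exhaustive_max largest n for exhaustive enumeration (default 20).
#' @param n_perm random sign patterns when not exhaustive (default 2^16).
#' @return [ClusterResult-class]; clusters sorted by increasing p.
#' @export
clusterPermutationTest <- function(diff, cluster_forming_alpha = 0.05,
                                   exhaustive_max = 20, n_perm = 65536L) {
  d <- differenceArray(diff)
  n <- dim(d)[1]
  if (n < 2L) stop("need at least 2 flies")
  nch <- dim(d)[2]; nfr <- dim(d)[3]
  thr <- stats::qt(1 - cluster_forming_alpha / 2, df = n - 1)
  # flies x cells, frequency fastest (channel-major cell order)
  xm <- matrix(aperm(d, c(3, 2, 1)), nrow = nch * nfr, ncol = n)
  m <- rowMeans(xm)
  s <- apply(xm, 1L, stats::sd)
  degen <- s == 0
  if (any(degen & m != 0)) {
    warning(sum(degen & m != 0), " zero-variance cell(s); t set to 0")
  }
  tvec <- ifelse(degen, 0, m / (s / sqrt(n)))
  row_adj <- channelAdjacency(featureChannels(diff))
  lab <- cluster_label_cpp(tvec, nch, nfr, row_adj, thr)
  exhaustive <- n <= exhaustive_max
  null_max <- cluster_perm_null_cpp(xm, nch, nfr, row_adj, thr,
                                    exhaustive, as.integer(n_perm))
  np <- length(null_max)
  masks <- list(); mass <- numeric(); pval <- numeric()
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      sel <- lab == k
      masks[[k]] <- matrix(sel, nch, nfr, byrow = TRUE)
      mass[k] <- sum(tvec[sel])
      b <- sum(null_max >= abs(mass[k]) - 1e-12)
      # exhaustive nulls include the identity flip, keeping p > 0; random
      # subsets add the observed arrangement explicitly
      pval[k] <- if (exhaustive) b / np else (b + 1) / (np + 1)
    }
    o <- order(pval, -abs(mass))
    masks <- masks[o]; mass <- mass[o]; pval <- pval[o]
  }
  new("ClusterResult",
      tmap = matrix(tvec, nch, nfr, byrow = TRUE),
      clusters = masks, mass = mass, p = pval,
      n_perm = np, exhaustive = exhaustive, threshold = thr,
      channels = featureChannels(diff), freqs = featureFreqs(diff))
}

#' Cohen's d effect-size map
#'
#' One-sample d per cell: mean of the per-fly differences divided by their
#' standard deviation. Zero-variance cells give d = 0 when the mean is also
#' zero; otherwise the value is capped at +/-`cap` with a warning.
#'
#' @param diff [DifferenceMap-class].
#' @param cap magnitude cap for degenerate cells (default 100).
#' @return channels x freqs matrix of d values with dimnames.
#' @export
effectSizeMap <- function(diff, cap = 100) {
  d <- differenceArray(diff)
  if (dim(d)[1] < 2L) stop("need at least 2 flies")
  m <- apply(d, c(2, 3), mean)
  s <- apply(d, c(2, 3), stats::sd)
  out <- m / s
  zero <- s == 0
  out[zero & m == 0] <- 0
  if (any(zero & m != 0)) {
    warning("zero-SD cells with nonzero mean; capped at +/-", cap)
    out[zero & m != 0] <- sign(m[zero & m != 0]) * cap
  }
  dimnames(out) <- list(channel = featureChannels(diff),
                        freq_hz = signif(featureFreqs(diff), 5))
  out
}

#' Post-hoc direction summary within a cluster
#'
#' Mean in-cluster difference per fly, its sign, and a one-sample t summary;
#' reports whether condition A exceeds condition B inside the cluster.
#'
#' @param diff [DifferenceMap-class].
#' @param mask logical channels x freqs cluster mask.
#' @param alpha significance level for the direction call (default 0.05).
#' @return list(per_fly, mean, t, df, p, direction) with direction one of
#'   "A > B", "A < B", "indeterminate".
#' @export
withinClusterPosthoc <- function(diff, mask, alpha = 0.05) {
  if (!any(mask)) stop("empty cluster mask")
  d <- differenceArray(diff)
  n <- dim(d)[1]
  per_fly <- vapply(seq_len(n), function(i) mean(d[i, , ][mask]), 0)
  m <- mean(per_fly); s <- stats::sd(per_fly)
  tt <- if (s > 0) m / (s / sqrt(n)) else ifelse(m == 0, 0, Inf * sign(m))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  a <- diff@conditions[1]; b <- diff@conditions[2]
  direction <- if (p < alpha && m > 0) paste(a, ">", b)
  else if (p < alpha && m < 0) paste(a, "<", b)
  else "indeterminate"
  list(per_fly = per_fly, mean = m, t = tt, df = n - 1, p = p,
       direction = direction)
}
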