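## The weighted average Pearson correlation metric, repeated k-fold CV,
## ROC-AUC, bootstrap intervals and model-comparison z-tests.

#' Pearson correlation with a defined value for constant input
#'
#' Sample Pearson correlation; when either vector is constant the
#' correlation is undefined and this returns 0, a zero-information
#' reading that keeps degenerate per-combination folds in the metric
#' instead of dropping them.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
pearsonSafe <- function(x, y) {
  stopIfNot(length(x) == length(y), "vectors differ in length")
  stopIfNot(length(x) >= 2L, "Pearson correlation needs >= 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Weighted average Pearson correlation over drug combinations
#'
#' The challenge's primary metric: per-combination Pearson correlations
#' rho_i between observed and predicted synergy, combined as
#' `sum(sqrt(n_i - 1) * rho_i) / sum(sqrt(n_i - 1))` where n_i is the
#' number of cell lines on which combination i was screened.
#' Combinations with n_i = 1 carry zero weight; if every combination has
#' n_i = 1 the metric is undefined and an error is raised.
#'
#' @param rho numeric vector of per-combination correlations, or a
#'   data.frame with columns `rho` and `n`.
#' @param n integer vector of per-combination cell-line counts.
#' @return the weighted average, a single number in [-1, 1].
#' @export
wapcc <- function(rho, n = NULL) {
  if (is.data.frame(rho)) { n <- rho$n; rho <- rho$rho }
  stopIfNot(length(rho) > 0, "no combinations to average over")
  stopIfNot(length(rho) == length(n), "rho and n differ in length")
  w <- sqrt(n - 1)
  stopIfNot(sum(w) > 0,
            "WAPCC undefined: every combination has a single cell line")
  sum(w * rho) / sum(w)
}

#' Repeated k-fold cross-validation under the WAPCC metric
#'
#' Shuffles experiments into k folds per repetition, trains the model on
#' k-1 folds and predicts the held-out fold, so each experiment is
#' predicted exactly once per repetition.  Per-combination correlations
#' rho_i are computed over each combination's out-of-fold predictions
#' pooled within a repetition; the repetition's WAPCC follows [wapcc()],
#' and the reported metric is the mean over repetitions.  When the
#' feature matrix carries synergy-network features and `refitNetwork` is
#' `TRUE` (the default leakage guard), the three network columns are
#' recomputed per fold from the training experiments only.
#'
#' @param spec a [modelSpec()].
#' @param fm a [SynergyFeatureMatrix-class].
#' @param k number of folds.
#' @param reps number of repetitions.
#' @param seed integer seed; fold shuffles use per-repetition substreams.
#' @param refitNetwork recompute synergy-network features per training
#'   fold (needs `drugA`/`drugB` in `colData`, as produced by
#'   [buildCohortFeatureMatrix()]).
#' @param permuteLabels permute the response once per repetition before
#'   splitting (null-distribution control).
#' @return a [CVResult-class].
#' @export
repeatedKFoldCV <- function(spec, fm, k = 10L, reps = 10L, seed = 1L,
                            refitNetwork = TRUE, permuteLabels = FALSE) {
  n <- ncol(fm)
  stopIfNot(n >= k, "need at least k experiments for k folds")
  X <- featureValues(fm, sparse = spec$kind == "xgboost")
  combos <- colData(fm)$combination
  cells <- colData(fm)$cellLine
  groups <- featureGroups(fm)
  netCols <- names(groups)[groups == "drug synergy network"]
  canRefit <- refitNetwork && length(netCols) &&
    all(c("drugA", "drugB") %in% colnames(colData(fm)))
  threshold <- metadata(fm)$threshold %||% 20
  if (canRefit) {
    baseExps <- data.frame(combination = combos,
                           drugA = colData(fm)$drugA,
                           drugB = colData(fm)$drugB,
                           cellLine = cells, stringsAsFactors = FALSE)
    comboPairs <- unique(baseExps[, c("combination", "drugA", "drugB")])
  }
  predictions <- vector("list", reps)
  repWapcc <- numeric(reps)
  rhoByRep <- vector("list", reps)
  for (r in seq_len(reps)) {
    y <- synergyScores(fm)
    if (permuteLabels)
      y <- withSubstream(seed, paste0("permute", r), sample(y))
    folds <- withSubstream(seed, paste0("rep", r),
                           sample(rep_len(seq_len(k), n)))
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      Xf <- X
      if (canRefit) {
        trainExps <- baseExps[!test, , drop = FALSE]
        trainExps$synergy <- y[!test]
        nf <- pairNetworkFeatures(trainExps,
                                  comboPairs[, c("drugA", "drugB")],
                                  threshold = threshold)
        rownames(nf) <- comboPairs$combination
        repl <- as.matrix(nf[combos, c("commonNeighbors", "jaccard",
                                       "adamicAdar")])
        Xf[, netCols] <- repl
      }
      m <- fitModel(spec, Xf[!test, , drop = FALSE], y[!test])
      pred[test] <- predict(m, Xf[test, , drop = FALSE])
    }
    perCombo <- lapply(split(seq_len(n), combos), function(idx) {
      rho <- if (length(idx) >= 2L) pearsonSafe(y[idx], pred[idx]) else 0
      c(rho = rho, n = length(idx))
    })
    pc <- do.call(rbind, perCombo)
    repWapcc[r] <- wapcc(pc[, "rho"], pc[, "n"])
    rhoByRep[[r]] <- pc[, "rho"]
    predictions[[r]] <- data.frame(combination = combos, cellLine = cells,
                                   observed = y, predicted = pred,
                                   repetition = r,
                                   stringsAsFactors = FALSE)
  }
  rhoMat <- do.call(cbind, rhoByRep)
  counts <- as.integer(table(combos)[rownames(rhoMat)])
  new("CVResult",
      predictions = do.call(rbind, predictions),
      perCombination = data.frame(combination = rownames(rhoMat),
                                  rho = rowMeans(rhoMat), n = counts,
                                  stringsAsFactors = FALSE,
                                  row.names = NULL),
      repetitions = repWapcc, wapcc = mean(repWapcc),
      seed = as.integer(seed))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a random positive scores above a random negative, ties counting
#' one half.
#'
#' @param yTrue 0/1 vector with both classes present.
#' @param scores numeric prediction scores.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(yTrue, scores) {
  stopIfNot(length(yTrue) == length(scores), "length mismatch")
  n1 <- sum(yTrue == 1); n0 <- sum(yTrue == 0)
  stopIfNot(n1 > 0 && n0 > 0,
            "ROC-AUC undefined with a single-class truth vector")
  r <- rank(scores)
  (sum(r[yTrue == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the WAPCC
#'
#' Resamples combinations (the weight-bearing unit of the metric) with
#' replacement and returns the percentile interval of the recomputed
#' WAPCC.  A replicate whose resample has zero total weight (all
#' single-cell-line combinations) is redrawn.
#'
#' @param perCombination data.frame with columns `rho` and `n` (e.g. the
#'   `perCombination` slot of a [CVResult-class]).
#' @param B number of bootstrap replicates.
#' @param alpha interval level (default 0.05 for a 95\% interval).
#' @param seed integer seed.
#' @return numeric vector `c(low, high)`.
#' @export
bootstrapCI <- function(perCombination, B = 1000L, alpha = 0.05,
                        seed = 1L) {
  rho <- perCombination$rho
  n <- perCombination$n
  N <- length(rho)
  set.seed(seed)
  stat <- vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(N, N, replace = TRUE)
      if (sum(sqrt(n[idx] - 1)) > 0) break
    }
    wapcc(rho[idx], n[idx])
  }, numeric(1))
  unname(stats::quantile(stat, c(alpha / 2, 1 - alpha / 2)))
}

#' Two-sample z-test on repetition-level metric summaries
#'
#' Compares two models' mean cross-validation metrics:
#' `z = (m1 - m2) / sqrt(s1^2/k1 + s2^2/k2)`, two-sided normal p-value.
#' With both variances zero, equal means give z = 0 / p = 1 and unequal
#' means give an infinite z / p = 0.
#'
#' @param m1,m2 metric means.
#' @param s1,s2 metric standard deviations (>= 0).
#' @param k1,k2 numbers of repetitions (>= 2).
#' @return list with elements `z` and `p`.
#' @export
twoSampleZTest <- function(m1, s1, k1, m2, s2, k2) {
  stopIfNot(k1 >= 2 && k2 >= 2, "z-test needs >= 2 repetitions per sample")
  stopIfNot(s1 >= 0 && s2 >= 0, "standard deviations must be >= 0")
  se <- sqrt(s1^2 / k1 + s2^2 / k2)
  if (se == 0) {
    if (m1 == m2) return(list(z = 0, p = 1))
    return(list(z = sign(m1 - m2) * Inf, p = 0))
  }
  z <- (m1 - m2) / se
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}
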