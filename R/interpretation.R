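## Gain-based feature importance, group aggregation, and KS
## target-association tests.

#' Gain-based feature importance of a tree model
#'
#' For boosted trees, each feature's summed split-quality improvement
#' ("gain") normalized to fractional contribution (all features sum to
#' 1); features never used in a split get 0.  For random forests the
#' impurity-decrease importance plays the same role.  Non-tree models are
#' an error.
#'
#' @param model a fitted [SynergyModel-class] of kind `"xgboost"` or
#'   `"random_forest"`.
#' @return data.frame with columns `feature`, `group`, `gain`, sorted by
#'   decreasing gain.
#' @export
gainImportance <- function(model) {
  kind <- model@spec$kind
  gains <- stats::setNames(numeric(length(model@featureNames)),
                           model@featureNames)
  if (kind == "xgboost") {
    imp <- xgboost::xgb.importance(model = model@fit,
                                   feature_names = model@featureNames)
    gains[imp$Feature] <- imp$Gain
  } else if (kind == "random_forest") {
    imp <- pmax(model@fit$variable.importance, 0)
    gains[names(imp)] <- imp
  } else {
    stop("gain importance needs a tree model, not kind '", kind, "'",
         call. = FALSE)
  }
  total <- sum(gains)
  if (total > 0) gains <- gains / total
  out <- data.frame(feature = names(gains),
                    group = unname(model@featureGroups[names(gains)]),
                    gain = unname(gains), stringsAsFactors = FALSE)
  out$group[is.na(out$group)] <- "ungrouped"
  out[order(-out$gain), , drop = FALSE]
}

#' Aggregate feature importances to feature groups
#'
#' Sums member features' gains per group (so the group totals preserve
#' the sum of 1 when every feature is grouped), sorted descending.
#'
#' @param importance data.frame from [gainImportance()], or a named
#'   numeric gain vector plus `groups`.
#' @param groups optional named character vector feature -> group
#'   (required when `importance` is a plain vector).
#' @return data.frame with columns `group` and `gain`, sorted descending.
#' @export
groupImportance <- function(importance, groups = NULL) {
  if (!is.data.frame(importance)) {
    g <- groups[names(importance)]
    g[is.na(g)] <- "ungrouped"
    importance <- data.frame(feature = names(importance), group = unname(g),
                             gain = unname(importance),
                             stringsAsFactors = FALSE)
  }
  agg <- stats::aggregate(gain ~ group, importance, sum)
  agg <- agg[order(-agg$gain), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Kolmogorov-Smirnov association between a target feature and synergy
#'
#' Stratifies experiments by whether their drug combination carries the
#' target feature (pair-encoded value > 0: either drug has it) and
#' compares the two strata's synergy-score distributions with the
#' two-sample KS test.  The reported direction is the sign of the median
#' difference (carrier minus non-carrier): positive means the feature
#' favours synergy, negative antagonism.
#'
#' @param synergy numeric vector of experiment synergy scores.
#' @param carrier logical/0-1 vector: does the experiment's combination
#'   carry the target feature.
#' @return list with elements `D`, `p`, `direction` and the stratum
#'   sizes `nCarrier`, `nOther`.
#' @export
ksTargetAssociation <- function(synergy, carrier) {
  stopIfNot(length(synergy) == length(carrier), "length mismatch")
  carrier <- carrier > 0
  stopIfNot(any(carrier) && any(!carrier),
            "both strata (carrier / non-carrier) must be non-empty")
  a <- synergy[carrier]
  b <- synergy[!carrier]
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(ks$statistic), p = ks$p.value,
       direction = sign(stats::median(a) - stats::median(b)),
       nCarrier = length(a), nOther = length(b))
}

#' Write an importance report
#'
#' @param importance data.frame from [gainImportance()].
#' @param path per-feature CSV path (columns FEATURE, GROUP, GAIN); a
#'   group summary is written alongside with suffix `_groups.csv`.
#' @return `path`, invisibly.
#' @export
writeImportance <- function(importance, path) {
  utils::write.csv(data.frame(FEATURE = importance$feature,
                              GROUP = importance$group,
                              GAIN = importance$gain),
                   path, row.names = FALSE)
  g <- groupImportance(importance)
  utils::write.csv(data.frame(GROUP = g$group, GAIN = g$gain),
                   sub("\\.csv$", "_groups.csv", path), row.names = FALSE)
  invisible(path)
}
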