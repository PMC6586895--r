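test_that("Pearson helper matches hand-computed values and conventions", {
  expect_equal(pearsonSafe(1:10, 3 * (1:10) + 1), 1)
  expect_equal(pearsonSafe(c(1, 2, 3), c(6, 4, 5)), -0.5)
  expect_equal(pearsonSafe(1:5, rep(2, 5)), 0)  # constant convention
  expect_error(pearsonSafe(1, 2), ">= 2")
})

test_that("WAPCC closed forms hold", {
  expect_equal(wapcc(0.7, 10), 0.7)                    # weights cancel
  expect_equal(wapcc(c(1, 0), c(5, 2)), 2 / 3)          # hand-worked
  base <- wapcc(c(0.5, 0.2), c(5, 9))
  expect_equal(wapcc(c(0.5, 0.2, -0.9), c(5, 9, 1)), base)  # zero weight
  expect_error(wapcc(c(0.5, 0.2), c(1, 1)), "undefined")
  # plain mean when all n equal; bounded by the rho range
  rho <- c(0.1, 0.5, -0.2)
  expect_equal(wapcc(rho, c(4, 4, 4)), mean(rho))
  set.seed(1)
  for (i in 1:20) {
    rho <- runif(6, -1, 1); n <- sample(2:10, 6, replace = TRUE)
    w <- wapcc(rho, n)
    expect_gte(w, min(rho)); expect_lte(w, max(rho))
    perm <- sample(6)
    expect_equal(wapcc(rho[perm], n[perm]), w)
  }
})

test_that("ROC-AUC equals normalized pair counting with tie handling", {
  expect_equal(rocAuc(c(0, 0, 1, 1), c(1, 2, 10, 20)), 1)
  expect_equal(rocAuc(c(0, 0, 1, 1), rep(1, 4)), 0.5)
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "single-class")
  set.seed(2)
  y <- rbinom(60, 1, 0.4); s <- rnorm(60) + y
  expect_equal(rocAuc(1 - y, s), 1 - rocAuc(y, s))
  skip_if_not_installed("pROC")
  expect_equal(rocAuc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("repeated CV is deterministic and saturates on a leaked response", {
  co <- smallCohort()
  fm <- buildCohortFeatureMatrix(co)
  spec <- modelSpec("xgboost", params = list(n_estimators = 60,
                                             max_depth = 3), seed = 5)
  cv1 <- repeatedKFoldCV(spec, fm, k = 5, reps = 2, seed = 17)
  cv2 <- repeatedKFoldCV(spec, fm, k = 5, reps = 2, seed = 17)
  expect_equal(cv1@wapcc, cv2@wapcc, tolerance = 1e-12)
  expect_equal(cv1@predictions$predicted, cv2@predictions$predicted,
               tolerance = 1e-12)
  expect_length(cv1@repetitions, 2)
  # every experiment predicted exactly once per repetition
  expect_equal(nrow(cv1@predictions), 2L * ncol(fm))

  # leak the response as a feature: near-perfect WAPCC
  leak <- fm
  leaked <- rbind(SummarizedExperiment::assay(fm),
                  leak_y = synergyScores(fm))
  fmLeak <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = leaked),
    rowData = S4Vectors::DataFrame(
      group = c(featureGroups(fm), leak_y = "monotherapy"),
      row.names = rownames(leaked)),
    colData = SummarizedExperiment::colData(fm))
  fmLeak <- new("SynergyFeatureMatrix", fmLeak)
  cvLeak <- repeatedKFoldCV(spec, fmLeak, k = 5, reps = 1, seed = 17,
                            refitNetwork = FALSE)
  expect_gte(cvLeak@wapcc, 0.99)
})

test_that("per-combination bookkeeping respects zero-weight singletons", {
  co <- smallCohort()
  fm <- buildCohortFeatureMatrix(co)
  spec <- modelSpec("linear")
  cv <- repeatedKFoldCV(spec, fm, k = 5, reps = 1, seed = 9,
                        refitNetwork = FALSE)
  pc <- cv@perCombination
  counts <- table(SummarizedExperiment::colData(fm)$combination)
  expect_equal(pc$n, as.integer(counts[pc$combination]))
  expect_equal(cv@repetitions[1], wapcc(pc$rho, pc$n), tolerance = 1e-12)
})

test_that("bootstrap intervals behave like percentile intervals", {
  degenerate <- data.frame(rho = rep(0.4, 8), n = rep(5, 8))
  expect_equal(bootstrapCI(degenerate, B = 50), c(0.4, 0.4))
  set.seed(3)
  for (i in 1:20) {
    pc <- data.frame(rho = runif(12, -1, 1),
                     n = sample(2:9, 12, replace = TRUE))
    ci <- bootstrapCI(pc, B = 200, seed = i)
    expect_lte(ci[1], wapcc(pc))
    expect_gte(ci[2], wapcc(pc))
  }
  # width shrinks roughly as 1/sqrt(combination count)
  set.seed(4)
  rho <- runif(200, 0, 0.8); n <- sample(3:9, 200, replace = TRUE)
  small <- data.frame(rho = rho[1:50], n = n[1:50])
  big <- data.frame(rho = rho, n = n)
  wSmall <- diff(bootstrapCI(small, B = 400, seed = 1))
  wBig <- diff(bootstrapCI(big, B = 400, seed = 1))
  expect_gt(wBig / wSmall, 0.25)
  expect_lt(wBig / wSmall, 0.75)
})

test_that("the two-sample z-test matches its normal-CDF oracle", {
  r <- twoSampleZTest(0.39, 0.02, 10, 0.36, 0.02, 10)
  expect_equal(r$z, 3.3541020, tolerance = 1e-6)
  expect_equal(r$p, 0.00079623, tolerance = 1e-6)
  expect_equal(twoSampleZTest(0.5, 0.1, 10, 0.5, 0.2, 10),
               list(z = 0, p = 1))
  swapped <- twoSampleZTest(0.36, 0.02, 10, 0.39, 0.02, 10)
  expect_equal(swapped$z, -r$z)
  expect_equal(swapped$p, r$p)
  expect_equal(twoSampleZTest(0.4, 0, 5, 0.3, 0, 5), list(z = Inf, p = 0))
  expect_error(twoSampleZTest(0.4, 0.1, 1, 0.3, 0.1, 10), "repetitions")
})
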