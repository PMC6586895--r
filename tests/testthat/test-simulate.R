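test_that("the generator is deterministic under seed and counts the grid", {
  a <- generateCohort(smallConfig(seed = 3))
  b <- generateCohort(smallConfig(seed = 3))
  expect_identical(a, b)
  d <- generateCohort(smallConfig(seed = 4))
  expect_false(identical(a$experiments$synergy, d$experiments$synergy))

  # coverage 1.0 -> the full grid; fractional coverage floors
  full <- generateCohort(simConfig(nDrugs = 10, nCellLines = 6,
                                   nCombos = 12, coverage = 1.0,
                                   nGenes = 30, nModules = 3, seed = 1))
  expect_equal(nrow(full$experiments), 12 * 6)
  part <- generateCohort(simConfig(nDrugs = 60, nCellLines = 40,
                                   nCombos = 150, coverage = 0.2,
                                   nGenes = 30, nModules = 3, seed = 1))
  expect_equal(nrow(part$experiments), floor(0.2 * 150 * 40))
})

test_that("an over-large combination request is infeasible", {
  expect_error(simConfig(nDrugs = 5, nCombos = 11),
               "exceeds the 10 unordered drug pairs")
})

test_that("substreams are independent: resizing genes leaves the screen alone", {
  a <- generateCohort(smallConfig(seed = 9))
  b <- generateCohort(simConfig(nDrugs = 12, nCellLines = 10, nCombos = 25,
                                nGenes = 120, nModules = 3, nProteins = 15,
                                nPathways = 8, nDomains = 12,
                                coverage = 0.6, seed = 9))
  expect_identical(a$experiments[, c("combination", "cellLine")],
                   b$experiments[, c("combination", "cellLine")])
  expect_identical(a$fingerprints, b$fingerprints)
})

test_that("planted modules have the prescribed correlation structure", {
  cfg <- simConfig(nDrugs = 10, nCombos = 20, nCellLines = 50,
                   nGenes = 150, nModules = 5, moduleSignalVar = 0.8,
                   seed = 5)
  x <- generateExpression(cfg)
  truth <- moduleTruth(cfg)
  co <- cor(t(x))
  same <- outer(truth, truth, "==")
  diag(same) <- NA
  within <- mean(co[which(same)], na.rm = TRUE)
  cross <- mean(abs(co[which(!same)]), na.rm = TRUE)
  expect_gt(within, 0.7)
  expect_lt(within, 0.9)

  cfg0 <- simConfig(nDrugs = 10, nCombos = 20, nCellLines = 50,
                    nGenes = 150, nModules = 5, moduleSignalVar = 0,
                    seed = 5)
  co0 <- cor(t(generateExpression(cfg0)))
  within0 <- mean(abs(co0[which(same)]), na.rm = TRUE)
  cross0 <- mean(abs(co0[which(!same)]), na.rm = TRUE)
  expect_lt(abs(within0 - cross0), 0.1)
})

test_that("a single all-gene module puts ~v of variance on the first PC", {
  cfg <- simConfig(nDrugs = 10, nCombos = 20, nCellLines = 50,
                   nGenes = 100, nModules = 1, moduleSignalVar = 0.8,
                   seed = 6)
  x <- generateExpression(cfg)
  pc <- prcomp(t(x))
  share <- pc$sdev[1]^2 / sum(pc$sdev^2)
  expect_lt(abs(share - 0.8), 0.1)
})

test_that("CNV coupling concentrates Spearman near the target", {
  cfg <- simConfig(nDrugs = 10, nCombos = 20, nCellLines = 85,
                   nGenes = 400, nModules = 4, cnvCoupledFraction = 0.5,
                   seed = 8)
  truth <- moduleTruth(cfg)
  x <- generateExpression(cfg, truth)
  coupled <- sample(names(truth), 200)
  cnv <- generateCnv(cfg, coupled, x)
  expect_true(all(cnv >= 0 & cnv <= 8))
  rs <- vapply(coupled, function(g) cor(rank(x[g, ]), rank(cnv[g, ])),
               numeric(1))
  expect_gte(mean(rs >= 0.4 & rs <= 0.8), 0.95)
  un <- setdiff(rownames(x), coupled)
  ru <- vapply(un, function(g) cor(rank(x[g, ]), rank(cnv[g, ])),
               numeric(1))
  expect_gte(mean(abs(ru) < 0.3), 0.95)
})

test_that("the synergy model reduces to pure noise and to exact effects", {
  cfg <- simConfig(nDrugs = 15, nCellLines = 20, nCombos = 50,
                   coverage = 1.0, nGenes = 30, nModules = 3,
                   noiseSd = 1,
                   effectSizes = c(intercept = 0, pathway = 0, module = 0,
                                   mutation = 0, mono = 0),
                   seed = 10)
  co <- generateCohort(cfg)
  expect_equal(nrow(co$experiments), 1000)
  expect_lt(abs(mean(co$experiments$synergy)), 0.1)
  expect_lt(abs(sd(co$experiments$synergy) - 1), 0.1)

  cfgP <- simConfig(nDrugs = 15, nCellLines = 20, nCombos = 50,
                    coverage = 1.0, nGenes = 30, nModules = 3,
                    noiseSd = 0,
                    effectSizes = c(intercept = 0, pathway = 10, module = 0,
                                    mutation = 0, mono = 0),
                    seed = 10)
  coP <- generateCohort(cfgP)
  ov <- coP$truth$comboPathwayOverlap[coP$experiments$combination]
  expect_true(any(ov) && any(!ov))
  expect_equal(unique(coP$experiments$synergy[ov]), 10)
  expect_equal(unique(coP$experiments$synergy[!ov]), 0)
})

test_that("OLS on the true design recovers the planted coefficients", {
  co <- defaultCohort()
  fit <- lm(co$experiments$synergy ~ pathwayOverlap + moduleMean +
              mutInteraction + dEinf, data = co$truth$design)
  est <- coef(summary(fit))
  truth <- co$truth$coefficients[c("intercept", "pathway", "module",
                                   "mutation", "mono")]
  expect_true(all(abs(est[, "Estimate"] - truth) <= 2 * est[, "Std. Error"]))
})

test_that("a missing effect-size coefficient is a config error", {
  expect_error(simConfig(effectSizes = c(intercept = 1, pathway = 1)),
               "module")
})
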