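test_that("module detection recovers planted modules and nothing from noise", {
  cfg <- simConfig(nDrugs = 10, nCombos = 20, nCellLines = 50,
                   nGenes = 150, nModules = 5, moduleSignalVar = 0.8,
                   seed = 21)
  truth <- moduleTruth(cfg)
  x <- generateExpression(cfg, truth)
  mods <- detectCoexpressionModules(x, nModules = 5)
  expect_gte(ari(mods@assignment[names(truth)], truth), 0.8)

  cfg0 <- simConfig(nDrugs = 10, nCombos = 20, nCellLines = 50,
                    nGenes = 150, nModules = 5, moduleSignalVar = 0,
                    seed = 21)
  x0 <- generateExpression(cfg0, truth)
  mods0 <- detectCoexpressionModules(x0, nModules = 5, minModuleSize = 1)
  expect_lt(ari(mods0@assignment[names(truth)], truth), 0.2)
})

test_that("module detection is invariant to gene and cell order", {
  x <- generateExpression(smallConfig())
  mods <- detectCoexpressionModules(x, nModules = 3)
  set.seed(2)
  xp <- x[sample(nrow(x)), sample(ncol(x))]
  modsP <- detectCoexpressionModules(xp, nModules = 3)
  expect_gte(ari(mods@assignment[rownames(x)],
                 modsP@assignment[rownames(x)]), 0.999)
})

test_that("perfectly correlated genes always share a module", {
  base <- rnorm(30)
  x <- rbind(g1 = base, g2 = 2 * base + 5, g3 = rnorm(30), g4 = rnorm(30))
  mods <- detectCoexpressionModules(x, nModules = 3, minModuleSize = 1)
  expect_equal(mods@assignment[["g1"]], mods@assignment[["g2"]])
})

test_that("module means reduce to member profiles and conserve the grand mean", {
  x <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  assign <- setNames(c("M1", "M2", "M2", "M2", "unassigned"), rownames(x))
  mm <- moduleMeanFeatures(x, assign)
  expect_equal(mm["M1", ], x["g1", ])
  expect_equal(mm["M2", ], colMeans(x[2:4, ]))
  # size-weighted mean of module rows = grand mean over assigned genes
  w <- c(M1 = 1, M2 = 3)
  expect_equal(colSums(mm * w) / sum(w), colMeans(x[1:4, ]))
  # all genes in one module, z-scored input -> near-zero row
  z <- t(scale(t(matrix(rnorm(2000), 40, 50))))
  dimnames(z) <- list(paste0("g", 1:40), paste0("c", 1:50))
  one <- moduleMeanFeatures(z, setNames(rep("M1", 40), rownames(z)))
  expect_lt(max(abs(one)), 4 / sqrt(40))
})

test_that("hypergeometric enrichment matches the combinatorial count", {
  universe <- paste0("g", 1:10)
  annotation <- list(term1 = paste0("g", 1:5))
  res <- moduleEnrichment(paste0("g", 1:4), annotation, universe)
  expect_equal(res$pRaw, 5 / 210, tolerance = 1e-12)
  expect_equal(res$pBonferroni, res$pRaw)  # single term tested
  # k = 0 has upper-tail probability 1
  res0 <- moduleEnrichment(paste0("g", 6:9), annotation, universe)
  expect_equal(res0$pRaw, 1)
  # Bonferroni never decreases p and p stays in (0, 1]
  annotation2 <- list(t1 = paste0("g", 1:5), t2 = paste0("g", 2:7),
                      t3 = character())
  res2 <- moduleEnrichment(paste0("g", 1:4), annotation2, universe)
  expect_equal(nrow(res2), 2)  # empty term skipped
  expect_true(all(res2$pBonferroni >= res2$pRaw))
  expect_true(all(res2$pRaw > 0 & res2$pRaw <= 1))
})

test_that("SNP filtering keeps cancer-gene variants seen at least once", {
  cells <- paste0("CL", 1:4)
  mut <- data.frame(
    cellLine = c("CL1", "CL2", "CL9", "CL1"),
    gene = c("BRAF", "OTHER", "TP53", "TP53"),
    variant = c("v1", "v2", "v3", "v4"))
  m <- filterSnps(mut, cancerGenes = c("BRAF", "TP53"), cellLines = cells)
  # v2 fails the cancer-gene gate; v3 occurs only outside the panel
  expect_setequal(colnames(m), c("v1", "v4"))
  expect_equal(m["CL1", "v1"], 1L)
  expect_equal(sum(m), 2L)
  g <- filterSnps(mut, cancerGenes = c("BRAF", "TP53"), cellLines = cells,
                  perGene = TRUE)
  expect_setequal(colnames(g), c("BRAF", "TP53"))
})

test_that("synthetic cancer-gene variants survive the filter exactly", {
  co <- smallCohort()
  cells <- co$cellLines$info$cellLine
  mut <- co$cellLines$mutations
  m <- filterSnps(mut, co$vocabularies$cancerGenes, cells)
  expected <- unique(mut$variant[mut$gene %in% co$vocabularies$cancerGenes &
                                   mut$cellLine %in% cells])
  expect_setequal(colnames(m), expected)
})

test_that("Fisher r-to-z p-values match the normal-CDF oracle", {
  expect_equal(fisherZPvalue(0, 85), 1)
  # frozen from an independent normal-CDF evaluation
  expect_equal(fisherZPvalue(0.17, 85), 0.1200633, tolerance = 1e-6)
  expect_equal(fisherZPvalue(1, 50), 0)
  expect_error(fisherZPvalue(0.5, 3), "n >= 4")
  # strictly decreasing in |r| at fixed n
  ps <- fisherZPvalue(seq(0, 0.9, by = 0.1), 40)
  expect_true(all(diff(ps) < 0))
})

test_that("CNV selection recovers planted coupling with the stated gates", {
  cfg <- simConfig(nDrugs = 10, nCombos = 20, nCellLines = 85,
                   nGenes = 300, nModules = 3, cnvCoupledFraction = 0.15,
                   seed = 31)
  co <- generateCohort(cfg)
  sel <- selectCnvGenes(co$cellLines$cnv, co$cellLines$expression,
                        co$vocabularies$cancerGenes)
  truthCoupled <- intersect(co$truth$coupledGenes,
                            co$vocabularies$cancerGenes)
  truthUncoupled <- setdiff(co$vocabularies$cancerGenes, truthCoupled)
  sens <- mean(sel$selected[sel$gene %in% truthCoupled])
  spec <- mean(!sel$selected[sel$gene %in% truthUncoupled])
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  # genes outside the cancer list are never selected, however correlated
  expect_false(any(sel$selected[!sel$gene %in% co$vocabularies$cancerGenes]))
  # monotone filter: loosening both gates never drops a selected gene
  looser <- selectCnvGenes(co$cellLines$cnv, co$cellLines$expression,
                           co$vocabularies$cancerGenes,
                           alpha = 0.05, rMin = 0.1)
  expect_true(all(looser$selected[sel$selected]))
})

test_that("constant copy number yields r = 0 and no selection", {
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  cnv <- matrix(2L, 4, 10, dimnames = dimnames(x))
  cnv[2, ] <- sample(0:6, 10, replace = TRUE)
  sel <- selectCnvGenes(cnv, x, cancerGenes = rownames(x))
  expect_equal(sel$spearman[sel$gene == "g1"], 0)
  expect_false(sel$selected[sel$gene == "g1"])
})
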