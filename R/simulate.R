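## Synthetic combination-screen generator with planted, recoverable structure.

#' Construct a synthetic-screen configuration
#'
#' Builds a validated [SimConfig-class].  The defaults describe the
#' reduced-scale cohort used throughout the package's tests: 60 drugs,
#' 40 cell lines and 150 combinations with 20\% of the combination x
#' cell-line grid screened (the sparsity of the public screen this
#' pipeline targets), 300 genes in 6 co-expression modules with
#' within-module correlation 0.8, 15\% of genes with copy-number/expression
#' coupling at Spearman ~0.6, and a synergy-generating model whose
#' deterministic part explains about half of the score variance
#' (`noiseSd = 8.5` against a planted-signal standard deviation of ~8.6).
#'
#' @param nDrugs,nCellLines,nCombos,nGenes,nModules,nProteins,nPathways,nDomains
#'   cohort dimensions; `nDomains` is the total over the four domain
#'   sources.
#' @param coverage screened fraction of the combination x cell-line grid.
#' @param moduleSignalVar fraction of expression variance from the module
#'   factor (equals the expected within-module pairwise correlation).
#' @param cnvCoupledFraction fraction of genes with CNV-expression coupling.
#' @param cnvTargetR target Spearman correlation for coupled genes.
#' @param noiseSd synergy noise standard deviation (Loewe-excess units).
#' @param effectSizes named coefficients of the synergy-generating model:
#'   `intercept`, `pathway` (shared-pathway indicator), `module` (designated
#'   module's mean expression), `mutation` (combo-targets-protein AND
#'   cell-carries-mutation interaction), `mono` (Einf difference).
#' @param fingerprintDensity Bernoulli density of synthetic fingerprints.
#' @param seed integer master seed.
#' @return a [SimConfig-class] object.
#' @export
simConfig <- function(nDrugs = 60, nCellLines = 40, nCombos = 150,
                      nGenes = 300, nModules = 6, nProteins = 60,
                      nPathways = 25, nDomains = 40,
                      coverage = 0.2, moduleSignalVar = 0.8,
                      cnvCoupledFraction = 0.15, cnvTargetR = 0.6,
                      noiseSd = 8.5,
                      effectSizes = c(intercept = 5, pathway = 8,
                                      module = 5, mutation = 10,
                                      mono = 0.12),
                      fingerprintDensity = 0.1, seed = 1L) {
  new("SimConfig",
      nDrugs = as.integer(nDrugs), nCellLines = as.integer(nCellLines),
      nCombos = as.integer(nCombos), nGenes = as.integer(nGenes),
      nModules = as.integer(nModules), nProteins = as.integer(nProteins),
      nPathways = as.integer(nPathways), nDomains = as.integer(nDomains),
      coverage = coverage, moduleSignalVar = moduleSignalVar,
      cnvCoupledFraction = cnvCoupledFraction, cnvTargetR = cnvTargetR,
      noiseSd = noiseSd, effectSizes = effectSizes,
      fingerprintDensity = fingerprintDensity, seed = as.integer(seed))
}

padId <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(n), i)

#' Planted module assignment for a configuration
#'
#' Genes are partitioned into `nModules` contiguous, near-equal modules.
#'
#' @param config a [SimConfig-class].
#' @return named character vector gene -> module id.
#' @export
moduleTruth <- function(config) {
  genes <- padId("G", seq_len(config@nGenes), config@nGenes)
  mod <- sort(rep_len(seq_len(config@nModules), config@nGenes))
  stats::setNames(padId("M", mod, config@nModules), genes)
}

#' Generate a gene x cell-line expression matrix with planted modules
#'
#' Gene g in module m on cell line c receives
#' `x_gc = sqrt(v) * F_mc + sqrt(1 - v) * eps_gc` with `F` and `eps`
#' independent standard normal and `v = moduleSignalVar`, so the expected
#' within-module pairwise correlation equals `v` and cross-module
#' correlations are zero in expectation.
#'
#' @param config a [SimConfig-class].
#' @param moduleAssignment named gene -> module vector; module sizes must
#'   partition the gene universe (default: [moduleTruth()]).
#' @return numeric matrix, genes x cell lines, with dimnames.
#' @export
generateExpression <- function(config, moduleAssignment = moduleTruth(config)) {
  v <- config@moduleSignalVar
  stopIfNot(v >= 0 && v < 1, "moduleSignalVar must lie in [0, 1)")
  stopIfNot(length(moduleAssignment) == config@nGenes,
            "module assignment must cover the gene universe")
  cells <- padId("CL", seq_len(config@nCellLines), config@nCellLines)
  genes <- names(moduleAssignment)
  mods <- sort(unique(moduleAssignment))
  withSubstream(config@seed, "expression", {
    f <- matrix(stats::rnorm(length(mods) * length(cells)),
                length(mods), length(cells), dimnames = list(mods, cells))
    eps <- matrix(stats::rnorm(length(genes) * length(cells)),
                  length(genes), length(cells), dimnames = list(genes, cells))
    x <- sqrt(v) * f[moduleAssignment, , drop = FALSE] + sqrt(1 - v) * eps
    dimnames(x) <- list(genes, cells)
    x
  })
}

# Latent loading that yields Spearman ~ targetR after quantile-binning the
# latent Gaussian to binomial copy numbers (bivariate-normal Spearman
# rho_s = (6/pi) asin(a/2), then a small tie attenuation; calibrated by
# Monte Carlo once and fixed).
cnvLatentLoading <- function(targetR) {
  a <- 2 * sin(pi * targetR / 6) / 0.985
  min(a, 0.999)
}

#' Generate a copy-number matrix with planted expression coupling
#'
#' Coupled genes receive integer copy numbers in [0, 8] obtained by
#' binomial quantile-mapping a latent Gaussian correlated with the gene's
#' expression, so that Spearman(expression, copy number) concentrates near
#' `cnvTargetR`; uncoupled genes get copy numbers independent of
#' expression with the same marginal distribution (Binomial(8, 0.25),
#' i.e. centred on the diploid count 2).
#'
#' @param config a [SimConfig-class].
#' @param coupledGenes character vector of coupled gene ids.
#' @param expression genes x cell-lines matrix from [generateExpression()].
#' @return integer matrix, genes x cell lines.
#' @export
generateCnv <- function(config, coupledGenes, expression) {
  genes <- rownames(expression)
  cells <- colnames(expression)
  a <- cnvLatentLoading(config@cnvTargetR)
  withSubstream(config@seed, "cnv", {
    latent <- matrix(stats::rnorm(length(genes) * length(cells)),
                     length(genes), length(cells),
                     dimnames = list(genes, cells))
    coupled <- intersect(coupledGenes, genes)
    # expression entries are marginally standard normal by construction
    latent[coupled, ] <- a * expression[coupled, , drop = FALSE] +
      sqrt(1 - a^2) * latent[coupled, , drop = FALSE]
    cnv <- stats::qbinom(stats::pnorm(latent), size = 8L, prob = 0.25)
    storage.mode(cnv) <- "integer"
    cnv
  })
}

generateDrugs <- function(config) {
  drugs <- padId("D", seq_len(config@nDrugs), config@nDrugs)
  proteins <- padId("P", seq_len(config@nProteins), config@nProteins)
  designatedProtein <- proteins[1L]
  withSubstream(config@seed, "drugs", {
    fingerprints <- matrix(
      as.integer(stats::runif(config@nDrugs * 166L) < config@fingerprintDensity),
      config@nDrugs, 166L,
      dimnames = list(drugs, paste0("maccs", seq_len(166L))))
    targets <- lapply(drugs, function(d) {
      t <- sample(proteins[-1L], sample(1:2, 1L))
      if (stats::runif(1) < 0.25) t <- c(designatedProtein, t)
      sort(unique(t))
    })
    names(targets) <- drugs
    list(drugs = drugs, proteins = proteins,
         designatedProtein = designatedProtein,
         fingerprints = fingerprints, targets = targets)
  })
}

generateVocabularies <- function(config, proteins) {
  sources <- c("pfam", "prosite", "smart", "superfamily")
  share <- c(0.35, 0.25, 0.2, 0.2)
  sizes <- pmax(1L, round(config@nDomains * share))
  sizes[1L] <- config@nDomains - sum(sizes[-1L])
  pathways <- padId("path", seq_len(config@nPathways), config@nPathways)
  withSubstream(config@seed, "vocabularies", {
    domainIds <- mapply(function(src, k)
      paste0(src, ":", padId("DOM", seq_len(k), k)),
      sources, sizes, SIMPLIFY = FALSE)
    domainMaps <- lapply(domainIds, function(ids) {
      m <- lapply(proteins, function(p)
        sort(sample(ids, sample(0:2, 1L, prob = c(0.3, 0.5, 0.2)))))
      names(m) <- proteins
      m
    })
    pathwayMap <- stats::setNames(lapply(proteins, function(p)
      sort(sample(pathways, sample(1:2, 1L)))), proteins)
    list(domainMaps = domainMaps, pathwayMap = pathwayMap,
         pathways = pathways, domainIds = domainIds)
  })
}

generateCellLines <- function(config, genes, cancerGenes, designatedGene) {
  cells <- padId("CL", seq_len(config@nCellLines), config@nCellLines)
  withSubstream(config@seed, "cellLines", {
    info <- data.frame(
      cellLine = cells,
      tissue = sample(c("breast", "lung", "colon", "skin"),
                      length(cells), replace = TRUE),
      disease = sample(paste0("disease", 1:5), length(cells), replace = TRUE),
      sex = sample(c("F", "M"), length(cells), replace = TRUE),
      stringsAsFactors = FALSE)
    # variant universe: a designated high-prevalence cancer variant plus a
    # mix of cancer-gene and non-cancer-gene variants
    nVariants <- 60L
    variantGenes <- c(designatedGene,
                      sample(cancerGenes, 19L, replace = TRUE),
                      sample(setdiff(genes, cancerGenes), nVariants - 20L,
                             replace = TRUE))
    variants <- paste0("var", seq_len(nVariants), "_", variantGenes)
    prevalence <- c(0.4, stats::runif(nVariants - 1L, 0.03, 0.3))
    calls <- lapply(seq_len(nVariants), function(i) {
      cells[stats::runif(length(cells)) < prevalence[i]]
    })
    mutations <- data.frame(
      cellLine = unlist(calls),
      gene = rep(variantGenes, lengths(calls)),
      variant = rep(variants, lengths(calls)),
      stringsAsFactors = FALSE)
    list(info = info, mutations = mutations,
         variants = variants, variantGenes = variantGenes)
  })
}

#' Generate a complete synthetic combination-screen cohort
#'
#' Produces drugs (fingerprints, targets), vocabularies (four domain
#' sources, pathways, cancer genes), cell lines (metadata, expression with
#' planted co-expression modules, copy number with planted
#' expression coupling, mutation calls), a screened subset of the
#' combination x cell-line grid, and synergy scores generated as
#' `intercept + beta_pathway * 1[shared pathway] + beta_module * (designated
#' module mean) + beta_mut * 1[combo targets designated protein AND cell
#' carries a mutation in the designated gene] + beta_mono * (Einf_A -
#' Einf_B) + N(0, noiseSd^2)`.  Monotherapy blocks carry per-experiment
#' dose-response parameters with log-uniform IC50 in [0.01, 10] uM, Hill
#' coefficient in [0.5, 3] and maximal kill in [20, 100]\%; an IC50 above
#' the drug's maximum assay concentration is recorded as missing
#' (censored).
#'
#' All randomness is drawn from substreams derived from `config@seed`, one
#' per component, so the same seed reproduces the cohort byte for byte and
#' resizing one component does not perturb the others.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `drugs` (data.frame with `drug`, `smiles`,
#'   list-column `targets`), `fingerprints` (drugs x 166 binary matrix),
#'   `cellLines` (list: `info`, `expression`, `cnv`, `mutations`),
#'   `experiments` (data.frame in [loadScreen()] layout), `vocabularies`
#'   (list: `domainMaps`, `pathwayMap`, `cancerGenes`, `pathways`,
#'   `domainIds`, `proteins`) and `truth` (planted structure: module
#'   assignment, designated module/protein/gene, coupled genes, the
#'   synergy design matrix and coefficients).
#' @export
generateCohort <- function(config) {
  validObject(config)
  drugInfo <- generateDrugs(config)
  vocab <- generateVocabularies(config, drugInfo$proteins)
  moduleAssignment <- moduleTruth(config)
  genes <- names(moduleAssignment)
  expression <- generateExpression(config, moduleAssignment)
  withSubstream(config@seed, "genes", {
    cancerGenes <- sort(sample(genes, max(2L, round(0.15 * length(genes)))))
    coupledGenes <- sort(sample(genes, round(config@cnvCoupledFraction *
                                               length(genes))))
  })
  designatedGene <- cancerGenes[1L]
  cnv <- generateCnv(config, coupledGenes, expression)
  cl <- generateCellLines(config, genes, cancerGenes, designatedGene)

  ## screened grid
  pairs <- t(utils::combn(drugInfo$drugs, 2L))
  withSubstream(config@seed, "screen", {
    comboIdx <- sort(sample(nrow(pairs), config@nCombos))
    combos <- pairs[comboIdx, , drop = FALSE]
    comboIds <- paste(combos[, 1L], combos[, 2L], sep = ".")
    grid <- expand.grid(combo = seq_len(config@nCombos),
                        cell = seq_len(config@nCellLines))
    nExp <- floor(config@coverage * nrow(grid))
    screened <- grid[sort(sample(nrow(grid), nExp)), , drop = FALSE]
  })

  cells <- cl$info$cellLine
  exps <- data.frame(
    combination = comboIds[screened$combo],
    drugA = combos[screened$combo, 1L],
    drugB = combos[screened$combo, 2L],
    cellLine = cells[screened$cell],
    stringsAsFactors = FALSE)

  ## monotherapy blocks (per experiment, per drug)
  withSubstream(config@seed, "monotherapy", {
    maxConc <- stats::setNames(
      exp(stats::runif(config@nDrugs, log(0.1), log(10))), drugInfo$drugs)
    n <- nrow(exps)
    for (side in c("A", "B")) {
      drug <- exps[[paste0("drug", side)]]
      ic50True <- exp(stats::runif(n, log(0.01), log(10)))
      mc <- maxConc[drug]
      censored <- ic50True > mc
      exps[[paste0("maxConc", side)]] <- unname(mc)
      exps[[paste0("ic50", side)]] <- ifelse(censored, NA_real_, ic50True)
      exps[[paste0("h", side)]] <- stats::runif(n, 0.5, 3)
      exps[[paste0("einf", side)]] <- stats::runif(n, 20, 100)
      exps[[paste0("qa", side)]] <- ifelse(stats::runif(n) < 0.95, 1, 0)
    }
  })

  ## planted synergy signal
  pathwaysOf <- function(targets) sort(unique(unlist(
    vocab$pathwayMap[intersect(targets, drugInfo$proteins)])))
  comboPathwayOverlap <- vapply(seq_len(config@nCombos), function(i) {
    length(intersect(pathwaysOf(drugInfo$targets[[combos[i, 1L]]]),
                     pathwaysOf(drugInfo$targets[[combos[i, 2L]]]))) > 0
  }, logical(1))
  names(comboPathwayOverlap) <- comboIds
  comboTargetsProtein <- vapply(seq_len(config@nCombos), function(i) {
    p <- drugInfo$designatedProtein
    p %in% drugInfo$targets[[combos[i, 1L]]] ||
      p %in% drugInfo$targets[[combos[i, 2L]]]
  }, logical(1))
  names(comboTargetsProtein) <- comboIds
  designatedModule <- moduleAssignment[[1L]]
  moduleMean <- colMeans(
    expression[names(moduleAssignment)[moduleAssignment == designatedModule],
               , drop = FALSE])
  mutatedCells <- unique(cl$mutations$cellLine[cl$mutations$gene ==
                                                 designatedGene])
  es <- config@effectSizes
  design <- data.frame(
    pathwayOverlap = as.numeric(comboPathwayOverlap[exps$combination]),
    moduleMean = unname(moduleMean[exps$cellLine]),
    mutInteraction = as.numeric(comboTargetsProtein[exps$combination] &
                                  exps$cellLine %in% mutatedCells),
    dEinf = exps$einfA - exps$einfB)
  signal <- es[["intercept"]] +
    es[["pathway"]] * design$pathwayOverlap +
    es[["module"]] * design$moduleMean +
    es[["mutation"]] * design$mutInteraction +
    es[["mono"]] * design$dEinf
  noise <- withSubstream(config@seed, "noise",
                         stats::rnorm(nrow(exps), 0, config@noiseSd))
  exps$synergy <- signal + noise
  exps <- exps[, c("combination", "drugA", "drugB", "cellLine", "synergy",
                   paste0(rep(MONO_FIELDS, 2L),
                          rep(c("A", "B"), each = length(MONO_FIELDS))))]
  rownames(exps) <- NULL

  drugsDf <- data.frame(drug = drugInfo$drugs, smiles = NA_character_,
                        targets = I(unname(drugInfo$targets)),
                        stringsAsFactors = FALSE)

  list(
    drugs = drugsDf,
    fingerprints = drugInfo$fingerprints,
    cellLines = list(info = cl$info, expression = expression, cnv = cnv,
                     mutations = cl$mutations),
    experiments = exps,
    vocabularies = list(domainMaps = vocab$domainMaps,
                        pathwayMap = vocab$pathwayMap,
                        cancerGenes = cancerGenes,
                        pathways = vocab$pathways,
                        domainIds = vocab$domainIds,
                        proteins = drugInfo$proteins),
    truth = list(
      moduleAssignment = moduleAssignment,
      designatedModule = designatedModule,
      designatedProtein = drugInfo$designatedProtein,
      designatedGene = designatedGene,
      coupledGenes = coupledGenes,
      cancerGenes = cancerGenes,
      coefficients = c(es, noiseSd = config@noiseSd),
      comboPathwayOverlap = comboPathwayOverlap,
      comboTargetsProtein = comboTargetsProtein,
      moduleMean = moduleMean,
      mutatedCells = mutatedCells,
      design = design,
      signal = signal)
  )
}

#' Write a synthetic cohort to the screen's text formats
#'
#' Writes `screen.csv`, `drugs.csv`, `fingerprints.csv`,
#' `expression.csv`, `cnv.csv`, `mutations.csv`, `cell_lines.csv`, four
#' domain GMT files, `pathways.gmt`, `cancer_genes.gmt` and `truth.json`
#' into a directory, in the formats understood by the loaders of this
#' package.
#'
#' @param cohort a cohort from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeScreen(cohort$experiments, file.path(dir, "screen.csv"))
  drugs <- data.frame(
    DRUG_ID = cohort$drugs$drug,
    SMILES = ifelse(is.na(cohort$drugs$smiles), "", cohort$drugs$smiles),
    TARGETS = vapply(cohort$drugs$targets, paste, character(1),
                     collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.csv(drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  fp <- data.frame(DRUG_ID = rownames(cohort$fingerprints),
                   BITS = apply(cohort$fingerprints, 1L, paste, collapse = ""),
                   stringsAsFactors = FALSE)
  utils::write.csv(fp, file.path(dir, "fingerprints.csv"), row.names = FALSE)
  writeOmicsMatrix(cohort$cellLines$expression,
                   file.path(dir, "expression.csv"))
  writeOmicsMatrix(cohort$cellLines$cnv, file.path(dir, "cnv.csv"))
  mut <- cohort$cellLines$mutations
  utils::write.csv(data.frame(CELL_LINE = mut$cellLine, GENE = mut$gene,
                              VARIANT_ID = mut$variant),
                   file.path(dir, "mutations.csv"), row.names = FALSE)
  info <- cohort$cellLines$info
  utils::write.csv(data.frame(CELL_LINE = info$cellLine,
                              TISSUE = info$tissue, DISEASE = info$disease,
                              SEX = info$sex),
                   file.path(dir, "cell_lines.csv"), row.names = FALSE)
  for (src in names(cohort$vocabularies$domainMaps))
    writeGmt(cohort$vocabularies$domainMaps[[src]],
             file.path(dir, paste0("domains_", src, ".gmt")))
  writeGmt(cohort$vocabularies$pathwayMap, file.path(dir, "pathways.gmt"))
  writeGmt(list(CANCER_GENES = cohort$vocabularies$cancerGenes),
           file.path(dir, "cancer_genes.gmt"))
  truth <- cohort$truth
  truth$design <- NULL  # recomputable; keep the JSON compact
  truth$signal <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
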