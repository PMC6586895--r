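## Assembly of the experiment-level feature matrix from feature providers.

expKey <- function(experiments)
  paste(experiments$combination, experiments$cellLine, sep = " / ")

#' Declare a block of features for assembly
#'
#' A feature block is a numeric matrix of feature columns keyed by
#' combination id, cell-line id or experiment key (`"combo / cell"`)
#' in its rownames, plus the feature-group label shared by its columns.
#'
#' @param values numeric matrix with keyed rownames and named columns.
#' @param group feature-group label (one of the feature classes).
#' @param keyedBy one of `"combination"`, `"cellLine"`, `"experiment"`.
#' @return the block, for [assembleFeatureMatrix()].
#' @export
featureBlock <- function(values, group,
                         keyedBy = c("combination", "cellLine",
                                     "experiment")) {
  keyedBy <- match.arg(keyedBy)
  values <- as.matrix(values)
  stopIfNot(!is.null(rownames(values)) &&
              (ncol(values) == 0L || !is.null(colnames(values))),
            "feature blocks need rownames (keys) and colnames (features)")
  list(values = values, group = group, keyedBy = keyedBy)
}

#' Assemble the experiment x feature matrix
#'
#' Expands each feature block to the experiment level (combination-keyed
#' and cell-line-keyed blocks are replicated across the experiments that
#' reference them), appends the five categorical identifier features
#' (combination, cell line, tissue, disease, sex) as stable integer codes
#' in sorted category order under the group `"trivial information"`, and
#' returns a [SynergyFeatureMatrix-class] with a deterministic column
#' order (blocks in the order supplied, features name-sorted within each
#' block).  Duplicate feature names across blocks are an error, as is an
#' experiment referencing a key absent from a block.
#'
#' @param experiments data.frame in [loadScreen()] layout.
#' @param blocks list of [featureBlock()]s.
#' @param cellInfo optional data.frame from [loadCellLineInfo()]; when
#'   absent the tissue/disease/sex identifiers are skipped.
#' @param categoricals include the categorical identifier features.
#' @return a [SynergyFeatureMatrix-class] (features x experiments).
#' @export
assembleFeatureMatrix <- function(experiments, blocks, cellInfo = NULL,
                                  categoricals = TRUE) {
  keys <- expKey(experiments)
  stopIfNot(!anyDuplicated(keys),
            "duplicated (combination, cell line) experiments")
  expanded <- lapply(blocks, function(b) {
    rowsNeeded <- switch(b$keyedBy,
                         combination = experiments$combination,
                         cellLine = experiments$cellLine,
                         experiment = keys)
    missing <- setdiff(unique(rowsNeeded), rownames(b$values))
    if (length(missing))
      stop("experiments reference ", b$keyedBy,
           " key(s) absent from the '", b$group, "' block: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    v <- b$values[rowsNeeded, , drop = FALSE]
    v <- v[, order(colnames(v)), drop = FALSE]
    rownames(v) <- keys
    v
  })
  groups <- rep(vapply(blocks, `[[`, character(1), "group"),
                vapply(expanded, ncol, integer(1)))
  X <- do.call(cbind, expanded)
  if (categoricals) {
    code <- function(x) as.integer(factor(x, levels = sort(unique(x))))
    cat <- cbind(id_combination = code(experiments$combination),
                 id_cellLine = code(experiments$cellLine))
    if (!is.null(cellInfo)) {
      info <- cellInfo[match(experiments$cellLine, cellInfo$cellLine), ,
                       drop = FALSE]
      unknown <- unique(experiments$cellLine[is.na(info$cellLine)])
      if (length(unknown))
        stop("experiments reference unknown cell line(s): ",
             paste(utils::head(unknown, 5L), collapse = ", "),
             call. = FALSE)
      cat <- cbind(cat, id_tissue = code(info$tissue),
                   id_disease = code(info$disease), id_sex = code(info$sex))
    }
    rownames(cat) <- keys
    X <- cbind(X, cat)
    groups <- c(groups, rep("trivial information", ncol(cat)))
  }
  dup <- colnames(X)[duplicated(colnames(X))]
  if (length(dup))
    stop("duplicate feature name(s) across blocks: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  stopIfNot(!anyNA(X), "assembled features contain missing values")
  se <- SummarizedExperiment(
    assays = list(features = t(X)),
    rowData = DataFrame(group = groups, row.names = colnames(X)),
    colData = DataFrame(combination = experiments$combination,
                        drugA = experiments$drugA,
                        drugB = experiments$drugB,
                        cellLine = experiments$cellLine,
                        synergy = experiments$synergy,
                        row.names = keys))
  new("SynergyFeatureMatrix", se)
}

#' Experiment x feature value matrix
#'
#' @param fm a [SynergyFeatureMatrix-class].
#' @param sparse return a `dgCMatrix` (the sparse path is much faster for
#'   tree boosting on the mostly-0/1/2 feature classes).
#' @return experiments x features matrix.
#' @export
featureValues <- function(fm, sparse = FALSE) {
  X <- t(assay(fm, "features"))
  if (sparse) methods::as(X, "CsparseMatrix") else X
}

#' Synergy response vector of a feature matrix
#' @param fm a [SynergyFeatureMatrix-class].
#' @return numeric vector, one score per experiment.
#' @export
synergyScores <- function(fm) colData(fm)$synergy

#' Drop feature groups (ablation hook)
#'
#' Removes exactly the features labelled with the given groups: the
#' ablation used to compare the full feature set against reduced
#' conditions (e.g. excluding monotherapy and gene expression modules to
#' mimic the restricted-molecular-data setting).
#'
#' @param fm a [SynergyFeatureMatrix-class].
#' @param groups character vector of group labels to remove.
#' @return a [SynergyFeatureMatrix-class] without those features.
#' @export
dropGroups <- function(fm, groups) {
  unknown <- setdiff(groups, unique(rowData(fm)$group))
  if (length(unknown))
    warning("no features in group(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  fm[!rowData(fm)$group %in% groups, ]
}

#' Build the full feature matrix of a cohort
#'
#' Convenience wrapper running every feature provider over a (synthetic or
#' loaded) cohort: fingerprint pair-sums plus a shared missingness count,
#' target/domain/pathway pair-sum encodings, synergy-network proximity
#' features (with the self-edge leakage guard), monotherapy vectors,
#' module mean expression, filtered binary mutations, selected copy
#' numbers, and the categorical identifiers.
#'
#' @param cohort a list shaped like [generateCohort()] output.
#' @param nModules module count for [detectCoexpressionModules()]
#'   (default: the number of planted modules when known, else 10).
#' @param threshold synergy threshold for the network features.
#' @param wholeNetwork disable the network leakage guard.
#' @param moduleSummary `"mean"` (default) or `"eigengene"`.
#' @return a [SynergyFeatureMatrix-class].
#' @export
buildCohortFeatureMatrix <- function(cohort, nModules = NULL,
                                     threshold = 20,
                                     wholeNetwork = FALSE,
                                     moduleSummary = c("mean", "eigengene")) {
  moduleSummary <- match.arg(moduleSummary)
  exps <- cohort$experiments
  drugs <- cohort$drugs
  vocab <- cohort$vocabularies
  combos <- unique(exps[, c("combination", "drugA", "drugB")])

  ## drug-pair blocks
  fp <- cohort$fingerprints
  fpMissing <- stats::setNames(!(drugs$drug %in% rownames(fp)), drugs$drug)
  fpOf <- function(d) if (fpMissing[[d]]) integer(166L) else fp[d, ]
  targetsOf <- stats::setNames(drugs$targets, drugs$drug)
  targetVocab <- sort(unique(unlist(targetsOf)))
  domVocab <- domainVocabulary(vocab$domainMaps)
  annotOf <- lapply(targetsOf, deriveDomainsPathways,
                    domainMaps = vocab$domainMaps,
                    pathwayMap = vocab$pathwayMap)
  comboBlock <- function(f, prefix) {
    m <- t(vapply(seq_len(nrow(combos)),
                  function(i) f(combos$drugA[i], combos$drugB[i]),
                  numeric(length(f(combos$drugA[1L], combos$drugB[1L])))))
    colnames(m) <- paste0(prefix, "_", colnames(m))
    rownames(m) <- combos$combination
    m
  }
  chem <- t(mapply(function(a, b) pairSum(fpOf(a), fpOf(b)),
                   combos$drugA, combos$drugB))
  colnames(chem) <- paste0("chem_", colnames(fp))
  chem <- cbind(chem, chem_fpMissing = as.integer(fpMissing[combos$drugA]) +
                  as.integer(fpMissing[combos$drugB]))
  rownames(chem) <- combos$combination
  targets <- t(mapply(function(a, b)
    setPairFeatures(targetsOf[[a]], targetsOf[[b]], targetVocab),
    combos$drugA, combos$drugB))
  colnames(targets) <- paste0("target_", targetVocab)
  rownames(targets) <- combos$combination
  domains <- t(mapply(function(a, b)
    setPairFeatures(annotOf[[a]]$domains, annotOf[[b]]$domains, domVocab),
    combos$drugA, combos$drugB))
  colnames(domains) <- paste0("domain_", domVocab)
  rownames(domains) <- combos$combination
  pathVocab <- vocab$pathways
  pathways <- t(mapply(function(a, b)
    setPairFeatures(annotOf[[a]]$pathways, annotOf[[b]]$pathways, pathVocab),
    combos$drugA, combos$drugB))
  colnames(pathways) <- paste0("pathway_", pathVocab)
  rownames(pathways) <- combos$combination

  netFeat <- pairNetworkFeatures(exps, combos[, c("drugA", "drugB")],
                                 threshold = threshold,
                                 wholeNetwork = wholeNetwork)
  net <- as.matrix(netFeat[, c("commonNeighbors", "jaccard", "adamicAdar")])
  colnames(net) <- paste0("net_", colnames(net))
  rownames(net) <- combos$combination

  ## cell-line blocks
  expr <- cohort$cellLines$expression
  if (is.null(nModules))
    nModules <- if (!is.null(cohort$truth))
      length(setdiff(unique(cohort$truth$moduleAssignment), "unassigned"))
    else 10L
  modules <- detectCoexpressionModules(expr, nModules = nModules)
  modMat <- if (moduleSummary == "mean") modules@moduleMeans
            else moduleEigengeneFeatures(expr, modules)
  modFeat <- t(modMat)
  colnames(modFeat) <- paste0("exprmod_", colnames(modFeat))

  cells <- cohort$cellLines$info$cellLine
  mut <- filterSnps(cohort$cellLines$mutations, vocab$cancerGenes, cells)
  colnames(mut) <- paste0("mut_", colnames(mut))
  cnvSel <- selectCnvGenes(cohort$cellLines$cnv, expr, vocab$cancerGenes)
  selGenes <- cnvSel$gene[cnvSel$selected]
  cnvFeat <- t(cohort$cellLines$cnv[selGenes, cells, drop = FALSE])
  if (length(selGenes)) colnames(cnvFeat) <- paste0("cnv_", selGenes)

  blocks <- list(
    featureBlock(chem, "chemical structure", "combination"),
    featureBlock(targets, "drug targets", "combination"),
    featureBlock(domains, "target protein domains", "combination"),
    featureBlock(pathways, "targeted pathways", "combination"),
    featureBlock(net, "drug synergy network", "combination"),
    featureBlock(monotherapyFeatures(exps), "monotherapy", "experiment"),
    featureBlock(modFeat, "gene expression modules", "cellLine"),
    featureBlock(mut, "mutations", "cellLine"),
    featureBlock(cnvFeat, "copy number", "cellLine"))
  # a filter may legitimately select nothing on a small cohort
  blocks <- Filter(function(b) ncol(b$values) > 0, blocks)
  fm <- assembleFeatureMatrix(exps, blocks,
                              cellInfo = cohort$cellLines$info)
  metadata(fm)$threshold <- threshold
  metadata(fm)$modules <- modules
  fm
}
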