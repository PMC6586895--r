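#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Configuration for the synthetic combination screen generator
#'
#' A `SimConfig` fixes every knob of the synthetic screen: the size of the
#' drug panel, cell-line panel and combination list, the gene universe and
#' its partition into co-expression modules, the target/pathway/domain
#' vocabularies, the screened fraction of the combination x cell-line grid,
#' the strength of the planted co-expression and CNV--expression structure,
#' and the coefficients of the synergy-generating model.  Defaults describe
#' a reduced-scale screen with the same structure as a large public
#' combination screen: roughly 20\% of the grid screened, tight
#' co-expression modules, and a synergy signal split between pathway
#' overlap, module expression, a target-by-mutation interaction and the
#' monotherapy response, calibrated so that the deterministic part explains
#' about half of the score variance.
#'
#' @slot nDrugs,nCellLines,nCombos,nGenes,nModules,nProteins,nPathways,nDomains
#'   integer counts defining the cohort dimensions.  `nDomains` is the total
#'   over the four domain sources.
#' @slot coverage fraction of the combination x cell-line grid screened,
#'   in (0, 1].
#' @slot moduleSignalVar fraction of expression variance contributed by the
#'   module factor, in [0, 1).  Equals the expected within-module pairwise
#'   correlation.
#' @slot cnvCoupledFraction fraction of genes whose copy number is coupled
#'   to their expression.
#' @slot cnvTargetR target Spearman correlation for coupled genes.
#' @slot noiseSd standard deviation of the Gaussian synergy noise.
#' @slot effectSizes named numeric vector with elements `intercept`,
#'   `pathway`, `module`, `mutation`, `mono`.
#' @slot fingerprintDensity Bernoulli density of the synthetic 166-bit
#'   fingerprints.
#' @slot seed integer master seed; all components draw from substreams
#'   derived from it.
#'
#' @seealso [simConfig()] for the user-facing constructor,
#'   [generateCohort()] for the generator itself.
#' @export
setClass("SimConfig", representation(
  nDrugs = "integer", nCellLines = "integer", nCombos = "integer",
  nGenes = "integer", nModules = "integer", nProteins = "integer",
  nPathways = "integer", nDomains = "integer",
  coverage = "numeric", moduleSignalVar = "numeric",
  cnvCoupledFraction = "numeric", cnvTargetR = "numeric",
  noiseSd = "numeric", effectSizes = "numeric",
  fingerprintDensity = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(nDrugs = object@nDrugs, nCellLines = object@nCellLines,
              nCombos = object@nCombos, nGenes = object@nGenes,
              nModules = object@nModules, nProteins = object@nProteins,
              nPathways = object@nPathways, nDomains = object@nDomains)
  if (any(counts < 1L))
    msg <- c(msg, paste0("counts must be >= 1: ",
                         paste(names(counts)[counts < 1L], collapse = ", ")))
  if (object@coverage <= 0 || object@coverage > 1)
    msg <- c(msg, "coverage must lie in (0, 1]")
  if (object@moduleSignalVar < 0 || object@moduleSignalVar >= 1)
    msg <- c(msg, "moduleSignalVar must lie in [0, 1)")
  if (object@cnvCoupledFraction < 0 || object@cnvCoupledFraction > 1)
    msg <- c(msg, "cnvCoupledFraction must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  needed <- c("intercept", "pathway", "module", "mutation", "mono")
  missing <- setdiff(needed, names(object@effectSizes))
  if (length(missing))
    msg <- c(msg, paste0("effectSizes lacks coefficient(s): ",
                         paste(missing, collapse = ", ")))
  maxCombos <- object@nDrugs * (object@nDrugs - 1) / 2
  if (object@nCombos > maxCombos)
    msg <- c(msg, sprintf(
      "nCombos = %d exceeds the %d unordered drug pairs available",
      object@nCombos, as.integer(maxCombos)))
  if (length(msg)) msg else TRUE
})

#' Undirected drug synergy network
#'
#' Drugs are nodes; an edge joins two drugs whose combination is
#' majority-synergistic across the cell lines on which it was screened
#' (strictly more than half of the scores exceed the synergy threshold,
#' conventionally 20 on the Loewe-excess scale).  The network is the
#' substrate for the three link-prediction proximity features
#' (common neighbors, Jaccard, Adamic-Adar).
#'
#' @slot nodes character vector of drug identifiers.
#' @slot edges two-column character matrix of unordered drug pairs, each
#'   row sorted lexicographically; no self-loops, no duplicates.
#'
#' @seealso [buildSynergyNetwork()], [commonNeighbors()],
#'   [jaccardCoefficient()], [adamicAdar()]
#' @export
setClass("SynergyNetwork", representation(
  nodes = "character", edges = "matrix"
))

setValidity("SynergyNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have exactly two columns")
  if (nrow(e)) {
    if (!is.character(e)) msg <- c(msg, "edges must be a character matrix")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edge rows must be sorted lexicographically")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
    if (!all(as.vector(e) %in% object@nodes))
      msg <- c(msg, "all edge endpoints must be declared nodes")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  if (length(msg)) msg else TRUE
})

#' Experiment-by-feature matrix with feature-group labels
#'
#' The assembled learning matrix of the pipeline, stored as a
#' `SummarizedExperiment`: rows are named features, columns are
#' (combination, cell line) experiments.  `rowData()$group` carries the
#' feature-class label of every feature (chemical structure, drug targets,
#' target protein domains, targeted pathways, drug synergy network,
#' monotherapy, gene expression modules, mutations, copy number, trivial
#' information, ...); `colData()` carries `combination`, `cellLine` and the
#' observed `synergy` score.  After assembly the matrix contains no missing
#' values.
#'
#' @seealso [assembleFeatureMatrix()], [featureGroups()], [dropGroups()]
#' @export
setClass("SynergyFeatureMatrix", contains = "SummarizedExperiment")

setValidity("SynergyFeatureMatrix", function(object) {
  msg <- character()
  if (!"group" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'group' column")
  need <- c("combination", "cellLine", "synergy")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be present and unique")
  if (length(SummarizedExperiment::assays(object)) &&
      anyNA(assay(object)))
    msg <- c(msg, "assembled feature values must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result with per-combination correlations
#'
#' Bookkeeping for repeated k-fold cross-validation under the weighted
#' average Pearson correlation (WAPCC) metric: out-of-fold predictions,
#' the per-combination Pearson correlations rho_i with their cell-line
#' counts n_i (averaged over repetitions), the per-repetition WAPCC values,
#' and their mean, the reported metric.  Combinations screened on a single
#' cell line carry zero weight (weight sqrt(n_i - 1)).
#'
#' @slot predictions data.frame with columns `combination`, `cellLine`,
#'   `observed`, `predicted`, `repetition`.
#' @slot perCombination data.frame with columns `combination`, `rho`, `n`.
#' @slot repetitions numeric vector of per-repetition WAPCC values.
#' @slot wapcc mean WAPCC over repetitions.
#' @slot seed integer seed used for fold assignment.
#'
#' @seealso [repeatedKFoldCV()], [wapcc()]
#' @export
setClass("CVResult", representation(
  predictions = "data.frame", perCombination = "data.frame",
  repetitions = "numeric", wapcc = "numeric", seed = "integer"
))

setValidity("CVResult", function(object) {
  msg <- character()
  pc <- object@perCombination
  need <- c("combination", "rho", "n")
  if (!all(need %in% colnames(pc)))
    msg <- c(msg, "perCombination needs columns combination, rho, n")
  else {
    if (any(pc$n < 1L)) msg <- c(msg, "per-combination n must be >= 1")
    if (any(abs(pc$rho) > 1 + 1e-12)) msg <- c(msg, "rho must lie in [-1, 1]")
  }
  if (length(object@wapcc) != 1L || is.na(object@wapcc) ||
      abs(object@wapcc) > 1 + 1e-12)
    msg <- c(msg, "wapcc must be a single value in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Fitted synergy regression or classification model
#'
#' Thin handle around one of the five supported backends (linear, lasso,
#' SVM, random forest, xgboost) remembering the feature names and groups it
#' was trained on, so that prediction can check the design and tree models
#' can export per-feature gain.
#'
#' @slot spec the [modelSpec()] the model was fitted under.
#' @slot fit the backend's fitted object.
#' @slot featureNames character vector of training feature names.
#' @slot featureGroups named character vector mapping feature -> group.
#'
#' @seealso [fitModel()], [gainImportance()]
#' @export
setClass("SynergyModel", representation(
  spec = "list", fit = "ANY", featureNames = "character",
  featureGroups = "character"
))

#' Gene co-expression module set
#'
#' The result of module detection on a gene x cell-line expression matrix:
#' a module assignment for each gene (`"unassigned"` for genes not in any
#' retained module) and the module x cell-line matrix of mean member
#' expression used as cell-line features.
#'
#' @slot assignment named character vector, gene -> module id or
#'   "unassigned".
#' @slot moduleMeans numeric matrix, modules x cell lines.
#'
#' @seealso [detectCoexpressionModules()], [moduleMeanFeatures()]
#' @export
setClass("ExpressionModuleSet", representation(
  assignment = "character", moduleMeans = "matrix"
))

setValidity("ExpressionModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by gene")
  mods <- setdiff(unique(object@assignment), "unassigned")
  if (!all(mods %in% rownames(object@moduleMeans)))
    msg <- c(msg, "every module must have a row in moduleMeans")
  if (length(msg)) msg else TRUE
})
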