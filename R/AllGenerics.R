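#' Feature-group labels of a feature matrix
#'
#' @param x a [SynergyFeatureMatrix-class].
#' @return named character vector mapping feature name to group label.
#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))

#' @rdname featureGroups
#' @export
setMethod("featureGroups", "SynergyFeatureMatrix", function(x) {
  stats::setNames(as.character(rowData(x)$group), rownames(x))
})

#' @rdname featureGroups
#' @export
setMethod("featureGroups", "SynergyModel", function(x) x@featureGroups)

#' Neighbor set of a drug in a synergy network
#'
#' @param net a [SynergyNetwork-class].
#' @param node a drug id.  Drugs absent from the network are treated as
#'   isolated (empty neighbor set).
#' @return character vector of neighboring drug ids.
#' @export
setGeneric("networkNeighbors",
           function(net, node) standardGeneric("networkNeighbors"))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nDrugs, "drugs x", object@nCellLines,
      "cell lines,", object@nCombos, "combinations,",
      sprintf("coverage %.2f", object@coverage), "\n")
  cat("  genes:", object@nGenes, "in", object@nModules,
      sprintf("modules (signal var %.2f);", object@moduleSignalVar),
      sprintf("CNV-coupled fraction %.2f (target r %.2f)",
              object@cnvCoupledFraction, object@cnvTargetR), "\n")
  cat("  vocabularies:", object@nProteins, "proteins,", object@nPathways,
      "pathways,", object@nDomains, "domains\n")
  es <- object@effectSizes
  cat("  synergy model:",
      paste(sprintf("%s=%.3g", names(es), es), collapse = ", "),
      sprintf("+ N(0, %.3g^2); seed %d", object@noiseSd, object@seed), "\n")
})

setMethod("show", "SynergyNetwork", function(object) {
  cat("SynergyNetwork:", length(object@nodes), "drugs,",
      nrow(object@edges), "synergistic edges\n")
})

setMethod("show", "SynergyFeatureMatrix", function(object) {
  grp <- table(rowData(object)$group)
  cat("SynergyFeatureMatrix:", nrow(object), "features x",
      ncol(object), "experiments\n")
  cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp),
                         collapse = ", "), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: WAPCC = %.4f over %d repetition(s); %d combinations\n",
    object@wapcc, length(object@repetitions), nrow(object@perCombination)))
})

setMethod("show", "SynergyModel", function(object) {
  cat("SynergyModel:", object@spec$kind, "(", object@spec$task, "),",
      length(object@featureNames), "features\n")
})

setMethod("show", "ExpressionModuleSet", function(object) {
  mods <- setdiff(unique(object@assignment), "unassigned")
  cat("ExpressionModuleSet:", length(mods), "modules over",
      length(object@assignment), "genes (",
      sum(object@assignment == "unassigned"), "unassigned )\n")
})
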