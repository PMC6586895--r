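## Cell-line features: co-expression modules, enrichment, mutation and CNV
## filters.

# Spearman correlation with average ranks; any constant vector yields 0
# (deterministic, no NaN propagation).
spearmanSafe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(rank(x), rank(y))
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Clusters genes on the dissimilarity `1 - |Pearson correlation|` with
#' average linkage and cuts the tree into `nModules` clusters; clusters
#' smaller than `minModuleSize` are merged into `"unassigned"`, as are
#' zero-variance genes (which have no defined correlation).  This is the
#' correlation-clustering core of the WGCNA-style workflow (module count
#' fixed by the caller; soft-thresholding and topological overlap are
#' deliberately not part of this step).
#'
#' @param expression genes x cell-lines numeric matrix (>= 3 cell lines).
#' @param nModules target number of clusters for the tree cut.
#' @param minModuleSize smallest retained module.
#' @return an [ExpressionModuleSet-class].
#' @export
detectCoexpressionModules <- function(expression, nModules,
                                      minModuleSize = 5L) {
  stopIfNot(ncol(expression) >= 3L,
            "module detection needs at least 3 cell lines")
  stopIfNot(nModules <= nrow(expression),
            "cannot cut %d genes into %d modules",
            nrow(expression), nModules)
  variances <- apply(expression, 1L, stats::var)
  keep <- variances > 0
  assignment <- stats::setNames(rep("unassigned", nrow(expression)),
                                rownames(expression))
  if (sum(keep) >= 2L) {
    co <- stats::cor(t(expression[keep, , drop = FALSE]))
    d <- stats::as.dist(1 - abs(co))
    tree <- stats::hclust(d, method = "average")
    cut <- stats::cutree(tree, k = min(nModules, sum(keep)))
    sizes <- table(cut)
    small <- as.integer(names(sizes)[sizes < minModuleSize])
    lab <- ifelse(cut %in% small, "unassigned",
                  padId("M", cut, max(cut)))
    assignment[names(cut)] <- lab
  }
  mods <- sort(setdiff(unique(assignment), "unassigned"))
  means <- moduleMeanFeatures(expression, assignment)
  new("ExpressionModuleSet", assignment = assignment,
      moduleMeans = means[mods, , drop = FALSE])
}

#' Module mean-expression features
#'
#' For each module, the mean expression of its member genes per cell line;
#' the module x cell-line matrix used as the "gene expression modules"
#' feature class.  Empty modules are dropped with a warning.
#'
#' @param expression genes x cell-lines numeric matrix.
#' @param modules an [ExpressionModuleSet-class] or a named gene -> module
#'   character vector; `"unassigned"` genes are excluded.
#' @return numeric matrix, modules x cell lines.
#' @export
moduleMeanFeatures <- function(expression, modules) {
  assignment <- if (is(modules, "ExpressionModuleSet"))
    modules@assignment else modules
  assignment <- assignment[intersect(names(assignment),
                                     rownames(expression))]
  mods <- sort(setdiff(unique(assignment), "unassigned"))
  empty <- mods[!mods %in% assignment]
  if (length(empty))
    warning("dropping empty module(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  rows <- lapply(mods, function(m) {
    members <- names(assignment)[assignment == m]
    colMeans(expression[members, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- mods
  out
}

#' Module eigengene features
#'
#' Alternative module summary: the first principal component of the
#' member genes' expression (sign fixed so the eigengene correlates
#' positively with the module mean).
#'
#' @inheritParams moduleMeanFeatures
#' @return numeric matrix, modules x cell lines.
#' @export
moduleEigengeneFeatures <- function(expression, modules) {
  assignment <- if (is(modules, "ExpressionModuleSet"))
    modules@assignment else modules
  mods <- sort(setdiff(unique(assignment), "unassigned"))
  rows <- lapply(mods, function(m) {
    members <- names(assignment)[assignment == m]
    x <- expression[members, , drop = FALSE]
    pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)$x[, 1L]
    mm <- colMeans(x)
    if (stats::sd(mm) > 0 && stats::cor(pc, mm) < 0) pc <- -pc
    pc
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(mods, colnames(expression))
  out
}

#' Hypergeometric term enrichment of a gene module
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' number of term-annotated genes in the module, with Bonferroni
#' correction over the number of terms tested.  Terms with no annotated
#' genes in the universe are skipped.
#'
#' @param moduleGenes character vector of module member genes (must be a
#'   subset of `universe`).
#' @param annotation named list term -> character vector of genes.
#' @param universe character vector, the gene universe.
#' @return data.frame with columns `term`, `overlap`, `termSize`,
#'   `pRaw`, `pBonferroni`, sorted by `pRaw`.
#' @export
moduleEnrichment <- function(moduleGenes, annotation, universe) {
  stopIfNot(all(moduleGenes %in% universe),
            "module genes must be contained in the universe")
  sizes <- vapply(annotation, function(g)
    length(intersect(g, universe)), integer(1))
  annotation <- annotation[sizes > 0L]
  sizes <- sizes[sizes > 0L]
  nTerms <- length(annotation)
  n <- length(moduleGenes)
  N <- length(universe)
  rows <- lapply(names(annotation), function(term) {
    K <- sizes[[term]]
    k <- length(intersect(annotation[[term]], moduleGenes))
    # P(X >= k) for X ~ Hypergeom(N, K, n)
    pRaw <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, termSize = K, pRaw = pRaw,
               pBonferroni = min(1, pRaw * nTerms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$pRaw), , drop = FALSE]
}

#' Binary mutation features restricted to cancer genes
#'
#' Keeps the variants whose gene is in the cancer-gene list and which
#' occur in at least one of the cell lines of interest; each kept variant
#' becomes a binary cell-line feature.  `perGene = TRUE` aggregates to one
#' column per mutated cancer gene instead.
#'
#' @param mutations data.frame with columns `cellLine`, `gene`, `variant`
#'   (see [loadMutations()]).
#' @param cancerGenes character vector of cancer-pathway genes.
#' @param cellLines cell lines defining the columns of the output (and the
#'   "occurs at least once" filter).
#' @param perGene aggregate variants to genes.
#' @return binary integer matrix, cell lines x kept variants (or genes).
#' @export
filterSnps <- function(mutations, cancerGenes, cellLines,
                       perGene = FALSE) {
  keep <- mutations$gene %in% cancerGenes &
    mutations$cellLine %in% cellLines
  mut <- mutations[keep, , drop = FALSE]
  feat <- if (perGene) mut$gene else mut$variant
  cols <- sort(unique(feat))
  m <- matrix(0L, length(cellLines), length(cols),
              dimnames = list(cellLines, cols))
  if (nrow(mut)) m[cbind(mut$cellLine, feat)] <- 1L
  m
}

#' Two-sided correlation p-value via the Fisher r-to-z transformation
#'
#' `z = atanh(r) * sqrt(n - 3)`; `p = 2 * (1 - Phi(|z|))`.  `r = +/-1`
#' gives `p = 0`.
#'
#' @param r correlation in [-1, 1].
#' @param n sample size (>= 4).
#' @return two-sided p-value.
#' @export
fisherZPvalue <- function(r, n) {
  stopIfNot(all(n >= 4L), "Fisher r-to-z needs n >= 4")
  stopIfNot(all(abs(r) <= 1), "correlations must lie in [-1, 1]")
  z <- atanh(pmin(pmax(r, -1), 1)) * sqrt(n - 3)
  ifelse(abs(r) == 1, 0, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Select copy-number features by expression correlation
#'
#' Per gene, the Spearman correlation (average ranks; constant vectors
#' give r = 0) between copy number and expression across cell lines, with
#' a Fisher r-to-z p-value.  A gene is selected when it is in the
#' cancer-gene list, `p < alpha`, and its correlation exceeds both the
#' median correlation over all genes and `rMin`.  Selected genes' copy
#' numbers become the "copy number" feature class.
#'
#' @param cnv,expression genes x cell-lines matrices sharing dimnames.
#' @param cancerGenes character vector of cancer-pathway genes.
#' @param alpha significance level (default 0.01).
#' @param rMin correlation floor (default 0.17).
#' @return data.frame with columns `gene`, `spearman`, `p`, `selected`;
#'   the all-gene median correlation is in attribute `medianR`.
#' @export
selectCnvGenes <- function(cnv, expression, cancerGenes, alpha = 0.01,
                           rMin = 0.17) {
  genes <- intersect(rownames(cnv), rownames(expression))
  cells <- intersect(colnames(cnv), colnames(expression))
  stopIfNot(length(cells) >= 4L,
            "CNV selection needs at least 4 shared cell lines")
  r <- vapply(genes, function(g)
    spearmanSafe(cnv[g, cells], expression[g, cells]), numeric(1))
  p <- fisherZPvalue(r, length(cells))
  medianR <- stats::median(r)
  selected <- genes %in% cancerGenes & p < alpha & r > medianR & r > rMin
  out <- data.frame(gene = genes, spearman = unname(r), p = unname(p),
                    selected = selected, stringsAsFactors = FALSE)
  attr(out, "medianR") <- medianR
  out
}

#' Write module assignments as a two-column CSV
#'
#' @param modules an [ExpressionModuleSet-class].
#' @param path output CSV path (columns `GENE`, `MODULE`).
#' @return `path`, invisibly.
#' @export
writeModuleAssignments <- function(modules, path) {
  utils::write.csv(data.frame(GENE = names(modules@assignment),
                              MODULE = unname(modules@assignment)),
                   path, row.names = FALSE)
  invisible(path)
}
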