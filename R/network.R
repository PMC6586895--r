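## Drug synergy network and link-prediction proximity features.

#' Majority-rule synergy label for one combination
#'
#' A combination is called synergistic when strictly more than half of its
#' synergy scores across cell lines exceed the threshold (strict
#' inequality on the score, strict majority on the count: a tie is not a
#' majority).
#'
#' @param scores numeric vector of the combination's synergy scores.
#' @param threshold synergy threshold (default 20, the operational
#'   threshold on the Loewe-excess scale).
#' @return single logical.
#' @export
labelCombinationSynergistic <- function(scores, threshold = 20) {
  stopIfNot(length(scores) > 0, "cannot label a combination without scores")
  sum(scores > threshold) > length(scores) / 2
}

#' Build the drug synergy network
#'
#' Nodes are all drugs appearing in the input combinations; an edge joins
#' the two drugs of every majority-synergistic combination
#' ([labelCombinationSynergistic()]).
#'
#' @param experiments data.frame in [loadScreen()] layout (training
#'   experiments only, when the network feeds cross-validated features).
#' @param threshold synergy threshold.
#' @return a [SynergyNetwork-class].
#' @export
buildSynergyNetwork <- function(experiments, threshold = 20) {
  nodes <- sort(unique(c(experiments$drugA, experiments$drugB)))
  key <- paste(experiments$drugA, experiments$drugB, sep = "\r")
  syn <- vapply(split(experiments$synergy, key),
                labelCombinationSynergistic, logical(1),
                threshold = threshold)
  edgeKeys <- names(syn)[syn]
  edges <- if (length(edgeKeys))
    do.call(rbind, strsplit(edgeKeys, "\r", fixed = TRUE))
  else matrix(character(), 0L, 2L)
  new("SynergyNetwork", nodes = nodes, edges = edges)
}

#' @rdname networkNeighbors
#' @export
setMethod("networkNeighbors", "SynergyNetwork", function(net, node) {
  e <- net@edges
  if (!nrow(e)) return(character())
  sort(unique(c(e[e[, 1L] == node, 2L], e[e[, 2L] == node, 1L])))
})

#' Link-prediction proximity features on the synergy network
#'
#' The three indices used as combination features, for a drug pair
#' (x, y) with neighbor sets Gamma(x), Gamma(y):
#' \describe{
#'   \item{`commonNeighbors`}{`|Gamma(x) n Gamma(y)|`}
#'   \item{`jaccardCoefficient`}{`|Gamma(x) n Gamma(y)| / |Gamma(x) u
#'     Gamma(y)|`, defined as 0 when the union is empty}
#'   \item{`adamicAdar`}{`sum over z in Gamma(x) n Gamma(y) of
#'     1 / log |Gamma(z)|` (natural logarithm); any common neighbor of two
#'     distinct drugs has degree >= 2, so every term is finite}
#' }
#' Drugs absent from the network are treated as isolated nodes.  All three
#' are symmetric in (x, y).
#'
#' @param net a [SynergyNetwork-class].
#' @param x,y drug ids.
#' @return a single number.
#' @export
commonNeighbors <- function(net, x, y) {
  length(intersect(networkNeighbors(net, x), networkNeighbors(net, y)))
}

#' @rdname commonNeighbors
#' @export
jaccardCoefficient <- function(net, x, y) {
  nx <- networkNeighbors(net, x)
  ny <- networkNeighbors(net, y)
  u <- length(union(nx, ny))
  if (u == 0L) 0 else length(intersect(nx, ny)) / u
}

#' @rdname commonNeighbors
#' @export
adamicAdar <- function(net, x, y) {
  common <- intersect(networkNeighbors(net, x), networkNeighbors(net, y))
  if (!length(common)) return(0)
  deg <- vapply(common, function(z) length(networkNeighbors(net, z)),
                numeric(1))
  sum(1 / log(deg))
}

#' Remove one edge from a synergy network
#'
#' @param net a [SynergyNetwork-class].
#' @param x,y endpoints of the edge to delete (order irrelevant); deleting
#'   an absent edge is a no-op.
#' @return a [SynergyNetwork-class].
#' @export
dropEdge <- function(net, x, y) {
  p <- canonicalPair(x, y)
  keep <- !(net@edges[, 1L] == p[1L] & net@edges[, 2L] == p[2L])
  new("SynergyNetwork", nodes = net@nodes,
      edges = net@edges[keep, , drop = FALSE])
}

#' Network proximity features for drug pairs
#'
#' Builds the synergy network from the training experiments only and
#' computes the three proximity indices for each query pair.  By default a
#' leakage guard removes the queried pair's own edge (if present) before
#' computing its features, so a pair never sees its own training label;
#' `wholeNetwork = TRUE` disables the guard and scores every pair on the
#' full network.
#'
#' @param trainExperiments data.frame in [loadScreen()] layout.
#' @param queryPairs two-column character matrix or data.frame of drug
#'   pairs; drugs unseen in training are isolated (all features 0).
#' @param threshold synergy threshold for [buildSynergyNetwork()].
#' @param wholeNetwork disable the self-edge leakage guard.
#' @return data.frame with columns `drugA`, `drugB`, `commonNeighbors`,
#'   `jaccard`, `adamicAdar`.
#' @export
pairNetworkFeatures <- function(trainExperiments, queryPairs,
                                threshold = 20, wholeNetwork = FALSE) {
  net <- buildSynergyNetwork(trainExperiments, threshold)
  queryPairs <- as.matrix(queryPairs)
  out <- data.frame(drugA = queryPairs[, 1L], drugB = queryPairs[, 2L],
                    commonNeighbors = numeric(nrow(queryPairs)),
                    jaccard = numeric(nrow(queryPairs)),
                    adamicAdar = numeric(nrow(queryPairs)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(queryPairs))) {
    x <- queryPairs[i, 1L]; y <- queryPairs[i, 2L]
    g <- if (wholeNetwork) net else dropEdge(net, x, y)
    out$commonNeighbors[i] <- commonNeighbors(g, x, y)
    out$jaccard[i] <- jaccardCoefficient(g, x, y)
    out$adamicAdar[i] <- adamicAdar(g, x, y)
  }
  out
}

#' Export a synergy network as an edge list
#'
#' @param net a [SynergyNetwork-class].
#' @param path output path for a two-column tab-separated edge list.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
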