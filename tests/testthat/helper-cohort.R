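# Shared fixtures (built in code) and independent brute-force oracles.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# A small, fast cohort for unit tests.
smallConfig <- function(seed = 7L, ...) {
  simConfig(nDrugs = 12, nCellLines = 10, nCombos = 25, nGenes = 60,
            nModules = 3, nProteins = 15, nPathways = 8, nDomains = 12,
            coverage = 0.6, seed = seed, ...)
}

smallCohort <- function() memo("smallCohort", generateCohort(smallConfig()))

# The default study cohort (generator defaults; the conditions every
# recovery check runs under).
defaultCohort <- function() memo("defaultCohort",
                                 generateCohort(simConfig(seed = 42L)))

defaultFeatureMatrix <- function() memo("defaultFM",
                                        buildCohortFeatureMatrix(defaultCohort()))

# --- independent brute-force link-prediction oracle (set operations on an
# --- explicit edge list; never touches the package's network class)
bfNeighbors <- function(edges, v) {
  if (!nrow(edges)) return(character())
  unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
}
bfCommonNeighbors <- function(edges, x, y)
  length(intersect(bfNeighbors(edges, x), bfNeighbors(edges, y)))
bfJaccard <- function(edges, x, y) {
  nx <- bfNeighbors(edges, x); ny <- bfNeighbors(edges, y)
  u <- union(nx, ny)
  if (!length(u)) 0 else length(intersect(nx, ny)) / length(u)
}
bfAdamicAdar <- function(edges, x, y) {
  common <- intersect(bfNeighbors(edges, x), bfNeighbors(edges, y))
  if (!length(common)) return(0)
  sum(vapply(common, function(z) 1 / log(length(bfNeighbors(edges, z))),
             numeric(1)))
}

# Toy graph used across network tests: edges A-B, A-C, B-C, C-D.
toyNetwork <- function() {
  new("SynergyNetwork", nodes = c("A", "B", "C", "D"),
      edges = rbind(c("A", "B"), c("A", "C"), c("B", "C"), c("C", "D")))
}

# Write a minimal well-formed screen CSV; returns the path.
writeTempScreen <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste(c("COMBINATION_ID", "DRUG_A", "DRUG_B", "CELL_LINE",
                    "SYNERGY_SCORE",
                    "MAX_CONC_A", "IC50_A", "H_A", "Einf_A", "QA_A",
                    "MAX_CONC_B", "IC50_B", "H_B", "Einf_B", "QA_B"),
                  collapse = ",")
  writeLines(c(header, rows), path)
  path
}

# Adjusted Rand index between two labelings (independent oracle: mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
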