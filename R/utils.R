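## Internal helpers shared across modules.

# Derive an independent substream seed from a master seed and a component
# name, so that e.g. enlarging the gene universe does not perturb the screen
# sample.  Kept below 2^31 - 1 (R integers are 32-bit).
substreamSeed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

withSubstream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substreamSeed(seed, component))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Canonical unordered drug pair: lexicographic order of the two ids.
canonicalPair <- function(a, b) {
  swap <- a > b
  cbind(ifelse(swap, b, a), ifelse(swap, a, b))
}

stopIfNot <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}

#' Screened fraction of a combination x cell-line grid
#'
#' The coverage of a combination screen: the number of measured
#' (combination, cell line) experiments divided by the size of the full
#' grid.  For the public screen this pipeline was designed around, 2790
#' experiments over 167 combinations and 85 cell lines give 19.6\%.
#'
#' @param nExperiments number of screened experiments, or a data.frame of
#'   experiments as returned by [loadScreen()] (rows counted, grid inferred
#'   from the distinct combinations and cell lines).
#' @param nCombinations,nCellLines grid dimensions (ignored when a
#'   data.frame is given).
#' @param percent return a percentage instead of a fraction.
#' @return a single numeric value.
#' @examples
#' screenCoverage(2790, 167, 85, percent = TRUE)  # 19.6
#' @export
screenCoverage <- function(nExperiments, nCombinations = NULL,
                           nCellLines = NULL, percent = FALSE) {
  if (is.data.frame(nExperiments)) {
    df <- nExperiments
    nCombinations <- length(unique(df$combination))
    nCellLines <- length(unique(df$cellLine))
    nExperiments <- nrow(df)
  }
  stopIfNot(!is.null(nCombinations) && !is.null(nCellLines),
            "grid dimensions are required")
  frac <- nExperiments / (nCombinations * nCellLines)
  if (percent) 100 * frac else frac
}
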