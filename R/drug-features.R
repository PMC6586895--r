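## Combination-level drug features: MACCS pair-sums, target/domain/pathway
## set encodings, monotherapy vectors.

#' MACCS structural-key fingerprint providers
#'
#' A fingerprint provider is a function mapping one SMILES string to a
#' binary vector of length 166 (the MACCS key dictionary).
#' `openBabelFingerprintProvider()` computes keys with the OpenBabel
#' toolkit via the ChemmineOB package (OpenBabel pads its fingerprints to
#' 256 bits; the 166 keys occupy the leading positions and the provider
#' truncates accordingly).  `tableFingerprintProvider()` serves
#' precomputed fingerprints from a `DRUG_ID -> bit string` table and needs
#' no chemistry toolkit; it looks drugs up by identifier rather than by
#' structure.
#'
#' @param path CSV with columns `DRUG_ID` and `BITS` (a string of 166
#'   `0`/`1` characters), as written by [writeCohort()].
#' @return a function `f(smiles)` (or `f(drugId)` for the table provider)
#'   returning an integer vector of length 166 with a logical attribute
#'   `missing`.
#' @seealso [maccsFingerprint()]
#' @export
openBabelFingerprintProvider <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("the OpenBabel provider needs the ChemmineOB package",
         call. = FALSE)
  function(smiles) {
    if (is.na(smiles) || !nzchar(smiles))
      return(structure(integer(166L), missing = TRUE))
    mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                    error = function(e) NULL)
    if (is.null(mol))
      stop("unparseable SMILES: ", smiles, call. = FALSE)
    bits <- ChemmineOB::fingerprint_OB(mol, "MACCS")
    structure(as.integer(bits[seq_len(166L)]), missing = FALSE)
  }
}

#' @rdname openBabelFingerprintProvider
#' @export
tableFingerprintProvider <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(BITS = "character"))
  stopIfNot(all(c("DRUG_ID", "BITS") %in% colnames(tab)),
            "fingerprint table needs DRUG_ID and BITS columns")
  bits <- lapply(tab$BITS, function(b)
    as.integer(strsplit(b, "", fixed = TRUE)[[1L]]))
  stopIfNot(all(lengths(bits) == 166L),
            "fingerprint bit strings must have length 166")
  names(bits) <- tab$DRUG_ID
  function(id) {
    if (is.na(id) || is.null(bits[[id]]))
      return(structure(integer(166L), missing = TRUE))
    structure(bits[[id]], missing = FALSE)
  }
}

#' Compute a MACCS key fingerprint
#'
#' Maps a SMILES string to the 166-bit MACCS structural-key vector through
#' a pluggable provider.  A missing SMILES yields the all-zero vector with
#' the `missing` attribute set (downstream assembly adds a missingness
#' indicator column); an unparseable non-empty SMILES is an error naming
#' the input.
#'
#' @param smiles a SMILES string, or `NA`.
#' @param provider a provider function, by default the OpenBabel one.
#' @return integer vector of length 166 with entries in \{0, 1\} and a
#'   logical attribute `missing`.
#' @examples
#' \dontrun{maccsFingerprint("CC(=O)Oc1ccccc1C(=O)O")  # aspirin}
#' @export
maccsFingerprint <- function(smiles,
                             provider = openBabelFingerprintProvider()) {
  fp <- provider(smiles)
  stopIfNot(length(fp) == 166L && all(fp %in% c(0L, 1L)),
            "provider must return a binary vector of length 166")
  fp
}

#' Pair-sum encoding of two binary feature vectors
#'
#' The combination-level encoding used for fingerprints, targets, domains
#' and pathways: the elementwise sum of the two drugs' binary vectors, so
#' a 2 marks a feature shared by both drugs, a 1 a feature of exactly one,
#' and a 0 a feature of neither.  Symmetric in its arguments.
#'
#' @param vecA,vecB binary vectors of equal length.
#' @return integer vector with entries in \{0, 1, 2\}.
#' @export
pairSum <- function(vecA, vecB) {
  stopIfNot(length(vecA) == length(vecB),
            "pair-sum requires equal-length vectors (%d vs %d)",
            length(vecA), length(vecB))
  stopIfNot(all(vecA %in% c(0, 1)) && all(vecB %in% c(0, 1)),
            "pair-sum operands must be binary")
  as.integer(vecA) + as.integer(vecB)
}

#' Pair-sum encoding of two id sets over a vocabulary
#'
#' Indicator-encodes each drug's id set over an ordered vocabulary and
#' pair-sums the indicators.  Ids outside the vocabulary are dropped with
#' a warning (putative annotation lists are incomplete and may reference
#' entities the vocabulary lacks).
#'
#' @param setA,setB character vectors of feature ids.
#' @param vocabulary ordered character vector of all feature ids.
#' @return named integer vector over `vocabulary` with entries in
#'   \{0, 1, 2\}.
#' @export
setPairFeatures <- function(setA, setB, vocabulary) {
  stopIfNot(length(vocabulary) > 0, "empty feature vocabulary")
  unknown <- setdiff(union(setA, setB), vocabulary)
  if (length(unknown))
    warning("ignoring id(s) outside the vocabulary: ",
            paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  a <- as.integer(vocabulary %in% setA)
  b <- as.integer(vocabulary %in% setB)
  stats::setNames(a + b, vocabulary)
}

#' Derive domain and pathway sets from a drug's protein targets
#'
#' Unions, over the drug's targets, each protein's structural domains
#' (from up to four sources, each id namespaced by its source to prevent
#' cross-source collisions) and its pathways.  Proteins absent from every
#' map contribute nothing.
#'
#' @param targets character vector of protein ids.
#' @param domainMaps named list of domain sources, each a named list
#'   protein -> character vector of namespaced domain ids.
#' @param pathwayMap named list protein -> character vector of pathway ids.
#' @return list with character elements `domains` and `pathways`.
#' @export
deriveDomainsPathways <- function(targets, domainMaps, pathwayMap) {
  domains <- sort(unique(unlist(lapply(domainMaps, function(m)
    unlist(m[intersect(targets, names(m))])))))
  pathways <- sort(unique(unlist(pathwayMap[intersect(targets,
                                                      names(pathwayMap))])))
  list(domains = as.character(domains), pathways = as.character(pathways))
}

#' Concatenated domain vocabulary over the four sources
#'
#' @param domainMaps as in [deriveDomainsPathways()]; alternatively a list
#'   of per-source domain-id vectors.
#' @return character vector: the concatenation of the four sources'
#'   (namespaced) domain vocabularies, source order preserved.
#' @export
domainVocabulary <- function(domainMaps) {
  unlist(lapply(domainMaps, function(m) {
    ids <- if (is.list(m)) sort(unique(unlist(m))) else m
    as.character(ids)
  }), use.names = FALSE)
}

#' Monotherapy feature vector of one experiment
#'
#' Per canonical drug (lexicographic order within the combination):
#' maximum assay concentration, IC50, an IC50 censoring flag, Hill
#' coefficient, maximal kill and the quality flag -- 12 values per
#' experiment.  An IC50 that was not reached within the tested
#' concentration range (missing) is imputed with the drug's maximum
#' concentration and flagged (`censor = 1`), preserving the ordering
#' information that the drug is at least that resistant.
#'
#' @param experiments data.frame in [loadScreen()] layout.
#' @return numeric matrix, experiments x 12, with columns
#'   `mono_maxConc_a`, `mono_ic50_a`, `mono_ic50Censored_a`, `mono_h_a`,
#'   `mono_einf_a`, `mono_qa_a` and the `_b` counterparts.
#' @export
monotherapyFeatures <- function(experiments) {
  block <- function(side) {
    s <- toupper(side)
    ic50 <- experiments[[paste0("ic50", s)]]
    maxc <- experiments[[paste0("maxConc", s)]]
    censored <- as.numeric(is.na(ic50))
    cbind(maxc, ifelse(is.na(ic50), maxc, ic50), censored,
          experiments[[paste0("h", s)]], experiments[[paste0("einf", s)]],
          experiments[[paste0("qa", s)]])
  }
  m <- cbind(block("a"), block("b"))
  colnames(m) <- paste0("mono_",
                        rep(c("maxConc", "ic50", "ic50Censored", "h",
                              "einf", "qa"), 2L),
                        rep(c("_a", "_b"), each = 6L))
  rownames(m) <- paste(experiments$combination, experiments$cellLine,
                       sep = " / ")
  m
}
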