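## Readers and writers for the screen's delimited-text release formats.

SCREEN_COLUMNS <- c("COMBINATION_ID", "DRUG_A", "DRUG_B", "CELL_LINE",
                    "SYNERGY_SCORE",
                    "MAX_CONC_A", "IC50_A", "H_A", "Einf_A", "QA_A",
                    "MAX_CONC_B", "IC50_B", "H_B", "Einf_B", "QA_B")

MONO_FIELDS <- c("maxConc", "ic50", "h", "einf", "qa")

#' Read a combination-screen table
#'
#' Reads the screen release format: one row per (drug combination,
#' cell line) experiment carrying the Loewe-excess synergy score and the
#' two drugs' monotherapy dose-response parameters (maximum assay
#' concentration, IC50, Hill coefficient, maximal kill, quality flag).
#' Within each row the two drugs are canonicalized to lexicographic order
#' and the monotherapy blocks follow them, so a screen written with the
#' drugs swapped loads to an identical table.  An empty IC50 cell is kept
#' as `NA` (the drug's IC50 was not reached within the tested range;
#' imputation happens at feature-construction time, not here).
#'
#' @param path path to a CSV file with header columns `COMBINATION_ID,
#'   DRUG_A, DRUG_B, CELL_LINE, SYNERGY_SCORE, MAX_CONC_A, IC50_A, H_A,
#'   Einf_A, QA_A, MAX_CONC_B, IC50_B, H_B, Einf_B, QA_B`.
#' @return data.frame with columns `combination`, `drugA`, `drugB`,
#'   `cellLine`, `synergy` and the ten monotherapy columns `maxConcA`,
#'   `ic50A`, `hA`, `einfA`, `qaA`, `maxConcB`, ..., `qaB`; one row per
#'   experiment, keyed uniquely by (combination, cellLine).
#' @seealso [writeScreen()], [experimentsFromCohort()]
#' @export
loadScreen <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(SCREEN_COLUMNS, colnames(raw))
  if (length(missing))
    stop("screen table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  syn <- suppressWarnings(as.numeric(raw$SYNERGY_SCORE))
  bad <- which(is.na(syn) & !is.na(raw$SYNERGY_SCORE))
  bad <- union(bad, which(is.na(raw$SYNERGY_SCORE)))
  if (length(bad))
    stop("non-numeric or missing SYNERGY_SCORE at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  df <- data.frame(
    combination = as.character(raw$COMBINATION_ID),
    drugA = as.character(raw$DRUG_A), drugB = as.character(raw$DRUG_B),
    cellLine = as.character(raw$CELL_LINE), synergy = syn,
    stringsAsFactors = FALSE)
  for (side in c("A", "B")) {
    df[[paste0("maxConc", side)]] <- as.numeric(raw[[paste0("MAX_CONC_", side)]])
    df[[paste0("ic50", side)]] <- suppressWarnings(as.numeric(raw[[paste0("IC50_", side)]]))
    df[[paste0("h", side)]] <- as.numeric(raw[[paste0("H_", side)]])
    df[[paste0("einf", side)]] <- as.numeric(raw[[paste0("Einf_", side)]])
    df[[paste0("qa", side)]] <- as.numeric(raw[[paste0("QA_", side)]])
  }
  df <- canonicalizeExperiments(df)
  key <- paste(df$combination, df$cellLine, sep = " / ")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicated (combination, cell line) experiment(s): ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  rownames(df) <- NULL
  df
}

# Swap drug A/B (and their monotherapy blocks) into lexicographic order.
canonicalizeExperiments <- function(df) {
  swap <- df$drugA > df$drugB
  if (any(swap)) {
    tmp <- df$drugA[swap]
    df$drugA[swap] <- df$drugB[swap]
    df$drugB[swap] <- tmp
    for (f in MONO_FIELDS) {
      a <- paste0(f, "A"); b <- paste0(f, "B")
      tmp <- df[[a]][swap]
      df[[a]][swap] <- df[[b]][swap]
      df[[b]][swap] <- tmp
    }
  }
  df
}

#' Write a combination-screen table
#'
#' Inverse of [loadScreen()]: writes the release CSV format so that
#' `loadScreen(writeScreen(x, f))` reproduces `x` up to float formatting.
#'
#' @param experiments data.frame in the layout returned by [loadScreen()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeScreen <- function(experiments, path) {
  out <- data.frame(
    COMBINATION_ID = experiments$combination,
    DRUG_A = experiments$drugA, DRUG_B = experiments$drugB,
    CELL_LINE = experiments$cellLine,
    SYNERGY_SCORE = experiments$synergy,
    MAX_CONC_A = experiments$maxConcA, IC50_A = experiments$ic50A,
    H_A = experiments$hA, Einf_A = experiments$einfA, QA_A = experiments$qaA,
    MAX_CONC_B = experiments$maxConcB, IC50_B = experiments$ic50B,
    H_B = experiments$hB, Einf_B = experiments$einfB, QA_B = experiments$qaB,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a drug annotation table
#'
#' @param path CSV with columns `DRUG_ID`, `SMILES` (may be empty) and
#'   `TARGETS` (semicolon-separated protein ids, may be empty).
#' @return data.frame with columns `drug` and `smiles` (`NA` when absent)
#'   and a list-column `targets` of character vectors.
#' @export
loadDrugAnnotations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("DRUG_ID", "SMILES", "TARGETS")
  missing <- setdiff(need, colnames(raw))
  if (length(missing))
    stop("drug table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  targets <- lapply(raw$TARGETS, function(t) {
    if (is.na(t) || !nzchar(t)) character() else
      unique(trimws(strsplit(t, ";", fixed = TRUE)[[1L]]))
  })
  data.frame(drug = as.character(raw$DRUG_ID),
             smiles = as.character(raw$SMILES),
             targets = I(targets), stringsAsFactors = FALSE)
}

#' Read a GMT-style gene/protein set file
#'
#' GMT is the tab-separated set format used for the protein-to-domain,
#' protein-to-pathway and cancer-gene vocabularies: one set per line as
#' `set_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#'
#' @param path GMT file path.
#' @return named list of character member vectors.
#' @export
loadGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed GMT line: ", substr(l, 1, 60), call. = FALSE)
    members <- parts[-c(1L, 2L)]
    members[nzchar(members)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' Write a GMT-style set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(id, desc, members)
    paste(c(id, desc, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes x cell-lines omics matrix
#'
#' @param path CSV whose first column holds gene ids and remaining columns
#'   one cell line each.
#' @param integerValues coerce values to integers (copy-number tables).
#' @return numeric matrix, genes in rows, cell lines in columns.
#' @export
loadOmicsMatrix <- function(path, integerValues = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- if (integerValues) "integer" else "double"
  rownames(m) <- as.character(raw[[1L]])
  m
}

#' Write a genes x cell-lines omics matrix
#' @param m numeric matrix with gene rownames and cell-line colnames.
#' @param path output CSV path.
#' @param idColumn name of the leading id column.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(m, path, idColumn = "GENE") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mutation call table
#'
#' @param path CSV with columns `CELL_LINE`, `GENE`, `VARIANT_ID`.
#' @return data.frame with columns `cellLine`, `gene`, `variant`.
#' @export
loadMutations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("CELL_LINE", "GENE", "VARIANT_ID")
  missing <- setdiff(need, colnames(raw))
  if (length(missing))
    stop("mutation table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  data.frame(cellLine = as.character(raw$CELL_LINE),
             gene = as.character(raw$GENE),
             variant = as.character(raw$VARIANT_ID),
             stringsAsFactors = FALSE)
}

#' Read cell-line metadata
#'
#' @param path CSV with columns `CELL_LINE`, `TISSUE`, `DISEASE`, `SEX`.
#' @return data.frame with columns `cellLine`, `tissue`, `disease`, `sex`.
#' @export
loadCellLineInfo <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("CELL_LINE", "TISSUE", "DISEASE", "SEX")
  missing <- setdiff(need, colnames(raw))
  if (length(missing))
    stop("cell-line table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  data.frame(cellLine = as.character(raw$CELL_LINE),
             tissue = as.character(raw$TISSUE),
             disease = as.character(raw$DISEASE),
             sex = as.character(raw$SEX), stringsAsFactors = FALSE)
}
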