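#' Read a genes x samples expression matrix from TSV
#'
#' Expects the cBioPortal tab-delimited export dialect: first column
#' `Hugo_Symbol` (any name is accepted), remaining columns one per sample.
#' Empty cells and `NA` become missing values, never zero.
#'
#' @param path path to a tab-delimited file.
#' @return numeric matrix, genes as rows (rownames = symbols), samples as
#'   columns.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                           colClasses = "character", na.strings = c("NA", ""))
  if (ncol(raw) < 2) stopf("expression file needs >= 1 sample column: %s", path)
  genes <- raw[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stopf("duplicate gene symbol(s) in %s: %s", path, paste(dup, collapse = ", "))
  ids <- colnames(raw)[-1]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate sample id(s) in %s: %s", path, paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-numeric expression value at gene '%s', sample '%s': '%s'",
          genes[bad[1, 1]], ids[bad[1, 2]], vals[bad[1, 1], bad[1, 2]])
  dimnames(num) <- list(genes, ids)
  num
}

#' Read a clinical table from TSV
#'
#' Required columns: `sample_id`, `os_months` (overall survival, months),
#' `event` (TRUE/1/DECEASED for death observed, FALSE/0/LIVING for censored,
#' i.e. alive at end of study). Optional: `grade` (II/III/IV, arabic 2/3/4
#' also accepted), `idh1_mutated`, `dfs_months`. Unknown grade values become
#' missing with a warning; missing optional columns are filled with NA so
#' ungraded analyses still run.
#'
#' @param path path to a tab-delimited file.
#' @return data.frame with columns sample_id, os_months, event, grade,
#'   idh1_mutated, dfs_months.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                           colClasses = "character", na.strings = c("NA", ""))
  need <- c("sample_id", "os_months", "event")
  missing <- setdiff(need, colnames(raw))
  if (length(missing))
    stopf("clinical file %s lacks required column(s): %s", path,
          paste(missing, collapse = ", "))
  id <- raw$sample_id
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stopf("duplicate sample_id(s): %s", paste(dup, collapse = ", "))
  os <- suppressWarnings(as.numeric(raw$os_months))
  if (any(is.na(os) & !is.na(raw$os_months)))
    stopf("non-numeric os_months for sample '%s'",
          id[which(is.na(os) & !is.na(raw$os_months))[1]])
  if (any(os < 0, na.rm = TRUE))
    stopf("negative os_months for sample '%s'", id[which(os < 0)[1]])
  event <- parse_event(raw$event, id)
  grade <- if ("grade" %in% colnames(raw)) parse_grade(raw$grade) else
    factor(rep(NA_character_, nrow(raw)), levels = c("II", "III", "IV"))
  idh1 <- if ("idh1_mutated" %in% colnames(raw)) {
    parse_logical(raw$idh1_mutated)
  } else rep(NA, nrow(raw))
  dfs <- if ("dfs_months" %in% colnames(raw)) {
    suppressWarnings(as.numeric(raw$dfs_months))
  } else rep(NA_real_, nrow(raw))
  data.frame(sample_id = id, os_months = os, event = event, grade = grade,
             idh1_mutated = idh1, dfs_months = dfs, stringsAsFactors = FALSE)
}

parse_event <- function(x, id) {
  key <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[key %in% c("TRUE", "T", "1", "DECEASED", "DEAD", "YES")] <- TRUE
  out[key %in% c("FALSE", "F", "0", "LIVING", "ALIVE", "NO")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stopf("unrecognized event value '%s' for sample '%s'",
          x[which(bad)[1]], id[which(bad)[1]])
  out
}

parse_logical <- function(x) {
  key <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[key %in% c("TRUE", "T", "1", "YES", "MUTATED")] <- TRUE
  out[key %in% c("FALSE", "F", "0", "NO", "WT", "WILD-TYPE", "WILDTYPE")] <- FALSE
  out
}

parse_grade <- function(x) {
  key <- toupper(trimws(x))
  map <- c("II" = "II", "2" = "II", "G2" = "II",
           "III" = "III", "3" = "III", "G3" = "III",
           "IV" = "IV", "4" = "IV", "G4" = "IV")
  out <- unname(map[key])
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown))
    warnf("unknown grade value(s) treated as missing: %s",
          paste(unique(x[unknown]), collapse = ", "))
  factor(out, levels = c("II", "III", "IV"))
}

#' Load one of the shipped iron gene panels
#'
#' Three panels ship with the package. `"selected8"` is the eight-gene
#' prognostic signature (STEAP3, HFE, TMPRSS6, SFXN1, TFRC, UROS, SLC11A2,
#' STEAP4). `"irgs16"` and `"iron61"` are curated stand-ins for the 16-gene
#' iron regulatory gene signature (IRGS) and the wider 61-gene iron
#' metabolism set: the published panels are not enumerated in a
#' machine-readable source, so these files (marked `_synthetic` on disk)
#' assemble canonical iron-handling genes — uptake, storage, export, heme
#' synthesis, iron-sulfur cluster assembly — around the constraint that the
#' eight-gene signature is contained in both supersets.
#'
#' @param name `"selected8"`, `"irgs16"`, or `"iron61"`; alternatively a
#'   path to a panel file (one gene symbol per line, `#` comments allowed).
#' @return character vector of gene symbols, with a `panel` attribute
#'   holding the panel name.
#' @export
iron_panel <- function(name = c("selected8", "irgs16", "iron61")) {
  files <- c(selected8 = "panel_selected8.txt",
             irgs16 = "panel_irgs16_synthetic.txt",
             iron61 = "panel_iron61_synthetic.txt")
  if (length(name) == 1 && file.exists(name) && !name %in% names(files)) {
    return(read_panel(name))
  }
  name <- match.arg(name)
  path <- system.file("extdata", files[[name]], package = "ironsig",
                      mustWork = TRUE)
  genes <- read_panel(path)
  attr(genes, "panel") <- name
  genes
}

#' Read a gene panel file (one symbol per line)
#'
#' @param path panel file; blank lines and `#` comments are skipped.
#' @return character vector of unique gene symbols, `panel` attribute set
#'   to the file name.
#' @export
read_panel <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(genes)) stopf("panel file %s contains no genes", path)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stopf("duplicate gene(s) in panel %s: %s", path, paste(dup, collapse = ", "))
  attr(genes, "panel") <- sub("\\.txt$", "", basename(path))
  genes
}
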