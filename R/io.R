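#' Read an expression cohort from TSV files
#'
#' @param valuesPath TSV: gene ids in the first column, one column per
#'   sample, header row of sample ids.
#' @param groupPath TSV with columns `sample`, `group` (two levels).
#' @param cohortId cohort identifier (default: values file name).
#' @param caseLevel case group label (default `"case"`).
#' @return an [ExpressionCohort-class].
#' @seealso [writeExpressionCohort()]
#' @export
readExpressionCohort <- function(valuesPath, groupPath,
                                 cohortId = basename(valuesPath),
                                 caseLevel = "case") {
    vals <- read.delim(valuesPath, row.names = 1, check.names = FALSE)
    grp <- read.delim(groupPath, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(grp)))
        stop("group file must have columns sample, group")
    if (!setequal(grp$sample, colnames(vals)))
        stop("sample ids differ between values and group files")
    grp <- grp[match(colnames(vals), grp$sample), ]
    ExpressionCohort(as.matrix(vals), grp$group, cohortId = cohortId,
                     caseLevel = caseLevel)
}

#' Write an expression cohort as TSV files
#'
#' @param cohort an [ExpressionCohort-class].
#' @param valuesPath,groupPath output paths (see [readExpressionCohort()]).
#' @export
writeExpressionCohort <- function(cohort, valuesPath, groupPath) {
    vals <- exprValues(cohort)
    out <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, valuesPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(sample = colnames(vals),
                           group = as.character(cohortGroups(cohort))),
                groupPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(valuesPath)
}

#' Read a cell-line (or sample) group map
#'
#' @param path TSV with columns `cell_line`, `group`.
#' @return data.frame.
#' @export
readGroupMap <- function(path) {
    gm <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("cell_line", "group") %in% names(gm)))
        stop("group map must have columns cell_line, group")
    gm
}

#' Read long-format array scans
#'
#' @param path TSV with columns `membrane`, `cell_line`, `replicate`,
#'   `motif_id`, `intensity`.
#' @return data.frame.
#' @export
readArrayScans <- function(path) {
    sc <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("membrane", "cell_line", "replicate", "motif_id", "intensity")
    if (!all(need %in% names(sc)))
        stop("array scans must have columns: ", paste(need, collapse = ", "))
    sc
}

#' Read a survival cohort table
#'
#' @param path TSV with at least `time` and `event` columns; `grade` and
#'   `subtype` columns, when present, become factors with their first
#'   (reference) level as coded in `refLevels`.
#' @param refLevels named list of level orderings for categorical columns.
#' @return data.frame.
#' @export
readSurvivalCohort <- function(path,
                               refLevels = list(
                                   grade = c("G1", "G2", "G3", "GNA"),
                                   subtype = c("LumA", "LumB", "Normal",
                                               "Her2", "Basal"))) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("time", "event") %in% names(tab)))
        stop("survival table must have columns time, event")
    for (col in names(refLevels))
        if (col %in% names(tab))
            tab[[col]] <- factor(tab[[col]], levels = refLevels[[col]])
    tab
}

#' Write a generic result table as TSV
#'
#' @param table data.frame.
#' @param path output path.
#' @export
writeResultTable <- function(table, path) {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write promoter sequences as FASTA
#'
#' @param sequences named [Biostrings::DNAStringSet] (record id = gene id).
#' @param path output path.
#' @export
writePromoterFasta <- function(sequences, path) {
    Biostrings::writeXStringSet(sequences, path)
    invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return named [Biostrings::DNAStringSet].
#' @export
readPromoterFasta <- function(path) Biostrings::readDNAStringSet(path)
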