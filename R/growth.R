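#' Bin a relative-growth value
#'
#' Growth is a percentage of the non-targeting (siLuc) control. Bins follow
#' the screen's reporting scheme: `"<33"` for values below 33, `"33-66"` for
#' 33 through 66 inclusive, `">66"` above 66. A value of exactly 66 counts
#' as reduced growth.
#'
#' @param value numeric vector of relative-growth percentages (>= 0).
#' @return character vector of bins.
#' @export
binGrowth <- function(value) {
    if (any(value < 0)) stop("relative growth must be non-negative")
    ifelse(value < 33, "<33", ifelse(value <= 66, "33-66", ">66"))
}

.checkGrowthInputs <- function(table, groupMap) {
    if (!all(c("siRNA", "cell_line", "mean") %in% names(table)))
        stop("growth table must have columns siRNA, cell_line, mean")
    if (!all(c("cell_line", "group") %in% names(groupMap)))
        stop("groupMap must have columns cell_line, group")
    miss <- setdiff(unique(table$cell_line), groupMap$cell_line)
    if (length(miss))
        stop("cell line(s) without group label: ", paste(miss, collapse = ", "))
    setNames(groupMap$group, groupMap$cell_line)
}

#' Call growth-critical siRNAs
#'
#' An siRNA is critical when its mean relative growth is at or below
#' `reducedMax` (default 66, i.e. growth suppressed by at least one third)
#' in at least `minLines` (default 2) basal-like cell lines. siRNAs missing
#' basal-like measurements are excluded with a warning.
#'
#' @param table long data.frame with columns `siRNA`, `cell_line`, `mean`
#'   (percent growth relative to control) and optionally `sd`.
#' @param groupMap data.frame `cell_line`, `group` with groups `"BLBC"` and
#'   `"non-BLBC"`.
#' @param minLines minimum number of reduced basal-like lines (default 2).
#' @param reducedMax inclusive reduced-growth cutoff in percent (default 66).
#' @return character vector of critical siRNA ids, in input order.
#' @export
callCritical <- function(table, groupMap, minLines = 2, reducedMax = 66) {
    grp <- .checkGrowthInputs(table, groupMap)
    if (sum(groupMap$group == "BLBC") < minLines)
        stop("fewer than minLines BLBC lines in groupMap")
    sirnas <- unique(table$siRNA)
    blbc <- table[grp[table$cell_line] == "BLBC", , drop = FALSE]
    n_meas <- table(factor(blbc$siRNA, levels = sirnas))
    if (any(n_meas == 0)) {
        warning("siRNA(s) without BLBC measurements excluded: ",
                paste(sirnas[n_meas == 0], collapse = ", "))
        sirnas <- sirnas[n_meas > 0]
    }
    red <- tapply(blbc$mean <= reducedMax, factor(blbc$siRNA, levels = sirnas),
                  sum)
    sirnas[red[sirnas] >= minLines]
}

#' Classify hit specificity in the secondary growth screen
#'
#' For every siRNA, counts the basal-like and non-basal-like cell lines with
#' growth at or below `reducedMax` and assigns a class: critical siRNAs
#' (reduced in >= `minLines` basal-like lines) are `"BLBC-specific"` when no
#' non-basal-like line is reduced, `"moderately-specific"` with exactly one,
#' and `"general"` with two or more; all others are `"not-critical"`.
#'
#' @inheritParams callCritical
#' @return data.frame: `siRNA`, `n_blbc_reduced`, `n_nonblbc_reduced`,
#'   `class`, plus one `bin_<cell_line>` column per cell line.
#' @export
classifySpecificity <- function(table, groupMap, minLines = 2,
                                reducedMax = 66) {
    grp <- .checkGrowthInputs(table, groupMap)
    critical <- callCritical(table, groupMap, minLines, reducedMax)
    sirnas <- unique(table$siRNA)
    is_blbc <- grp[table$cell_line] == "BLBC"
    n_b <- tapply(table$mean <= reducedMax & is_blbc,
                  factor(table$siRNA, levels = sirnas), sum)
    n_n <- tapply(table$mean <= reducedMax & !is_blbc,
                  factor(table$siRNA, levels = sirnas), sum)
    cls <- ifelse(!sirnas %in% critical, "not-critical",
           ifelse(n_n[sirnas] == 0, "BLBC-specific",
           ifelse(n_n[sirnas] == 1, "moderately-specific", "general")))
    out <- data.frame(siRNA = sirnas,
                      n_blbc_reduced = as.integer(n_b[sirnas]),
                      n_nonblbc_reduced = as.integer(n_n[sirnas]),
                      class = cls, stringsAsFactors = FALSE)
    # per-line growth bins for reporting
    lines <- unique(table$cell_line)
    for (cl in lines) {
        v <- table$mean[table$cell_line == cl][
            match(sirnas, table$siRNA[table$cell_line == cl])]
        out[[paste0("bin_", cl)]] <- ifelse(is.na(v), NA, binGrowth(pmax(v, 0)))
    }
    rownames(out) <- NULL
    out
}

#' Read a growth-screen table
#'
#' @param path TSV with columns `siRNA`, `cell_line`, `mean`, `sd`.
#' @return data.frame.
#' @export
readGrowthTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("siRNA", "cell_line", "mean") %in% names(tab)))
        stop("growth table must have columns siRNA, cell_line, mean")
    tab
}
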