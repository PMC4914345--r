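#' Normalize array spot intensities to the reference spot
#'
#' Divides every spot intensity by the reference (TFIID) intensity of the
#' same membrane, so each membrane's values become relative binding
#' intensities with the reference mapping to 1. Rescaling a whole membrane
#' by a constant therefore leaves the output unchanged.
#'
#' @param scans long-format data.frame with columns `membrane`, `cell_line`,
#'   `replicate`, `motif_id`, `intensity`.
#' @param referenceId reference spot id (default `"TFIID"`).
#' @return the input with an added `rel_intensity` column.
#' @export
normalizeToReference <- function(scans, referenceId = "TFIID") {
    need <- c("membrane", "cell_line", "replicate", "motif_id", "intensity")
    if (!all(need %in% names(scans)))
        stop("scans must have columns: ", paste(need, collapse = ", "))
    refs <- scans[scans$motif_id == referenceId, ]
    if (any(!scans$membrane %in% refs$membrane))
        stop("membrane(s) without reference spot '", referenceId, "': ",
             paste(setdiff(scans$membrane, refs$membrane), collapse = ", "))
    if (any(refs$intensity <= 0))
        stop("non-positive reference intensity on membrane(s): ",
             paste(refs$membrane[refs$intensity <= 0], collapse = ", "))
    ref_by_mem <- setNames(refs$intensity, refs$membrane)
    scans$rel_intensity <- scans$intensity / ref_by_mem[scans$membrane]
    scans
}

#' Per-cell-line mean relative intensity
#'
#' Arithmetic mean over replicates, per motif and cell line. A motif absent
#' from some replicates is averaged over the replicates where it is present,
#' with a warning.
#'
#' @param normScans output of [normalizeToReference()].
#' @return data.frame with `cell_line`, `motif_id`, `mean_rel_intensity`,
#'   `n_replicates`.
#' @export
summarizeCellLines <- function(normScans) {
    if (!"rel_intensity" %in% names(normScans))
        stop("run normalizeToReference() first")
    agg <- stats::aggregate(rel_intensity ~ cell_line + motif_id,
                            data = normScans, FUN = mean)
    cnt <- stats::aggregate(rel_intensity ~ cell_line + motif_id,
                            data = normScans, FUN = length)
    names(agg)[3] <- "mean_rel_intensity"
    agg$n_replicates <- cnt$rel_intensity
    n_rep <- vapply(split(normScans$replicate, normScans$cell_line),
                    function(r) length(unique(r)), numeric(1))
    if (any(agg$n_replicates < n_rep[agg$cell_line]))
        warning("some motifs are missing in a subset of replicates; ",
                "means use the replicates present")
    agg[order(agg$cell_line, agg$motif_id), ]
}

#' Compare DNA-binding between cell-line groups
#'
#' For each motif, compares the per-cell-line mean relative intensities of
#' the case (basal-like) group against the control group with a two-sided
#' Student (equal-variance) t-test; the unit of replication is the cell
#' line. Fold change is the ratio of the group means of those per-line
#' means, on the raw (not log) scale.
#'
#' @param lineMeans data.frame from [summarizeCellLines()].
#' @param groupMap data.frame with columns `cell_line`, `group`.
#' @param case the case group label (default `"BLBC"`).
#' @param referenceId reference spot excluded from the comparison
#'   (default `"TFIID"`).
#' @param welch use Welch instead of Student's pooled-variance test
#'   (default FALSE).
#' @return data.frame: `motif_id`, `mean_case`, `mean_control`,
#'   `fold_change`, `t_statistic`, `p_value`.
#' @export
compareGroups <- function(lineMeans, groupMap, case = "BLBC",
                          referenceId = "TFIID", welch = FALSE) {
    if (!all(c("cell_line", "group") %in% names(groupMap)))
        stop("groupMap must have columns cell_line, group")
    miss <- setdiff(unique(lineMeans$cell_line), groupMap$cell_line)
    if (length(miss))
        stop("cell line(s) without group label: ",
             paste(miss, collapse = ", "))
    grp <- setNames(groupMap$group, groupMap$cell_line)
    lineMeans <- lineMeans[lineMeans$motif_id != referenceId, , drop = FALSE]
    lineMeans$group <- grp[lineMeans$cell_line]
    if (length(unique(lineMeans$group)) != 2L)
        stop("exactly two groups required")
    out <- lapply(split(lineMeans, lineMeans$motif_id), function(d) {
        x <- d$mean_rel_intensity[d$group == case]
        y <- d$mean_rel_intensity[d$group != case]
        if (length(x) < 2L || length(y) < 2L)
            stop("motif '", d$motif_id[1], "': need >= 2 cell lines per group")
        # variance indistinguishable from zero at machine precision
        # (e.g. noiseless simulations) is treated as degenerate
        degenerate <- var(x) + var(y) <=
            1e-20 * (mean(x)^2 + mean(y)^2 + .Machine$double.xmin)
        if (degenerate) {
            if (isTRUE(all.equal(mean(x), mean(y)))) {
                warning("motif '", d$motif_id[1],
                        "': zero variance and equal means; p set to 1")
                tt <- list(statistic = c(t = 0), p.value = 1)
            } else {
                tt <- list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
                           p.value = .Machine$double.xmin)
            }
        } else {
            tt <- stats::t.test(x, y, var.equal = !welch)
        }
        data.frame(motif_id = d$motif_id[1], mean_case = mean(x),
                   mean_control = mean(y),
                   fold_change = mean(x) / mean(y),
                   t_statistic = unname(tt$statistic),
                   p_value = tt$p.value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Select motifs with increased binding in the case group
#'
#' The published filter: fold change strictly greater than `fcMin` and
#' p-value strictly less than `alpha`. A motif with fold change exactly
#' `fcMin` is excluded.
#'
#' @param comparisons data.frame from [compareGroups()].
#' @param fcMin fold-change cutoff (default 1.4).
#' @param alpha p-value cutoff (default 0.05).
#' @return character vector of selected motif ids, smallest p first.
#' @export
selectBoundMotifs <- function(comparisons, fcMin = 1.4, alpha = 0.05) {
    stopifnot(fcMin > 0, alpha > 0)
    sel <- comparisons$fold_change > fcMin & comparisons$p_value < alpha
    ids <- comparisons$motif_id[sel]
    ids[order(comparisons$p_value[sel])]
}
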