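#' One-sided differential-expression p-values for a cohort
#'
#' Per-gene one-sided Welch (unequal-variance) two-sample t-test for higher
#' expression in the case (TNBC-like) group than the control group,
#' vectorized over all genes of the cohort. When both groups of a gene have
#' zero variance, the convention is p = 0.5 for equal means (the one-sided p
#' of t = 0, with a warning) and p near 0/1 for a non-zero difference.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param genes optional character vector restricting the genes tested.
#' @return named numeric vector of p-values in `(0, 1]`.
#' @seealso [dePValueOneSided()] for a single gene.
#' @export
dePValues <- function(cohort, genes = NULL) {
    x <- exprValues(cohort)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(x))
        if (length(miss))
            stop("gene(s) not in cohort '", cohortId(cohort), "': ",
                 paste(head(miss, 5), collapse = ", "))
        x <- x[genes, , drop = FALSE]
    }
    grp <- cohortGroups(cohort)
    case <- grp == caseLevel(cohort)
    n1 <- sum(case); n2 <- sum(!case)
    if (n1 < 2L || n2 < 2L)
        stop("need at least 2 samples per group")
    m1 <- rowMeans(x[, case, drop = FALSE])
    m2 <- rowMeans(x[, !case, drop = FALSE])
    v1 <- apply(x[, case, drop = FALSE], 1, var)
    v2 <- apply(x[, !case, drop = FALSE], 1, var)
    se2 <- v1 / n1 + v2 / n2
    p <- numeric(nrow(x))
    zero <- se2 == 0
    if (any(zero)) {
        eq <- zero & (m1 == m2)
        if (any(eq))
            warning(sum(eq), " gene(s) with zero variance in both groups ",
                    "and equal means; p set to 0.5")
        p[eq] <- 0.5
        p[zero & m1 > m2] <- .Machine$double.xmin
        p[zero & m1 < m2] <- 1
    }
    ok <- !zero
    if (any(ok)) {
        t_stat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
        df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) +
                           (v2[ok] / n2)^2 / (n2 - 1))
        p[ok] <- pt(t_stat, df, lower.tail = FALSE)
    }
    p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
    names(p) <- rownames(x)
    p
}

#' @rdname dePValues
#' @param geneId a single gene id present in the cohort.
#' @export
dePValueOneSided <- function(cohort, geneId) {
    dePValues(cohort, genes = geneId)[[1]]
}

#' Rank genes by significance
#'
#' Ascending p-value order, rank 1 = most significant; tied p-values receive
#' the average of the tied rank positions.
#'
#' @param p named numeric vector of p-values.
#' @return named numeric vector of ranks.
#' @export
rankBySignificance <- function(p) {
    if (!length(p)) stop("empty p-value map")
    rank(p, ties.method = "average")
}

#' Median-rank meta-analysis across cohorts
#'
#' Each cohort ranks its genes by one-sided significance; a gene's summary
#' rank is the median of its per-cohort ranks over the cohorts where it was
#' measured, and its summary p-value (`median_rank_p`) is the p-value
#' observed in the cohort that realizes the median rank. With an even number
#' of cohorts the less-significant (larger) of the two middle ranks is used,
#' so the reported p always comes from an actual cohort; if several cohorts
#' share the median rank the largest (most conservative) of their p-values
#' is reported. Genes measured in fewer than `minFractionMeasured` of the
#' cohorts are excluded and listed in the `"excluded"` attribute.
#'
#' @param pByCohort named list (one element per cohort) of named p-value
#'   vectors, e.g. from [dePValues()] per cohort.
#' @param minFractionMeasured minimum fraction of cohorts in which a gene
#'   must be measured (default 0.5).
#' @return data.frame with columns `gene_id`, `median_rank`,
#'   `median_rank_p`, `n_cohorts_measured`, ordered by `median_rank`;
#'   attribute `"excluded"` holds dropped gene ids.
#' @export
medianRankAggregate <- function(pByCohort, minFractionMeasured = 0.5) {
    if (!length(pByCohort)) stop("at least one cohort required")
    ranks <- lapply(pByCohort, rankBySignificance)
    genes <- sort(unique(unlist(lapply(pByCohort, names))))
    k <- length(pByCohort)
    R <- P <- matrix(NA_real_, length(genes), k)
    for (i in seq_len(k)) {
        idx <- match(names(pByCohort[[i]]), genes)
        R[idx, i] <- ranks[[i]]
        P[idx, i] <- pByCohort[[i]]
    }
    n_meas <- rowSums(!is.na(R))
    keep <- n_meas >= minFractionMeasured * k
    stat <- vapply(which(keep), function(j) {
        r <- R[j, ]; p <- P[j, ]
        ok <- !is.na(r)
        med <- sort(r[ok])[ceiling((sum(ok) + 1) / 2)]  # upper middle if even
        c(med, max(p[ok][r[ok] == med]))
    }, numeric(2))
    out <- data.frame(gene_id = genes[keep],
                      median_rank = stat[1, ],
                      median_rank_p = stat[2, ],
                      n_cohorts_measured = as.integer(n_meas[keep]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$median_rank, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    excluded <- genes[!keep]
    if (length(excluded))
        message(length(excluded), " gene(s) measured in fewer than ",
                minFractionMeasured, " of cohorts excluded")
    attr(out, "excluded") <- excluded
    out
}

#' Run the RNA meta-analysis over a list of cohorts
#'
#' Convenience composition: per-cohort one-sided Welch p-values, then
#' [medianRankAggregate()].
#'
#' @param cohorts list of [ExpressionCohort-class] objects.
#' @inheritParams medianRankAggregate
#' @return see [medianRankAggregate()].
#' @export
metaRankScreen <- function(cohorts, minFractionMeasured = 0.5) {
    p <- lapply(cohorts, dePValues)
    names(p) <- vapply(cohorts, cohortId, character(1))
    medianRankAggregate(p, minFractionMeasured = minFractionMeasured)
}

#' Select candidate transcription factors from the meta-analysis
#'
#' Whitelisted transcription-factor genes whose median-rank p-value falls
#' below `alpha` (raw, uncorrected — the screen's published rule), sorted by
#' median rank.
#'
#' @param meta data.frame from [medianRankAggregate()].
#' @param alpha significance cutoff (default 0.05).
#' @param tfWhitelist character vector of transcription-factor gene ids to
#'   which the selection is restricted; must be non-empty.
#' @param adjust p-adjustment method (default "none").
#' @return character vector of gene ids, best median rank first.
#' @export
selectCandidates <- function(meta, alpha = 0.05, tfWhitelist,
                             adjust = "none") {
    if (missing(tfWhitelist) || !length(tfWhitelist))
        stop("tfWhitelist must be a non-empty gene set")
    stopifnot(alpha >= 0, alpha <= 1)
    m <- meta[meta$gene_id %in% tfWhitelist, , drop = FALSE]
    p <- stats::p.adjust(m$median_rank_p, method = adjust)
    m <- m[p < alpha, , drop = FALSE]
    m$gene_id[order(m$median_rank, m$gene_id)]
}
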