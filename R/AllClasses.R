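#' @useDynLib blbcscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats median pt rbinom rexp rnorm runif sd setNames var
#'   binom.test fisher.test quantile uniroot rlnorm rmultinom
#' @importFrom utils read.delim write.table head
NULL

#' Expression cohort container
#'
#' A single cohort of the RNA screen: a gene-by-sample matrix of log-scale
#' expression values together with a binary subtype label per sample
#' (case = TNBC/basal-like, control = non-TNBC). The class extends
#' [SummarizedExperiment::SummarizedExperiment]; the group label lives in
#' `colData(x)$group` and the case level name in `metadata(x)$caseLevel`.
#'
#' @slot .Data inherited SummarizedExperiment slots; use the constructor
#'   [ExpressionCohort()] rather than `new()`.
#'
#' @seealso [ExpressionCohort()], [dePValues()], [medianRankAggregate()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass ExpressionCohort
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
    msg <- character()
    grp <- SummarizedExperiment::colData(object)$group
    if (is.null(grp))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        if (!is.factor(grp) || nlevels(grp) != 2L)
            msg <- c(msg, "'group' must be a factor with exactly 2 levels")
        else if (any(table(grp) == 0L))
            msg <- c(msg, "both groups must be non-empty")
    }
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    cl <- S4Vectors::metadata(object)$caseLevel
    if (is.null(cl) || (!is.null(grp) && is.factor(grp) && !cl %in% levels(grp)))
        msg <- c(msg, "metadata caseLevel must name one of the group levels")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param values numeric gene-by-sample matrix of log-scale expression; must
#'   have unique rownames (gene ids). Column names default to `S1..Sn`.
#' @param group character or factor of length `ncol(values)` with exactly two
#'   distinct values.
#' @param cohortId single string identifying the cohort.
#' @param caseLevel which group level is the case (TNBC-like) group.
#'
#' @return An [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
#' ec <- ExpressionCohort(m, rep(c("case", "control"), each = 5), "c1")
#' cohortId(ec)
#' @export
ExpressionCohort <- function(values, group, cohortId = "cohort",
                             caseLevel = "case") {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("S", seq_len(ncol(values)))
    group <- as.factor(group)
    if (length(group) != ncol(values))
        stop("'group' must have one label per sample column")
    if (!caseLevel %in% levels(group))
        stop("caseLevel '", caseLevel, "' not among group labels")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(group = group,
                                       row.names = colnames(values)))
    S4Vectors::metadata(se) <- list(cohortId = as.character(cohortId),
                                    caseLevel = caseLevel)
    new("ExpressionCohort", se)
}

#' @describeIn ExpressionCohort cohort identifier
#' @param x an `ExpressionCohort`
#' @export
cohortId <- function(x) S4Vectors::metadata(x)$cohortId

#' @describeIn ExpressionCohort the expression matrix
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn ExpressionCohort per-sample group factor
#' @export
cohortGroups <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn ExpressionCohort name of the case (TNBC-like) level
#' @export
caseLevel <- function(x) S4Vectors::metadata(x)$caseLevel

setMethod("show", "ExpressionCohort", function(object) {
    grp <- cohortGroups(object)
    cat("ExpressionCohort '", cohortId(object), "': ",
        nrow(object), " genes x ", ncol(object), " samples (",
        sum(grp == caseLevel(object)), " case / ",
        sum(grp != caseLevel(object)), " control)\n", sep = "")
})

#' Position weight matrix with TRANSFAC-style counts
#'
#' Per-position base counts for a transcription-factor binding motif, plus the
#' pseudocount used when deriving frequencies for matrix-similarity scoring.
#' Derived quantities (frequencies, information weights, min/max achievable
#' scores) are computed by the accessors so the stored object stays a plain
#' count matrix.
#'
#' @slot motifId motif identifier.
#' @slot counts position-by-base (A,C,G,T) non-negative count matrix.
#' @slot pseudocount per-base pseudocount added before frequency computation
#'   (default 0.25) so no frequency is zero.
#'
#' @seealso [PWMatrix()], [scoreSite()], [scanPromoter()]
#' @exportClass PWMatrix
setClass("PWMatrix",
         representation(motifId = "character",
                        counts = "matrix",
                        pseudocount = "numeric"))

setValidity("PWMatrix", function(object) {
    msg <- character()
    cts <- object@counts
    if (ncol(cts) != 4L || !identical(colnames(cts), c("A", "C", "G", "T")))
        msg <- c(msg, "counts must have columns A, C, G, T")
    if (any(cts < 0) || any(!is.finite(cts)))
        msg <- c(msg, "counts must be finite and non-negative")
    if (length(object@pseudocount) != 1L || object@pseudocount < 0)
        msg <- c(msg, "pseudocount must be a single non-negative number")
    if (nrow(cts) >= 1L && !length(msg)) {
        if (any(rowSums(cts) + 4 * object@pseudocount <= 0))
            msg <- c(msg, "every position must have positive total after pseudocount")
        w <- .pwmWeightMatrix(cts, object@pseudocount)
        if (sum(apply(w, 1, max)) <= sum(apply(w, 1, min)))
            msg <- c(msg, "degenerate matrix: max achievable score equals min")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PWMatrix
#'
#' @param counts numeric position-by-base matrix; columns are taken in
#'   A, C, G, T order (column names, if present, are checked).
#' @param motifId motif identifier string.
#' @param pseudocount per-base pseudocount (default 0.25).
#' @return A [PWMatrix-class] object.
#' @examples
#' pwm <- PWMatrix(rbind(c(8, 0, 0, 0), c(0, 0, 8, 0),
#'                       c(0, 8, 0, 0), c(0, 0, 0, 8)), "toy")
#' pwmConsensus(pwm)
#' @export
PWMatrix <- function(counts, motifId = "motif", pseudocount = 0.25) {
    counts <- as.matrix(counts)
    if (!is.null(colnames(counts))) {
        if (!all(c("A", "C", "G", "T") %in% colnames(counts)))
            stop("counts columns must be named A, C, G, T")
        counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
    } else if (ncol(counts) == 4L) {
        colnames(counts) <- c("A", "C", "G", "T")
    } else stop("counts must have 4 base columns")
    if (nrow(counts) < 4L)
        warning("motif '", motifId, "' is shorter than 4 positions")
    new("PWMatrix", motifId = as.character(motifId), counts = counts,
        pseudocount = pseudocount)
}

# information-weighted score matrix w[i, b] = I(i) * f_i(b), the per-position
# contribution of observing base b; shared by scoring, scanning and validity
.pwmWeightMatrix <- function(counts, pseudocount) {
    f <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
    info <- rowSums(f * log(4 * f))
    w <- f * info
    dimnames(w) <- list(NULL, c("A", "C", "G", "T"))
    w
}

#' @describeIn PWMatrix motif identifier
#' @param x a `PWMatrix`
#' @export
motifId <- function(x) x@motifId

#' @describeIn PWMatrix motif length in positions
#' @export
pwmLength <- function(x) nrow(x@counts)

#' @describeIn PWMatrix raw count matrix
#' @export
pwmCounts <- function(x) x@counts

#' @describeIn PWMatrix per-position base frequencies after pseudocount
#' @export
pwmFrequencies <- function(x)
    (x@counts + x@pseudocount) / (rowSums(x@counts) + 4 * x@pseudocount)

#' @describeIn PWMatrix per-position information weights
#'   `I(i) = sum_b f_i(b) log(4 f_i(b))` (nats; 0 for a uniform position)
#' @export
pwmInformation <- function(x) {
    f <- pwmFrequencies(x)
    rowSums(f * log(4 * f))
}

#' @describeIn PWMatrix consensus sequence (highest-frequency base per
#'   position, ties broken A<C<G<T)
#' @export
pwmConsensus <- function(x) {
    f <- pwmFrequencies(x)
    paste(c("A", "C", "G", "T")[apply(f, 1, which.max)], collapse = "")
}

#' @describeIn PWMatrix minimum and maximum achievable information-weighted
#'   score sums (the normalization range of [scoreSite()])
#' @export
pwmScoreRange <- function(x) {
    w <- .pwmWeightMatrix(x@counts, x@pseudocount)
    c(min = sum(apply(w, 1, min)), max = sum(apply(w, 1, max)))
}

setMethod("show", "PWMatrix", function(object) {
    cat("PWMatrix '", object@motifId, "': ", nrow(object@counts),
        " bp, consensus ", pwmConsensus(object), "\n", sep = "")
})
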