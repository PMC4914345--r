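#' Dichotomize a continuous marker
#'
#' Splits expression values into low/high at the cohort median (default) or
#' mean; a subject is "high" when strictly above the cutpoint.
#'
#' @param values numeric vector with at least two distinct values.
#' @param method `"median"` or `"mean"`.
#' @return factor with levels `low`, `high`; attributes `"cutpoint"` and
#'   `"counts"`.
#' @export
dichotomize <- function(values, method = c("median", "mean")) {
    method <- match.arg(method)
    if (length(unique(values)) < 2L)
        stop("marker is constant; cannot dichotomize")
    cut <- if (method == "median") median(values) else mean(values)
    lab <- factor(ifelse(values > cut, "high", "low"),
                  levels = c("low", "high"))
    attr(lab, "cutpoint") <- cut
    attr(lab, "counts") <- c(low = sum(lab == "low"), high = sum(lab == "high"))
    lab
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate of the survival function for each group, via
#' [survival::survfit()].
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group grouping factor (a single group if omitted).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival` (one row per distinct time within group).
#' @export
kmFit <- function(time, event, group = NULL) {
    if (any(time < 0)) stop("negative follow-up time")
    if (is.null(group)) group <- rep("all", length(time))
    group <- as.factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    if (nlevels(group) == 1L) {
        grp <- rep(levels(group), length(fit$time))
    } else {
        grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    }
    data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv,
               stringsAsFactors = FALSE)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Observed-minus-expected events over the pooled event times with
#' hypergeometric variance, via [survival::survdiff()]; 1-df chi-square.
#'
#' @inheritParams kmFit
#' @param group two-level grouping.
#' @return list with `statistic` (chi-square), `p`, and the per-group
#'   observed/expected event counts.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    if (nlevels(droplevels(group)) != 2L)
        stop("log-rank test requires exactly two groups")
    if (sum(event) == 0) {
        warning("no events observed; p set to 1")
        return(list(statistic = 0, p = 1,
                    observed = c(0, 0), expected = c(0, 0)))
    }
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    list(statistic = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         observed = sd$obs, expected = sd$exp)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Fits a Cox model by Newton-Raphson maximization of the partial
#' likelihood with Efron tie handling ([survival::coxph()]); reports
#' hazard ratios with Wald 95% confidence intervals and p-values in the
#' layout of a prognostic-factor table. Categorical covariates must be
#' factors with their reference level first.
#'
#' @param data data.frame holding time, event and covariate columns.
#' @param terms character vector of covariate column names.
#' @param timeCol,eventCol names of the time and event columns.
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return list with elements `table` (data.frame: `term`, `coef`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `se`, `p`), `loglik` (log partial
#'   likelihood at the solution), `converged`, and the underlying `fit`.
#' @export
coxFit <- function(data, terms, timeCol = "time", eventCol = "event",
                   ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    if (!all(c(timeCol, eventCol, terms) %in% names(data)))
        stop("missing column(s): ",
             paste(setdiff(c(timeCol, eventCol, terms), names(data)),
                   collapse = ", "))
    if (sum(data[[eventCol]]) == 0) stop("no events; cannot fit")
    fml <- stats::as.formula(paste0(
        "survival::Surv(", timeCol, ", ", eventCol, ") ~ ",
        paste(terms, collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = ties)
    s <- summary(fit)
    co <- s$coefficients
    tab <- data.frame(term = rownames(co),
                      coef = co[, "coef"],
                      hazard_ratio = exp(co[, "coef"]),
                      ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      se = co[, "se(coef)"],
                      p = co[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    list(table = tab, loglik = fit$loglik[2],
         converged = is.null(fit$info) || fit$iter < 50, fit = fit)
}

#' Marker survival analysis in one call
#'
#' Dichotomizes the marker, runs the Kaplan-Meier / log-rank comparison of
#' the high and low groups, and fits the multivariate Cox model with the
#' dichotomized marker plus the supplied covariates.
#'
#' @param cohort data.frame with `time`, `event`, `marker` and covariate
#'   columns.
#' @param covariates character vector of covariate column names for the Cox
#'   model (may be empty).
#' @param dichotomizeBy `"median"` (default) or `"mean"`.
#' @return list: `groups` (factor), `km` (from [kmFit()]), `logrank`,
#'   `cox` (from [coxFit()]).
#' @export
markerSurvival <- function(cohort, covariates = character(),
                           dichotomizeBy = c("median", "mean")) {
    dichotomizeBy <- match.arg(dichotomizeBy)
    grp <- dichotomize(cohort$marker, dichotomizeBy)
    cohort$marker_high <- as.integer(grp == "high")
    lr <- logrankTest(cohort$time, cohort$event, grp)
    km <- kmFit(cohort$time, cohort$event, grp)
    cx <- coxFit(cohort, c("marker_high", covariates))
    list(groups = grp, km = km, logrank = lr, cox = cx)
}
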