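# Independent brute-force oracles, written directly from the definitions and
# kept free of the package's internal code paths.

# information-weighted matrix similarity score of one site (plain formula)
oracleMSS <- function(counts, subseq, pseudocount = 0.25) {
    bases <- c("A", "C", "G", "T")
    f <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
    info <- apply(f, 1, function(fr) sum(fr * log(4 * fr)))
    chars <- strsplit(toupper(subseq), "")[[1]]
    stopifnot(length(chars) == nrow(counts))
    s <- smin <- smax <- 0
    for (i in seq_len(nrow(counts))) {
        contrib <- info[i] * f[i, ]
        bi <- match(chars[i], bases)
        s <- s + if (!is.na(bi)) contrib[[bi]] else min(contrib)
        smin <- smin + min(contrib)
        smax <- smax + max(contrib)
    }
    (s - smin) / (smax - smin)
}

oracleRevComp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
          collapse = "")
}

# exhaustive window enumeration over both strands
oracleScan <- function(counts, sequence, threshold, pseudocount = 0.25,
                       bothStrands = TRUE) {
    L <- nrow(counts)
    n <- nchar(sequence)
    out <- data.frame(position = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    if (n < L) return(out)
    for (pos in seq_len(n - L + 1)) {
        win <- substr(sequence, pos, pos + L - 1)
        sc <- oracleMSS(counts, win, pseudocount)
        if (sc >= threshold)
            out <- rbind(out, data.frame(position = pos, strand = "+",
                                         score = sc,
                                         stringsAsFactors = FALSE))
        if (bothStrands) {
            sc2 <- oracleMSS(counts, oracleRevComp(win), pseudocount)
            if (sc2 >= threshold)
                out <- rbind(out, data.frame(position = pos, strand = "-",
                                             score = sc2,
                                             stringsAsFactors = FALSE))
        }
    }
    out <- out[order(out$position, out$strand == "-"), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# median-rank aggregation by literal sort / median / lookup
oracleMedianRank <- function(pByCohort, minFrac = 0.5) {
    genes <- sort(unique(unlist(lapply(pByCohort, names))))
    k <- length(pByCohort)
    rows <- list()
    for (g in genes) {
        r <- p <- numeric()
        for (i in seq_len(k)) {
            pv <- pByCohort[[i]]
            if (g %in% names(pv)) {
                r <- c(r, rank(pv, ties.method = "average")[[g]])
                p <- c(p, pv[[g]])
            }
        }
        if (length(r) < minFrac * k) next
        med <- sort(r)[ceiling((length(r) + 1) / 2)]
        rows[[g]] <- data.frame(gene_id = g, median_rank = med,
                                median_rank_p = max(p[r == med]),
                                n_cohorts_measured = length(r),
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$median_rank, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# random sharply peaked PWM counts for scanner tests
randomPwmCounts <- function(L) {
    t(vapply(sample.int(4, L, replace = TRUE), function(b) {
        ct <- runif(4, 0, 3)
        ct[b] <- ct[b] + runif(1, 5, 20)
        ct
    }, numeric(4)))
}

randomDna <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# Cox partial log-likelihood for one covariate, Breslow form (no ties in the
# fixtures that use it)
oracleCoxLoglik <- function(beta, time, event, x) {
    s <- 0
    for (i in which(event == 1)) {
        risk <- time >= time[i]
        s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
}

# two-group log-rank chi-square from first principles
oracleLogrank <- function(time, event, group) {
    group <- as.factor(group)
    g1 <- levels(group)[1]
    o_minus_e <- 0
    v <- 0
    for (t in sort(unique(time[event == 1]))) {
        at_risk <- time >= t
        n <- sum(at_risk)
        n1 <- sum(at_risk & group == g1)
        d <- sum(event == 1 & time == t)
        d1 <- sum(event == 1 & time == t & group == g1)
        o_minus_e <- o_minus_e + (d1 - d * n1 / n)
        if (n > 1)
            v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    chisq <- o_minus_e^2 / v
    list(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

tinyCohort <- function(values, group, id = "c", case = "case")
    ExpressionCohort(values, group, cohortId = id, caseLevel = case)
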