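test_that("configuration validation names the offending field", {
    expect_s3_class(simConfig(), "SimConfig")
    expect_error(simConfig(nPlantedDe = 10, nTfGenes = 5), "nPlantedDe")
    expect_error(simConfig(nTfGenes = 50, nGenes = 10), "nTfGenes")
    expect_error(simConfig(motifPlantRate = 1.2), "motifPlantRate")
    expect_error(simConfig(censorRate = -0.1), "censorRate")
    expect_error(simConfig(nCohorts = 0), "nCohorts")
    expect_error(simConfig(baseComposition = c(1, 0, 0)), "baseComposition")
    expect_error(simConfig(nPlantedMotifs = 20, nMotifs = 5),
                 "nPlantedMotifs")
})

test_that("generators are deterministic and mutually independent", {
    cfg <- simConfig(seed = 31, nCohorts = 2, nGenes = 60, nTfGenes = 10,
                     nSamplesPerGroup = 5, nPlantedDe = 3, nTargetGenes = 5,
                     nControlGenes = 6, nMotifs = 5, nPlantedMotifs = 2,
                     promoterLength = 120)
    e1 <- simExpressionCohorts(cfg)
    e2 <- simExpressionCohorts(cfg)
    expect_identical(exprValues(e1$cohorts[[1]]), exprValues(e2$cohorts[[1]]))
    expect_identical(e1$truth, e2$truth)
    pw <- simMotifLibrary(cfg)
    p1 <- simPromoters(cfg, pw)
    p2 <- simPromoters(cfg, pw)
    expect_identical(as.character(p1$sequences), as.character(p2$sequences))
    expect_identical(p1$truth, p2$truth)
    # expression output does not depend on whether promoters were generated
    e3 <- simExpressionCohorts(cfg)
    expect_identical(exprValues(e1$cohorts[[2]]), exprValues(e3$cohorts[[2]]))
    # different seeds give different data
    cfg2 <- simConfig(seed = 32, nCohorts = 2, nGenes = 60, nTfGenes = 10,
                      nSamplesPerGroup = 5, nPlantedDe = 3, nTargetGenes = 5,
                      nControlGenes = 6, nMotifs = 5, nPlantedMotifs = 2,
                      promoterLength = 120)
    expect_false(identical(exprValues(simExpressionCohorts(cfg2)$cohorts[[1]]),
                           exprValues(e1$cohorts[[1]])))
})

test_that("a zero effect size plants nothing and shifts nothing", {
    cfg <- simConfig(seed = 13, nCohorts = 3, nGenes = 200, nTfGenes = 50,
                     nSamplesPerGroup = 25, effectSize = 0, nPlantedDe = 20)
    sim <- simExpressionCohorts(cfg)
    expect_length(sim$truth$de_tfs, 0)
    # pooled across cohorts, group mean differences stay near zero
    d <- unlist(lapply(sim$cohorts, function(co) {
        g <- cohortGroups(co) == caseLevel(co)
        rowMeans(exprValues(co)[, g]) - rowMeans(exprValues(co)[, !g])
    }))
    expect_lt(abs(mean(d)), 0.02)
    expect_lt(max(abs(d)), 5 * sqrt(2 / 25))
})

test_that("planted expression effects give the analytic t-test power", {
    # power of the one-sided two-sample t at delta = 2, n = 30/group,
    # alpha = 0.05 from the noncentral t distribution
    n <- 30; delta <- 2
    ncp <- delta / sqrt(2 / n)
    crit <- qt(0.95, 2 * n - 2)
    power <- 1 - pt(crit, 2 * n - 2, ncp = ncp)
    expect_gt(power, 0.999)
    cfg <- simConfig(seed = 19, nCohorts = 5, nGenes = 150, nTfGenes = 40,
                     nSamplesPerGroup = 30, effectSize = 2, nPlantedDe = 20)
    sim <- simExpressionCohorts(cfg)
    rejections <- unlist(lapply(sim$cohorts, function(co)
        dePValues(co)[sim$truth$de_tfs] < 0.05))
    expect_gte(mean(rejections), 0.95)
})

test_that("cohort dropout thins gene panels per cohort", {
    cfg <- simConfig(seed = 23, nCohorts = 4, nGenes = 300, nTfGenes = 30,
                     nSamplesPerGroup = 5, cohortDropout = 0.3)
    sim <- simExpressionCohorts(cfg)
    sizes <- vapply(sim$cohorts, nrow, numeric(1))
    expect_true(all(sizes == 210))
    panels <- lapply(sim$cohorts, rownames)
    expect_false(identical(panels[[1]], panels[[2]]))
})

test_that("promoter planting respects rates and records insertions", {
    cfg <- simConfig(seed = 41, nGenes = 800, nTfGenes = 10,
                     nTargetGenes = 40, nControlGenes = 200, nMotifs = 6,
                     nPlantedMotifs = 2, motifPlantRate = 0.5,
                     promoterLength = 500)
    pw <- simMotifLibrary(cfg)
    pr <- simPromoters(cfg, pw)
    expect_length(pr$sequences, 240)
    ins <- pr$truth$insertions[[pr$truth$planted_motifs[1]]]
    # sites recorded only in target promoters at roughly the plant rate
    expect_true(all(ins$gene %in% pr$targetGenes))
    expect_gt(nrow(ins), 40 * 0.5 - 3 * sqrt(40 * 0.25))
    expect_lt(nrow(ins), 40 * 0.5 + 3 * sqrt(40 * 0.25))
    # each recorded site is present at the recorded position
    for (j in seq_len(min(5, nrow(ins))))
        expect_identical(
            substr(as.character(pr$sequences[[ins$gene[j]]]), ins$position[j],
                   ins$position[j] + nchar(ins$site[j]) - 1),
            ins$site[j])
    # a too-short promoter errors
    cfg_bad <- simConfig(seed = 1, promoterLength = 5, motifLength = 10,
                         nMotifs = 3, nPlantedMotifs = 1)
    expect_error(simPromoters(cfg_bad, simMotifLibrary(cfg)),
                 "shorter than longest motif")
    expect_error(simPromoters(cfg, pw, targetGenes = c("a", "b"),
                              controlGenes = c("b", "c")), "disjoint")
    expect_error(simPromoters(cfg, list()), "empty")
})

test_that("promoter FASTA and expression TSVs round-trip through the readers", {
    cfg <- simConfig(seed = 43, nGenes = 100, nTfGenes = 8, nTargetGenes = 6,
                     nControlGenes = 10, nMotifs = 3, nPlantedMotifs = 1,
                     promoterLength = 150, nCohorts = 1,
                     nSamplesPerGroup = 4)
    pr <- simPromoters(cfg, simMotifLibrary(cfg))
    fa <- tempfile(fileext = ".fa")
    writePromoterFasta(pr$sequences, fa)
    back <- readPromoterFasta(fa)
    expect_identical(names(back), names(pr$sequences))
    expect_identical(as.character(back), as.character(pr$sequences))
    co <- simExpressionCohorts(cfg)$cohorts[[1]]
    vp <- tempfile(fileext = ".tsv"); gp <- tempfile(fileext = ".tsv")
    writeExpressionCohort(co, vp, gp)
    co2 <- readExpressionCohort(vp, gp, cohortId = cohortId(co))
    expect_equal(exprValues(co2), exprValues(co), tolerance = 1e-12)
    expect_identical(as.character(cohortGroups(co2)),
                     as.character(cohortGroups(co)))
})

test_that("null arrays keep the joint filter near its nominal level", {
    # one test motif per independently simulated array: reference-spot noise
    # is shared across every spot of a membrane, so tests on one array are
    # correlated and only independent arrays give a binomial calibration
    cmp <- do.call(rbind, lapply(1:300, function(s) {
        cfg <- simConfig(seed = 5000 + s, arrayFc = 1, arrayCv = 0.15)
        arr <- suppressWarnings(
            simArrayIntensities(cfg, motifIds = "M0001"))
        stopifnot(length(arr$truth$bound_motifs) == 0)
        compareGroups(summarizeCellLines(normalizeToReference(arr$scans)),
                      arr$groupMap)
    }))
    k <- sum(cmp$p_value < 0.05)
    expect_gte(k, qbinom(0.005, 300, 0.05))
    expect_lte(k, qbinom(0.995, 300, 0.05))
    joint <- sum(cmp$p_value < 0.05 & cmp$fold_change > 1.4)
    expect_lte(joint, k)
})

test_that("survival generation hits its censoring target across rates", {
    for (cr in c(0.2, 0.5, 0.8)) {
        cfg <- simConfig(seed = 61, nSubjects = 1500, censorRate = cr)
        sim <- simSurvivalCohort(cfg)
        expect_lt(abs(1 - mean(sim$cohort$event) - cr), 0.05)
    }
    cfg0 <- simConfig(seed = 61, nSubjects = 50, censorRate = 0)
    expect_true(all(simSurvivalCohort(cfg0)$cohort$event == 1))
})
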