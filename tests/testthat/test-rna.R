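test_that("one-sided Welch p matches a hand computation on six numbers", {
    vals <- rbind(gX = c(2, 3, 4, 0, 1, 2))
    co <- tinyCohort(vals, rep(c("case", "control"), each = 3))
    # Welch by hand: means 3 and 1, variances 1 and 1, se^2 = 2/3,
    # t = 2 / sqrt(2/3), df = (2/3)^2 / (2 * (1/3)^2 / 2) = 4
    t_hand <- 2 / sqrt(2 / 3)
    df_hand <- (2 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
    p_hand <- pt(t_hand, df_hand, lower.tail = FALSE)
    expect_equal(dePValueOneSided(co, "gX"), p_hand, tolerance = 1e-12)
    expect_equal(df_hand, 4)
    # and against t.test as a second, independent route
    expect_equal(dePValueOneSided(co, "gX"),
                 t.test(c(2, 3, 4), c(0, 1, 2),
                        alternative = "greater")$p.value,
                 tolerance = 1e-12)
})

test_that("group-label swap reflects the one-sided p", {
    set.seed(42)
    vals <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
    grp <- rep(c("case", "control"), each = 5)
    p_fwd <- dePValues(tinyCohort(vals, grp))
    p_rev <- dePValues(ExpressionCohort(vals, grp, caseLevel = "control"))
    expect_equal(unname(p_fwd + p_rev), rep(1, 4), tolerance = 1e-10)
})

test_that("degenerate inputs follow the stated conventions", {
    vals <- rbind(flat = rep(5, 8), up = rep(c(7, 5), each = 4))
    co <- tinyCohort(vals, rep(c("case", "control"), each = 4))
    expect_warning(p <- dePValues(co), "zero variance")
    expect_equal(unname(p["flat"]), 0.5)
    expect_lt(p["up"], 1e-100)
    expect_error(dePValues(co, genes = "nope"), "not in cohort")
    one <- tinyCohort(rbind(g = rnorm(3)), c("case", "control", "control"))
    expect_error(dePValues(one), "2 samples per group")
})

test_that("significance ranking is order-invariant and averages ties", {
    p <- c(a = 0.01, b = 0.5, c = 0.9)
    expect_equal(rankBySignificance(p), c(a = 1, b = 2, c = 3))
    p2 <- c(a = 0.2, b = 0.2, c = 0.9)
    expect_equal(rankBySignificance(p2), c(a = 1.5, b = 1.5, c = 3))
    sh <- sample(p)
    expect_equal(rankBySignificance(sh)[names(p)], rankBySignificance(p))
    expect_error(rankBySignificance(numeric()), "empty")
})

test_that("median-rank aggregation follows its definition on small cases", {
    # single cohort: identity
    p1 <- list(c1 = c(a = 0.01, b = 0.2))
    m1 <- medianRankAggregate(p1)
    expect_equal(m1$median_rank, c(1, 2))
    expect_equal(m1$median_rank_p, c(0.01, 0.2))
    # odd count: rank {3, 7, 9} with p {0.001, 0.03, 0.2} -> 7 / 0.03
    mk <- function(r, p, G = 10) {
        # cohort where gene "g" lands at rank r with p-value p
        below <- if (r > 1) seq(p / 1000, p * 0.9, length.out = r - 1)
                 else numeric()
        above <- if (r < G) seq(min(p * 1.1 + 1e-4, 0.99), 0.999,
                                length.out = G - r)
                 else numeric()
        full <- c(below, p, above)
        names(full) <- c(paste0("lo", seq_along(below)), "g",
                         paste0("hi", seq_along(above)))
        full
    }
    set.seed(1)
    cohorts <- list(mk(3, 0.001), mk(7, 0.03), mk(9, 0.2))
    m <- medianRankAggregate(cohorts)
    g <- m[m$gene_id == "g", ]
    expect_equal(g$median_rank, 7)
    expect_equal(g$median_rank_p, 0.03)
    # even count: the less-significant of the two middle ranks
    cohorts4 <- list(mk(2, 0.001), mk(4, 0.01), mk(6, 0.05), mk(8, 0.3))
    g4 <- subset(medianRankAggregate(cohorts4), gene_id == "g")
    expect_equal(g4$median_rank, 6)
    expect_equal(g4$median_rank_p, 0.05)
})

test_that("aggregation equals the brute-force oracle on random tables", {
    set.seed(99)
    for (rep in 1:25) {
        k <- sample(2:8, 1)
        G <- sample(10:60, 1)
        genes <- paste0("g", seq_len(G))
        pby <- lapply(seq_len(k), function(i) {
            keep <- sort(sample(genes, round(G * runif(1, 0.7, 1))))
            setNames(runif(length(keep)), keep)
        })
        names(pby) <- paste0("c", seq_len(k))
        got <- medianRankAggregate(pby)
        attr(got, "excluded") <- NULL
        expect_equal(got, oracleMedianRank(pby))
    }
})

test_that("sparsely measured genes are excluded and reported", {
    pby <- list(c1 = c(a = 0.1, b = 0.2), c2 = c(a = 0.3, b = 0.1),
                c3 = c(a = 0.2, b = 0.6), c4 = c(b = 0.5, rare = 0.01))
    expect_message(m <- medianRankAggregate(pby, minFractionMeasured = 0.5),
                   "excluded")
    expect_false("rare" %in% m$gene_id)
    expect_identical(attr(m, "excluded"), "rare")
})

test_that("candidate selection respects alpha and the whitelist", {
    meta <- data.frame(gene_id = c("tf1", "tf2", "other"),
                       median_rank = c(2, 9, 1),
                       median_rank_p = c(0.001, 0.2, 1e-6),
                       n_cohorts_measured = 3)
    wl <- c("tf1", "tf2")
    expect_identical(selectCandidates(meta, 0.05, wl), "tf1")
    expect_identical(selectCandidates(meta, 0, wl), character(0))
    expect_identical(selectCandidates(meta, 1, wl), c("tf1", "tf2"))
    expect_error(selectCandidates(meta, 0.05, character()), "non-empty")
})

test_that("planted effects are recovered and a larger effect never hurts the rank", {
    cfg <- simConfig(seed = 11, nCohorts = 5, nGenes = 200, nTfGenes = 40,
                     nSamplesPerGroup = 30, effectSize = 2, nPlantedDe = 10)
    sim <- simExpressionCohorts(cfg)
    meta <- metaRankScreen(sim$cohorts)
    hits <- selectCandidates(meta, 0.05, tfWhitelist(cfg))
    expect_gte(mean(sim$truth$de_tfs %in% hits), 0.95)
    fp <- setdiff(hits, sim$truth$de_tfs)
    expect_lte(length(fp) / (cfg$nTfGenes - cfg$nPlantedDe), 0.07)

    # monotonicity on matched noise: same noise matrices, growing shift
    set.seed(5)
    noise <- lapply(1:3, function(i)
        matrix(rnorm(50 * 20), 50, 20, dimnames = list(paste0("g", 1:50),
                                                       NULL)))
    grp <- rep(c("case", "control"), each = 10)
    rank_of <- function(eff) {
        cohorts <- lapply(seq_along(noise), function(i) {
            v <- noise[[i]]
            v["g1", grp == "case"] <- v["g1", grp == "case"] + eff
            tinyCohort(v, grp, id = paste0("c", i))
        })
        m <- metaRankScreen(cohorts)
        m$median_rank[m$gene_id == "g1"]
    }
    effs <- c(0, 0.5, 1, 2, 4)
    rks <- vapply(effs, rank_of, numeric(1))
    expect_true(all(diff(rks) <= 0))
})

test_that("multi-cohort median-rank selection is conservative under the null", {
    set.seed(21)
    rates <- replicate(40, {
        pby <- lapply(1:5, function(i) setNames(runif(80), paste0("g", 1:80)))
        m <- medianRankAggregate(pby)
        mean(m$median_rank_p < 0.05)
    })
    expect_lte(mean(rates), 0.05)
})
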