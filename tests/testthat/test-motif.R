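toyPwm <- function() PWMatrix(rbind(c(8, 0, 0, 0), c(0, 0, 8, 0),
                                    c(0, 8, 0, 0), c(0, 0, 0, 8)), "toy")

test_that("TRANSFAC records round-trip through write and parse", {
    pwms <- list(toyPwm(),
                 PWMatrix(rbind(c(1, 2, 3, 4), c(9, 0, 0, 1),
                                c(2, 2, 5, 1), c(0, 0, 0, 7),
                                c(3, 3, 1, 3)), "m2"))
    names(pwms) <- c("toy", "m2")
    path <- tempfile(fileext = ".transfac")
    writeTransfac(pwms, path)
    back <- parseTransfac(path)
    expect_length(back, 2)
    expect_identical(names(back), c("toy", "m2"))
    expect_equal(pwmCounts(back$m2), pwmCounts(pwms$m2))
})

test_that("a documentation-style TRANSFAC block parses to known counts", {
    block <- c("ID V$TOY_01",
               "XX",
               "NA toy factor",
               "P0      A      C      G      T",
               "01      2      0      8      0      G",
               "02     10      0      0      0      A",
               "03      0      5      0      5      Y",
               "XX",
               "//")
    path <- tempfile()
    writeLines(block, path)
    expect_warning(got <- parseTransfac(path), "shorter than 4")
    expect_identical(names(got), "V$TOY_01")
    expect_equal(unname(pwmCounts(got[[1]])),
                 rbind(c(2, 0, 8, 0), c(10, 0, 0, 0), c(0, 5, 0, 5)))
})

test_that("malformed TRANSFAC input fails with location information", {
    p1 <- tempfile()
    writeLines(c("ID m1", "01 1 2 3 4 N", "02 1 x 3 4 N", "//"), p1)
    expect_error(parseTransfac(p1), "line 3")
    p2 <- tempfile()
    writeLines(c("ID m1", "01 1 2 3 4 N"), p2)
    expect_error(parseTransfac(p2), "terminator")
})

test_that("site scoring hits the score-range endpoints by construction", {
    pwm <- toyPwm()
    expect_equal(scoreSite(pwm, "AGCT"), 1)
    # anti-consensus: the minimum base at every position
    expect_equal(scoreSite(pwm, "CAAA"), 0)
    expect_error(scoreSite(pwm, "AGC"), "length")
})

test_that("site scoring matches the hand formula on a fixed matrix", {
    cts <- rbind(c(5, 1, 1, 1), c(0, 6, 2, 0), c(1, 1, 1, 5),
                 c(2, 2, 2, 2))
    pwm <- PWMatrix(cts, "fixed")
    for (s in c("ACGT", "ACTA", "TTTT", "GCNT"))
        expect_equal(scoreSite(pwm, s), oracleMSS(cts, s),
                     tolerance = 1e-12)
})

test_that("scanning equals exhaustive enumeration on random instances", {
    set.seed(17)
    for (i in 1:20) {
        L <- sample(4:12, 1)
        cts <- randomPwmCounts(L)
        seqc <- randomDna(sample(40:300, 1))
        thr <- runif(1, 0.7, 0.95)
        got <- scanPromoter(PWMatrix(cts, "r"), seqc, threshold = thr)
        expect_equal(got, oracleScan(cts, seqc, thr), tolerance = 1e-12)
    }
})

test_that("scanning finds planted sites and respects strand symmetry", {
    pwm <- toyPwm()
    set.seed(8)
    seqc <- paste0(randomDna(99), "AGCT", randomDna(97))
    hits <- scanPromoter(pwm, seqc, threshold = 0.999)
    expect_true(100 %in% hits$position[hits$strand == "+"])
    # AGCT is its own reverse complement: every + hit pairs with a - hit
    expect_equal(hits$position[hits$strand == "+"],
                 hits$position[hits$strand == "-"])
    # sequence shorter than the motif is an empty hit list, not an error
    expect_identical(nrow(scanPromoter(pwm, "AG")), 0L)
    # strand order at one position is deterministic: + first
    both <- scanPromoter(pwm, "AGCT", threshold = 0.5)
    expect_identical(both$strand, c("+", "-"))
})

test_that("occurrence counts are reverse-complement invariant and monotone in threshold", {
    set.seed(33)
    cts <- randomPwmCounts(8)
    pwm <- PWMatrix(cts, "m")
    seqs <- Biostrings::DNAStringSet(vapply(1:30, function(i)
        randomDna(200), character(1)))
    rc <- Biostrings::reverseComplement(seqs)
    for (thr in c(0.75, 0.85, 0.95)) {
        k_fwd <- blbcscreen:::.countOccurrences(pwm, seqs, thr)
        k_rc <- blbcscreen:::.countOccurrences(pwm, rc, thr)
        expect_identical(k_fwd, k_rc)
    }
    ks <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.99), function(thr)
        blbcscreen:::.countOccurrences(pwm, seqs, thr), numeric(1))
    expect_true(all(diff(ks) <= 0))
})

test_that("enrichment testing matches closed-form tails", {
    # all 10 targets hit, 0 of 1000 controls: Fisher p is one hypergeometric
    # term computed from factorials
    pwm <- toyPwm()
    targets <- rep(paste0(strrep("T", 10), "AGCT", strrep("T", 10)), 10)
    controls <- rep(strrep("T", 24), 1000)
    rec <- suppressWarnings(motifEnrichment(pwm, targets, controls,
                                            threshold = 0.99))
    expect_equal(rec$k_target, 10)
    expect_equal(rec$k_control, 0)
    p_hyper <- exp(lchoose(10, 10) + lchoose(1000, 0) - lchoose(1010, 10))
    expect_equal(rec$p_fisher, p_hyper, tolerance = 1e-9)
    # binomial null proportion is floored when controls have no occurrences
    expect_warning(motifEnrichment(pwm, targets, controls, threshold = 0.99),
                   "floored")
    p_floor <- pbinom(9, 10, 0.5 / 1000, lower.tail = FALSE)
    expect_equal(rec$p_binomial, p_floor, tolerance = 1e-9)
})

test_that("equal occurrence proportions give a null upper-tail p", {
    pwm <- toyPwm()
    with_site <- paste0(strrep("T", 10), "AGCT", strrep("T", 10))
    without <- strrep("T", 24)
    targets <- c(rep(with_site, 2), rep(without, 8))
    controls <- c(rep(with_site, 20), rep(without, 80))
    rec <- motifEnrichment(pwm, targets, controls, threshold = 0.99)
    expect_gt(rec$p_binomial, 0.5)
    expect_gt(rec$p_fisher, 0.5)
})

test_that("signature derivation intersects per-cohort selections", {
    set.seed(7)
    grp <- rep(c("case", "control"), each = 15)
    mkco <- function(up, id) {
        v <- matrix(rnorm(20 * 30), 20, 30,
                    dimnames = list(paste0("g", 1:20), NULL))
        v[up, grp == "case"] <- v[up, grp == "case"] + 4
        tinyCohort(v, grp, id = id)
    }
    cohorts <- list(mkco(1:6, "a"), mkco(4:10, "b"), mkco(5:12, "c"))
    sig <- deriveSignatureGeneSet(cohorts, alpha = 0.01)
    expect_setequal(sig, paste0("g", 5:6))
    # alpha = 1 keeps every measured gene
    expect_setequal(deriveSignatureGeneSet(cohorts, alpha = 1),
                    paste0("g", 1:20))
    expect_error(deriveSignatureGeneSet(list()), "at least one")
})

test_that("control-gene sampling is seeded, disjoint and uniform", {
    universe <- paste0("g", 1:30)
    excl <- paste0("g", 1:5)
    s1 <- sampleControlGenes(universe, excl, n = 10, seed = 4)
    s2 <- sampleControlGenes(universe, excl, n = 10, seed = 4)
    expect_identical(s1, s2)
    expect_length(intersect(s1, excl), 0)
    expect_setequal(sampleControlGenes(universe, excl, n = 25, seed = 1),
                    setdiff(universe, excl))
    expect_error(sampleControlGenes(universe, excl, n = 26, seed = 1),
                 "short by 1")
    # empirical inclusion frequency ~ n / pool
    inc <- rowMeans(vapply(1:400, function(s)
        universe %in% sampleControlGenes(universe, excl, n = 10, seed = s),
        logical(30)))
    expect_true(all(abs(inc[6:30] - 10 / 25) < 0.1))
    expect_true(all(inc[1:5] == 0))
})

test_that("promoter extraction honours strand, coordinates and truncation", {
    cfg <- simConfig(seed = 2, nGenes = 40, nTfGenes = 5, nTargetGenes = 6,
                     nControlGenes = 8, nMotifs = 4, nPlantedMotifs = 2,
                     promoterLength = 1200)
    pr <- simPromoters(cfg, simMotifLibrary(cfg))
    got <- extractPromoters(pr$genome, pr$geneTable)
    expect_identical(as.character(got), as.character(pr$sequences))
    # force truncation: move a plus-strand TSS too close to the contig start
    gt <- pr$geneTable[pr$geneTable$strand == "+", ][1, ]
    gt$tss <- 500
    gt$exon1_end <- 700
    expect_warning(tr <- extractPromoters(pr$genome, gt), "truncated")
    expect_equal(Biostrings::width(tr), 700)
    expect_error(extractPromoters(pr$genome,
                                  transform(gt, chrom = "chrZZ")),
                 "not in genome")
})
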