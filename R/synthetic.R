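#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards, so seeded draws never perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Independent per-generator substreams: one master seed expands into a fixed
# seed per generator name, so adding a generator never shifts the others.
.substreamSeed <- function(seed, stream) {
    offsets <- c(expression = 11L, promoters = 23L, array = 37L,
                 growth = 53L, survival = 71L, truth = 89L, controls = 97L)
    if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
    ((as.numeric(seed) %% 65521) * 31013 + offsets[[stream]] * 104729) %%
        2147483647
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators.
#' Defaults mirror the published screen's dimensions: 15 expression cohorts,
#' a 702-gene transcription-factor whitelist, a 117-gene target set against
#' 1500 controls, a 345-motif library, and 2 kb promoters; the survival
#' generator's default true hazard ratios are the published
#' prognostic-table values.
#'
#' @param seed master seed; it fully determines every generator's output via
#'   independent substreams.
#' @param nCohorts number of expression cohorts (default 15).
#' @param nGenes genes in the expression universe (default 10000).
#' @param nTfGenes size of the transcription-factor whitelist (default 702);
#'   whitelist genes are the first `nTfGenes` gene ids.
#' @param nSamplesPerGroup samples per group per cohort (default 30); may be
#'   a vector of length `nCohorts` for heterogeneous cohorts.
#' @param effectSize standardized mean shift of planted differential TFs in
#'   the case group (default 1).
#' @param nPlantedDe number of planted differential TF genes (default 50,
#'   capped at `nTfGenes`).
#' @param cohortDropout fraction of genes randomly absent from each cohort,
#'   emulating platform differences (default 0).
#' @param promoterLength promoter length in bases (default 2000: 1 kb
#'   upstream plus first exon).
#' @param nTargetGenes target (signature) promoter-set size (default 117).
#' @param nControlGenes control promoter-set size (default 1500).
#' @param nMotifs motif-library size (default 345).
#' @param motifLength motif length in bases (default 10).
#' @param nPlantedMotifs motifs planted in target promoters (default 10,
#'   capped at `nMotifs`).
#' @param motifPlantRate fraction of target promoters carrying a planted
#'   site (default 0.5).
#' @param controlPlantRate background plant rate in control promoters
#'   (default 0).
#' @param baseComposition length-4 probability vector over A,C,G,T for
#'   background sequence (default uniform).
#' @param arrayFc true case/control binding fold change of bound motifs
#'   (default 2).
#' @param arrayCv coefficient of variation of multiplicative spot noise
#'   (default 0.15).
#' @param growthNoiseSd SD (percent growth) of the growth-screen noise
#'   (default 10).
#' @param nSubjects survival-cohort size (default 1992).
#' @param survBetas named numeric vector of true log-hazard coefficients for
#'   the survival generator.
#' @param censorRate target fraction of censored subjects (default 0.7).
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1,
                      nCohorts = 15, nGenes = 10000, nTfGenes = 702,
                      nSamplesPerGroup = 30, effectSize = 1,
                      nPlantedDe = min(50, nTfGenes),
                      cohortDropout = 0,
                      promoterLength = 2000, nTargetGenes = 117,
                      nControlGenes = 1500, nMotifs = 345, motifLength = 10,
                      nPlantedMotifs = min(10, nMotifs), motifPlantRate = 0.5,
                      controlPlantRate = 0,
                      baseComposition = rep(0.25, 4),
                      arrayFc = 2, arrayCv = 0.15,
                      growthNoiseSd = 10,
                      nSubjects = 1992,
                      survBetas = c(marker = log(1.42), size = log(1.01),
                                    gradeG2 = log(1.54), gradeG3 = log(1.69),
                                    node = log(2.22), subtypeLumB = log(2.04),
                                    subtypeNormal = log(1.71),
                                    subtypeHer2 = log(2.21),
                                    subtypeBasal = log(1.84)),
                      censorRate = 0.7) {
    cfg <- mget(names(formals()))
    chk_pos_int <- function(field) {
        v <- cfg[[field]]
        if (!is.numeric(v) || any(v < 1) || any(v != round(v)))
            stop("invalid configuration: '", field,
                 "' must be a positive integer")
    }
    for (f in c("nCohorts", "nGenes", "nTfGenes", "nSamplesPerGroup",
                "nPlantedDe", "promoterLength", "nTargetGenes",
                "nControlGenes", "nMotifs", "motifLength", "nPlantedMotifs",
                "nSubjects"))
        chk_pos_int(f)
    for (f in c("motifPlantRate", "controlPlantRate", "cohortDropout",
                "censorRate")) {
        v <- cfg[[f]]
        if (!is.numeric(v) || v < 0 || v > 1)
            stop("invalid configuration: '", f, "' must be in [0, 1]")
    }
    if (cfg$nPlantedDe > cfg$nTfGenes)
        stop("invalid configuration: 'nPlantedDe' exceeds 'nTfGenes'")
    if (cfg$nTfGenes > cfg$nGenes)
        stop("invalid configuration: 'nTfGenes' exceeds 'nGenes'")
    if (cfg$nPlantedMotifs > cfg$nMotifs)
        stop("invalid configuration: 'nPlantedMotifs' exceeds 'nMotifs'")
    if (!length(cfg$nSamplesPerGroup) %in% c(1L, cfg$nCohorts))
        stop("invalid configuration: 'nSamplesPerGroup' must have length 1 or nCohorts")
    if (length(cfg$baseComposition) != 4L ||
        abs(sum(cfg$baseComposition) - 1) > 1e-8)
        stop("invalid configuration: 'baseComposition' must be 4 probabilities summing to 1")
    if (cfg$effectSize < 0)
        stop("invalid configuration: 'effectSize' must be non-negative")
    if (cfg$arrayFc <= 0 || cfg$arrayCv < 0)
        stop("invalid configuration: 'arrayFc' must be positive and 'arrayCv' non-negative")
    if (cfg$growthNoiseSd < 0)
        stop("invalid configuration: 'growthNoiseSd' must be non-negative")
    structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
    cat("SimConfig (seed ", x$seed, "): ", x$nCohorts, " cohorts x ",
        x$nGenes, " genes (", x$nTfGenes, " TFs, ", x$nPlantedDe,
        " planted DE); ", x$nMotifs, " motifs (", x$nPlantedMotifs,
        " planted); ", x$nTargetGenes, "/", x$nControlGenes,
        " target/control promoters of ", x$promoterLength, " bp\n", sep = "")
    invisible(x)
}

.geneIds <- function(cfg) sprintf("g%05d", seq_len(cfg$nGenes))

#' Transcription-factor whitelist of a configuration
#'
#' @param cfg a [simConfig()] object.
#' @return character vector of the `nTfGenes` whitelist gene ids.
#' @export
tfWhitelist <- function(cfg) .geneIds(cfg)[seq_len(cfg$nTfGenes)]

#' Generate expression cohorts with planted differential TFs
#'
#' Each cohort holds independent standard-normal log-expression noise for
#' every gene; the planted differentially expressed TF genes get a mean
#' shift of `effectSize` in the case group in every cohort. With
#' `cohortDropout > 0` a random gene subset is absent per cohort, emulating
#' platform differences.
#'
#' @param cfg a [simConfig()] object.
#' @return list with `cohorts` (list of [ExpressionCohort-class]) and
#'   `truth` (list with `de_tfs`, the planted gene ids).
#' @export
simExpressionCohorts <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    genes <- .geneIds(cfg)
    tfs <- tfWhitelist(cfg)
    de_tfs <- if (cfg$effectSize > 0 && cfg$nPlantedDe > 0)
        withSeed(.substreamSeed(cfg$seed, "truth"),
                 sort(sample(tfs, cfg$nPlantedDe)))
    else character()
    npg <- rep(cfg$nSamplesPerGroup, length.out = cfg$nCohorts)
    cohorts <- withSeed(.substreamSeed(cfg$seed, "expression"), {
        lapply(seq_len(cfg$nCohorts), function(i) {
            keep <- genes
            if (cfg$cohortDropout > 0)
                keep <- sort(sample(genes,
                                    round((1 - cfg$cohortDropout) *
                                          length(genes))))
            n <- npg[i]
            vals <- matrix(rnorm(length(keep) * 2 * n), length(keep), 2 * n,
                           dimnames = list(keep, NULL))
            grp <- rep(c("case", "control"), each = n)
            planted <- keep %in% de_tfs
            vals[planted, grp == "case"] <-
                vals[planted, grp == "case"] + cfg$effectSize
            ExpressionCohort(vals, grp, cohortId = sprintf("cohort%02d", i))
        })
    })
    list(cohorts = cohorts, truth = list(de_tfs = de_tfs))
}

#' Generate a synthetic TRANSFAC-style motif library
#'
#' Random sharply peaked count matrices: at every position one base carries
#' most of the 20 observations, so each motif has a well-defined consensus
#' and a usable similarity-score range.
#'
#' @param cfg a [simConfig()] object.
#' @return named list of [PWMatrix-class] objects (`M001`, `M002`, ...).
#' @export
simMotifLibrary <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    withSeed(.substreamSeed(cfg$seed, "promoters") + 1, {
        pwms <- lapply(seq_len(cfg$nMotifs), function(i) {
            cons <- sample.int(4, cfg$motifLength, replace = TRUE)
            counts <- t(vapply(cons, function(b) {
                ct <- rep(0, 4)
                ct[b] <- 19
                minor <- sample(setdiff(1:4, b), 1)
                ct[minor] <- 1
                ct
            }, numeric(4)))
            PWMatrix(counts, motifId = sprintf("M%03d", i))
        })
        names(pwms) <- vapply(pwms, motifId, character(1))
        pwms
    })
}

# draw one site from the PWM's base frequencies
.samplePwmSite <- function(pwm) {
    f <- pwmFrequencies(pwm)
    paste(c("A", "C", "G", "T")[apply(f, 1, function(p) sample.int(4, 1,
                                                                  prob = p))],
          collapse = "")
}

.randomSeq <- function(n, p) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
}

#' Generate promoter sequences with planted motif sites
#'
#' Background promoters are i.i.d. draws from `baseComposition`. For each
#' planted motif, a site sampled from the PWM is inserted (overwriting the
#' background) at a random position in a `motifPlantRate` fraction of target
#' promoters, and at `controlPlantRate` in controls. A toy genome plus gene
#' table (1-based inclusive `tss` / `exon1_end`, mixed strands) is emitted
#' so promoter extraction can be round-tripped.
#'
#' @param cfg a [simConfig()] object.
#' @param pwms motif library (list of [PWMatrix-class]); non-empty.
#' @param targetGenes,controlGenes disjoint character vectors of gene ids;
#'   defaults derive them from the configuration's gene universe.
#' @param plantMotifs motif ids to plant; default: the first
#'   `nPlantedMotifs` of the library.
#' @return list: `sequences` (named DNAStringSet, targets then controls),
#'   `targetGenes`, `controlGenes`, `genome` (DNAStringSet), `geneTable`,
#'   and `truth` (planted motif ids and per-motif insertion records).
#' @export
simPromoters <- function(cfg, pwms, targetGenes = NULL, controlGenes = NULL,
                         plantMotifs = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (!length(pwms)) stop("pwm library is empty")
    maxlen <- max(vapply(pwms, pwmLength, numeric(1)))
    if (cfg$promoterLength < maxlen)
        stop("promoterLength ", cfg$promoterLength,
             " shorter than longest motif (", maxlen, ")")
    genes <- .geneIds(cfg)
    nonTf <- setdiff(genes, tfWhitelist(cfg))
    if (is.null(targetGenes))
        targetGenes <- nonTf[seq_len(cfg$nTargetGenes)]
    if (is.null(controlGenes))
        controlGenes <- nonTf[cfg$nTargetGenes + seq_len(cfg$nControlGenes)]
    if (length(intersect(targetGenes, controlGenes)))
        stop("target and control gene sets must be disjoint")
    if (is.null(plantMotifs))
        plantMotifs <- names(pwms)[seq_len(min(cfg$nPlantedMotifs,
                                               length(pwms)))]
    all_genes <- c(targetGenes, controlGenes)
    is_target <- all_genes %in% targetGenes
    withSeed(.substreamSeed(cfg$seed, "promoters"), {
        seqs <- vapply(all_genes, function(g)
            .randomSeq(cfg$promoterLength, cfg$baseComposition), character(1))
        insertions <- list()
        for (mid in plantMotifs) {
            pwm <- pwms[[mid]]
            L <- pwmLength(pwm)
            rate <- ifelse(is_target, cfg$motifPlantRate, cfg$controlPlantRate)
            carry <- runif(length(all_genes)) < rate
            rec <- data.frame(gene = character(), position = integer(),
                              site = character(), stringsAsFactors = FALSE)
            for (i in which(carry)) {
                site <- .samplePwmSite(pwm)
                pos <- sample.int(cfg$promoterLength - L + 1L, 1L)
                substr(seqs[i], pos, pos + L - 1L) <- site
                rec <- rbind(rec, data.frame(gene = all_genes[i],
                                             position = pos, site = site,
                                             stringsAsFactors = FALSE))
            }
            insertions[[mid]] <- rec
        }
        # toy genome: one contig per gene, promoter embedded between flanks
        flank <- 50L
        strand <- sample(c("+", "-"), length(all_genes), replace = TRUE)
        contigs <- character(length(all_genes))
        tss <- exon1 <- integer(length(all_genes))
        for (i in seq_along(all_genes)) {
            fl <- .randomSeq(flank, cfg$baseComposition)
            fr <- .randomSeq(flank, cfg$baseComposition)
            core <- if (strand[i] == "+") seqs[i] else
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(seqs[i])))
            contigs[i] <- paste0(fl, core, fr)
            if (strand[i] == "+") {
                tss[i] <- flank + 1001L
                exon1[i] <- flank + cfg$promoterLength
            } else {
                exon1[i] <- flank + 1L
                tss[i] <- flank + cfg$promoterLength - 1000L
            }
        }
        sequences <- Biostrings::DNAStringSet(seqs)
        names(sequences) <- all_genes
        genome <- Biostrings::DNAStringSet(contigs)
        names(genome) <- paste0("chr_", all_genes)
        geneTable <- data.frame(gene = all_genes,
                                chrom = paste0("chr_", all_genes),
                                strand = strand, tss = tss,
                                exon1_end = exon1, stringsAsFactors = FALSE)
        list(sequences = sequences, targetGenes = targetGenes,
             controlGenes = controlGenes, genome = genome,
             geneTable = geneTable,
             truth = list(planted_motifs = plantMotifs,
                          insertions = insertions))
    })
}

.defaultGroupMap <- function() {
    data.frame(cell_line = c("HCC1143", "HCC1937", "BT20", "MDA468",
                             "T47D", "MCF7", "BT474", "ZR751"),
               group = rep(c("BLBC", "non-BLBC"), each = 4),
               stringsAsFactors = FALSE)
}

#' Generate protein/DNA array spot intensities
#'
#' Long-format spot intensities per membrane (one membrane per cell line and
#' replicate, triplicate by default). Each motif has a lognormal baseline
#' binding level; bound motifs are multiplied by `arrayFc` in the case
#' (BLBC) group. Noise is multiplicative lognormal with coefficient of
#' variation `arrayCv`; each membrane has its own scale factor, removed by
#' reference normalization. A reference spot (`TFIID`) is always emitted.
#'
#' @param cfg a [simConfig()] object.
#' @param motifIds motif ids to spot; the reference id is appended with a
#'   warning when absent.
#' @param groupMap data.frame `cell_line`, `group`; default: the 4 + 4
#'   published cell-line panel.
#' @param boundMotifs motif ids truly more bound in the case group
#'   (default: first `nPlantedMotifs` of `motifIds`).
#' @param nReplicates membranes per cell line (default 3).
#' @param referenceId reference spot id (default `"TFIID"`).
#' @return list: `scans` (long data.frame `membrane`, `cell_line`,
#'   `replicate`, `motif_id`, `intensity`), `groupMap`, `truth`
#'   (`bound_motifs`).
#' @export
simArrayIntensities <- function(cfg, motifIds, groupMap = .defaultGroupMap(),
                                boundMotifs = NULL, nReplicates = 3,
                                referenceId = "TFIID") {
    stopifnot(inherits(cfg, "SimConfig"))
    if (!referenceId %in% motifIds) {
        warning("reference spot '", referenceId, "' added to motif ids")
        motifIds <- c(motifIds, referenceId)
    }
    if (is.null(boundMotifs)) {
        pool <- setdiff(motifIds, referenceId)
        boundMotifs <- pool[seq_len(min(cfg$nPlantedMotifs, length(pool)))]
    }
    if (cfg$arrayFc == 1) boundMotifs <- character()
    sdlog <- sqrt(log(1 + cfg$arrayCv^2))
    noise <- function(n) if (sdlog == 0) rep(1, n) else
        rlnorm(n, -sdlog^2 / 2, sdlog)   # mean-1 multiplicative noise
    withSeed(.substreamSeed(cfg$seed, "array"), {
        base_level <- setNames(rlnorm(length(motifIds), 0, 0.25), motifIds)
        base_level[referenceId] <- 1
        rows <- list()
        for (i in seq_len(nrow(groupMap))) {
            cl <- groupMap$cell_line[i]
            mult <- ifelse(motifIds %in% boundMotifs &
                           groupMap$group[i] == "BLBC", cfg$arrayFc, 1)
            for (r in seq_len(nReplicates)) {
                scale <- rlnorm(1, log(1000), 0.2)   # membrane exposure
                ints <- scale * base_level * mult * noise(length(motifIds))
                rows[[length(rows) + 1L]] <- data.frame(
                    membrane = paste0(cl, "_rep", r), cell_line = cl,
                    replicate = r, motif_id = motifIds,
                    intensity = unname(ints), stringsAsFactors = FALSE)
            }
        }
        list(scans = do.call(rbind, rows), groupMap = groupMap,
             truth = list(bound_motifs = boundMotifs))
    })
}

#' Generate a secondary growth-screen table
#'
#' Non-critical siRNAs are centered at 100% growth; planted critical TFs
#' follow a per-line suppression pattern (default: means of 50 in BLBC
#' lines, 95 in non-BLBC lines). Gaussian noise with SD `growthNoiseSd` is
#' added to the reported means; negative draws are floored at 0.
#'
#' @param cfg a [simConfig()] object.
#' @param tfs character vector of siRNA target gene ids.
#' @param groupMap data.frame `cell_line`, `group` (default: 3 BLBC + 3
#'   non-BLBC lines).
#' @param criticalTfs gene ids planted as BLBC growth-critical (default
#'   none).
#' @param pattern named numeric of length 2 giving the planted means,
#'   `c(BLBC = 50, nonBLBC = 95)` by default.
#' @return list: `table` (long data.frame `siRNA`, `cell_line`, `mean`,
#'   `sd`), `groupMap`, `truth` (`critical_tfs`).
#' @export
simGrowthTable <- function(cfg, tfs,
                           groupMap = data.frame(
                               cell_line = c("BT20", "HCC1143", "MDA468",
                                             "MCF7", "T47D", "ZR751"),
                               group = rep(c("BLBC", "non-BLBC"), each = 3),
                               stringsAsFactors = FALSE),
                           criticalTfs = character(),
                           pattern = c(BLBC = 50, nonBLBC = 95)) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (length(setdiff(criticalTfs, tfs)))
        stop("criticalTfs must be a subset of tfs")
    withSeed(.substreamSeed(cfg$seed, "growth"), {
        grid <- expand.grid(siRNA = tfs, cell_line = groupMap$cell_line,
                            stringsAsFactors = FALSE)
        grp <- setNames(groupMap$group, groupMap$cell_line)
        center <- ifelse(grid$siRNA %in% criticalTfs,
                         ifelse(grp[grid$cell_line] == "BLBC",
                                pattern[["BLBC"]], pattern[["nonBLBC"]]),
                         100)
        grid$mean <- pmax(0, center + rnorm(nrow(grid), 0, cfg$growthNoiseSd))
        grid$sd <- round(pmax(1, rnorm(nrow(grid), cfg$growthNoiseSd,
                                       cfg$growthNoiseSd / 3)), 1)
        grid <- grid[order(match(grid$siRNA, tfs),
                           match(grid$cell_line, groupMap$cell_line)), ]
        rownames(grid) <- NULL
        list(table = grid, groupMap = groupMap,
             truth = list(critical_tfs = criticalTfs))
    })
}

#' Generate a survival cohort under exponential proportional hazards
#'
#' Event times are exponential with subject rate
#' `lambda0 * exp(linear predictor)`; the linear predictor is the sum of
#' the configured true log-hazard coefficients times the covariates
#' (binary high-marker indicator from a median split of a standard-normal
#' marker, tumor size in mm, grade, nodal status, intrinsic subtype).
#' Independent uniform censoring is calibrated analytically so the expected
#' censored fraction equals `censorRate`.
#'
#' @param cfg a [simConfig()] object; `cfg$survBetas` supplies the true
#'   coefficients (missing names default to 0).
#' @param lambda0 baseline hazard per unit time (default 0.002).
#' @return list: `cohort` (data.frame `time`, `event`, `marker`, `size`,
#'   `grade`, `node`, `subtype`), `truth` (`betas`, `lambda0`).
#' @export
simSurvivalCohort <- function(cfg, lambda0 = 0.002) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (cfg$censorRate < 0) stop("censorRate must be non-negative")
    b <- function(nm) if (nm %in% names(cfg$survBetas))
        cfg$survBetas[[nm]] else 0
    withSeed(.substreamSeed(cfg$seed, "survival"), {
        n <- cfg$nSubjects
        marker <- rnorm(n)
        high <- as.integer(marker > median(marker))
        size <- rgamma(n, shape = 4, scale = 6.5)           # tumor size, mm
        grade <- factor(sample(c("G1", "G2", "G3", "GNA"), n, replace = TRUE,
                               prob = c(170, 775, 957, 90) / 1992),
                        levels = c("G1", "G2", "G3", "GNA"))
        node <- rbinom(n, 1, 950 / 1992)
        subtype <- factor(sample(c("LumA", "LumB", "Normal", "Her2", "Basal"),
                                 n, replace = TRUE,
                                 prob = c(721, 492, 202, 240, 331) / 1986),
                          levels = c("LumA", "LumB", "Normal", "Her2",
                                     "Basal"))
        lp <- b("marker") * high + b("size") * (size - mean(size)) +
            b("gradeG2") * (grade == "G2") + b("gradeG3") * (grade == "G3") +
            b("gradeGNA") * (grade == "GNA") + b("node") * node +
            b("subtypeLumB") * (subtype == "LumB") +
            b("subtypeNormal") * (subtype == "Normal") +
            b("subtypeHer2") * (subtype == "Her2") +
            b("subtypeBasal") * (subtype == "Basal")
        rate <- lambda0 * exp(lp)
        tt <- rexp(n, rate)
        if (cfg$censorRate == 0) {
            time <- tt; event <- rep(1L, n)
        } else {
            # E[censored | C ~ U(0, bmax)] = mean over subjects of
            # (1 - exp(-r bmax)) / (r bmax); solve for bmax
            cens_frac <- function(bmax)
                mean((1 - exp(-rate * bmax)) / (rate * bmax))
            bmax <- uniroot(function(bm) cens_frac(bm) - cfg$censorRate,
                            lower = 1e-6, upper = 1e9, tol = 1e-8)$root
            cc <- runif(n, 0, bmax)
            event <- as.integer(tt <= cc)
            time <- pmin(tt, cc)
        }
        cohort <- data.frame(time = time, event = event, marker = marker,
                             size = size, grade = grade, node = node,
                             subtype = subtype)
        list(cohort = cohort,
             truth = list(betas = cfg$survBetas, lambda0 = lambda0))
    })
}
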