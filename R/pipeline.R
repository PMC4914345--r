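#' Run the full primary screen on synthetic data
#'
#' End-to-end composition of the three assays with planted ground truth:
#'
#' 1. *RNA*: simulated expression cohorts, per-cohort one-sided testing,
#'    median-rank aggregation, candidate selection at `alphaRna`.
#' 2. *DNA*: three signature cohorts with strongly elevated target genes,
#'    signature-set derivation at `alphaGeneset`, seeded control-gene
#'    sampling, promoter simulation with planted motif sites, similarity
#'    scanning at `scanThreshold`, exact-binomial enrichment at
#'    `alphaMotif`, motif-to-gene mapping.
#' 3. *Protein*: simulated reference-normalized binding arrays, per-line
#'    summaries, Student t comparison, the joint fold-change/p filter.
#'
#' Candidates are the genes found by at least `minAssays` assays. The
#' synthetic motif library annotates motif `i` to TF gene `i`, planted
#' motifs are the motifs of planted differential TFs, and bound motifs a
#' configurable fraction of those, so recovery of the planted truth can be
#' measured.
#'
#' @param cfg a [simConfig()] object.
#' @param alphaRna RNA median-rank cutoff (default 0.05).
#' @param alphaGeneset per-cohort signature cutoff (default 0.01).
#' @param alphaMotif motif-enrichment cutoff (default 0.05).
#' @param fcMin,alphaArray protein-array filter (defaults 1.4, 0.05).
#' @param minAssays integration rule (default 2).
#' @param scanThreshold similarity-score scan threshold (default 0.85).
#' @param genesetEffect effect size of target genes in the signature
#'   cohorts (default 3, large enough for near-exact recovery).
#' @param boundFraction fraction of planted motifs also truly bound on the
#'   array (default 0.5).
#' @return list with `candidates` (the [integrateAssays()] table), per-stage
#'   gene/motif sets, `truth`, and a `funnel` of counts at each filter.
#' @export
runPrimaryScreen <- function(cfg, alphaRna = 0.05, alphaGeneset = 0.01,
                             alphaMotif = 0.05, fcMin = 1.4,
                             alphaArray = 0.05, minAssays = 2,
                             scanThreshold = 0.85, genesetEffect = 3,
                             boundFraction = 0.5) {
    stopifnot(inherits(cfg, "SimConfig"))

    ## RNA stage
    expr <- simExpressionCohorts(cfg)
    meta <- metaRankScreen(expr$cohorts)
    rnaGenes <- selectCandidates(meta, alpha = alphaRna,
                                 tfWhitelist = tfWhitelist(cfg))

    ## DNA stage: signature set from three dedicated cohorts
    sigCfg <- cfg
    sigCfg$seed <- cfg$seed + 1
    sigCfg$nCohorts <- 3
    sigCfg$effectSize <- genesetEffect
    sigCfg$nPlantedDe <- 0
    sigTargets <- setdiff(.geneIds(cfg),
                          tfWhitelist(cfg))[seq_len(cfg$nTargetGenes)]
    sigCohorts <- withSeed(.substreamSeed(sigCfg$seed, "expression"), {
        npg <- rep(sigCfg$nSamplesPerGroup, length.out = 3)
        lapply(1:3, function(i) {
            n <- npg[i]
            vals <- matrix(rnorm(cfg$nGenes * 2 * n), cfg$nGenes, 2 * n,
                           dimnames = list(.geneIds(cfg), NULL))
            grp <- rep(c("case", "control"), each = n)
            planted <- .geneIds(cfg) %in% sigTargets
            vals[planted, grp == "case"] <-
                vals[planted, grp == "case"] + genesetEffect
            ExpressionCohort(vals, grp, cohortId = sprintf("sig%02d", i))
        })
    })
    signature <- deriveSignatureGeneSet(sigCohorts, alpha = alphaGeneset)
    perCohortSig <- unique(unlist(lapply(sigCohorts, function(co) {
        p <- dePValues(co)
        names(p)[p < alphaGeneset]
    })))
    controls <- sampleControlGenes(.geneIds(cfg),
                                   excluded = union(perCohortSig, signature),
                                   n = cfg$nControlGenes,
                                   seed = .substreamSeed(cfg$seed, "controls"))

    pwms <- simMotifLibrary(cfg)
    # annotate every planted differential TF to a motif first, so the
    # planted truth is recoverable by the motif-based assays; remaining
    # motifs cycle over the rest of the whitelist
    de_tfs <- expr$truth$de_tfs
    if (length(de_tfs) > length(pwms))
        stop("nMotifs must be >= nPlantedDe for a recoverable truth")
    others <- setdiff(tfWhitelist(cfg), de_tfs)
    n_rest <- length(pwms) - length(de_tfs)
    motifGeneMap <- data.frame(
        motif_id = names(pwms),
        gene_symbol = c(de_tfs,
                        others[(seq_len(n_rest) - 1L) %% length(others) + 1L]),
        stringsAsFactors = FALSE)
    geneMotif <- setNames(motifGeneMap$motif_id, motifGeneMap$gene_symbol)
    plantMotifs <- unname(geneMotif[de_tfs])
    prom <- simPromoters(cfg, pwms, targetGenes = signature,
                         controlGenes = controls,
                         plantMotifs = plantMotifs)
    targets_seq <- prom$sequences[prom$targetGenes]
    controls_seq <- prom$sequences[prom$controlGenes]
    enrich <- motifEnrichmentTable(pwms, targets_seq, controls_seq,
                                   threshold = scanThreshold)
    dnaMotifs <- selectEnriched(enrich, alpha = alphaMotif)
    dnaGenes <- suppressWarnings(mapMotifsToGenes(dnaMotifs, motifGeneMap))

    ## Protein stage
    boundMotifs <- plantMotifs[seq_len(ceiling(boundFraction *
                                               length(plantMotifs)))]
    arr <- simArrayIntensities(cfg, motifIds = names(pwms),
                               boundMotifs = boundMotifs)
    norm <- normalizeToReference(arr$scans)
    lm_ <- summarizeCellLines(norm)
    comp <- compareGroups(lm_, arr$groupMap)
    protMotifs <- selectBoundMotifs(comp, fcMin = fcMin, alpha = alphaArray)
    proteinGenes <- suppressWarnings(mapMotifsToGenes(protMotifs,
                                                      motifGeneMap))

    candidates <- integrateAssays(rnaGenes, dnaGenes, proteinGenes,
                                  minAssays = minAssays)
    funnel <- c(tf_whitelist = cfg$nTfGenes,
                rna_selected = length(rnaGenes),
                signature_genes = length(signature),
                motifs_enriched = length(dnaMotifs),
                dna_genes = length(dnaGenes),
                motifs_bound = length(protMotifs),
                protein_genes = length(proteinGenes),
                candidates = sum(candidates$candidate))
    list(candidates = candidates, rnaGenes = rnaGenes, dnaGenes = dnaGenes,
         proteinGenes = proteinGenes, signature = signature,
         enrichment = enrich, comparisons = comp,
         motifGeneMap = motifGeneMap, meta = meta, funnel = funnel,
         truth = list(de_tfs = expr$truth$de_tfs,
                      planted_motifs = plantMotifs,
                      bound_motifs = boundMotifs))
}

#' Run the secondary growth screen
#'
#' @param table growth table (`siRNA`, `cell_line`, `mean`, `sd`) or a path
#'   to a TSV of that shape.
#' @param groupMap data.frame `cell_line`, `group` or path to a TSV.
#' @param minLines,reducedMax hit-calling rule (defaults 2 and 66).
#' @return the [classifySpecificity()] table, with the critical set in the
#'   `"critical"` attribute.
#' @export
runSecondaryScreen <- function(table, groupMap, minLines = 2,
                               reducedMax = 66) {
    if (is.character(table)) table <- readGrowthTable(table)
    if (is.character(groupMap))
        groupMap <- read.delim(groupMap, stringsAsFactors = FALSE)
    calls <- classifySpecificity(table, groupMap, minLines = minLines,
                                 reducedMax = reducedMax)
    attr(calls, "critical") <- calls$siRNA[calls$class != "not-critical"]
    calls
}

#' Planted-truth recall of the primary screen
#'
#' @param screen result of [runPrimaryScreen()].
#' @return fraction of planted differential TFs among the final candidates.
#' @export
screenRecall <- function(screen) {
    truth <- screen$truth$de_tfs
    if (!length(truth)) return(NA_real_)
    mean(truth %in% candidateGenes(screen$candidates))
}

#' Write and read a run configuration
#'
#' Serializes a [simConfig()] (plus optional screen thresholds) as YAML so a
#' run can be archived and repeated; `readRunConfig()` re-validates through
#' [simConfig()], and a written configuration reads back identical.
#'
#' @param cfg a [simConfig()] object.
#' @param path YAML file path.
#' @param thresholds optional named list of screen thresholds stored
#'   alongside the generator settings.
#' @return `writeRunConfig()` returns `path`; `readRunConfig()` returns a
#'   list with elements `cfg` and `thresholds`.
#' @export
writeRunConfig <- function(cfg, path, thresholds = list()) {
    stopifnot(inherits(cfg, "SimConfig"))
    sim <- unclass(cfg)
    sim$survBetas <- as.list(sim$survBetas)   # keep names in the YAML map
    yaml::write_yaml(list(simulation = sim, thresholds = thresholds), path,
                     precision = 15)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    sim <- raw$simulation
    for (f in c("survBetas", "baseComposition", "nSamplesPerGroup"))
        if (!is.null(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
    list(cfg = do.call(simConfig, sim),
         thresholds = raw$thresholds)
}
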