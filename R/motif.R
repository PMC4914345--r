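#' Parse a TRANSFAC-style flat file of position weight matrices
#'
#' Reads records delimited by `//`. Within a record, `ID` (or `AC`/`NA` as
#' fallback) names the motif and numbered rows carry four base counts in
#' A, C, G, T order, optionally followed by a consensus letter. `P0`/`PO`
#' column headers and `XX` spacers are ignored.
#'
#' @param path path to a TRANSFAC flat file.
#' @param pseudocount per-base pseudocount for the returned matrices.
#' @return A named list of [PWMatrix-class] objects in file order.
#' @seealso [writeTransfac()]
#' @export
parseTransfac <- function(path, pseudocount = 0.25) {
    lines <- readLines(path)
    pwms <- list()
    id <- acc <- nm <- NA_character_
    rows <- list()
    rec_start <- 1L
    flush <- function(term_line) {
        if (all(is.na(c(id, acc, nm))) && !length(rows)) return(NULL)
        if (!length(rows))
            stop("record ending at line ", term_line,
                 " has no count rows (id: ", id, ")")
        mid <- if (!is.na(id)) id else if (!is.na(acc)) acc else nm
        counts <- do.call(rbind, rows)
        PWMatrix(counts, motifId = mid, pseudocount = pseudocount)
    }
    for (i in seq_along(lines)) {
        ln <- lines[[i]]
        if (grepl("^//", ln)) {
            p <- flush(i)
            if (!is.null(p)) pwms[[p@motifId]] <- p
            id <- acc <- nm <- NA_character_
            rows <- list()
            rec_start <- i + 1L
            next
        }
        code <- substr(ln, 1L, 2L)
        val <- trimws(substr(ln, 3L, nchar(ln)))
        if (code == "ID") id <- val
        else if (code == "AC") acc <- val
        else if (code == "NA") nm <- val
        else if (grepl("^[0-9]+\\s", ln)) {
            parts <- strsplit(trimws(ln), "\\s+")[[1]]
            if (length(parts) < 5L)
                stop("malformed count row at line ", i, " (record ",
                     if (!is.na(id)) id else rec_start, "): '", ln, "'")
            cts <- suppressWarnings(as.numeric(parts[2:5]))
            if (any(is.na(cts)))
                stop("non-numeric count at line ", i, " (record ",
                     if (!is.na(id)) id else rec_start, "): '", ln, "'")
            rows[[length(rows) + 1L]] <- cts
        }
        # other field codes (XX, P0, BF, DE, ...) carry no counts
    }
    if (length(rows) || !all(is.na(c(id, acc, nm))))
        stop("file ends without '//' terminator (record starting near line ",
             rec_start, ")")
    pwms
}

#' Write PWMatrix objects as a TRANSFAC flat file
#'
#' @param pwms list of [PWMatrix-class] objects.
#' @param path output path.
#' @export
writeTransfac <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (p in pwms) {
        writeLines(c(paste("ID", p@motifId), "P0      A      C      G      T"),
                   con)
        cts <- pwmCounts(p)
        cons <- strsplit(pwmConsensus(p), "")[[1]]
        for (i in seq_len(nrow(cts)))
            writeLines(sprintf("%02d %6g %6g %6g %6g %s", i,
                               cts[i, 1], cts[i, 2], cts[i, 3], cts[i, 4],
                               cons[i]), con)
        writeLines("//", con)
    }
    invisible(path)
}

# map a character sequence to integer codes 0..3 (ACGT), 4 otherwise
.seqToInt <- function(sequence) {
    s <- chartr("acgtu", "ACGTT", as.character(sequence))
    m <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    m[is.na(m)] <- 5L
    m - 1L
}

.revCompInt <- function(seq_int) {
    out <- rev(seq_int)
    comp <- c(3L, 2L, 1L, 0L, 4L)   # A<->T, C<->G, N->N
    comp[out + 1L]
}

#' Matrix similarity score of one site
#'
#' Scores a subsequence of the motif's length against a PWM with the
#' information-weighted, min-max-normalized matrix similarity score:
#' `score = (S - Smin) / (Smax - Smin)` where
#' `S = sum_i I(i) f_i(b_i)`, `I(i) = sum_b f_i(b) log(4 f_i(b))`, and
#' `Smin`/`Smax` are the worst/best achievable sums. An `N` contributes the
#' position minimum. The consensus sequence scores exactly 1, the
#' anti-consensus exactly 0.
#'
#' @param pwm a [PWMatrix-class].
#' @param subsequence character (or DNAString) of length `pwmLength(pwm)`
#'   over A, C, G, T, N.
#' @return similarity score in `[0, 1]`.
#' @examples
#' pwm <- PWMatrix(rbind(c(8, 0, 0, 0), c(0, 0, 8, 0),
#'                       c(0, 8, 0, 0), c(0, 0, 0, 8)), "toy")
#' scoreSite(pwm, "AGCT")
#' @export
scoreSite <- function(pwm, subsequence) {
    si <- .seqToInt(subsequence)
    if (length(si) != pwmLength(pwm))
        stop("subsequence length ", length(si), " != motif length ",
             pwmLength(pwm))
    w <- .pwmWeightMatrix(pwm@counts, pwm@pseudocount)
    wmin <- apply(w, 1, min)
    vals <- wmin                       # N contributes the position minimum
    ok <- si < 4L
    vals[ok] <- w[cbind(which(ok), si[ok] + 1L)]
    rng <- c(sum(wmin), sum(apply(w, 1, max)))
    (sum(vals) - rng[1]) / (rng[2] - rng[1])
}

#' Scan a promoter sequence for PWM hits
#'
#' Slides the motif over the sequence (and, by default, its reverse
#' complement), reporting every window whose matrix similarity score
#' ([scoreSite()]) reaches the threshold. Positions are 1-based starts on
#' the forward strand regardless of strand; output rows are ordered by
#' position, with `+` before `-` at the same position.
#'
#' @param pwm a [PWMatrix-class].
#' @param sequence character or DNAString; a sequence shorter than the motif
#'   yields an empty hit list.
#' @param threshold similarity score cutoff in `[0, 1]` (default 0.85).
#' @param bothStrands scan the reverse complement too (default TRUE).
#' @return data.frame with columns `position`, `strand`, `score`.
#' @export
scanPromoter <- function(pwm, sequence, threshold = 0.85, bothStrands = TRUE) {
    stopifnot(threshold >= 0, threshold <= 1)
    si <- .seqToInt(sequence)
    L <- pwmLength(pwm)
    empty <- data.frame(position = integer(), strand = character(),
                        score = numeric(), stringsAsFactors = FALSE)
    if (length(si) < L) return(empty)
    w <- .pwmWeightMatrix(pwm@counts, pwm@pseudocount)
    wmin <- apply(w, 1, min)
    rng <- c(sum(wmin), sum(apply(w, 1, max)))
    norm <- function(s) (s - rng[1]) / (rng[2] - rng[1])
    fwd <- norm(scan_scores(si, w, wmin))
    fi <- which(fwd >= threshold)
    hits <- data.frame(position = fi, strand = rep("+", length(fi)),
                       score = fwd[fi], stringsAsFactors = FALSE)
    if (bothStrands) {
        rv <- norm(scan_scores(.revCompInt(si), w, wmin))
        ri <- which(rv >= threshold)
        if (length(ri)) {
            n <- length(si)
            hits <- rbind(hits, data.frame(
                position = n - ri - L + 2L,   # window start on forward strand
                strand = rep("-", length(ri)),
                score = rv[ri], stringsAsFactors = FALSE))
        }
    }
    hits <- hits[order(hits$position, hits$strand == "-"), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

# integer-coded forward and reverse-complement strands, computed once per set
.precompStrands <- function(sequences) {
    fwd <- lapply(as.character(sequences), .seqToInt)
    list(fwd = fwd, rev = lapply(fwd, .revCompInt))
}

# number of sequences with >= 1 hit for one pwm; `precomp` avoids re-coding
# the sequences for every motif of a library
.countOccurrences <- function(pwm, sequences, threshold, bothStrands = TRUE,
                              precomp = NULL) {
    w <- .pwmWeightMatrix(pwm@counts, pwm@pseudocount)
    wmin <- apply(w, 1, min)
    rng <- c(sum(wmin), sum(apply(w, 1, max)))
    cut <- rng[1] + threshold * (rng[2] - rng[1])
    if (is.null(precomp)) precomp <- .precompStrands(sequences)
    sum(scan_any_hit(precomp$fwd, precomp$rev, w, wmin, cut, bothStrands))
}

#' Motif over-representation in target versus control promoters
#'
#' Counts, for one motif, the promoters containing at least one hit
#' (binary per-promoter occurrence) in the target and control sets, and
#' tests over-representation two ways: an upper-tail exact binomial test of
#' the target count at the control occurrence proportion, and a one-sided
#' Fisher exact test on the 2x2 occurrence table. The binomial test is the
#' default decision rule.
#'
#' @param pwm a [PWMatrix-class].
#' @param targets,controls DNAStringSet (or character vector) of promoter
#'   sequences; both non-empty.
#' @param threshold scan similarity threshold (default 0.85).
#' @param bothStrands scan both strands (default TRUE).
#' @return one-row data.frame: `motif_id`, `k_target`, `n_target`,
#'   `k_control`, `n_control`, `p_binomial`, `p_fisher`.
#' @export
motifEnrichment <- function(pwm, targets, controls, threshold = 0.85,
                            bothStrands = TRUE) {
    if (!length(targets) || !length(controls))
        stop("target and control sets must be non-empty")
    .motifEnrichmentPre(pwm, .precompStrands(targets), length(targets),
                        .precompStrands(controls), length(controls),
                        threshold, bothStrands)
}

.motifEnrichmentPre <- function(pwm, preT, nt, preC, nc, threshold,
                                bothStrands) {
    kt <- .countOccurrences(pwm, NULL, threshold, bothStrands, precomp = preT)
    kc <- .countOccurrences(pwm, NULL, threshold, bothStrands, precomp = preC)
    p0 <- kc / nc
    if (kc == 0L && kt > 0L) {
        p0 <- 0.5 / nc
        warning("motif '", motifId(pwm),
                "': no control occurrences; null proportion floored at 0.5/",
                nc)
    }
    pb <- stats::binom.test(kt, nt, p = p0, alternative = "greater")$p.value
    pf <- stats::fisher.test(matrix(c(kt, nt - kt, kc, nc - kc), nrow = 2),
                             alternative = "greater")$p.value
    data.frame(motif_id = motifId(pwm), k_target = kt, n_target = nt,
               k_control = kc, n_control = nc,
               p_binomial = pb, p_fisher = pf, stringsAsFactors = FALSE)
}

#' Enrichment table over a motif library
#'
#' @param pwms list of [PWMatrix-class] objects.
#' @inheritParams motifEnrichment
#' @return data.frame with one [motifEnrichment()] row per motif.
#' @export
motifEnrichmentTable <- function(pwms, targets, controls, threshold = 0.85,
                                 bothStrands = TRUE) {
    preT <- .precompStrands(targets)
    preC <- .precompStrands(controls)
    do.call(rbind, lapply(pwms, .motifEnrichmentPre, preT = preT,
                          nt = length(targets), preC = preC,
                          nc = length(controls), threshold = threshold,
                          bothStrands = bothStrands))
}

#' Select over-represented motifs
#'
#' @param records data.frame from [motifEnrichmentTable()].
#' @param alpha significance cutoff (default 0.05, uncorrected).
#' @param test which p-value decides: exact binomial (default) or Fisher.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default "none").
#' @return character vector of selected motif ids, most significant first.
#' @export
selectEnriched <- function(records, alpha = 0.05,
                           test = c("binomial", "fisher"), adjust = "none") {
    test <- match.arg(test)
    p <- if (test == "binomial") records$p_binomial else records$p_fisher
    p <- stats::p.adjust(p, method = adjust)
    sel <- which(p < alpha)
    records$motif_id[sel[order(p[sel])]]
}

#' Signature gene set from independent cohorts
#'
#' Intersects, across cohorts, the genes significantly more highly expressed
#' in the case group (one-sided Welch p below `alpha` per cohort) — the rule
#' that builds the basal-like signature gene set whose promoters feed the
#' motif screen.
#'
#' @param cohorts list of [ExpressionCohort-class] objects (typically three).
#' @param alpha per-cohort one-sided significance cutoff (default 0.01).
#' @return character vector of gene ids, sorted.
#' @export
deriveSignatureGeneSet <- function(cohorts, alpha = 0.01) {
    if (!length(cohorts)) stop("at least one cohort required")
    sets <- lapply(cohorts, function(co) {
        p <- dePValues(co)
        names(p)[p < alpha]
    })
    sort(Reduce(intersect, sets))
}

#' Seeded control-gene sample
#'
#' Draws `n` control genes uniformly without replacement from the universe
#' after removing the excluded (case-elevated) genes.
#'
#' @param universe character vector of candidate gene ids.
#' @param excluded gene ids to remove before sampling.
#' @param n sample size (default 1500).
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return character vector of `n` gene ids.
#' @export
sampleControlGenes <- function(universe, excluded = character(), n = 1500,
                               seed = 1) {
    pool <- setdiff(universe, excluded)
    if (length(pool) < n)
        stop("control pool has ", length(pool), " genes; ", n,
             " requested (short by ", n - length(pool), ")")
    withSeed(seed, sample(pool, n))
}

#' Extract promoter regions from a genome
#'
#' Promoter = 1 kb upstream of the TSS through the end of exon 1, on the
#' gene's strand. The gene table uses 1-based inclusive coordinates with
#' columns `gene`, `chrom`, `strand`, `tss`, `exon1_end`. Regions running
#' off a contig edge are truncated with a warning; minus-strand regions are
#' reverse-complemented.
#'
#' @param genome named [Biostrings::DNAStringSet] of contigs.
#' @param geneTable data.frame as described above.
#' @param upstream bases upstream of the TSS (default 1000).
#' @return [Biostrings::DNAStringSet] named by gene.
#' @export
extractPromoters <- function(genome, geneTable, upstream = 1000) {
    need <- c("gene", "chrom", "strand", "tss", "exon1_end")
    if (!all(need %in% names(geneTable)))
        stop("geneTable must have columns: ", paste(need, collapse = ", "))
    seqs <- character(nrow(geneTable))
    for (i in seq_len(nrow(geneTable))) {
        g <- geneTable[i, ]
        if (!g$chrom %in% names(genome))
            stop("contig '", g$chrom, "' not in genome (gene ", g$gene, ")")
        clen <- Biostrings::width(genome[g$chrom])
        if (g$strand == "+") {
            s <- g$tss - upstream; e <- g$exon1_end
        } else {
            s <- g$exon1_end; e <- g$tss + upstream
        }
        if (s < 1 || e > clen) {
            warning("promoter of ", g$gene, " truncated at contig edge")
            s <- max(s, 1); e <- min(e, clen)
        }
        sq <- Biostrings::subseq(genome[[g$chrom]], s, e)
        if (g$strand == "-") sq <- Biostrings::reverseComplement(sq)
        seqs[i] <- as.character(sq)
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- geneTable$gene
    out
}
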