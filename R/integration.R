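#' Map motifs to the transcription-factor genes that recognize them
#'
#' @param motifs character vector of motif ids.
#' @param motifGeneMap data.frame with columns `motif_id`, `gene_symbol`
#'   (one pair per row); a motif may map to several genes.
#' @return character vector: the sorted union of mapped gene symbols.
#'   Motifs without a mapping are reported with a warning and carried in
#'   the `"unmapped"` attribute.
#' @export
mapMotifsToGenes <- function(motifs, motifGeneMap) {
    if (!all(c("motif_id", "gene_symbol") %in% names(motifGeneMap)))
        stop("motifGeneMap must have columns motif_id, gene_symbol")
    hit <- motifGeneMap[motifGeneMap$motif_id %in% motifs, , drop = FALSE]
    unmapped <- setdiff(motifs, motifGeneMap$motif_id)
    if (length(unmapped))
        warning(length(unmapped), " motif(s) without gene annotation: ",
                paste(head(unmapped, 5), collapse = ", "))
    genes <- sort(unique(hit$gene_symbol))
    attr(genes, "unmapped") <- unmapped
    genes
}

#' Integrate the three assays into a candidate table
#'
#' Builds the full membership table over the union of genes returned by the
#' RNA, DNA-motif and protein-binding screens and flags as candidates the
#' genes found by at least `minAssays` of the three. Candidates sort first
#' (by number of supporting assays, descending, then alphabetically). The
#' `"venn"` attribute carries the seven-region occupancy counts.
#'
#' @param rnaGenes,dnaGenes,proteinGenes character vectors of gene symbols
#'   selected by each assay (any may be empty).
#' @param minAssays minimum number of supporting assays (1-3, default 2).
#' @return data.frame: `gene`, `in_rna`, `in_dna`, `in_protein`,
#'   `n_assays`, `candidate`; attribute `"venn"` is a named integer vector
#'   over regions `rna_only`, `dna_only`, `protein_only`, `rna_dna_only`,
#'   `rna_protein_only`, `dna_protein_only`, `all_three`.
#' @export
integrateAssays <- function(rnaGenes, dnaGenes, proteinGenes,
                            minAssays = 2) {
    if (!minAssays %in% 1:3)
        stop("minAssays must be 1, 2 or 3")
    genes <- sort(unique(c(rnaGenes, dnaGenes, proteinGenes)))
    tab <- data.frame(gene = genes,
                      in_rna = genes %in% rnaGenes,
                      in_dna = genes %in% dnaGenes,
                      in_protein = genes %in% proteinGenes,
                      stringsAsFactors = FALSE)
    tab$n_assays <- tab$in_rna + tab$in_dna + tab$in_protein
    tab$candidate <- tab$n_assays >= minAssays
    tab <- tab[order(-tab$n_assays, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    venn <- c(
        rna_only = sum(tab$in_rna & !tab$in_dna & !tab$in_protein),
        dna_only = sum(!tab$in_rna & tab$in_dna & !tab$in_protein),
        protein_only = sum(!tab$in_rna & !tab$in_dna & tab$in_protein),
        rna_dna_only = sum(tab$in_rna & tab$in_dna & !tab$in_protein),
        rna_protein_only = sum(tab$in_rna & !tab$in_dna & tab$in_protein),
        dna_protein_only = sum(!tab$in_rna & tab$in_dna & tab$in_protein),
        all_three = sum(tab$in_rna & tab$in_dna & tab$in_protein))
    attr(tab, "venn") <- venn
    tab
}

#' Candidate genes from an integration table
#'
#' @param candidateTable data.frame from [integrateAssays()].
#' @return character vector of candidate gene symbols, in table order.
#' @export
candidateGenes <- function(candidateTable)
    candidateTable$gene[candidateTable$candidate]
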