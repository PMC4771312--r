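# Gene-neighborhood extraction around focal genes (e.g. TBDTs), family
# enrichment by one-sided Fisher's exact test with BH correction, and
# colocalization-rule locus classification.

#' Extract the gene neighborhood around a focal gene
#'
#' Returns the genes within \code{windowGenes} positions of the focal gene
#' in contig gene order (up to \code{2 * windowGenes + 1} records),
#' truncated at contig ends.  The focal gene is included and flagged in a
#' \code{focal} metadata column.
#'
#' @param genome a [GenomeTable-class].
#' @param geneId focal gene id.
#' @param windowGenes window half-width in genes (default 10, the
#'   conventional span for transporter-context analyses).
#' @return a GRanges subset of the genome's gene records with an added
#'   \code{focal} column.
#' @export
extractNeighborhood <- function(genome, geneId, windowGenes = 10L) {
    gr <- geneRecords(genome)
    md <- mcols(gr)
    i <- match(geneId, md$gene_id)
    if (is.na(i))
        mtStop("unknown_gene_error", paste("unknown gene:", geneId))
    contig <- as.character(seqnames(gr))[i]
    on_contig <- which(as.character(seqnames(gr)) == contig)
    idx <- md$index[i]
    sel <- on_contig[md$index[on_contig] >= idx - windowGenes &
                     md$index[on_contig] <= idx + windowGenes]
    sel <- sel[order(mcols(gr)$index[sel])]
    out <- gr[sel]
    mcols(out)$focal <- mcols(out)$gene_id == geneId
    out
}

#' Test family enrichment in focal-gene neighborhoods
#'
#' For each focal set (e.g. an MCL cluster of TBDTs) the neighborhoods of
#' its members are unioned (a gene in two overlapping neighborhoods counts
#' once) and each family is tested for over-representation inside the
#' union versus the rest of the pooled gene universe with a one-sided
#' (greater) Fisher's exact test.  Genes with multiple family labels
#' contribute to each family's counts.  Benjamini-Hochberg correction is
#' applied jointly across all (focal set, family) pairs.
#'
#' @param genome a [GenomeTable-class] (the pooled universe).
#' @param focalSets named list of character vectors of focal gene ids.
#' @param families character vector of family labels to test (default:
#'   all labels present).
#' @param windowGenes neighborhood half-width (default 10).
#' @return data.frame with columns focal_set, family, a, b, c, d,
#'   odds_ratio, p, q.
#' @export
enrichmentTest <- function(genome, focalSets, families = NULL,
                           windowGenes = 10L) {
    gr <- geneRecords(genome)
    if (!length(gr))
        mtStop("invalid_input_error", "empty gene universe")
    md <- mcols(gr)
    fam_list <- md$families
    if (is.null(families))
        families <- sort(unique(unlist(fam_list)))
    fam_has <- vapply(families, function(fam)
        vapply(fam_list, function(f) fam %in% f, logical(1)),
        logical(length(gr)))
    fam_has <- matrix(fam_has, nrow = length(gr),
                      dimnames = list(NULL, families))
    res <- list()
    for (set_name in names(focalSets)) {
        inside <- logical(length(gr))
        for (gid in focalSets[[set_name]]) {
            nb <- extractNeighborhood(genome, gid, windowGenes)
            inside[match(mcols(nb)$gene_id, md$gene_id)] <- TRUE
        }
        n_in <- sum(inside)
        n_out <- length(gr) - n_in
        for (fam in families) {
            has <- fam_has[, fam]
            a <- sum(has & inside); b <- n_in - a
            cc <- sum(has & !inside); d <- n_out - cc
            # one-sided (greater) Fisher p = upper hypergeometric tail
            p <- stats::phyper(a - 1, a + cc, b + d, a + b,
                               lower.tail = FALSE)
            or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
            res[[length(res) + 1L]] <- data.frame(
                focal_set = set_name, family = fam, a = a, b = b, c = cc,
                d = d, odds_ratio = or, p = p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, res)
    out$q <- bhAdjust(out$p)
    rownames(out) <- NULL
    out
}

#' Default locus classification rules
#'
#' First-match-wins, ordered: biosynthesis cluster (NRPS enterobactin
#' synthase subunits) before heme (hutB + hmuS colocalization) before
#' catecholate (fatB) before hydroxamate (fhuD) before unknown-class
#' siderophore (siderophore-interacting protein or superfamily-level
#' substrate-binding protein), with "ambiguous" as total fallback.
#'
#' Each rule is a list with \code{class}, \code{anyOf} and/or \code{allOf}
#' character vectors of family labels, and optionally
#' \code{requireMotif = TRUE}.
#'
#' @return list of rules usable by [classifyLocus()].
#' @export
defaultLocusRules <- function() {
    list(
        list(class = "biosynthesis_cluster",
             anyOf = c("entE", "entF", "NRPS")),
        list(class = "heme", allOf = c("hutB", "hmuS")),
        list(class = "siderophore_catecholate", anyOf = "fatB"),
        list(class = "siderophore_hydroxamate", anyOf = "fhuD"),
        list(class = "siderophore_unknown",
             anyOf = c("SIP", "PBP_superfamily")))
}

#' Classify a focal locus from its neighborhood evidence
#'
#' Applies an ordered rule set to the families present in a neighborhood
#' (and, optionally, the presence of an assigned regulatory-motif hit) and
#' returns the first matching class, with the evidence that fired.  A pure
#' function: identical inputs give identical calls; the fallback class is
#' \code{"ambiguous"}.
#'
#' @param neighborhood GRanges from [extractNeighborhood()].
#' @param motifHits optional motif-hit data.frame; a motif is "present"
#'   when one of its \code{assigned_gene} values falls in the
#'   neighborhood.
#' @param rules ordered rule list (default [defaultLocusRules()]).
#' @return list with \code{class} and \code{evidence} (character vector).
#' @export
classifyLocus <- function(neighborhood, motifHits = NULL,
                          rules = defaultLocusRules()) {
    fams <- unique(unlist(mcols(neighborhood)$families))
    motif_present <- FALSE
    if (!is.null(motifHits) && nrow(motifHits))
        motif_present <- any(stats::na.omit(motifHits$assigned_gene) %in%
                             mcols(neighborhood)$gene_id)
    for (rule in rules) {
        ok <- TRUE
        ev <- character(0)
        if (!is.null(rule$allOf)) {
            if (!all(rule$allOf %in% fams)) ok <- FALSE
            else ev <- c(ev, rule$allOf)
        }
        if (ok && !is.null(rule$anyOf)) {
            present <- intersect(rule$anyOf, fams)
            if (!length(present)) ok <- FALSE else ev <- c(ev, present)
        }
        if (ok && isTRUE(rule$requireMotif)) {
            if (!motif_present) ok <- FALSE
            else ev <- c(ev, "motif")
        }
        if (ok) return(list(class = rule$class, evidence = ev))
    }
    list(class = "ambiguous", evidence = character(0))
}

#' Classify all focal loci of a genome collection
#'
#' Convenience wrapper applying [extractNeighborhood()] +
#' [classifyLocus()] to each focal gene.
#'
#' @inheritParams enrichmentTest
#' @param focalGenes character vector of focal gene ids.
#' @param motifHits optional motif-hit data.frame.
#' @param rules ordered rule list.
#' @return data.frame (focal_gene, class, evidence).
#' @export
classifyLoci <- function(genome, focalGenes, motifHits = NULL,
                         rules = defaultLocusRules(), windowGenes = 10L) {
    calls <- lapply(focalGenes, function(gid) {
        nb <- extractNeighborhood(genome, gid, windowGenes)
        cl <- classifyLocus(nb, motifHits, rules)
        data.frame(focal_gene = gid, class = cl$class,
                   evidence = paste(cl$evidence, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, calls)
}
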