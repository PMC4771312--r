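#' Accessors for MetalTraits classes
#'
#' `counts()` returns the genome-by-trait integer matrix, `binaryView()`
#' its presence/absence (0/1) view, `genomeIds()`/`traitNames()` the
#' dimnames.  `geneRecords()` returns the underlying GRanges of a
#' [GenomeTable-class]; `nodeIds()`/`edgeList()` the components of a
#' [SimilarityGraph-class].
#'
#' @param x a MetalTraits object.
#' @return See the individual accessor descriptions.
#' @name accessors
#' @aliases counts binaryView genomeIds traitNames geneRecords nodeIds
#'   edgeList
#' @examples
#' tt <- TraitTable(matrix(c(2L, 0L), 1, 2,
#'                  dimnames = list("g1", c("TBDT", "fatB"))))
#' counts(tt)
#' binaryView(tt)
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("binaryView", function(x) standardGeneric("binaryView"))

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname accessors
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @rdname accessors
#' @export
setGeneric("geneRecords", function(x) standardGeneric("geneRecords"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname accessors
setMethod("counts", "TraitTable", function(x) x@counts)

#' @rdname accessors
setMethod("binaryView", "TraitTable", function(x) {
    b <- x@counts > 0L
    storage.mode(b) <- "integer"
    b
})

#' @rdname accessors
setMethod("genomeIds", "TraitTable", function(x) rownames(x@counts))

#' @rdname accessors
setMethod("traitNames", "TraitTable", function(x) colnames(x@counts))

#' @rdname accessors
setMethod("geneRecords", "GenomeTable", function(x) x@genes)

#' @rdname accessors
setMethod("genomeIds", "GenomeTable",
          function(x) unique(mcols(x@genes)$genome_id))

#' @rdname accessors
setMethod("nodeIds", "SimilarityGraph", function(x) x@nodes)

#' @rdname accessors
setMethod("edgeList", "SimilarityGraph", function(x) x@edges)

setMethod("show", "TraitTable", function(object) {
    m <- object@counts
    cat("TraitTable:", nrow(m), "genomes x", ncol(m), "traits\n")
    cat("  non-zero cells:", sum(m > 0), "/", length(m), "\n")
    cat("  traits:", paste(utils::head(colnames(m), 6), collapse = ", "),
        if (ncol(m) > 6) "..." else "", "\n")
})

setMethod("show", "GenomeTable", function(object) {
    gr <- object@genes
    cat("GenomeTable:", length(gr), "genes on",
        length(unique(as.character(seqnames(gr)))), "contigs in",
        length(unique(mcols(gr)$genome_id)), "genomes\n")
})

setMethod("show", "SimilarityGraph", function(object) {
    cat("SimilarityGraph:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges\n")
})

setMethod("show", "OrdinationModel", function(object) {
    ev <- object@eigenvalues
    cat("OrdinationModel:", nrow(object@scores), "samples,",
        length(ev), "axes\n")
    pv <- if (sum(ev) > 0) round(100 * ev[1:min(2, length(ev))] / sum(ev), 1)
          else rep(0, min(2, length(ev)))
    cat("  variance explained by first axes (%):",
        paste(pv, collapse = ", "), "\n")
})

#' Dimensions of a TraitTable
#' @param x a TraitTable.
#' @return integer vector (genomes, traits).
#' @export
setMethod("dim", "TraitTable", function(x) dim(x@counts))
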