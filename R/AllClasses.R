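#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end strand
NULL

#' Genome-by-trait inventory matrix
#'
#' A rectangular matrix of non-negative integer counts with genomes as rows
#' and transporter families (traits) as columns.  This is the central
#' inventory object of the package: the machine analog of a per-genome
#' metal-uptake "presence/abundance grid".  A binary presence/absence view
#' is always derivable as \code{counts > 0}.
#'
#' @slot counts integer matrix, genomes x traits, with unique dimnames.
#'
#' @seealso [TraitTable()], [buildInventory()], [binaryView()]
#' @exportClass TraitTable
setClass("TraitTable", representation(counts = "matrix"))

setValidity("TraitTable", function(object) {
    m <- object@counts
    if (!is.numeric(m))
        return("counts must be a numeric matrix")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("counts must carry genome (row) and trait (column) names")
    if (anyDuplicated(rownames(m)))
        return("genome ids must be unique")
    if (anyDuplicated(colnames(m)))
        return("trait labels must be unique")
    if (any(m < 0) || any(m != floor(m)))
        return("counts must be non-negative integers")
    TRUE
})

#' Construct a TraitTable
#'
#' @param counts numeric matrix of non-negative integers with genome row
#'   names and trait column names.
#' @return A [TraitTable-class] object.
#' @examples
#' m <- matrix(c(1L, 0L, 2L, 1L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("TBDT", "fatB")))
#' TraitTable(m)
#' @export
TraitTable <- function(counts) {
    storage.mode(counts) <- "integer"
    new("TraitTable", counts = counts)
}

#' Ordered gene records for a genome collection
#'
#' Wraps a \linkS4class{GRanges} whose seqnames are contig ids and whose
#' metadata columns carry \code{gene_id}, \code{genome_id}, \code{index}
#' (0-based position in gene order within the contig) and \code{families}
#' (a \code{CharacterList} of family labels, possibly empty per gene).
#' Coordinates follow GRanges conventions (1-based closed) on input/output;
#' all package arithmetic on upstream windows is done in 0-based half-open
#' space internally.
#'
#' @slot genes GRanges of gene records.
#'
#' @exportClass GenomeTable
setClass("GenomeTable", representation(genes = "GRanges"))

setValidity("GenomeTable", function(object) {
    gr <- object@genes
    md <- mcols(gr)
    need <- c("gene_id", "genome_id", "index", "families")
    if (!all(need %in% colnames(md)))
        return(paste("missing metadata columns:",
                     paste(setdiff(need, colnames(md)), collapse = ", ")))
    if (anyDuplicated(md$gene_id))
        return("gene ids must be unique")
    if (!is(md$families, "CharacterList"))
        return("families must be a CharacterList")
    # indices consecutive from 0 within each contig
    by_contig <- split(md$index, as.character(seqnames(gr)))
    ok <- vapply(by_contig, function(ix)
        identical(sort(as.integer(ix)), seq_along(ix) - 1L), logical(1))
    if (!all(ok))
        return("gene indices must be consecutive 0..(n-1) within each contig")
    TRUE
})

#' Construct a GenomeTable
#'
#' @param genes a GRanges with metadata columns \code{gene_id},
#'   \code{genome_id}, \code{index} and \code{families}; or a data.frame
#'   with columns \code{contig_id}, \code{start}, \code{end}, \code{strand},
#'   \code{gene_id}, \code{genome_id}, \code{index} and \code{families}
#'   (comma-separated string or list column).
#' @return A [GenomeTable-class] object.
#' @export
GenomeTable <- function(genes) {
    if (is.data.frame(genes)) {
        fam <- genes$families
        if (is.character(fam)) {
            fam <- CharacterList(lapply(strsplit(fam, ","), function(x)
                x[nzchar(x)]))
        } else if (is.list(fam)) {
            fam <- CharacterList(fam)
        }
        gr <- GRanges(seqnames = genes$contig_id,
                      ranges = IRanges(start = genes$start, end = genes$end),
                      strand = genes$strand)
        mcols(gr) <- DataFrame(gene_id = genes$gene_id,
                               genome_id = genes$genome_id,
                               index = as.integer(genes$index),
                               families = fam)
        genes <- gr
    }
    new("GenomeTable", genes = genes)
}

#' Weighted undirected protein similarity graph
#'
#' Node ids are stored in canonical (sorted) order; edges are undirected,
#' stored once with \code{node_a < node_b}, strictly positive finite
#' weights and no self-loops.
#'
#' @slot nodes character vector of unique node ids (sorted).
#' @slot edges data.frame with columns node_a, node_b, weight.
#'
#' @exportClass SimilarityGraph
setClass("SimilarityGraph",
         representation(nodes = "character", edges = "data.frame"))

setValidity("SimilarityGraph", function(object) {
    e <- object@edges
    if (!all(c("node_a", "node_b", "weight") %in% colnames(e)))
        return("edges must have columns node_a, node_b, weight")
    if (anyDuplicated(object@nodes))
        return("node ids must be unique")
    if (nrow(e)) {
        if (any(e$node_a == e$node_b))
            return("self-loops are not allowed")
        if (!all(c(e$node_a, e$node_b) %in% object@nodes))
            return("edges reference unknown nodes")
        if (any(!is.finite(e$weight)) || any(e$weight <= 0))
            return("edge weights must be finite and positive")
        key <- paste(e$node_a, e$node_b, sep = "\r")
        if (anyDuplicated(key))
            return("duplicate edges")
    }
    TRUE
})

#' Construct a SimilarityGraph
#'
#' Edges may be given in any orientation and are canonicalized; duplicate
#' (a, b)/(b, a) pairs are an error.
#'
#' @param edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{weight}.
#' @param nodes optional character vector of node ids (to declare isolated
#'   nodes); defaults to the union of edge endpoints.
#' @return A [SimilarityGraph-class] object.
#' @examples
#' g <- SimilarityGraph(data.frame(node_a = "p1", node_b = "p2", weight = 1))
#' nodeIds(g)
#' @export
SimilarityGraph <- function(edges, nodes = NULL) {
    edges <- as.data.frame(edges)
    if (nrow(edges)) {
        a <- pmin(as.character(edges$node_a), as.character(edges$node_b))
        b <- pmax(as.character(edges$node_a), as.character(edges$node_b))
        edges <- data.frame(node_a = a, node_b = b,
                            weight = as.numeric(edges$weight),
                            stringsAsFactors = FALSE)
        edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(node_a = character(), node_b = character(),
                            weight = numeric())
    }
    if (is.null(nodes))
        nodes <- unique(c(edges$node_a, edges$node_b))
    nodes <- sort(unique(as.character(nodes)))
    new("SimilarityGraph", nodes = nodes, edges = edges)
}

#' PCA ordination model
#'
#' Result of [pcaOrdination()]: sample scores, feature loadings and
#' eigenvalues (variances along each component, non-increasing).  With all
#' components retained, \code{scores \%*\% t(loadings)} reconstructs the
#' centered (and optionally scaled) data matrix.
#'
#' @slot scores numeric matrix, samples x axes.
#' @slot loadings numeric matrix, features x axes.
#' @slot eigenvalues numeric vector, non-increasing, non-negative.
#' @slot center logical; was the data centered.
#' @slot scale logical; was the data scaled to unit variance.
#'
#' @exportClass OrdinationModel
setClass("OrdinationModel",
         representation(scores = "matrix", loadings = "matrix",
                        eigenvalues = "numeric", center = "logical",
                        scale = "logical"))

setValidity("OrdinationModel", function(object) {
    ev <- object@eigenvalues
    if (any(ev < -1e-12)) return("eigenvalues must be non-negative")
    if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-12))
        return("eigenvalues must be non-increasing")
    if (ncol(object@scores) != ncol(object@loadings))
        return("scores and loadings must agree on axis count")
    TRUE
})
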