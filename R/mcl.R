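# Markov clustering (MCL) of weighted similarity graphs, implemented from
# scratch on dense column-stochastic matrices (problem sizes here are
# hundreds to low thousands of nodes).

#' MCL configuration
#'
#' @param inflation inflation exponent (> 1; default 2, the canonical MCL
#'   setting).
#' @param expansion expansion (matrix power) exponent (integer >= 2).
#' @param selfLoop "max_edge" (each node's self-loop weight = its maximum
#'   incident edge weight, damping flow) or a positive constant.
#' @param pruneThreshold entries below this are zeroed each iteration.
#' @param maxIterations iteration cap.
#' @param convergenceTol stop when the max absolute change falls below
#'   this.
#' @return list of class "MCLConfig".
#' @export
mclConfig <- function(inflation = 2, expansion = 2L,
                      selfLoop = "max_edge", pruneThreshold = 1e-5,
                      maxIterations = 200L, convergenceTol = 1e-8) {
    if (inflation <= 1)
        mtStop("invalid_spec_error", "inflation must be > 1")
    if (expansion < 2)
        mtStop("invalid_spec_error", "expansion must be >= 2")
    structure(list(inflation = inflation, expansion = as.integer(expansion),
                   selfLoop = selfLoop, pruneThreshold = pruneThreshold,
                   maxIterations = as.integer(maxIterations),
                   convergenceTol = convergenceTol), class = "MCLConfig")
}

#' One MCL iteration (exposed for testing)
#'
#' Expansion (matrix power), inflation (elementwise power followed by
#' column renormalization), pruning below the threshold, and a final
#' renormalization.  Input and output are column-stochastic.
#'
#' @param M column-stochastic square matrix.
#' @param cfg an [mclConfig()].
#' @return the next column-stochastic iterate.
#' @export
mclIterate <- function(M, cfg = mclConfig()) {
    E <- M
    for (i in seq_len(cfg$expansion - 1L)) E <- E %*% M
    E <- E ^ cfg$inflation
    E <- .colNormalize(E)
    E[E < cfg$pruneThreshold] <- 0
    .colNormalize(E)
}

.colNormalize <- function(M) {
    cs <- colSums(M)
    if (any(cs == 0))
        mtStop("numerical_degeneracy_error",
               "column sums to zero after pruning")
    sweep(M, 2, cs, "/")
}

#' Cluster a similarity graph with MCL
#'
#' Builds the column-stochastic flow matrix (with self-loops), iterates
#' expansion/inflation/pruning to convergence, and reads clusters from the
#' attractor structure of the limit matrix: nodes with positive diagonal
#' are attractors; attractors that exchange flow form one attractor
#' system; every other node joins the system it flows to (overlaps
#' resolved to the larger system, ties by lexicographically smallest
#' member).  Clusters are labelled \code{MCL1, MCL2, ...} by decreasing
#' size (ties by smallest member); singletons are labelled
#' \code{MCLnull}.
#'
#' @param graph a [SimilarityGraph-class].
#' @param cfg an [mclConfig()].
#' @return named character vector: node id -> cluster label, with
#'   attributes \code{"iterations"} and \code{"converged"}.
#' @examples
#' g <- SimilarityGraph(data.frame(
#'     node_a = c("a", "a", "b", "x", "x", "y"),
#'     node_b = c("b", "c", "c", "y", "z", "z"), weight = 1))
#' mclCluster(g)
#' @export
mclCluster <- function(graph, cfg = mclConfig()) {
    nodes <- nodeIds(graph)
    n <- length(nodes)
    if (!n) mtStop("invalid_graph_error", "empty graph")
    e <- edgeList(graph)
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (nrow(e)) {
        ia <- match(e$node_a, nodes); ib <- match(e$node_b, nodes)
        A[cbind(ia, ib)] <- e$weight
        A[cbind(ib, ia)] <- e$weight
    }
    if (identical(cfg$selfLoop, "max_edge")) {
        mx <- apply(A, 1, max)
        diag(A) <- ifelse(mx > 0, mx, 1)
    } else {
        diag(A) <- as.numeric(cfg$selfLoop)
    }
    M <- .colNormalize(A)
    converged <- FALSE
    it <- 0L
    while (it < cfg$maxIterations) {
        it <- it + 1L
        M2 <- mclIterate(M, cfg)
        if (max(abs(M2 - M)) < cfg$convergenceTol) {
            M <- M2; converged <- TRUE; break
        }
        M <- M2
    }
    if (!converged)
        warning("MCL did not converge in ", cfg$maxIterations,
                " iterations; clusters read from the final iterate")
    part <- .readClusters(M, nodes)
    attr(part, "iterations") <- it
    attr(part, "converged") <- converged
    part
}

.readClusters <- function(M, nodes) {
    n <- length(nodes)
    eps <- 1e-9
    attractors <- which(diag(M) > eps)
    if (!length(attractors)) attractors <- seq_len(n)  # degenerate guard
    # attractor systems: connected components of the symmetrized positive
    # submatrix among attractors
    sub <- (M[attractors, attractors, drop = FALSE] > eps) |
        t(M[attractors, attractors, drop = FALSE] > eps)
    sys_id <- .components(sub)
    systems <- split(attractors, sys_id)
    member_sets <- lapply(systems, function(att) {
        flows <- which(colSums(M[att, , drop = FALSE] > eps) > 0)
        sort(unique(c(att, flows)))
    })
    # resolve overlaps: larger system wins, tie lexicographic smallest
    # member
    sizes <- lengths(member_sets)
    firsts <- vapply(member_sets, function(s) min(nodes[s]), character(1))
    pref <- order(-sizes, firsts)
    assign <- integer(n)
    for (si in pref) {
        free <- member_sets[[si]][assign[member_sets[[si]]] == 0L]
        assign[free] <- si
    }
    assign[assign == 0L] <- max(assign) + seq_len(sum(assign == 0L))
    clusters <- split(seq_len(n), assign)
    # label by descending size, ties by smallest member; singletons MCLnull
    csz <- lengths(clusters)
    cfirst <- vapply(clusters, function(s) min(nodes[s]), character(1))
    ord <- order(-csz, cfirst)
    labels <- character(n)
    lab_i <- 0L
    for (ci in ord) {
        members <- clusters[[ci]]
        if (length(members) == 1L) {
            labels[members] <- "MCLnull"
        } else {
            lab_i <- lab_i + 1L
            labels[members] <- sprintf("MCL%d", lab_i)
        }
    }
    names(labels) <- nodes
    labels
}

# connected components of a logical adjacency matrix (small n)
.components <- function(adj) {
    n <- nrow(adj)
    comp <- integer(n)
    cur <- 0L
    for (i in seq_len(n)) {
        if (comp[i] != 0L) next
        cur <- cur + 1L
        queue <- i
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (comp[v] != 0L) next
            comp[v] <- cur
            queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
    }
    comp
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
    tab <- table(a, b)
    choose2 <- function(x) x * (x - 1) / 2
    sum_ij <- sum(choose2(tab))
    sum_a <- sum(choose2(rowSums(tab)))
    sum_b <- sum(choose2(colSums(tab)))
    n2 <- choose2(sum(tab))
    expected <- sum_a * sum_b / n2
    maxi <- (sum_a + sum_b) / 2
    if (maxi == expected) return(1)
    (sum_ij - expected) / (maxi - expected)
}
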