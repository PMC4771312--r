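#' Simulate a Yule (pure-birth) phylogeny
#'
#' Generates a rooted, binary, ultrametric tree under a pure-birth process
#' conditioned on the number of tips.  The birth rate is chosen so that the
#' expected root-to-tip depth equals \code{scale}: the process is run until
#' \code{nTips} lineages exist plus one extra exponential waiting time, and
#' the root edge is discarded, giving expected depth
#' \eqn{\sum_{k=2}^{n} 1/(k\lambda)}.
#'
#' @param nTips positive integer, number of tips.
#' @param scale positive real, expected root-to-tip depth (default 1).
#' @param seed integer seed; fixed seed gives a bit-identical tree.
#' @return an \code{ape} \code{phylo} object with tips labelled
#'   \code{t1..tN} and strictly positive branch lengths.
#' @examples
#' tr <- simTree(8, seed = 1)
#' ape::is.binary(tr)
#' @export
simTree <- function(nTips, scale = 1, seed) {
    if (!is.numeric(nTips) || length(nTips) != 1 || nTips < 1 ||
        nTips != floor(nTips))
        mtStop("invalid_spec_error", "nTips must be a positive integer")
    if (!is.numeric(scale) || scale <= 0)
        mtStop("invalid_spec_error", "scale must be positive")
    n <- as.integer(nTips)
    if (n == 1L) {
        tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                             tip.label = "t1", edge.length = scale,
                             Nnode = 1L),
                        class = "phylo", order = "cladewise")
        return(tr)
    }
    withSeed(seed, {
        lambda <- sum(1 / (2:n)) / scale
        waits <- stats::rexp(n, rate = (1:n) * lambda)
        times <- cumsum(waits)          # times[k] = time when k+1 lineages
        total <- times[n]               # sampling time (after n lineages)
        # active lineages: parent internal node id and birth time
        par <- c(0L)                    # 0 = above the root (dropped)
        birth <- c(0)
        edge_par <- integer(2 * n - 2); edge_child <- integer(2 * n - 2)
        edge_len <- numeric(2 * n - 2); ne <- 0L
        for (k in 1:(n - 1)) {
            j <- if (k == 1L) 1L else sample.int(k, 1)
            node <- n + k               # internal ids n+1 .. 2n-1
            if (par[j] != 0L) {
                ne <- ne + 1L
                edge_par[ne] <- par[j]; edge_child[ne] <- node
                edge_len[ne] <- times[k] - birth[j]
            }
            par <- c(par[-j], node, node)
            birth <- c(birth[-j], times[k], times[k])
        }
        for (j in seq_len(n)) {         # pending lineages become tips
            ne <- ne + 1L
            edge_par[ne] <- par[j]; edge_child[ne] <- j
            edge_len[ne] <- total - birth[j]
        }
        tr <- structure(list(edge = cbind(edge_par, edge_child,
                                          deparse.level = 0),
                             tip.label = paste0("t", 1:n),
                             edge.length = edge_len, Nnode = n - 1L),
                        class = "phylo")
        ape::reorder.phylo(tr, "cladewise")
    })
}

#' Simulate a binary trait on a tree
#'
#' Three generating models for a presence/absence trait over the tips of a
#' rooted tree:
#' \describe{
#'   \item{random}{each tip independently positive with probability
#'     \code{prevalence} (no phylogenetic signal).}
#'   \item{clumped}{the smallest clade containing at least
#'     \code{round(prevalence * nTips)} tips and seeded at \code{cladeTip}
#'     is marked positive, then trimmed to the exact count by dropping the
#'     tips patristically farthest from \code{cladeTip} (ties broken by tip
#'     label order).}
#'   \item{brownian_threshold}{a Brownian value is simulated along branches
#'     (root value 0, increments Normal(0, branch length)) and thresholded
#'     at the empirical quantile matching \code{prevalence}, so the
#'     realized positive count is exactly \code{round(prevalence * nTips)};
#'     ties broken by tip label order.}
#' }
#'
#' @param tree a \code{phylo} tree.
#' @param model one of "random", "clumped", "brownian_threshold".
#' @param prevalence real in (0, 1].
#' @param cladeTip tip label anchoring the clumped clade (defaults to the
#'   first tip label).
#' @param seed integer seed.
#' @param traitName column label for the output (default "trait").
#' @return a [TraitTable-class] with one binary column over the tips.
#' @examples
#' tr <- simTree(16, seed = 1)
#' tt <- simTraits(tr, "clumped", prevalence = 0.25, seed = 2)
#' sum(counts(tt))
#' @export
simTraits <- function(tree, model = c("random", "clumped",
                                      "brownian_threshold"),
                      prevalence, cladeTip = NULL, seed,
                      traitName = "trait") {
    model <- match.arg(model)
    if (!is.numeric(prevalence) || prevalence <= 0 || prevalence > 1)
        mtStop("invalid_spec_error", "prevalence must be in (0, 1]")
    tips <- tree$tip.label
    n <- length(tips)
    k <- round(prevalence * n)
    if (k < 1 && model != "random")
        mtStop("invalid_spec_error",
               "prevalence too small: target positive count is 0")
    x <- withSeed(seed, {
        switch(model,
        random = as.integer(stats::runif(n) < prevalence),
        clumped = {
            if (is.null(cladeTip)) cladeTip <- tips[1]
            if (!cladeTip %in% tips)
                mtStop("unknown_tip_error",
                       paste("cladeTip not in tree:", cladeTip))
            if (n == 1L) {
                1L
            } else {
                anchor <- match(cladeTip, tips)
                parent <- integer(n + tree$Nnode)
                parent[tree$edge[, 2]] <- tree$edge[, 1]
                desc <- .descendantTips(tree)
                node <- anchor
                while (length(.nodeTips(desc, node, n)) < k &&
                       parent[node] != 0L)
                    node <- parent[node]
                clade <- .nodeTips(desc, node, n)
                if (length(clade) > k) {
                    d <- stats::cophenetic(tree)[tips[anchor], tips[clade]]
                    # farthest first; ties: later labels dropped first
                    ord <- order(-d, -xtfrm(tips[clade]))
                    clade <- clade[-ord[seq_len(length(clade) - k)]]
                }
                out <- integer(n); out[clade] <- 1L; out
            }
        },
        brownian_threshold = {
            v <- .brownianTips(tree, 1)[, 1]
            ord <- order(-v, tips)       # ties: earlier label wins
            out <- integer(n); out[ord[seq_len(k)]] <- 1L; out
        })
    })
    m <- matrix(x, ncol = 1, dimnames = list(tips, traitName))
    TraitTable(m)
}

# tips descending from each node: list indexed by node id
.descendantTips <- function(tree) {
    n <- length(tree$tip.label)
    nn <- n + tree$Nnode
    desc <- vector("list", nn)
    for (i in seq_len(n)) desc[[i]] <- i
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (e in seq_len(nrow(po))) {
        p <- po[e, 1]; ch <- po[e, 2]
        desc[[p]] <- c(desc[[p]], desc[[ch]])
    }
    desc
}

.nodeTips <- function(desc, node, n) desc[[node]][desc[[node]] <= n]

# Brownian tip values: P independent replicates, root value 0,
# increments Normal(0, branch length).  Returns nTips x P matrix.
.brownianTips <- function(tree, P) {
    tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    n <- length(tree$tip.label)
    nn <- n + tree$Nnode
    inc <- matrix(stats::rnorm(nrow(tree$edge) * P), nrow(tree$edge), P) *
        sqrt(tree$edge.length)
    val <- matrix(0, nn, P)
    for (e in seq_len(nrow(tree$edge)))
        val[tree$edge[e, 2], ] <- val[tree$edge[e, 1], ] + inc[e, ]
    val[seq_len(n), , drop = FALSE]
}

#' Simulate annotated genomes with planted transporter loci
#'
#' Generates one contig per genome with \code{genesPerGenome} genes of
#' fixed length, background family labels sampled from \code{familyPool},
#' and zero or more locus templates (ordered family tuples such as
#' TBDT-hutB-hmuS) planted as contiguous same-strand gene runs with a
#' per-genome probability.  A 300-bp random upstream record is emitted per
#' gene (FASTA id = gene id); optionally a motif is planted verbatim (with
#' a stated number of random mismatches) at a fixed offset in the upstream
#' record of the first gene of every planted locus.
#'
#' @param nGenomes number of genomes.
#' @param genesPerGenome genes per genome; must be at least the longest
#'   template length.
#' @param familyPool named numeric vector of sampling weights for
#'   background family labels (a label of "" means no family).
#' @param locusTemplates list of lists with elements \code{name},
#'   \code{families} (character vector) and \code{prob} (per-genome
#'   planting probability).
#' @param motifPlant optional list with elements \code{motif} (string),
#'   \code{offset} (0-based offset into the 300-bp upstream window) and
#'   \code{mismatches} (count of random mismatch positions).
#' @param upstreamBp width of the upstream window (default 300).
#' @param seed integer seed.
#' @return list with components \code{genomes} ([GenomeTable-class]),
#'   \code{upstream} (\code{DNAStringSet}, one record per gene) and
#'   \code{planted} (data.frame of ground truth: genome, template, first
#'   gene index/id, strand).
#' @examples
#' sim <- simGenomes(3, 20,
#'     familyPool = c(other = 1),
#'     locusTemplates = list(list(name = "heme",
#'         families = c("TBDT", "hutB", "hmuS"), prob = 1)),
#'     seed = 7)
#' sim$planted
#' @export
simGenomes <- function(nGenomes, genesPerGenome,
                       familyPool = c(other = 1),
                       locusTemplates = list(),
                       motifPlant = NULL, upstreamBp = 300L, seed) {
    maxlen <- if (length(locusTemplates))
        max(vapply(locusTemplates, function(t) length(t$families), 1L))
        else 0L
    if (maxlen > genesPerGenome)
        mtStop("invalid_spec_error",
               "locus template longer than genesPerGenome")
    if (!is.null(motifPlant) &&
        motifPlant$offset + nchar(motifPlant$motif) > upstreamBp)
        mtStop("invalid_spec_error",
               "planted motif does not fit in the upstream window")
    withSeed(seed, {
        gene_w <- 900L; spacing <- 1000L
        rows <- vector("list", nGenomes)
        planted <- list()
        up_seq <- character(0)
        up_ids <- character(0)
        for (g in seq_len(nGenomes)) {
            gid <- sprintf("g%d", g)
            fam <- sample(names(familyPool), genesPerGenome, replace = TRUE,
                          prob = familyPool)
            fams <- as.list(fam)
            fams[fam == ""] <- list(character(0))
            strands <- sample(c("+", "-"), genesPerGenome, replace = TRUE)
            taken <- logical(genesPerGenome)
            first_idx <- integer(0); first_tpl <- character(0)
            for (tpl in locusTemplates) {
                L <- length(tpl$families)
                if (stats::runif(1) >= tpl$prob) next
                starts <- which(!vapply(seq_len(genesPerGenome - L + 1),
                    function(s) any(taken[s:(s + L - 1)]), logical(1)))
                if (!length(starts)) next   # no room left
                s <- starts[sample.int(length(starts), 1)]
                st <- sample(c("+", "-"), 1)
                fams[s:(s + L - 1)] <- as.list(tpl$families)
                strands[s:(s + L - 1)] <- st
                taken[s:(s + L - 1)] <- TRUE
                first <- if (st == "+") s else s + L - 1L
                first_idx <- c(first_idx, first)
                first_tpl <- c(first_tpl, tpl$name)
                planted[[length(planted) + 1L]] <- data.frame(
                    genome_id = gid, template = tpl$name,
                    start_index = s - 1L, strand = st,
                    first_gene = sprintf("%s_%04d", gid, first))
            }
            gene_ids <- sprintf("%s_%04d", gid, seq_len(genesPerGenome))
            rows[[g]] <- data.frame(
                contig_id = gid,
                start = (seq_len(genesPerGenome) - 1L) * spacing + 1L,
                end = (seq_len(genesPerGenome) - 1L) * spacing + gene_w,
                strand = strands, gene_id = gene_ids, genome_id = gid,
                index = seq_len(genesPerGenome) - 1L,
                stringsAsFactors = FALSE)
            rows[[g]]$families <- fams
            ups <- vapply(seq_len(genesPerGenome), function(i)
                paste(sample(c("A", "C", "G", "T"), upstreamBp,
                             replace = TRUE), collapse = ""), character(1))
            if (!is.null(motifPlant) && length(first_idx)) {
                for (i in first_idx) {
                    mot <- strsplit(motifPlant$motif, "")[[1]]
                    if (motifPlant$mismatches > 0) {
                        pos <- sample.int(length(mot),
                                          motifPlant$mismatches)
                        for (p in pos)
                            mot[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                     mot[p]), 1)
                    }
                    s0 <- strsplit(ups[i], "")[[1]]
                    s0[(motifPlant$offset + 1):(motifPlant$offset +
                                                length(mot))] <- mot
                    ups[i] <- paste(s0, collapse = "")
                }
            }
            up_seq <- c(up_seq, ups)
            up_ids <- c(up_ids, gene_ids)
        }
        df <- do.call(rbind, rows)
        upstream <- Biostrings::DNAStringSet(up_seq)
        names(upstream) <- up_ids
        planted <- if (length(planted)) do.call(rbind, planted) else
            data.frame(genome_id = character(), template = character(),
                       start_index = integer(), strand = character(),
                       first_gene = character())
        list(genomes = GenomeTable(df), upstream = upstream,
             planted = planted)
    })
}

#' Simulate a planted-partition similarity graph
#'
#' Within-cluster node pairs are connected with probability \code{pIn} at
#' mean weight \code{weightIn}; between-cluster pairs with probability
#' \code{pOut} at mean weight \code{weightOut}.  Weights are positive with
#' small (10\%) relative jitter around their means.
#'
#' @param clusterSizes integer vector of planted cluster sizes.
#' @param pIn,pOut edge probabilities in [0, 1].
#' @param weightIn,weightOut positive mean edge weights.
#' @param seed integer seed.
#' @return list with \code{graph} ([SimilarityGraph-class]) and
#'   \code{membership} (named integer vector of planted cluster labels).
#' @examples
#' g <- simSimilarityGraph(c(3, 3), pIn = 1, pOut = 0, seed = 1)
#' nrow(edgeList(g$graph))
#' @export
simSimilarityGraph <- function(clusterSizes, pIn, pOut, weightIn = 100,
                               weightOut = 30, seed) {
    if (any(clusterSizes < 1))
        mtStop("invalid_spec_error", "cluster sizes must be >= 1")
    if (pIn < 0 || pIn > 1 || pOut < 0 || pOut > 1)
        mtStop("invalid_spec_error", "edge probabilities must be in [0, 1]")
    n <- sum(clusterSizes)
    memb <- rep(seq_along(clusterSizes), clusterSizes)
    ids <- sprintf("n%03d", seq_len(n))
    names(memb) <- ids
    withSeed(seed, {
        pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        within <- memb[pairs[, 1]] == memb[pairs[, 2]]
        p <- ifelse(within, pIn, pOut)
        w_mean <- ifelse(within, weightIn, weightOut)
        keep <- stats::runif(nrow(pairs)) < p
        w <- pmax(stats::rnorm(sum(keep), w_mean[keep],
                               0.1 * w_mean[keep]), 0.1 * w_mean[keep])
        edges <- data.frame(node_a = ids[pairs[keep, 1]],
                            node_b = ids[pairs[keep, 2]], weight = w)
        list(graph = SimilarityGraph(edges, nodes = ids),
             membership = memb)
    })
}

#' Simulate a two-lineage trait count matrix with covariates
#'
#' Emulates a genomes-by-transporter count matrix for two lineages with
#' unequal within-group dispersion (one tight cluster and one dispersed,
#' as in a SAR11 vs Roseobacter comparison) plus one continuous metadata
#' covariate constructed with a stated linear relation to the per-genome
#' total count.  Defaults mirror the study conditions emulated throughout
#' the package: 42 dispersed "patch-adapted" genomes vs 22 tight
#' "background-adapted" genomes over 20 transporter categories.
#'
#' @param nPerGroup two integers (>= 2): group sizes.
#' @param nFeatures number of transporter categories.
#' @param groupDispersion two positive reals: within-group noise SD per
#'   group (0 allowed: identical rows within the group).
#' @param covariateEffect slope of the covariate on the per-genome row sum
#'   (0 gives an independent covariate).
#' @param seed integer seed.
#' @return list with \code{counts} ([TraitTable-class]) and
#'   \code{metadata} (data.frame: genome_id, lineage, covariate).
#' @examples
#' sim <- simCountMatrix(c(5, 5), nFeatures = 4, seed = 3)
#' dim(counts(sim$counts))
#' @export
simCountMatrix <- function(nPerGroup = c(42L, 22L), nFeatures = 20L,
                           groupDispersion = c(5, 1),
                           covariateEffect = 0.5, seed) {
    if (any(nPerGroup < 2))
        mtStop("invalid_spec_error", "each group needs >= 2 genomes")
    if (any(groupDispersion < 0))
        mtStop("invalid_spec_error", "dispersions must be non-negative")
    withSeed(seed, {
        mu <- lapply(1:2, function(g) stats::runif(nFeatures, 10, 40))
        rows <- list()
        lin <- c("lineageA", "lineageB")
        for (g in 1:2) {
            noise <- matrix(stats::rnorm(nPerGroup[g] * nFeatures, 0,
                                         max(groupDispersion[g], 1e-12)),
                            nPerGroup[g], nFeatures)
            if (groupDispersion[g] == 0) noise[] <- 0
            rows[[g]] <- round(matrix(mu[[g]], nPerGroup[g], nFeatures,
                                      byrow = TRUE) + noise)
        }
        m <- do.call(rbind, rows)
        m[m < 0] <- 0
        rownames(m) <- sprintf("g%02d", seq_len(sum(nPerGroup)))
        colnames(m) <- sprintf("trait%02d", seq_len(nFeatures))
        rs <- rowSums(m)
        covariate <- covariateEffect * rs +
            stats::rnorm(nrow(m), 0, stats::sd(rs) * 0.5 + 1)
        metadata <- data.frame(genome_id = rownames(m),
                               lineage = rep(lin, nPerGroup),
                               covariate = covariate)
        list(counts = TraitTable(m), metadata = metadata)
    })
}
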