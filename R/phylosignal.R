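# Phylogenetic trait-conservation statistics for binary traits:
# consenTRAIT trait depth (tau_D) with permutation null and multi-tree
# aggregation, and the Fritz-Purvis dispersion statistic D with random
# and Brownian-threshold nulls.  All computations are vectorized over
# replicate trait columns so permutation/simulation nulls run in a single
# linear pass per tree.

#' consenTRAIT configuration
#'
#' @param positiveFraction minimum fraction of positive tips for a clade
#'   to qualify (default 0.90, the algorithm's conventional threshold).
#' @param nPermutations permutations for the significance test (default
#'   1000).
#' @param singletonDepthFactor depth contributed by a positive tip outside
#'   every qualifying clade, as a fraction of its terminal branch length
#'   (default 0.5).
#' @param alpha significance level annotated in outputs (default 0.1).
#' @param seed integer seed for the permutation null.
#' @return list of class "ConsentraitConfig".
#' @export
consentraitConfig <- function(positiveFraction = 0.90,
                              nPermutations = 1000L,
                              singletonDepthFactor = 0.5, alpha = 0.1,
                              seed = 1L) {
    stopifnot(positiveFraction > 0.5, positiveFraction <= 1)
    structure(list(positiveFraction = positiveFraction,
                   nPermutations = as.integer(nPermutations),
                   singletonDepthFactor = singletonDepthFactor,
                   alpha = alpha, seed = seed),
              class = "ConsentraitConfig")
}

# Precompute per-tree structures reused across trait columns.
.treeIndex <- function(tree) {
    tree <- ape::reorder.phylo(tree, "cladewise")
    n <- length(tree$tip.label)
    nn <- n + tree$Nnode
    parent <- integer(nn)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    depth <- numeric(nn)
    for (e in seq_len(nrow(tree$edge)))   # parents precede children
        depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] +
            tree$edge.length[e]
    desc <- .descendantTips(tree)
    internal <- (n + 1L):nn
    I <- matrix(FALSE, n, tree$Nnode)
    for (j in seq_along(internal))
        I[.nodeTips(desc, internal[j], n), j] <- TRUE
    storage.mode(I) <- "numeric"
    tips_per_node <- colSums(I)
    mean_tip_depth <- as.numeric(crossprod(I, depth[seq_len(n)])) /
        tips_per_node - depth[internal]
    term_bl <- numeric(n)
    tip_edges <- tree$edge[, 2] <= n
    term_bl[tree$edge[tip_edges, 2]] <- tree$edge.length[tip_edges]
    # parent of an internal node expressed as an index into `internal`
    # (0 for the root, whose parent qualifies nothing)
    pi <- parent[internal]
    parent_internal <- ifelse(pi == 0L, 0L, pi - n)
    list(tree = tree, n = n, internal = internal, I = I,
         tipsPerNode = tips_per_node, meanTipDepth = mean_tip_depth,
         termBl = term_bl, parentInternal = parent_internal,
         tipLabels = tree$tip.label)
}

# tau_D for each column of a binary tip x replicate matrix X.
# Returns list(tau, maximal) where maximal is the logical node x P matrix
# of maximal qualifying clades.
.tauDBatch <- function(idx, X, positiveFraction = 0.90,
                       singletonFactor = 0.5) {
    X <- as.matrix(X)
    pos_count <- crossprod(idx$I, X)                 # nodes x P
    frac <- pos_count / idx$tipsPerNode
    qual <- frac >= positiveFraction & pos_count > 0
    parent_qual <- matrix(FALSE, nrow(qual), ncol(qual))
    has_par <- idx$parentInternal > 0L
    parent_qual[has_par, ] <- qual[idx$parentInternal[has_par], ,
                                   drop = FALSE]
    maximal <- qual & !parent_qual
    covered <- (idx$I %*% maximal) > 0               # tips x P
    singleton <- X > 0 & !covered
    numer <- as.numeric(crossprod(maximal, idx$meanTipDepth)) +
        as.numeric(crossprod(singleton, singletonFactor * idx$termBl))
    denom <- colSums(maximal) + colSums(singleton)
    tau <- ifelse(denom > 0, numer / denom, NA_real_)
    list(tau = tau, maximal = maximal)
}

.traitVector <- function(trait, labels) {
    if (is(trait, "TraitTable")) {
        m <- counts(trait)
        if (ncol(m) != 1)
            stop("supply a single trait column")
        trait <- stats::setNames(as.integer(m[, 1] > 0), rownames(m))
    }
    if (is.null(names(trait)))
        stop("trait must be named by tip label")
    missing <- setdiff(labels, names(trait))
    if (length(missing))
        mtStop("label_mismatch_error",
               paste("trait missing for tips:",
                     paste(utils::head(missing, 5), collapse = ", ")))
    as.integer(trait[labels] > 0)
}

#' consenTRAIT trait depth on one tree
#'
#' The trait depth tau_D is the mean phylogenetic depth of the maximal
#' clades in which the trait is (near-)universally present: internal
#' nodes whose tip set has a positive fraction of at least
#' \code{positiveFraction} and whose parent does not qualify, each
#' contributing its mean branch-length distance to its tips.  Positive
#' tips outside every qualifying clade contribute
#' \code{singletonDepthFactor} times their terminal branch length.
#'
#' @param tree a rooted \code{phylo} tree with branch lengths.
#' @param trait binary vector named by tip label, or a one-column
#'   [TraitTable-class].
#' @param cfg a [consentraitConfig()].
#' @return list with \code{tauD} and \code{clades} (data.frame: node id,
#'   depth, n_tips; singletons have node = NA).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' consentraitDepth(tr, c(A = 1, B = 1, C = 1, D = 1))$tauD  # 2
#' @export
consentraitDepth <- function(tree, trait, cfg = consentraitConfig()) {
    idx <- .treeIndex(tree)
    x <- .traitVector(trait, idx$tipLabels)
    if (sum(x) < 1)
        mtStop("undefined_trait_error", "trait has no positive tips")
    r <- .tauDBatch(idx, matrix(x, ncol = 1), cfg$positiveFraction,
                    cfg$singletonDepthFactor)
    max_nodes <- which(r$maximal[, 1])
    covered <- (idx$I %*% r$maximal[, 1, drop = FALSE]) > 0
    singles <- which(x > 0 & !covered[, 1])
    clades <- rbind(
        if (length(max_nodes)) data.frame(
            node = idx$internal[max_nodes],
            depth = idx$meanTipDepth[max_nodes],
            n_tips = idx$tipsPerNode[max_nodes]),
        if (length(singles)) data.frame(
            node = NA_integer_,
            depth = cfg$singletonDepthFactor * idx$termBl[singles],
            n_tips = 1))
    list(tauD = r$tau[1], clades = clades)
}

#' consenTRAIT test across a tree set
#'
#' Computes tau_D on each supplied tree (e.g. bootstrap replicates),
#' reports the mean and SD across trees, and a permutation p-value: the
#' tip-to-trait assignment is permuted \code{nPermutations} times (the
#' same permutations applied to every tree), the across-tree mean tau_D
#' recomputed, and the add-one estimator
#' \eqn{p = (1 + \#\{\tau_{perm} \ge \tau_{obs}\}) / (1 + N)} returned.
#'
#' @param trees a \code{phylo}, a list of them, or a \code{multiPhylo};
#'   all must share the same tip label set.
#' @param trait binary vector named by tip label, or one-column
#'   [TraitTable-class].
#' @param cfg a [consentraitConfig()].
#' @return list with \code{tauD} (mean), \code{tauSD}, \code{pPerm},
#'   \code{perTree} (vector) and \code{nPermutations}.
#' @export
consentraitTest <- function(trees, trait, cfg = consentraitConfig()) {
    if (is(trees, "phylo")) trees <- list(trees)
    labels <- trees[[1]]$tip.label
    for (tr in trees)
        if (!setequal(tr$tip.label, labels))
            mtStop("label_mismatch_error",
                   "trees do not share one tip label set")
    x <- .traitVector(trait, labels)
    if (sum(x) < 1)
        mtStop("undefined_trait_error", "trait has no positive tips")
    P <- cfg$nPermutations
    perms <- withSeed(cfg$seed,
        replicate(P, sample.int(length(x))))
    X <- cbind(x, matrix(x[perms], nrow = length(x)))
    taus <- matrix(NA_real_, length(trees), P + 1L)
    for (ti in seq_along(trees)) {
        idx <- .treeIndex(trees[[ti]])
        ord <- match(idx$tipLabels, labels)
        taus[ti, ] <- .tauDBatch(idx, X[ord, , drop = FALSE],
                                 cfg$positiveFraction,
                                 cfg$singletonDepthFactor)$tau
    }
    col_mean <- colMeans(taus)
    obs <- col_mean[1]
    p <- permPvalue(sum(col_mean[-1] >= obs), P)
    per_tree <- taus[, 1]
    list(tauD = obs,
         tauSD = if (length(per_tree) > 1) stats::sd(per_tree) else 0,
         pPerm = p,
         perTree = per_tree, nPermutations = P)
}

#' Sum of sister-clade differences for a binary trait
#'
#' Internal-node values are computed tips-to-root as the unweighted mean
#' of child values; the statistic is the sum over internal nodes of the
#' absolute deviations of the child values from their mean (equal to the
#' absolute difference of the two child values at bifurcations).  This is
#' the raw quantity behind the Fritz-Purvis D statistic: small sums mean
#' phylogenetically clumped traits.
#'
#' @param tree rooted \code{phylo}.
#' @param trait binary vector named by tip label, or one-column
#'   [TraitTable-class].
#' @return the sister-difference sum (a non-negative real).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' sisterDifferenceSum(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1
#' @export
sisterDifferenceSum <- function(tree, trait) {
    idx <- .treeIndex(tree)
    x <- .traitVector(trait, idx$tipLabels)
    if (length(unique(x)) < 2)
        mtStop("degenerate_trait_error", "trait is constant across tips")
    .sigmaDBatch(idx$tree, matrix(x, ncol = 1))[1]
}

# Sigma-d for every column of tips x P matrix X.
.sigmaDBatch <- function(tree, X) {
    po <- ape::reorder.phylo(tree, "postorder")
    n <- length(po$tip.label)
    nn <- n + po$Nnode
    P <- ncol(X)
    V <- matrix(0, nn, P)
    V[seq_len(n), ] <- X
    contrib <- numeric(P)
    e <- 1L
    edges <- po$edge
    ne <- nrow(edges)
    while (e <= ne) {
        p <- edges[e, 1]
        last <- e
        while (last < ne && edges[last + 1L, 1] == p) last <- last + 1L
        kids <- edges[e:last, 2]
        Vk <- V[kids, , drop = FALSE]
        m <- colMeans(Vk)
        V[p, ] <- m
        contrib <- contrib + colSums(abs(sweep(Vk, 2, m)))
        e <- last + 1L
    }
    contrib
}

#' Fritz-Purvis phylogenetic dispersion statistic D
#'
#' Scales the observed sister-difference sum between the expectations
#' under two nulls: \eqn{D = (\Sigma d_{obs} - \overline{\Sigma
#' d}_{Brownian}) / (\overline{\Sigma d}_{random} - \overline{\Sigma
#' d}_{Brownian})}.  Random null: tip-label permutations of the observed
#' trait.  Brownian null: threshold-model simulations (root 0, increments
#' Normal(0, branch length), thresholded at the empirical quantile
#' matching the observed prevalence, ties broken by tip label order).
#' D is about 1 for phylogenetically random traits, about 0 for
#' Brownian-threshold traits, and negative for extreme clumping.
#'
#' @param tree rooted \code{phylo}.
#' @param trait non-constant binary vector named by tip label, or
#'   one-column [TraitTable-class].
#' @param nRandom,nBrownian null-draw counts (default 1000 each).
#' @param seed integer seed.
#' @return list with \code{sumDObs}, \code{D}, \code{pRandom} (add-one
#'   fraction of random draws at or below the observed sum; small means
#'   more clumped than random), \code{pBrownian}, \code{nSim}.
#' @export
fritzPurvisD <- function(tree, trait, nRandom = 1000L, nBrownian = 1000L,
                         seed = 1L) {
    idx <- .treeIndex(tree)
    x <- .traitVector(trait, idx$tipLabels)
    if (length(unique(x)) < 2)
        mtStop("degenerate_trait_error", "trait is constant across tips")
    obs <- .sigmaDBatch(idx$tree, matrix(x, ncol = 1))[1]
    k <- sum(x)
    labels <- idx$tipLabels
    withSeed(seed, {
        Xr <- matrix(x[c(replicate(nRandom, sample.int(length(x))))],
                     nrow = length(x))
        sd_r <- .sigmaDBatch(idx$tree, Xr)
        B <- .brownianTips(idx$tree, nBrownian)
        Xb <- apply(B, 2, function(v) {
            out <- integer(length(v))
            out[order(-v, labels)[seq_len(k)]] <- 1L
            out
        })
        sd_b <- .sigmaDBatch(idx$tree, Xb)
        mr <- mean(sd_r); mb <- mean(sd_b)
        if (abs(mr - mb) < .Machine$double.eps * 100)
            mtStop("undefined_D_error",
                   "random and Brownian null distributions coincide")
        list(sumDObs = obs, D = (obs - mb) / (mr - mb),
             pRandom = permPvalue(sum(sd_r <= obs), nRandom),
             pBrownian = permPvalue(sum(sd_b <= obs), nBrownian),
             nSim = c(random = nRandom, brownian = nBrownian))
    })
}

#' Cohen's d from summary statistics
#'
#' \eqn{d = |m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2}} with the pooled-SD
#' denominator over two groups.  Conventional bands: small below 0.5,
#' large above 1.
#'
#' @param mean1,sd1,mean2,sd2 group summary statistics (sds >= 0, not
#'   both 0 unless the means agree).
#' @return the effect size (Inf, flagged by a warning, when both SDs are
#'   0 and the means differ).
#' @examples
#' cohensD(0.0400, 0.0025, 0.2785, 0.0127)  # about 26
#' @export
cohensD <- function(mean1, sd1, mean2, sd2) {
    stopifnot(sd1 >= 0, sd2 >= 0)
    denom <- sqrt((sd1^2 + sd2^2) / 2)
    if (denom == 0) {
        if (mean1 == mean2) return(0)
        warning("both SDs are zero with different means: infinite effect")
        return(Inf)
    }
    abs(mean1 - mean2) / denom
}

#' Classify a Cohen's d effect size
#' @param d effect size from [cohensD()].
#' @return "small" (d < 0.5), "medium", or "large" (d > 1).
#' @export
effectSizeClass <- function(d) {
    ifelse(d < 0.5, "small", ifelse(d > 1, "large", "medium"))
}

#' Welch's unequal-variance t test from summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries; n1, n2 >= 2.
#' @return list with \code{t}, \code{df} (Welch-Satterthwaite) and the
#'   two-sided \code{p}.
#' @export
welchT <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2 || n2 < 2)
        mtStop("invalid_input_error", "group sizes must be >= 2")
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se2 <- v1 + v2
    if (se2 == 0)
        return(list(t = 0, df = n1 + n2 - 2, p = 1))
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Curated trait-depth summary statistics
#'
#' Loads the bundled per-lineage tau_D summary table (trait category,
#' metal, lineage, mean and SD of trait depth across bootstrap trees) for
#' the two marine alphaproteobacterial lineages the package's study
#' conditions emulate.
#'
#' @return data.frame with columns trait, metal, lineage, mean, sd.
#' @export
traitDepthSummary <- function() {
    path <- system.file("extdata", "trait_depth_summary.tsv",
                        package = "MetalTraits", mustWork = TRUE)
    readTsv(path)
}

#' Compare trait depths between two lineages
#'
#' For every trait category present in both lineages of a trait-depth
#' summary table, computes Cohen's d between the lineage means, its
#' effect-size class, and which lineage has the larger mean.
#'
#' @param summary data.frame with columns trait, lineage, mean, sd (e.g.
#'   [traitDepthSummary()]).
#' @param lineages length-2 character vector naming the lineages to
#'   compare (default: the two lineages present).
#' @return data.frame with one row per shared trait: trait, mean/sd per
#'   lineage, cohens_d, effect_class, larger_in.
#' @export
compareTraitDepths <- function(summary, lineages = NULL) {
    if (is.null(lineages))
        lineages <- unique(summary$lineage)
    stopifnot(length(lineages) == 2)
    s1 <- summary[summary$lineage == lineages[1], ]
    s2 <- summary[summary$lineage == lineages[2], ]
    shared <- intersect(s1$trait, s2$trait)
    rows <- lapply(shared, function(tr) {
        r1 <- s1[s1$trait == tr, ][1, ]
        r2 <- s2[s2$trait == tr, ][1, ]
        d <- cohensD(r1$mean, r1$sd, r2$mean, r2$sd)
        data.frame(trait = tr,
                   mean1 = r1$mean, sd1 = r1$sd,
                   mean2 = r2$mean, sd2 = r2$sd,
                   cohens_d = d, effect_class = effectSizeClass(d),
                   larger_in = ifelse(r2$mean > r1$mean, lineages[2],
                                      lineages[1]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "lineages") <- lineages
    out
}
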