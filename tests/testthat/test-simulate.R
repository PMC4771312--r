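test_that("simTree handles the degenerate single-tip case", {
    tr <- simTree(1, scale = 2, seed = 1)
    expect_s3_class(tr, "phylo")
    expect_equal(tr$tip.label, "t1")
    expect_equal(tr$Nnode, 1L)
    expect_equal(tr$edge.length, 2)
    expect_error(simTree(0, seed = 1), class = "invalid_spec_error")
})

test_that("simTree is deterministic and well-formed across seeds", {
    a <- ape::write.tree(simTree(16, seed = 42))
    b <- ape::write.tree(simTree(16, seed = 42))
    expect_identical(a, b)
    expect_false(identical(a, ape::write.tree(simTree(16, seed = 43))))
    for (s in 1:200) {
        tr <- simTree(64, seed = s)
        expect_length(tr$tip.label, 64)
        expect_true(all(tr$edge.length > 0))
        expect_true(ape::is.rooted(tr))
        expect_true(ape::is.binary(tr))
    }
})

test_that("simTree expected depth tracks the scale parameter", {
    depths <- vapply(1:100, function(s) {
        tr <- simTree(32, scale = 3, seed = 900 + s)
        max(ape::node.depth.edgelength(tr))
    }, numeric(1))
    expect_gt(mean(depths), 3 * 0.6)
    expect_lt(mean(depths), 3 * 1.6)
})

test_that("simTraits saturates at prevalence 1 and validates input", {
    tr <- simTree(10, seed = 3)
    for (m in c("random", "clumped", "brownian_threshold")) {
        tt <- simTraits(tr, m, prevalence = 1, seed = 5)
        expect_equal(sum(counts(tt)), 10, info = m)
    }
    expect_error(simTraits(tr, "random", prevalence = 0, seed = 1),
                 class = "invalid_spec_error")
    expect_error(simTraits(tr, "random", prevalence = 1.2, seed = 1),
                 class = "invalid_spec_error")
    expect_error(simTraits(tr, "clumped", prevalence = 0.5,
                           cladeTip = "nope", seed = 1),
                 class = "unknown_tip_error")
})

test_that("clumped traits mark the anchored cherry on a balanced tree", {
    tr <- balancedOctet()
    tt <- simTraits(tr, "clumped", prevalence = 0.25, cladeTip = "t1",
                    seed = 9)
    x <- counts(tt)[, 1]
    expect_equal(sort(names(x)[x == 1]), c("t1", "t2"))
})

test_that("brownian_threshold realizes the prevalence exactly", {
    tr <- simTree(64, seed = 7)
    for (s in 1:100) {
        tt <- simTraits(tr, "brownian_threshold", prevalence = 0.5,
                        seed = s)
        expect_equal(sum(counts(tt)), 32L)
    }
})

test_that("simGenomes plants loci contiguously and honors probabilities", {
    tpl <- list(list(name = "heme", families = c("TBDT", "hutB", "hmuS"),
                     prob = 1))
    sim <- simGenomes(10, 20, locusTemplates = tpl, seed = 11)
    expect_equal(nrow(sim$planted), 10)
    gr <- geneRecords(sim$genomes)
    md <- S4Vectors::mcols(gr)
    for (g in unique(sim$planted$genome_id)) {
        s0 <- sim$planted$start_index[sim$planted$genome_id == g]
        sel <- md$genome_id == g & md$index %in% (s0 + 0:2)
        fams <- unlist(md$families[sel][order(md$index[sel])])
        expect_equal(fams, c("TBDT", "hutB", "hmuS"))
    }
    # error when the template does not fit
    expect_error(simGenomes(2, 2, locusTemplates = tpl, seed = 1),
                 class = "invalid_spec_error")
})

test_that("simGenomes planting rate matches the binomial expectation", {
    tpl <- list(list(name = "L", families = c("TBDT", "fatB"),
                     prob = 0.4))
    sim <- simGenomes(500, 8, locusTemplates = tpl, seed = 13)
    n <- nrow(sim$planted)
    sd3 <- 3 * sqrt(500 * 0.4 * 0.6)
    expect_gt(n, 200 - sd3)
    expect_lt(n, 200 + sd3)
})

test_that("planted motifs are recoverable verbatim at the stated offset", {
    motif <- "AATGATAATGATTATCATT"
    tpl <- list(list(name = "L", families = c("TBDT", "fatB"), prob = 1))
    sim <- simGenomes(10, 10, locusTemplates = tpl,
                      motifPlant = list(motif = motif, offset = 100,
                                        mismatches = 0), seed = 17)
    for (g in sim$planted$first_gene) {
        up <- as.character(sim$upstream[[g]])
        expect_equal(substr(up, 101, 100 + nchar(motif)), motif)
    }
})

test_that("simSimilarityGraph builds exact cliques at p_in=1, p_out=0", {
    g <- simSimilarityGraph(c(3, 3), pIn = 1, pOut = 0, seed = 19)
    e <- edgeList(g$graph)
    expect_equal(nrow(e), 6)   # two disjoint triangles
    same <- g$membership[e$node_a] == g$membership[e$node_b]
    expect_true(all(same))
    g5 <- simSimilarityGraph(5, pIn = 1, pOut = 0, seed = 19)
    expect_equal(nrow(edgeList(g5$graph)), 10)  # complete graph K5
    expect_error(simSimilarityGraph(c(3, 3), pIn = 2, pOut = 0, seed = 1),
                 class = "invalid_spec_error")
})

test_that("between-cluster edge counts match the binomial expectation", {
    counts <- vapply(1:50, function(s) {
        g <- simSimilarityGraph(c(20, 20), pIn = 0.9, pOut = 0.05,
                                seed = s)
        e <- edgeList(g$graph)
        sum(g$membership[e$node_a] != g$membership[e$node_b])
    }, numeric(1))
    expect_lt(abs(mean(counts) - 0.05 * 400),
              3 * sqrt(400 * 0.05 * 0.95 / 50))
})

test_that("simCountMatrix dispersion and covariate contracts hold", {
    sim0 <- simCountMatrix(c(4, 4), nFeatures = 6,
                           groupDispersion = c(0, 0), seed = 23)
    m <- counts(sim0$counts)
    expect_true(all(m[1, ] == t(m[2:4, ])))
    expect_true(all(m[5, ] == t(m[6:8, ])))
    # covariateEffect = 0 gives an independent covariate
    rhos <- vapply(1:100, function(s) {
        sim <- simCountMatrix(c(10, 10), nFeatures = 8,
                              covariateEffect = 0, seed = 100 + s)
        suppressWarnings(stats::cor(rowSums(counts(sim$counts)),
                                    sim$metadata$covariate,
                                    method = "spearman"))
    }, numeric(1))
    expect_lt(abs(mean(rhos)), 3 / sqrt(100 * 19))
    expect_error(simCountMatrix(c(1, 5), seed = 1),
                 class = "invalid_spec_error")
})

test_that("all generators are bit-identical under a fixed seed", {
    expect_identical(ape::write.tree(simTree(20, seed = 5)),
                     ape::write.tree(simTree(20, seed = 5)))
    tr <- simTree(20, seed = 5)
    expect_identical(counts(simTraits(tr, "random", 0.3, seed = 6)),
                     counts(simTraits(tr, "random", 0.3, seed = 6)))
    a <- simGenomes(3, 10, seed = 7)
    b <- simGenomes(3, 10, seed = 7)
    expect_identical(as.character(a$upstream), as.character(b$upstream))
    expect_identical(edgeList(simSimilarityGraph(c(5, 5), 0.8, 0.1,
                                                 seed = 8)$graph),
                     edgeList(simSimilarityGraph(c(5, 5), 0.8, 0.1,
                                                 seed = 8)$graph))
    expect_identical(counts(simCountMatrix(c(3, 3), 4, seed = 9)$counts),
                     counts(simCountMatrix(c(3, 3), 4, seed = 9)$counts))
})
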