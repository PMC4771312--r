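test_that("Bray-Curtis matches hand values and metric properties", {
    m <- rbind(a = c(2, 2), b = c(1, 1), c = c(1, 0), d = c(0, 1))
    D <- brayCurtis(m)
    expect_equal(D["a", "b"], 1 / 3)
    expect_equal(D["c", "d"], 1)
    expect_equal(D["a", "a"], 0)
    expect_error(brayCurtis(rbind(c(1, 1), c(0, 0))),
                 class = "undefined_dissimilarity_error")
    expect_error(brayCurtis(rbind(c(-1, 1), c(1, 1))),
                 class = "invalid_input_error")
    set.seed(127)
    for (i in 1:10) {
        M <- matrix(rpois(60, 5) + 1, 10, 6)
        D <- brayCurtis(M)
        expect_equal(D, t(D))
        expect_true(all(D >= 0 & D <= 1))
        expect_true(all(diag(D) == 0))
        # cross-check against the field-standard implementation
        expect_equal(unname(D), unname(as.matrix(
            vegan::vegdist(M, method = "bray"))), tolerance = 1e-12)
    }
})

test_that("PCA conserves variance and reconstructs the data", {
    set.seed(131)
    M <- matrix(rnorm(120), 20, 6)
    ord <- pcaOrdination(M)
    cen <- scale(M, scale = FALSE)
    expect_equal(sum(ord@eigenvalues), sum(cen^2) / (nrow(M) - 1),
                 tolerance = 1e-10)
    expect_lt(max(abs(ord@scores %*% t(ord@loadings) - cen)), 1e-8)
    # rank-1 data: second eigenvalue vanishes
    M2 <- cbind(1:10, 2 * (1:10))
    expect_lt(pcaOrdination(M2)@eigenvalues[2], 1e-10)
    # deterministic sign convention
    ord2 <- pcaOrdination(M)
    expect_identical(ord@loadings, ord2@loadings)
    expect_true(all(apply(ord@loadings, 2, function(v)
        v[which.max(abs(v))] > 0)))
    expect_error(pcaOrdination(cbind(rep(1, 5), rnorm(5)), scale = TRUE),
                 class = "zero_variance_error")
})

test_that("envfit self-fit and orthogonal-fit behave as designed", {
    set.seed(137)
    S <- matrix(rnorm(80), 40, 2)
    ef <- envfitPerm(S, S[, 1], nPermutations = 199, seed = 5)
    expect_equal(ef$rSquared, 1, tolerance = 1e-12)
    expect_equal(ef$pPerm, 1 / 200)
    expect_equal(abs(ef$direction[1]), 1, tolerance = 1e-10)
    # residuals of a variable regressed on the axes are orthogonal
    v <- rnorm(40)
    res <- residuals(lm(v ~ S))
    expect_equal(envfitPerm(S, res, nPermutations = 99,
                            seed = 5)$rSquared, 0, tolerance = 1e-10)
    expect_error(envfitPerm(S, rep(1, 40)),
                 class = "zero_variance_error")
    expect_error(envfitPerm(S, factor(rep("a", 40))),
                 class = "invalid_factor_error")
})

test_that("envfit R2 agrees with vegan::envfit", {
    set.seed(139)
    S <- matrix(rnorm(60), 30, 2)
    v <- S %*% c(1, 2) + rnorm(30, 0, 0.5)
    ours <- envfitPerm(S, as.numeric(v), nPermutations = 99, seed = 7)
    theirs <- vegan::envfit(S, data.frame(v = as.numeric(v)),
                            permutations = 99)
    expect_equal(ours$rSquared, unname(theirs$vectors$r["v"]),
                 tolerance = 1e-10)
    f <- factor(rep(c("p", "q"), 15))
    ours_f <- envfitPerm(S, f, nPermutations = 99, seed = 7)
    theirs_f <- vegan::envfit(S, data.frame(f = f), permutations = 99)
    expect_equal(ours_f$rSquared, unname(theirs_f$factors$r["f"]),
                 tolerance = 1e-10)
})

test_that("dispersion test sees equal spread as null", {
    set.seed(149)
    base <- matrix(rnorm(40), 20, 2)
    S <- rbind(base, base + 10)   # translated copy: identical spread
    g <- rep(c("r", "s"), each = 20)
    r <- dispersionTest(S, g, nPermutations = 199, seed = 9)
    expect_lt(r$F, 1e-20)
    expect_gt(r$pPerm, 0.5)
    expect_equal(unname(r$groupMeanDistance[1]),
                 unname(r$groupMeanDistance[2]))
    expect_error(dispersionTest(S, rep("x", 40)),
                 class = "invalid_group_error")
    expect_error(dispersionTest(S, c("a", rep("b", 39))),
                 class = "invalid_group_error")
})

test_that("Spearman screen matches the rank formula and flags constants", {
    m <- cbind(x = 1:10, y = (1:10)^2, z = -(1:10),
               w = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), k = rep(1, 10))
    r <- spearmanScreen(m, data.frame(var1 = c("x", "x", "x", "x"),
                                      var2 = c("y", "z", "w", "k")))
    expect_equal(r$rho[1], 1)
    expect_equal(r$rho[2], -1)
    # average-rank oracle
    rx <- rank(m[, "x"]); rw <- rank(m[, "w"])
    expect_equal(r$rho[3], sum((rx - mean(rx)) * (rw - mean(rw))) /
                     sqrt(sum((rx - mean(rx))^2) * sum((rw - mean(rw))^2)),
                 tolerance = 1e-12)
    expect_true(is.na(r$rho[4]))
    expect_true(is.na(r$q[4]))   # excluded from BH
})

test_that("chi-squared matches the longhand expected-count formula", {
    r0 <- chiSquaredTest(matrix(10, 2, 2))
    expect_equal(r0$statistic, 0)
    expect_equal(r0$p, 1)
    expect_equal(r0$df, 1)
    set.seed(151)
    for (i in 1:10) {
        tab <- matrix(rpois(12, 8) + 1, 3, 4)
        r <- chiSquaredTest(tab)
        E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        expect_equal(r$statistic, sum((tab - E)^2 / E),
                     tolerance = 1e-12)
        expect_equal(r$df, 6)
        expect_equal(r$p, pchisq(r$statistic, 6, lower.tail = FALSE),
                     tolerance = 1e-12)
    }
    expect_error(chiSquaredTest(matrix(c(0, 0, 1, 2), 2, 2)),
                 class = "invalid_table_error")
})

test_that("BH adjustment follows the step-up procedure", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(157)
    p <- runif(30)
    q <- bhAdjust(p)
    expect_true(all(order(p) == order(q) | q[order(p)] ==
                        cummax(q[order(p)])))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_error(bhAdjust(c(0.5, 1.2)), class = "invalid_input_error")
})

test_that("BH controls the empirical FDR on mixed p-value sets", {
    set.seed(163)
    fdrs <- vapply(1:200, function(i) {
        null_p <- runif(40)
        alt_p <- rbeta(10, 0.1, 10)
        q <- bhAdjust(c(null_p, alt_p))
        rej <- q < 0.05
        if (!any(rej)) return(0)
        sum(rej[1:40]) / sum(rej)
    }, numeric(1))
    expect_lte(mean(fdrs), 0.05 + 3 * sd(fdrs) / sqrt(200))
})
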