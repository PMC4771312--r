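# Multivariate layer: Bray-Curtis dissimilarity, PCA ordination with a
# deterministic sign convention, envfit-style vector/factor fitting with
# permutation p-values, a permutation group-dispersion test, Spearman
# correlation screens with BH correction, and Pearson's chi-squared test.

#' Bray-Curtis dissimilarity
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all
#' row pairs of a non-negative sample-by-feature matrix.  Symmetric, zero
#' diagonal, values in [0, 1].
#'
#' @param m non-negative numeric matrix (samples x features) or a
#'   [TraitTable-class].
#' @return a symmetric dissimilarity matrix with the input's row names.
#' @examples
#' brayCurtis(rbind(a = c(2, 2), b = c(1, 1)))["a", "b"]  # 1/3
#' @export
brayCurtis <- function(m) {
    if (is(m, "TraitTable")) m <- counts(m)
    m <- as.matrix(m)
    if (any(m < 0))
        mtStop("invalid_input_error", "entries must be non-negative")
    if (any(rowSums(m) == 0))
        mtStop("undefined_dissimilarity_error",
               "all-zero row: Bray-Curtis undefined")
    n <- nrow(m)
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
        xi <- m[i, ]
        for (j in (i + 1):n) {
            D[i, j] <- D[j, i] <- sum(abs(xi - m[j, ])) / sum(xi + m[j, ])
        }
    }
    D
}

#' PCA ordination
#'
#' Principal components analysis of a sample-by-feature matrix via
#' singular value decomposition of the centered (optionally unit-variance
#' scaled) data, with a deterministic sign convention: each loading
#' vector's largest-magnitude entry is made positive.  Eigenvalues are
#' the variances along each component; their sum equals the total
#' variance of the (centered, scaled) data.
#'
#' @param m numeric matrix (samples x features) or [TraitTable-class].
#' @param center center columns (default TRUE).
#' @param scale scale columns to unit variance (default FALSE; an error
#'   if a feature is constant).
#' @return an [OrdinationModel-class].
#' @export
pcaOrdination <- function(m, center = TRUE, scale = FALSE) {
    if (is(m, "TraitTable")) m <- counts(m)
    m <- as.matrix(m)
    if (nrow(m) < 2 || ncol(m) < 2)
        mtStop("invalid_input_error", "need >= 2 samples and >= 2 features")
    if (scale && any(apply(m, 2, stats::sd) == 0))
        mtStop("zero_variance_error",
               "constant feature cannot be scaled to unit variance")
    pc <- stats::prcomp(m, center = center, scale. = scale)
    load <- pc$rotation
    flip <- apply(load, 2, function(v) v[which.max(abs(v))] < 0)
    load[, flip] <- -load[, flip]
    scores <- pc$x
    scores[, flip] <- -scores[, flip]
    new("OrdinationModel", scores = scores, loadings = load,
        eigenvalues = pc$sdev^2, center = center, scale = scale)
}

#' Fit a variable to ordination axes (envfit-style)
#'
#' Continuous variables are regressed on the first \code{k} ordination
#' axes; \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and the direction is the unit
#' vector of regression coefficients.  Factors score \eqn{R^2 = 1 -
#' SS_{within}/SS_{total}} of the scores around level centroids.
#' Significance comes from permuting the variable across samples, with
#' the add-one estimator \eqn{p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\}) /
#' (1 + N)}.
#'
#' @param scores sample-by-axis score matrix (e.g.
#'   \code{scores(pcaOrdination(...))}) or an [OrdinationModel-class].
#' @param variable numeric vector (vector fit) or factor/character
#'   (factor fit), one value per sample.
#' @param k number of leading axes to fit against (default 2, the
#'   plotted plane).
#' @param nPermutations default 999.
#' @param seed integer seed.
#' @return list with \code{kind}, \code{rSquared}, \code{pPerm} and, for
#'   vectors, \code{direction} (unit vector over the k axes).
#' @export
envfitPerm <- function(scores, variable, k = 2L, nPermutations = 999L,
                       seed = 1L) {
    if (is(scores, "OrdinationModel")) scores <- scores@scores
    S <- as.matrix(scores)[, seq_len(min(k, ncol(scores))), drop = FALSE]
    n <- nrow(S)
    if (length(variable) != n)
        mtStop("invalid_input_error",
               "variable length must equal the sample count")
    is_factor <- is.character(variable) || is.factor(variable)
    if (is_factor) {
        f <- factor(variable)
        if (nlevels(f) < 2)
            mtStop("invalid_factor_error", "factor needs >= 2 levels")
        r2_fun <- function(fv) {
            tot <- sum(scale(S, scale = FALSE)^2)
            within <- 0
            for (lev in levels(fv)) {
                Sg <- S[fv == lev, , drop = FALSE]
                within <- within + sum(scale(Sg, scale = FALSE)^2)
            }
            1 - within / tot
        }
        obs <- r2_fun(f)
        perm_stat <- function(ix) r2_fun(f[ix])
    } else {
        if (stats::sd(variable) == 0)
            mtStop("zero_variance_error", "constant variable")
        X <- cbind(1, S)
        r2_fun <- function(v) {
            fit <- stats::lm.fit(X, v)
            1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
        }
        obs <- r2_fun(variable)
        coefs <- unname(stats::lm.fit(X, variable)$coefficients[-1])
        direction <- coefs / sqrt(sum(coefs^2))
        perm_stat <- function(ix) r2_fun(variable[ix])
    }
    perm <- withSeed(seed, vapply(seq_len(nPermutations),
        function(i) perm_stat(sample.int(n)), numeric(1)))
    out <- list(kind = if (is_factor) "factor" else "vector",
                rSquared = obs,
                pPerm = permPvalue(sum(perm >= obs - 1e-12), nPermutations))
    if (!is_factor) out$direction <- direction
    out
}

#' Permutation test for group dispersion differences
#'
#' Computes each sample's distance to its group centroid in the
#' ordination space, the one-way F statistic on those distances, and a
#' p-value from permuting the group labels.  Large F with small p
#' indicates groups with significantly different spread (e.g. one tight
#' and one dispersed lineage cloud).
#'
#' @param scores sample-by-axis matrix or [OrdinationModel-class].
#' @param groups group labels, one per sample; >= 2 groups, each of
#'   size >= 2.
#' @param nPermutations default 999.
#' @param seed integer seed.
#' @return list with \code{F}, \code{pPerm} and \code{groupMeanDistance}
#'   (named vector of mean distance to centroid per group).
#' @export
dispersionTest <- function(scores, groups, nPermutations = 999L,
                           seed = 1L) {
    if (is(scores, "OrdinationModel")) scores <- scores@scores
    S <- as.matrix(scores)
    f <- factor(groups)
    if (nlevels(f) < 2)
        mtStop("invalid_group_error", "need >= 2 groups")
    if (any(table(f) < 2))
        mtStop("invalid_group_error", "every group needs >= 2 members")
    dists <- function(fv) {
        d <- numeric(nrow(S))
        for (lev in levels(fv)) {
            sel <- fv == lev
            cen <- colMeans(S[sel, , drop = FALSE])
            d[sel] <- sqrt(rowSums(sweep(S[sel, , drop = FALSE], 2,
                                         cen)^2))
        }
        d
    }
    fstat <- function(d, fv) {
        gm <- tapply(d, fv, mean)
        ng <- tabulate(fv)
        ssb <- sum(ng * (gm - mean(d))^2)
        ssw <- sum((d - gm[as.integer(fv)])^2)
        dfb <- nlevels(fv) - 1
        dfw <- length(d) - nlevels(fv)
        (ssb / dfb) / (ssw / dfw)
    }
    d_obs <- dists(f)
    F_obs <- fstat(d_obs, f)
    # permute group labels over the fixed distances-to-own-centroid
    # (the exchangeable quantity under the equal-dispersion null)
    perm <- withSeed(seed, vapply(seq_len(nPermutations), function(i)
        fstat(d_obs[sample.int(length(f))], f), numeric(1)))
    list(F = F_obs,
         pPerm = permPvalue(sum(perm >= F_obs - 1e-12), nPermutations),
         groupMeanDistance = tapply(d_obs, f, mean))
}

#' Spearman correlation screen with BH correction
#'
#' Rank correlations (average ranks for ties) with two-sided p-values for
#' a requested set of variable pairs, BH-adjusted jointly.  Pairs
#' involving a constant variable are flagged (rho = NA) and excluded from
#' the BH adjustment.
#'
#' @param m numeric matrix (observations x variables) with column names.
#' @param pairs two-column matrix or data.frame of variable names to
#'   test (default: all distinct pairs).
#' @return data.frame with columns var1, var2, rho, p, q.
#' @export
spearmanScreen <- function(m, pairs = NULL) {
    m <- as.matrix(m)
    if (is.null(pairs)) {
        cmb <- utils::combn(colnames(m), 2)
        pairs <- data.frame(var1 = cmb[1, ], var2 = cmb[2, ])
    }
    pairs <- as.data.frame(pairs)
    res <- lapply(seq_len(nrow(pairs)), function(i) {
        x <- m[, pairs[[1]][i]]; y <- m[, pairs[[2]][i]]
        if (length(x) < 3)
            mtStop("invalid_input_error", "need >= 3 observations")
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            return(data.frame(var1 = pairs[[1]][i], var2 = pairs[[2]][i],
                              rho = NA_real_, p = NA_real_))
        ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                               exact = FALSE))
        data.frame(var1 = pairs[[1]][i], var2 = pairs[[2]][i],
                   rho = unname(ct$estimate), p = ct$p.value)
    })
    out <- do.call(rbind, res)
    out$q <- NA_real_
    ok <- !is.na(out$p)
    out$q[ok] <- bhAdjust(out$p[ok])
    out
}

#' Pearson's chi-squared test of independence
#'
#' No continuity correction by default (set \code{correct = TRUE} for
#' the Yates-corrected 2x2 variant).
#'
#' @param tab contingency table (matrix of counts) with positive row and
#'   column sums.
#' @param correct apply the continuity correction (default FALSE).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chiSquaredTest <- function(tab, correct = FALSE) {
    tab <- as.matrix(tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        mtStop("invalid_table_error", "zero row or column marginal")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p-values to q-values controlling the false discovery rate:
#' \eqn{q_i = \min_{j \ge i} m \, p_{(j)} / j}, returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        mtStop("invalid_input_error", "p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
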