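test_that("parseDomainHits handles empty input and computes ranks", {
    p <- tempfile()
    writeLines(character(0), p)
    h <- parseDomainHits(p)
    expect_equal(nrow(h), 0)
    expect_equal(nrow(attr(h, "errors")), 0)

    p2 <- writeHitTable(list(
        c("g1|q1", "mA", "1e-20", "50", "specific", "TBDT"),
        c("g1|q1", "mB", "1e-10", "40", "specific", "fatB")))
    h2 <- parseDomainHits(p2)
    expect_equal(h2$rank_for_query[h2$model_id == "mA"], 1L)
    expect_equal(h2$rank_for_query[h2$model_id == "mB"], 2L)
    expect_equal(unique(h2$genome_id), "g1")
})

test_that("malformed rows are collected and only fatal past threshold", {
    p <- tempfile()
    good <- paste(c("g1|q1", "mA", "100", "100", "0", "0", "1", "100",
                    "1", "100", "1e-10", "50", "specific", "TBDT"),
                  collapse = "\t")
    writeLines(c("only\ttwo", good), p)
    expect_error(parseDomainHits(p), class = "malformed_input_error")
    h <- parseDomainHits(p, maxBadFraction = 0.6)
    expect_equal(attr(h, "errors")$line, 1L)
    expect_equal(nrow(h), 1)
})

test_that("1000 synthetic rows survive a write -> parse round trip", {
    set.seed(31)
    n <- 1000
    hits <- data.frame(
        query_id = sprintf("g%d|q%04d", sample(1:20, n, TRUE), 1:n),
        model_id = sprintf("m%02d", sample(1:30, n, TRUE)),
        evalue = 10^-runif(n, 3, 30),
        bitscore = round(runif(n, 20, 500), 1),
        hit_class = sample(c("specific", "superfamily", "nonspecific"),
                           n, TRUE),
        family_label = sprintf("fam%02d", sample(1:10, n, TRUE)),
        stringsAsFactors = FALSE)
    hits$genome_id <- sub("\\|.*", "", hits$query_id)
    p <- tempfile()
    writeDomainHits(hits, p)
    back <- parseDomainHits(p)
    ord <- order(hits$query_id, hits$model_id)
    bord <- order(back$query_id, back$model_id)
    for (col in c("query_id", "genome_id", "model_id", "family_label",
                  "hit_class"))
        expect_identical(back[[col]][bord], hits[[col]][ord])
    expect_equal(back$evalue[bord], hits$evalue[ord], tolerance = 1e-9)
    expect_equal(back$bitscore[bord], hits$bitscore[ord])
})

test_that("the e-value threshold is strict and specific hits survive", {
    p <- writeHitTable(list(
        c("g1|q1", "mA", "1e-4", "50", "specific", "TBDT"),
        c("g1|q2", "mB", "1e-10", "60", "specific", "fatB")))
    f <- filterHits(parseDomainHits(p))
    expect_equal(f$query_id, "g1|q2")
    expect_false(f$superfamily)
})

test_that("filtering matches a brute-force bidirectional oracle", {
    # exhaustive check on random bitscore matrices, queries x models,
    # one genome
    for (s in 1:20) {
        set.seed(s)
        nq <- sample(2:5, 1); nm <- sample(2:5, 1)
        bs <- matrix(sample(seq(30, 300, by = 10), nq * nm), nq, nm)
        rows <- list()
        for (i in seq_len(nq)) for (j in seq_len(nm))
            rows[[length(rows) + 1L]] <- c(
                sprintf("g1|q%d", i), sprintf("m%d", j), "1e-10",
                as.character(bs[i, j]), "specific", sprintf("fam%d", j))
        f <- filterHits(parseDomainHits(writeHitTable(rows)))
        # oracle: mutual best (no bitscore ties by construction)
        expected <- list()
        for (i in seq_len(nq)) for (j in seq_len(nm))
            if (bs[i, j] == max(bs[i, ]) && bs[i, j] == max(bs[, j]))
                expected[[length(expected) + 1L]] <-
                    c(sprintf("g1|q%d", i), sprintf("m%d", j))
        got <- paste(f$query_id, f$model_id)
        want <- vapply(expected, paste, character(1), collapse = " ")
        expect_setequal(got, want)
    }
})

test_that("superfamily-only queries are tagged rather than dropped", {
    p <- writeHitTable(list(
        c("g1|q1", "mA", "1e-10", "50", "superfamily", "troA"),
        c("g1|q2", "mB", "1e-10", "70", "specific", "znuA"),
        c("g1|q2", "mC", "1e-12", "30", "superfamily", "troA")))
    f <- filterHits(parseDomainHits(p))
    expect_setequal(f$query_id, c("g1|q1", "g1|q2"))
    expect_true(f$superfamily[f$query_id == "g1|q1"])
    expect_false(f$superfamily[f$query_id == "g1|q2"])
    inv <- buildInventory(f, "g1", c("troA", "znuA"))
    expect_equal(counts(inv)["g1", "znuA"], 1L)
    expect_equal(counts(inv)["g1", "troA_superfamily"], 1L)
    expect_equal(counts(inv)["g1", "troA"], 0L)
})

test_that("filtering is idempotent and order-invariant", {
    set.seed(37)
    rows <- lapply(1:60, function(i) c(
        sprintf("g%d|q%d", sample(1:3, 1), sample(1:10, 1)),
        sprintf("m%d", sample(1:6, 1)),
        format(10^-runif(1, 2, 20)), as.character(round(runif(1, 20, 200))),
        sample(c("specific", "superfamily", "nonspecific"), 1),
        sprintf("fam%d", sample(1:4, 1))))
    h <- parseDomainHits(writeHitTable(rows))
    f1 <- filterHits(h)
    f2 <- filterHits(f1)
    expect_identical(f1, f2)
    # row order of the input table does not matter
    hshuf <- parseDomainHits(writeHitTable(rows[sample(length(rows))]))
    fshuf <- filterHits(hshuf)
    key <- function(x) sort(paste(x$query_id, x$model_id))
    expect_identical(key(f1), key(fshuf))
})

test_that("buildInventory counts match declarations and retained hits", {
    inv0 <- buildInventory(filterHits(parseDomainHits({
        p <- tempfile(); writeLines(character(0), p); p
    })), c("g1", "g2"), c("TBDT", "fatB"))
    expect_equal(dim(inv0), c(2L, 2L))
    expect_true(all(counts(inv0) == 0))

    p <- writeHitTable(list(
        c("g1|q1", "mA", "1e-10", "50", "specific", "TBDT"),
        c("g1|q2", "mA2", "1e-10", "60", "specific", "TBDT")))
    f <- filterHits(parseDomainHits(p))
    inv <- buildInventory(f, "g1", "TBDT")
    expect_equal(counts(inv)["g1", "TBDT"], 2L)
    expect_equal(binaryView(inv)["g1", "TBDT"], 1L)
    expect_equal(sum(counts(inv)), nrow(f))
    expect_error(buildInventory(f, "gOther", "TBDT"),
                 class = "unknown_label_error")
})

test_that("inventory counts recover a planted ground truth", {
    tpl <- list(list(name = "heme", families = c("TBDT", "hutB", "hmuS"),
                     prob = 0.7))
    sim <- simGenomes(20, 15, locusTemplates = tpl, seed = 41)
    md <- S4Vectors::mcols(geneRecords(sim$genomes))
    rows <- list()
    for (i in seq_along(md$gene_id)) {
        for (fam in md$families[[i]])
            rows[[length(rows) + 1L]] <- c(
                paste0(md$genome_id[i], "|", md$gene_id[i]), paste0("m_", fam),
                "1e-12", "100", "specific", fam)
    }
    f <- filterHits(parseDomainHits(writeHitTable(rows)))
    genomes <- sprintf("g%d", 1:20)
    inv <- buildInventory(f, genomes, c("TBDT", "hutB", "hmuS", "other",
                                        "SIP", "fatB"))
    planted_per_genome <- table(factor(sim$planted$genome_id,
                                       levels = genomes))
    expect_equal(unname(counts(inv)[genomes, "hutB"]),
                 as.integer(planted_per_genome))
    expect_equal(unname(counts(inv)[genomes, "hmuS"]),
                 as.integer(planted_per_genome))
})
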