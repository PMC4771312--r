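furbox19 <- "AATGATAATGATTATCATT"

test_that("exact reference matches are found on both strands", {
    sp <- motifSpec("furbox", 19, referenceSeqs = furbox19,
                    maxMismatches = 0)
    h <- scanReferenceMotifs(c(u1 = furbox19), sp)
    expect_equal(h$start, 0L)
    expect_equal(h$strand, "+")
    expect_equal(h$mismatches, 0L)
    # near-palindrome: the reverse complement differs at one position
    sp1 <- motifSpec("furbox", 19, referenceSeqs = furbox19,
                     maxMismatches = 1)
    h1 <- scanReferenceMotifs(c(u1 = furbox19), sp1)
    expect_setequal(h1$strand, c("+", "-"))
    expect_equal(h1$mismatches[h1$strand == "-"], 1L)

    asym <- "ACGTACGTACGTACGTACG"
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(asym)))
    sp2 <- motifSpec("m", 19, referenceSeqs = asym, maxMismatches = 0)
    h2 <- scanReferenceMotifs(c(u1 = rc), sp2)
    expect_equal(h2$strand, "-")
    expect_equal(h2$start, 0L)
})

test_that("reference of the wrong length is rejected", {
    expect_error(motifSpec("m", 19, referenceSeqs = "ACGT"),
                 class = "invalid_spec_error")
    expect_error(motifSpec("m", 15, armLength = 7, spacer = 3),
                 class = "invalid_spec_error")
})

test_that("reference scan equals the brute-force all-window oracle", {
    set.seed(47)
    seqs <- setNames(lapply(1:100, function(i) randomDna(1000)),
                     sprintf("r%03d", 1:100))
    # plant a few exact and perturbed copies so hits actually occur
    seqs[["r001"]] <- paste0(substr(seqs[["r001"]], 1, 100), furbox19,
                             substr(seqs[["r001"]], 120, 1000))
    sp <- motifSpec("furbox", 19, referenceSeqs = furbox19,
                    maxMismatches = 2)
    got <- scanReferenceMotifs(Biostrings::DNAStringSet(unlist(seqs)), sp)
    want <- bruteForceScan(seqs, furbox19, 2)
    key <- function(d) sort(paste(d$record_id, d$start, d$strand,
                                  d$mismatches))
    expect_identical(key(got), key(want))
})

test_that("hit sets mirror under reverse complement and grow with
           tolerance", {
    set.seed(53)
    s <- randomDna(400)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    ref <- "ACGTAGGCTAACGTAGGCT"
    for (mm in 2:4) {
        sp <- motifSpec("m", 19, referenceSeqs = ref, maxMismatches = mm)
        h_f <- scanReferenceMotifs(c(x = s), sp)
        h_r <- scanReferenceMotifs(c(x = rc), sp)
        mirrored <- data.frame(
            start = 400 - h_r$start - 19L,
            strand = ifelse(h_r$strand == "+", "-", "+"))
        expect_setequal(paste(h_f$start, h_f$strand),
                        paste(mirrored$start, mirrored$strand))
        if (mm > 2) {
            sp_lo <- motifSpec("m", 19, referenceSeqs = ref,
                               maxMismatches = mm - 1L)
            expect_gte(nrow(h_f),
                       nrow(scanReferenceMotifs(c(x = s), sp_lo)))
        }
    }
})

test_that("zero-mismatch scan of a motif-free record is empty", {
    sp <- motifSpec("m", 19, referenceSeqs = furbox19, maxMismatches = 0)
    expect_equal(nrow(scanReferenceMotifs(c(x = strrep("A", 200)), sp)), 0)
})

test_that("7-1-7 inverted repeats are detected structurally", {
    sp <- motifSpec("fur717", 15, armLength = 7, spacer = 1)
    h <- scanInvertedRepeats(c(u = "AAACCCTGAGGGTTT"), sp)
    expect_equal(nrow(h), 1)
    expect_equal(h$start, 0L)
    expect_equal(h$palindromic_pairs, 7L)
    # A-A pairs fail reverse-complement pairing
    expect_equal(nrow(scanInvertedRepeats(c(u = strrep("A", 15)), sp)), 0)
})

test_that("planted 7-1-7 repeats are recovered at exact offsets", {
    motif <- "AAACCCTGAGGGTTT"
    tpl <- list(list(name = "L", families = c("TBDT", "fatB"), prob = 1))
    sim <- simGenomes(50, 6, locusTemplates = tpl,
                      motifPlant = list(motif = motif, offset = 120,
                                        mismatches = 0), seed = 59)
    sp <- motifSpec("fur717", 15, armLength = 7, spacer = 1)
    h <- scanInvertedRepeats(sim$upstream, sp)
    for (g in sim$planted$first_gene)
        expect_true(any(h$record_id == g & h$start == 120L),
                    info = g)
})

test_that("hits are assigned to the nearest downstream gene in range", {
    gt <- makeGenomeTable(c("TBDT", "other"), strand = "+")
    # gene 1 starts at 0-based 1000; hit at 950 is 50 bp upstream
    hits <- data.frame(record_id = "gX", start = 950L, strand = "+",
                       mismatches = 0L, palindromic_pairs = NA,
                       assigned_gene = NA, motif_name = "m",
                       stringsAsFactors = FALSE)
    h <- assignHitsToGenes(hits, gt, windowBp = 300)
    expect_equal(h$assigned_gene, "gX_002")
    hits$start <- 500L   # 500 bp upstream of gene 2 start
    h2 <- assignHitsToGenes(hits, gt, windowBp = 300)
    expect_true(is.na(h2$assigned_gene))
    hits$record_id <- "nope"
    expect_error(assignHitsToGenes(hits, gt),
                 class = "unknown_reference_error")
})

test_that("assignment equals a brute-force nearest-downstream search", {
    set.seed(61)
    for (rep in 1:10) {
        n <- 12
        strands <- sample(c("+", "-"), n, TRUE)
        gt <- makeGenomeTable(rep("fam", n), strand = strands)
        gr <- geneRecords(gt)
        starts0 <- GenomicRanges::start(gr) - 1L
        ends0 <- GenomicRanges::end(gr)
        hits <- data.frame(record_id = "gX",
                           start = sample(0:12000, 30), strand =
                               sample(c("+", "-"), 30, TRUE),
                           mismatches = 0L, palindromic_pairs = NA,
                           assigned_gene = NA, motif_name = "m",
                           stringsAsFactors = FALSE)
        got <- assignHitsToGenes(hits, gt, windowBp = 400)
        for (i in seq_len(nrow(hits))) {
            cand <- which(strands == hits$strand[i])
            d <- if (hits$strand[i] == "+")
                starts0[cand] - hits$start[i]
            else hits$start[i] - ends0[cand]
            ok <- which(d >= 0 & d <= 400)
            want <- if (length(ok))
                S4Vectors::mcols(gr)$gene_id[cand[ok[which.min(d[ok])]]]
            else NA_character_
            expect_identical(got$assigned_gene[i], want)
        }
    }
})
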