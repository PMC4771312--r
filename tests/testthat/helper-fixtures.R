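# Shared fixture builders (everything generated in code; no binary data).

# balanced 4-tip tree with unit branches: ((A,B),(C,D))
balancedQuartet <- function() {
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# balanced 8-tip tree over t1..t8, unit branches
balancedOctet <- function() {
    ape::read.tree(text = paste0(
        "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
        "((t5:1,t6:1):1,(t7:1,t8:1):1):1);"))
}

# write a domain-hit table; rows = list of c(qseqid, model, evalue,
# bitscore, class, family)
writeHitTable <- function(rows, path = tempfile(fileext = ".tsv")) {
    lines <- vapply(rows, function(r)
        paste(r[1], r[2], "100", "100", "0", "0", "1", "100", "1", "100",
              r[3], r[4], r[5], r[6], sep = "\t"), character(1))
    writeLines(lines, path)
    path
}

# small genome table: one contig, n genes, given family labels (list or
# character vector; "" = none), all on + strand unless stated
makeGenomeTable <- function(families, strand = "+", genome_id = "gX") {
    n <- length(families)
    if (is.character(families)) families <- as.list(families)
    families <- lapply(families, function(f) f[nzchar(f)])
    df <- data.frame(contig_id = genome_id,
                     start = (seq_len(n) - 1L) * 1000L + 1L,
                     end = (seq_len(n) - 1L) * 1000L + 900L,
                     strand = rep(strand, length.out = n),
                     gene_id = sprintf("%s_%03d", genome_id, seq_len(n)),
                     genome_id = genome_id, index = seq_len(n) - 1L,
                     stringsAsFactors = FALSE)
    df$families <- families
    GenomeTable(df)
}

# random DNA string
randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force Hamming scan oracle: all windows, both strands, best
# mismatch count over references
bruteForceScan <- function(seqs, refs, maxMismatches) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]),
                                 collapse = "")
    L <- nchar(refs[1])
    out <- list()
    for (id in names(seqs)) {
        s <- strsplit(seqs[[id]], "")[[1]]
        nw <- length(s) - L + 1L
        if (nw < 1) next
        for (st in c("+", "-")) {
            pats <- if (st == "+") refs else vapply(refs, revcomp,
                                                    character(1))
            pmat <- do.call(rbind, strsplit(pats, ""))
            for (w in seq_len(nw)) {
                win <- s[w:(w + L - 1L)]
                mm <- min(rowSums(pmat != matrix(win, nrow(pmat), L,
                                                 byrow = TRUE)))
                if (mm <= maxMismatches)
                    out[[length(out) + 1L]] <- data.frame(
                        record_id = id, start = w - 1L, strand = st,
                        mismatches = mm, stringsAsFactors = FALSE)
            }
        }
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(record_id = character(), start = integer(),
                   strand = character(), mismatches = integer())
}

# exhaustive hypergeometric upper-tail oracle from the explicit pmf
hyperTailOracle <- function(a, b, cc, d) {
    N <- a + b + cc + d; K <- a + cc; n <- a + b
    ks <- a:min(K, n)
    sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
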