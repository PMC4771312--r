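# Fur-box-like regulatory motif detection: reference-based Hamming scans
# (19-bp palindromes) and structural 7-1-7 inverted-repeat scans.

#' Motif search specification
#'
#' @param name motif name carried into hit records.
#' @param length motif length in bp (19 for the classical Fur box, 15 for
#'   the 7-1-7 variant).
#' @param referenceSeqs optional character vector of known motif strings,
#'   all of length \code{length}.
#' @param armLength,spacer inverted-repeat geometry; must satisfy
#'   \code{2 * armLength + spacer == length} when used.
#' @param maxMismatches mismatch tolerance for reference scans (default 3
#'   for 19-bp motifs, 2 otherwise; the scan is exhaustive, so this is the
#'   only sensitivity knob).
#' @param minPalindromicPairs minimum reverse-complement-paired arm
#'   positions for an inverted-repeat hit (default = armLength).
#' @return a list of class \code{"MotifSpec"}.
#' @export
motifSpec <- function(name, length, referenceSeqs = NULL,
                      armLength = NULL, spacer = NULL,
                      maxMismatches = if (length >= 19) 3L else 2L,
                      minPalindromicPairs = armLength) {
    if (!is.null(armLength)) {
        if (is.null(spacer)) spacer <- length - 2L * armLength
        if (2L * armLength + spacer != length)
            mtStop("invalid_spec_error",
                   "armLength * 2 + spacer must equal motif length")
    }
    if (maxMismatches >= length)
        mtStop("invalid_spec_error", "maxMismatches must be < length")
    if (!is.null(referenceSeqs) && any(nchar(referenceSeqs) != length))
        mtStop("invalid_spec_error",
               "all reference sequences must have the declared length")
    structure(list(name = name, length = as.integer(length),
                   referenceSeqs = referenceSeqs,
                   armLength = armLength, spacer = spacer,
                   maxMismatches = as.integer(maxMismatches),
                   minPalindromicPairs = minPalindromicPairs),
              class = "MotifSpec")
}

.emptyMotifHits <- function() {
    data.frame(record_id = character(), start = integer(),
               strand = character(), mismatches = integer(),
               palindromic_pairs = integer(), assigned_gene = character(),
               motif_name = character(), stringsAsFactors = FALSE)
}

#' Scan sequences for matches to reference motifs
#'
#' Exhaustive Hamming-distance scan of every window on both strands
#' against every reference sequence; a window is reported once, with its
#' best (minimum) mismatch count over the references, when that count is
#' within \code{maxMismatches}.  Non-ACGT bases count as mismatches.
#' Overlapping hits are reported individually.  Coordinates are 0-based
#' offsets of the window start on the forward strand of the record.
#'
#' @param records a \code{DNAStringSet} (or named character vector).
#' @param spec a [motifSpec()] with non-empty \code{referenceSeqs}.
#' @return data.frame of motif hits (record_id, start, strand, mismatches,
#'   palindromic_pairs = NA, assigned_gene = NA, motif_name).
#' @examples
#' recs <- Biostrings::DNAStringSet(c(u1 = "AATGATAATGATTATCATT"))
#' sp <- motifSpec("furbox", 19, referenceSeqs = "AATGATAATGATTATCATT",
#'                 maxMismatches = 0)
#' scanReferenceMotifs(recs, sp)
#' @export
scanReferenceMotifs <- function(records, spec) {
    if (is.null(spec$referenceSeqs) || !length(spec$referenceSeqs))
        mtStop("invalid_spec_error", "referenceSeqs must be non-empty")
    records <- .asDNAStringSet(records)
    L <- spec$length
    hits <- list()
    for (ri in seq_along(records)) {
        subject <- records[[ri]]
        if (length(subject) < L) next
        nw <- length(subject) - L + 1L
        best_fwd <- rep(L, nw); best_rev <- rep(L, nw)
        for (ref in spec$referenceSeqs) {
            pat <- Biostrings::DNAString(ref)
            best_fwd <- pmin(best_fwd, .windowMismatches(pat, subject,
                                                         spec$maxMismatches))
            rc <- Biostrings::reverseComplement(pat)
            best_rev <- pmin(best_rev, .windowMismatches(rc, subject,
                                                         spec$maxMismatches))
        }
        for (st in c("+", "-")) {
            best <- if (st == "+") best_fwd else best_rev
            at <- which(best <= spec$maxMismatches)
            if (length(at))
                hits[[length(hits) + 1L]] <- data.frame(
                    record_id = names(records)[ri], start = at - 1L,
                    strand = st, mismatches = best[at],
                    palindromic_pairs = NA_integer_,
                    assigned_gene = NA_character_,
                    motif_name = spec$name, stringsAsFactors = FALSE)
        }
    }
    out <- if (length(hits)) do.call(rbind, hits) else .emptyMotifHits()
    out <- out[order(out$record_id, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# mismatch count of `pat` at every window start of `subject`; positions
# with more than max_mm mismatches are reported as nchar(pat) (capped).
.windowMismatches <- function(pat, subject, max_mm) {
    L <- length(pat)
    nw <- length(subject) - L + 1L
    mm <- rep(L, nw)
    # matchPattern enumerates qualifying windows; neditStartingAt gives
    # their exact mismatch counts
    m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm,
                                  with.indels = FALSE)
    if (length(m)) {
        st <- Biostrings::start(m)
        mm[st] <- Biostrings::neditStartingAt(pat, subject, starting.at = st)
    }
    mm
}

.asDNAStringSet <- function(records) {
    if (is.character(records)) records <- Biostrings::DNAStringSet(records)
    if (is.null(names(records)))
        names(records) <- sprintf("record%d", seq_along(records))
    records
}

#' Scan sequences for inverted repeats (e.g. the 7-1-7 Fur box)
#'
#' A window of \code{spec$length} qualifies when at least
#' \code{minPalindromicPairs} of its \code{armLength} arm positions
#' satisfy reverse-complement pairing (position i of the left arm pairs
#' with the mirrored position of the right arm).  If reference sequences
#' are supplied, the window must also pass the Hamming criterion of
#' [scanReferenceMotifs()].  Because the structure is self-complementary,
#' hits are reported on the + strand.
#'
#' @param records a \code{DNAStringSet} (or named character vector).
#' @param spec a [motifSpec()] with \code{armLength}/\code{spacer} set.
#' @return data.frame of motif hits with \code{palindromic_pairs} filled.
#' @examples
#' recs <- c(u1 = "AAACCCTGAGGGTTT")
#' sp <- motifSpec("furbox717", 15, armLength = 7, spacer = 1)
#' scanInvertedRepeats(recs, sp)
#' @export
scanInvertedRepeats <- function(records, spec) {
    if (is.null(spec$armLength))
        mtStop("invalid_spec_error", "armLength/spacer not configured")
    records <- .asDNAStringSet(records)
    L <- spec$length; A <- spec$armLength
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_ok <- NULL
    if (!is.null(spec$referenceSeqs) && length(spec$referenceSeqs))
        ref_ok <- scanReferenceMotifs(records, spec)
    hits <- list()
    for (ri in seq_along(records)) {
        s <- strsplit(as.character(records[[ri]]), "")[[1]]
        n <- length(s)
        if (n < L) next
        nw <- n - L + 1L
        pairs <- integer(nw)
        for (i in seq_len(A)) {
            left <- s[seq_len(nw) + i - 1L]
            right <- s[seq_len(nw) + L - i]
            pairs <- pairs + as.integer(!is.na(comp[left]) &
                                        comp[left] == right)
        }
        at <- which(pairs >= spec$minPalindromicPairs)
        if (!is.null(ref_ok)) {
            ok <- ref_ok$start[ref_ok$record_id == names(records)[ri]]
            at <- at[(at - 1L) %in% ok]
        }
        if (length(at))
            hits[[length(hits) + 1L]] <- data.frame(
                record_id = names(records)[ri], start = at - 1L,
                strand = "+", mismatches = NA_integer_,
                palindromic_pairs = pairs[at],
                assigned_gene = NA_character_,
                motif_name = spec$name, stringsAsFactors = FALSE)
    }
    out <- if (length(hits)) do.call(rbind, hits) else .emptyMotifHits()
    rownames(out) <- NULL
    out
}

#' Assign motif hits to downstream genes
#'
#' Hits located on contigs are assigned to the nearest downstream gene
#' start on the matching strand within \code{windowBp} of the motif;
#' for a + strand gene the motif must lie upstream of (before) the gene
#' start, for a - strand gene beyond the gene end.  Hits with no
#' qualifying gene get \code{assigned_gene = NA}.  Hits on per-gene
#' upstream records (record id = gene id) are assigned to that gene when
#' the motif lies within \code{windowBp} of the gene-proximal end of the
#' record.
#'
#' @param hits data.frame from a scan function.
#' @param genome a [GenomeTable-class].
#' @param windowBp assignment window in bp (default 300).
#' @param upstreamRecords logical: are the scanned records per-gene
#'   upstream windows rather than contigs (default FALSE)?
#' @param upstreamBp width of the upstream records (needed when
#'   \code{upstreamRecords = TRUE}; default 300).
#' @return the hits data.frame with \code{assigned_gene} filled.
#' @export
assignHitsToGenes <- function(hits, genome, windowBp = 300L,
                              upstreamRecords = FALSE, upstreamBp = 300L) {
    gr <- geneRecords(genome)
    md <- mcols(gr)
    if (!nrow(hits)) return(hits)
    if (upstreamRecords) {
        known <- hits$record_id %in% md$gene_id
        if (any(!known))
            mtStop("unknown_reference_error",
                   paste("hits on unknown upstream records:",
                         paste(unique(hits$record_id[!known]),
                               collapse = ", ")))
        # distance from motif start to the gene-proximal (right) end
        dist <- upstreamBp - hits$start
        hits$assigned_gene <- ifelse(dist <= windowBp, hits$record_id,
                                     NA_character_)
        return(hits)
    }
    contigs <- as.character(seqnames(gr))
    known <- hits$record_id %in% contigs
    if (any(!known))
        mtStop("unknown_reference_error",
               paste("hits on unknown contigs:",
                     paste(unique(hits$record_id[!known]), collapse = ", ")))
    g_start0 <- start(gr) - 1L      # 0-based gene starts
    g_end0 <- end(gr)               # 0-based half-open ends
    g_strand <- as.character(strand(gr))
    assigned <- rep(NA_character_, nrow(hits))
    for (i in seq_len(nrow(hits))) {
        on_contig <- contigs == hits$record_id[i] &
            g_strand == hits$strand[i]
        if (!any(on_contig)) next
        idx <- which(on_contig)
        if (hits$strand[i] == "+") {
            d <- g_start0[idx] - hits$start[i]
        } else {
            d <- hits$start[i] - g_end0[idx]
        }
        ok <- d >= 0 & d <= windowBp
        if (any(ok)) {
            j <- idx[ok][which.min(d[ok])]
            assigned[i] <- md$gene_id[j]
        }
    }
    hits$assigned_gene <- assigned
    hits
}
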